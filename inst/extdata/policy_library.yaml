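# The 18 fixture policy scenarios, one entry per policy.  Entries with a
# `steps` list are applied sequentially in the order given.
policies:
  - name: "General price +10%"
    kind: general_price_change
    percent: 10
  - name: "General price +25%"
    kind: general_price_change
    percent: 25
  - name: "Low priced off trade products +25%"
    kind: low_priced_change
    percent: 25
    cutoff: 40
    scope: off_trade
  - name: "Low priced on trade products +25%"
    kind: low_priced_change
    percent: 25
    cutoff: 100
    scope: on_trade
  - name: "All low priced products +10%"
    steps:
      - {kind: low_priced_change, percent: 10, cutoff: 40, scope: off_trade}
      - {kind: low_priced_change, percent: 10, cutoff: 100, scope: on_trade}
  - name: "Minimum price 15p"
    kind: minimum_unit_price
    floor: 15
  - name: "Minimum price 25p"
    kind: minimum_unit_price
    floor: 25
  - name: "Minimum price 50p"
    kind: minimum_unit_price
    floor: 50
  - name: "Minimum price 70p"
    kind: minimum_unit_price
    floor: 70
  - name: "Minimum price 40p off / 100p on"
    steps:
      - {kind: minimum_unit_price, floor: 40, scope: off_trade}
      - {kind: minimum_unit_price, floor: 100, scope: on_trade}
  - name: "30p minimum price beers only"
    kind: minimum_unit_price
    floor: 30
    beverages: [beer]
  - name: "Ban off trade discounting >50%"
    kind: discount_restriction
    max_discount: 0.5
    scope: off_trade
  - name: "Ban off trade discounting >20%"
    kind: discount_restriction
    max_discount: 0.2
    scope: off_trade
  - name: "Total ban off trade discounting"
    kind: discount_restriction
    max_discount: 0
    scope: off_trade
  - name: "Ban off trade discount if usual <30p"
    kind: discount_restriction
    max_discount: 0
    cutoff: 30
    scope: off_trade
  - name: "Total advertising ban"
    kind: relative_consumption_change
    percent: -26.9
  - name: "10% reduction in outlet density"
    kind: relative_consumption_change
    percent: 13.2
  - name: "10% reduction in licensing hours"
    kind: relative_consumption_change
    percent: -1.2
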