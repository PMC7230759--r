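# Slovenian Protective Food symbol. Traffic-light "no red" screening for
# most categories, with overrides: dairy products must have < 3 g total
# fat and < 1.5 g saturated fat per 100 g (strict comparisons); cooking
# oils must be eligible to carry an authorised nutrition/health claim,
# operationalised here as a high-unsaturated-fat claim predicate.
model: protective_food
version: "1992"
dairy_categories: [cheese, yoghurt_plain, yoghurt_flavoured, yoghurt_drink_flavoured]
dairy_rules:
  total_fat_max: 3.0     # strict <
  sat_fat_max: 1.5       # strict <
oil_claim:
  # unsaturated fat >= 70% of total fat AND unsaturated fat supplies
  # > 20% of energy, at 37 kJ per g of fat
  min_unsat_share: 0.70
  min_energy_share: 0.20
  kj_per_g_fat: 37
traffic_light_config: traffic-light-fsa-2007
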