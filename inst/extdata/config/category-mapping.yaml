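# Mapping from the seven leaf food categories to each model's internal
# category. "default" catches any leaf not listed explicitly.
# FSANZ cheese resolution is conditional on calcium content (>= limit ->
# category 3); when calcium is unrecorded the product falls back to
# npsc_2 with a warning.
version: "1"
models:
  nutriscore:
    cooking_oil: added_fats
    cheese: cheese
    default: general_food
  ofcom:
    yoghurt_drink_flavoured: drink
    default: food
  hsr:
    cooking_oil: oils
    cheese: dairy_cheese
    yoghurt_plain: dairy_food
    yoghurt_flavoured: dairy_food
    yoghurt_drink_flavoured: dairy_food
    default: food
  fsanz:
    cooking_oil: npsc_3
    cheese: conditional_calcium   # npsc_3 if calcium_mg >= limit else npsc_2
    yoghurt_drink_flavoured: npsc_1
    default: npsc_2
fsanz_calcium_limit_mg: 320
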