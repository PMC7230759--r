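# Nordic Keyhole symbol (2015 regulation), restricted to the seven leaf
# categories in scope. Limits are per 100 g; rules within a category block
# combine conjunctively. Sweeteners are not permitted in any Keyhole
# category. Derived quantities: sat_fat_ratio_pct = 100 * sat fat / total
# fat. Wholegrain is % of cereal dry matter.
model: keyhole
version: "2015"
forbid_sweetener_all: true
categories:
  breakfast_cereals:
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 8, units: g/100g}
      - {nutrient: total_sugars_g, comparator: le, limit: 13, units: g/100g}
      - {nutrient: fibre_g, comparator: ge, limit: 6, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 1.0, units: g/100g}
  pasta:
    rules:
      - {nutrient: wholegrain_pct, comparator: ge, limit: 50, units: "% dry matter"}
      - {nutrient: fibre_g, comparator: ge, limit: 6, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 0.1, units: g/100g}
  cheese:
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 17, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 1.5, units: g/100g}
  yoghurt_plain:
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 1.5, units: g/100g}
      - {nutrient: added_sugars_g, comparator: le, limit: 0, units: g/100g}
  yoghurt_flavoured:
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 1.5, units: g/100g}
      - {nutrient: added_sugars_g, comparator: le, limit: 4, units: g/100g}
  yoghurt_drink_flavoured:
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 0.7, units: g/100g}
      - {nutrient: added_sugars_g, comparator: le, limit: 4, units: g/100g}
  cooking_oil:
    rules:
      - {nutrient: sat_fat_ratio_pct, comparator: le, limit: 20, units: "% of fat"}
      - {nutrient: salt_g, comparator: le, limit: 1.0, units: g/100g}
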