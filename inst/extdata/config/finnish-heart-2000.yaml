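# Finnish Heart Symbol ("better choice"), restricted to the seven leaf
# categories in scope (the full scheme distinguishes ~58 categories).
model: finnish_heart
version: "2000"
categories:
  breakfast_cereals:
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 5, units: g/100g}
      - {nutrient: total_sugars_g, comparator: le, limit: 16, units: g/100g}
      - {nutrient: fibre_g, comparator: ge, limit: 6, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 1.0, units: g/100g}
  pasta:
    rules:
      - {nutrient: fibre_g, comparator: ge, limit: 6, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 0.7, units: g/100g}
  cheese:
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 17, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 1.2, units: g/100g}
  yoghurt_plain:
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 2, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 0.7, units: g/100g}
  yoghurt_flavoured:
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 2, units: g/100g}
      - {nutrient: total_sugars_g, comparator: le, limit: 12, units: g/100g}
      - {nutrient: added_sugars_g, comparator: le, limit: 10, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 0.7, units: g/100g}
  yoghurt_drink_flavoured:
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 1, units: g/100g}
      - {nutrient: total_sugars_g, comparator: le, limit: 8, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 0.7, units: g/100g}
  cooking_oil:
    rules:
      - {nutrient: sat_fat_ratio_pct, comparator: le, limit: 20, units: "% of fat"}
      - {nutrient: trans_fat_g, comparator: le, limit: 1, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 1.0, units: g/100g}
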