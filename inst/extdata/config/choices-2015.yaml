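# Dutch Choices Programme symbol (international criteria, 2015
# generation), restricted to the seven leaf categories in scope.
model: choices
version: "2015"
categories:
  breakfast_cereals:
    rules:
      - {nutrient: sat_fat_g, comparator: le, limit: 3, units: g/100g}
      - {nutrient: total_sugars_g, comparator: le, limit: 20, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 1.0, units: g/100g}
      - {nutrient: fibre_g, comparator: ge, limit: 4, units: g/100g}
      - {nutrient: trans_fat_g, comparator: le, limit: 0.1, units: g/100g}
  pasta:
    rules:
      - {nutrient: sat_fat_g, comparator: le, limit: 1.1, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 0.25, units: g/100g}
      - {nutrient: trans_fat_g, comparator: le, limit: 0.1, units: g/100g}
  cheese:
    rules:
      - {nutrient: sat_fat_g, comparator: le, limit: 15, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 2.3, units: g/100g}
  yoghurt_plain:
    rules:
      - {nutrient: sat_fat_g, comparator: le, limit: 1.4, units: g/100g}
      - {nutrient: added_sugars_g, comparator: le, limit: 5, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 0.25, units: g/100g}
  yoghurt_flavoured:
    rules:
      - {nutrient: sat_fat_g, comparator: le, limit: 1.4, units: g/100g}
      - {nutrient: total_sugars_g, comparator: le, limit: 12, units: g/100g}
      - {nutrient: added_sugars_g, comparator: le, limit: 5, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 0.25, units: g/100g}
  yoghurt_drink_flavoured:
    rules:
      - {nutrient: sat_fat_g, comparator: le, limit: 1.4, units: g/100g}
      - {nutrient: total_sugars_g, comparator: le, limit: 12, units: g/100g}
      - {nutrient: added_sugars_g, comparator: le, limit: 5, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 0.25, units: g/100g}
  cooking_oil:
    rules:
      - {nutrient: sat_fat_ratio_pct, comparator: le, limit: 30, units: "% of fat"}
      - {nutrient: trans_fat_g, comparator: le, limit: 1, units: g/100g}
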