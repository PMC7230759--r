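# WHO Regional Office for Europe nutrient profile model (2015),
# per-category limits for foods that may be marketed to children,
# restricted to the seven leaf categories in scope. The energy rule
# applies to pasta only; sweetener bans apply to cereals and yoghurts.
model: whoe
version: "2015"
categories:
  breakfast_cereals:
    forbid_sweetener: true
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 10, units: g/100g}
      - {nutrient: total_sugars_g, comparator: le, limit: 15, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 1.6, units: g/100g}
  pasta:
    rules:
      - {nutrient: energy_kj, comparator: le, limit: 1700, units: kJ/100g}
      - {nutrient: total_fat_g, comparator: le, limit: 10, units: g/100g}
      - {nutrient: sat_fat_g, comparator: le, limit: 4, units: g/100g}
      - {nutrient: total_sugars_g, comparator: le, limit: 10, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 1.2, units: g/100g}
  cheese:
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 20, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 1.3, units: g/100g}
  yoghurt_plain:
    forbid_sweetener: true
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 2.5, units: g/100g}
      - {nutrient: total_sugars_g, comparator: le, limit: 10, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 0.2, units: g/100g}
  yoghurt_flavoured:
    forbid_sweetener: true
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 2.5, units: g/100g}
      - {nutrient: total_sugars_g, comparator: le, limit: 10, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 0.2, units: g/100g}
  yoghurt_drink_flavoured:
    forbid_sweetener: true
    rules:
      - {nutrient: total_fat_g, comparator: le, limit: 2.5, units: g/100g}
      - {nutrient: total_sugars_g, comparator: le, limit: 10, units: g/100g}
      - {nutrient: salt_g, comparator: le, limit: 0.2, units: g/100g}
  cooking_oil:
    rules:
      - {nutrient: sat_fat_g, comparator: le, limit: 20, units: g/100g}
      - {nutrient: trans_fat_g, comparator: le, limit: 1, units: g/100g}
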