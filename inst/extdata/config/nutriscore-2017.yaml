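# Nutri-Score, 2017 foods algorithm (Sante publique France).
# Negative (N) points from energy, saturated fat (ratio of total fat for
# added fats), total sugars and sodium; positive (P) points from
# fruit/vegetable/nut content, fibre (AOAC) and protein.
model: nutriscore
version: "2017"
categories: [general_food, cheese, added_fats]
negative:
  energy:
    field: energy_kj
    comparator: gt
    thresholds: [335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350]
  sat_fat:
    field: sat_fat_g
    comparator: gt
    thresholds: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
  # added fats only: 100 * saturated / total fat
  sat_fat_ratio:
    field: sat_fat_ratio_pct
    comparator: ge
    thresholds: [10, 16, 22, 28, 34, 40, 46, 52, 58, 64]
  sugars:
    field: total_sugars_g
    comparator: gt
    thresholds: [4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45]
  sodium:
    field: sodium_mg
    comparator: gt
    thresholds: [90, 180, 270, 360, 450, 540, 630, 720, 810, 900]
positive:
  fvn:
    field: fvn_pct
    comparator: gt
    thresholds: [40, 60, 80]
    points: [1, 2, 5]
  fibre:
    field: fibre_g
    comparator: gt
    thresholds: [0.9, 1.9, 2.8, 3.7, 4.7]
  protein:
    field: protein_g
    comparator: gt
    thresholds: [1.6, 3.2, 4.8, 6.4, 8.0]
protein_rule:
  negative_min: 11
  fvn_full_points: 5
  exempt_categories: [cheese]
grades:
  labels: [A, B, C, D, E]
  upper: [-1, 2, 10, 18, .inf]
healthier_grades: [A, B]
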