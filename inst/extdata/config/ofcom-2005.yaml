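# Ofcom (UK FSA 2004/2005) nutrient profile model used to gate advertising
# of foods to children. A-points (energy, saturated fat, total sugars,
# sodium; max 10 each) minus C-points (fruit/veg/nuts max 5, fibre max 5,
# protein max 5). Fibre thresholds here are the AOAC variant (EU labels
# declare AOAC fibre); the NSP ladder is kept alongside for reference.
model: ofcom
version: "2004/2005"
categories: [food, drink]
negative:
  energy:
    field: energy_kj
    comparator: gt
    thresholds: [335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350]
  sat_fat:
    field: sat_fat_g
    comparator: gt
    thresholds: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
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
  # NSP variant (unused by default): [0.7, 1.4, 2.1, 2.8, 3.5]
  protein:
    field: protein_g
    comparator: gt
    thresholds: [1.6, 3.2, 4.8, 6.4, 8.0]
protein_rule:
  negative_min: 11
  fvn_full_points: 5
  exempt_categories: []
# "less healthy" at score >= cutoff; permitted (healthier) iff score < cutoff
cutoffs:
  food: 4
  drink: 1
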