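# FSANZ Nutrient Profiling Scoring Criterion (NPSC), gating health-claim
# use in Australia/New Zealand. Baseline points (energy, saturated fat,
# total sugars, sodium) minus modifying points (FVNL, protein, fibre).
# Category 1 = beverages, 2 = general foods, 3 = oils/spreads and cheese
# with >= 320 mg calcium per 100 g. Category 3 uses the extended saturated
# fat ladder (up to 30 points).
model: fsanz
version: "NPSC-2016"
categories: [npsc_1, npsc_2, npsc_3]
negative:
  energy:
    field: energy_kj
    comparator: gt
    thresholds: [335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350]
  sat_fat:
    field: sat_fat_g
    comparator: gt
    thresholds: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
  sat_fat_extended:
    field: sat_fat_g
    comparator: gt
    thresholds: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
                 11.2, 12.5, 13.9, 15.5, 17.3, 19.3, 21.6, 24.1, 26.9, 30.0,
                 33.5, 37.4, 41.7, 46.6, 52.0, 58.0, 64.7, 72.3, 80.6, 90.0]
  sugars:
    field: total_sugars_g
    comparator: gt
    thresholds: [4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45]
  sodium:
    field: sodium_mg
    comparator: gt
    thresholds: [90, 180, 270, 360, 450, 540, 630, 720, 810, 900]
extended_sat_fat_categories: [npsc_3]
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
  negative_min: 13
  fvn_full_points: 5
  exempt_categories: []
# eligible to carry claims iff score < cutoff
cutoffs:
  npsc_1: 1
  npsc_2: 4
  npsc_3: 28
calcium_limit_mg: 320
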