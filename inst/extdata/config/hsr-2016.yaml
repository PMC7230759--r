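# Health Star Rating (Australia/New Zealand, 2016 calculator). Baseline
# points (energy, saturated fat, total sugars, sodium) minus modifying
# points (FVNL, protein, fibre), mapped to 0.5-5.0 stars through
# category-specific score->star breakpoint tables. Categories used here:
# food (HSR category 2), dairy_food (2D), oils (3), dairy_cheese (3D).
# The score->star breakpoints are a transcription of the published
# calculator maps for these four categories.
model: hsr
version: "2016"
categories: [food, dairy_food, oils, dairy_cheese]
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
    thresholds: [5.0, 8.9, 12.8, 16.8, 20.7, 24.6, 28.5, 32.4, 36.3, 40.2]
  sodium:
    field: sodium_mg
    comparator: gt
    thresholds: [90, 180, 270, 360, 450, 540, 630, 720, 810, 900]
extended_sat_fat_categories: [oils, dairy_cheese]
positive:
  fvn:
    field: fvn_pct
    comparator: gt
    thresholds: [25, 43, 52, 63, 67, 80, 90, 99]
    points: [1, 2, 3, 4, 5, 6, 7, 8]
  fibre:
    field: fibre_g
    comparator: gt
    thresholds: [0.9, 1.9, 2.8, 3.7, 4.7, 5.4, 6.3, 7.3, 8.4, 9.7,
                 11.2, 13.0, 15.0, 17.3, 20.0]
  protein:
    field: protein_g
    comparator: gt
    thresholds: [1.6, 3.2, 4.8, 6.4, 8.0, 9.6, 11.6, 13.9, 16.7, 20.0,
                 24.0, 28.9, 34.7, 41.6, 50.0]
protein_rule:
  negative_min: 13
  fvn_full_points: 5
  exempt_categories: []
# stars awarded for final score <= upper bound (first band that fits);
# scores above the last bound receive 0.5 stars
star_map:
  food:
    stars: [5.0, 4.5, 4.0, 3.5, 3.0, 2.5, 2.0, 1.5, 1.0]
    upper: [-11, -7, -2, 2, 6, 10, 15, 20, 25]
  dairy_food:
    stars: [5.0, 4.5, 4.0, 3.5, 3.0, 2.5, 2.0, 1.5, 1.0]
    upper: [-2, 0, 2, 4, 6, 8, 11, 14, 17]
  oils:
    stars: [5.0, 4.5, 4.0, 3.5, 3.0, 2.5, 2.0, 1.5, 1.0]
    upper: [13, 16, 20, 23, 27, 30, 34, 37, 41]
  dairy_cheese:
    stars: [5.0, 4.5, 4.0, 3.5, 3.0, 2.5, 2.0, 1.5, 1.0]
    upper: [4, 8, 12, 16, 20, 24, 28, 32, 36]
healthier_min_stars: 3.5
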