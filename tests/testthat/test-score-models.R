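zero_panel <- nutrient_panel(energy_kj = 0, total_fat_g = 0, sat_fat_g = 0,
                             total_sugars_g = 0, salt_g = 0, protein_g = 0)

test_that("Nutri-Score worked examples reproduce the 2017 tables", {
  s0 <- score_nutriscore(zero_panel, "general_food", CONFIGS$nutriscore)
  expect_equal(s0$final_score, 0)
  expect_equal(s0$grade, "B")
  expect_true(s0$healthier)

  yog <- nutrient_panel(energy_kj = 260, total_fat_g = 3.5, sat_fat_g = 2.4,
                        total_sugars_g = 4.7, salt_g = 0.1, protein_g = 4)
  s <- score_nutriscore(yog, "general_food", CONFIGS$nutriscore)
  expect_equal(s$points$energy, 0)
  expect_equal(s$points$sat_fat, 2)
  expect_equal(s$points$sugars, 1)
  expect_equal(s$points$sodium, 0)
  expect_equal(s$negative_total, 3)
  expect_equal(s$positive_total, 2)
  expect_equal(s$final_score, 1)
  expect_equal(s$grade, "B")

  oil <- nutrient_panel(energy_kj = 3700, total_fat_g = 100, sat_fat_g = 14,
                        total_sugars_g = 0, salt_g = 0, protein_g = 0)
  s <- score_nutriscore(oil, "added_fats", CONFIGS$nutriscore)
  expect_equal(s$points$energy, 10)
  expect_equal(s$points$sat_fat, 1)   # 14% saturated share
  expect_equal(s$negative_total, 11)
  expect_true(s$protein_suppressed)
  expect_equal(s$final_score, 11)
  expect_equal(s$grade, "D")
  expect_false(s$healthier)
})

test_that("Nutri-Score class boundaries behave per the shipped bands", {
  # scores -1/0/2/3 via sugar steps; sugars 4.6 -> 1 N point etc.
  panel_with_score <- function(target_sugar_pts, protein_g = 0) {
    nutrient_panel(energy_kj = 0, total_fat_g = 0, sat_fat_g = 0,
                   total_sugars_g = c(0, 5, 10, 14, 19)[target_sugar_pts + 1],
                   salt_g = 0, protein_g = protein_g)
  }
  grades <- vapply(0:4, function(k) {
    score_nutriscore(panel_with_score(k), "general_food", CONFIGS$nutriscore)$grade
  }, character(1))
  expect_equal(grades, c("B", "B", "B", "C", "C"))  # scores 0,1,2,3,4
  s <- score_nutriscore(panel_with_score(0, protein_g = 2), "general_food",
                        CONFIGS$nutriscore)
  expect_equal(s$final_score, -1)
  expect_equal(s$grade, "A")
})

test_that("protein suppression engages iff preconditions hold, never for cheese", {
  # N = 11 (energy 10 + sugars 1), fvn 0, protein 10
  hot <- nutrient_panel(energy_kj = 3700, total_fat_g = 0, sat_fat_g = 0,
                        total_sugars_g = 5, salt_g = 0, protein_g = 10)
  gen <- score_nutriscore(hot, "general_food", CONFIGS$nutriscore)
  expect_true(gen$protein_suppressed)
  expect_equal(gen$positive_total, 0)

  che <- score_nutriscore(hot, "cheese", CONFIGS$nutriscore)
  expect_false(che$protein_suppressed)
  expect_equal(che$positive_total, 5)
  expect_equal(che$final_score, gen$final_score - 5)

  # below the N threshold the rule stays off
  mild <- nutrient_panel(energy_kj = 3300, total_fat_g = 0, sat_fat_g = 0,
                         total_sugars_g = 0, salt_g = 0, protein_g = 10)
  expect_false(score_nutriscore(mild, "general_food",
                                CONFIGS$nutriscore)$protein_suppressed)

  # full FVN points release protein despite high N
  fv <- nutrient_panel(energy_kj = 3700, total_fat_g = 0, sat_fat_g = 0,
                       total_sugars_g = 5, salt_g = 0, protein_g = 10,
                       fvn_pct = 90)
  expect_false(score_nutriscore(fv, "general_food",
                                CONFIGS$nutriscore)$protein_suppressed)
})

test_that("zero-fat added fat scores 0 ratio points with a warning", {
  p <- nutrient_panel(energy_kj = 100, total_fat_g = 0, sat_fat_g = 0,
                      total_sugars_g = 0, salt_g = 0, protein_g = 0)
  expect_warning(s <- score_nutriscore(p, "added_fats", CONFIGS$nutriscore),
                 "zero total fat")
  expect_equal(s$points$sat_fat, 0)
})

test_that("Ofcom examples and the drink cut-off boundary", {
  s0 <- score_ofcom(zero_panel, "food", CONFIGS$ofcom)
  expect_equal(s0$final_score, 0)
  expect_true(s0$healthier)

  oil <- nutrient_panel(energy_kj = 3700, total_fat_g = 100, sat_fat_g = 14,
                        total_sugars_g = 0, salt_g = 0, protein_g = 0)
  s <- score_ofcom(oil, "food", CONFIGS$ofcom)
  expect_gte(s$negative_total, 20)
  expect_equal(s$positive_total, 0)
  expect_false(s$healthier)

  expect_true(score_ofcom(zero_panel, "drink", CONFIGS$ofcom)$healthier)
  one <- nutrient_panel(energy_kj = 340, total_fat_g = 0, sat_fat_g = 0,
                        total_sugars_g = 0, salt_g = 0, protein_g = 0)
  s1 <- score_ofcom(one, "drink", CONFIGS$ofcom)
  expect_equal(s1$final_score, 1)
  expect_false(s1$healthier)
  expect_true(score_ofcom(one, "food", CONFIGS$ofcom)$healthier)  # 1 < 4
})

test_that("FSANZ cut-offs are strict and npsc_3 uses the extended ladder", {
  expect_true(score_fsanz(zero_panel, "npsc_2", CONFIGS$fsanz)$healthier)

  # score exactly 4 (energy 1350 -> 4 pts) is not eligible in npsc_2
  four <- nutrient_panel(energy_kj = 1350, total_fat_g = 0, sat_fat_g = 0,
                         total_sugars_g = 0, salt_g = 0, protein_g = 0)
  s4 <- score_fsanz(four, "npsc_2", CONFIGS$fsanz)
  expect_equal(s4$final_score, 4)
  expect_false(s4$healthier)
  three <- nutrient_panel(energy_kj = 1010, total_fat_g = 0, sat_fat_g = 0,
                          total_sugars_g = 0, salt_g = 0, protein_g = 0)
  expect_true(score_fsanz(three, "npsc_2", CONFIGS$fsanz)$healthier)

  # reference olive-oil fixture, hand-scored against the shipped npsc_3
  # tables: energy 10, sat fat 13 (extended ladder), no modifying points
  oil <- nutrient_panel(energy_kj = 3700, total_fat_g = 100, sat_fat_g = 14,
                        total_sugars_g = 0, salt_g = 0, protein_g = 0)
  s <- score_fsanz(oil, "npsc_3", CONFIGS$fsanz)
  expect_equal(s$points$energy, 10)
  expect_equal(s$points$sat_fat, 13)
  expect_equal(s$final_score, 23)
  expect_true(s$healthier)   # 23 < 28
  # same oil under the standard ladder would cap sat fat at 10
  expect_equal(score_fsanz(oil, "npsc_2", CONFIGS$fsanz)$points$sat_fat, 10)
})

test_that("HSR stars map from score with the 3.5-star harmonisation", {
  s0 <- score_hsr(zero_panel, "food", CONFIGS$hsr)
  expect_equal(s0$final_score, 0)

  # reference breakfast-cereal fixture, hand-scored against the shipped
  # tables: baseline 4+0+6+2 = 12, modifying fibre 6 + protein 4
  cereal <- nutrient_panel(energy_kj = 1600, total_fat_g = 2.5, sat_fat_g = 0.5,
                           total_sugars_g = 25, salt_g = 0.5, fibre_g = 6,
                           protein_g = 8)
  s <- score_hsr(cereal, "food", CONFIGS$hsr)
  expect_equal(s$negative_total, 12)
  expect_false(s$protein_suppressed)
  expect_equal(s$positive_total, 10)
  expect_equal(s$final_score, 2)
  expect_equal(s$stars, 3.5)
  expect_true(s$healthier)

  # one score point past the 3.5-star band drops to 3.0 stars: not healthier
  p3 <- nutrient_panel(energy_kj = 340, total_fat_g = 1.2, sat_fat_g = 1.1,
                       total_sugars_g = 5.1, salt_g = 0, protein_g = 0)
  s3 <- score_hsr(p3, "food", CONFIGS$hsr)
  expect_equal(s3$final_score, 3)
  expect_equal(s3$stars, 3.0)
  expect_false(s3$healthier)

  # extended saturated-fat ladder for oils
  oil <- nutrient_panel(energy_kj = 3700, total_fat_g = 100, sat_fat_g = 14,
                        total_sugars_g = 0, salt_g = 0, protein_g = 0)
  so <- score_hsr(oil, "oils", CONFIGS$hsr)
  expect_equal(so$points$sat_fat, 13)
  expect_equal(so$final_score, 23)
  expect_equal(so$stars, 3.5)
})

test_that("component points match the independent ladder oracle", {
  set.seed(421)
  for (i in 1:150) expect_true(points_match_oracle(random_panel()))
})

test_that("score models are monotone in harmful and beneficial nutrients", {
  set.seed(422)
  for (i in 1:60) {
    panel <- random_panel()
    category <- sample(leaf_categories(), 1)
    expect_equal(monotone_violations(panel, category,
                                     c("nutriscore", "hsr", "ofcom", "fsanz")),
                 character(0))
  }
})
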