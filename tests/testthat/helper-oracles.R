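# Shared fixtures and independent oracles. The oracles deliberately use
# a different algebraic/algorithmic route than the implementation.

# configs loaded once per test run
CONFIGS <- lapply(stats::setNames(fop_models(), fop_models()), load_model_config)
MAPPING <- load_category_mapping()

# independent threshold-ladder oracle: reverse linear scan instead of
# the implementation's sum-of-exceedances
oracle_points <- function(value, comp) {
  thr <- as.numeric(comp$thresholds)
  pts <- if (is.null(comp$points)) seq_along(thr) else as.numeric(comp$points)
  for (k in rev(seq_along(thr))) {
    ok <- if (identical(comp$comparator, "ge")) value >= thr[[k]] else value > thr[[k]]
    if (ok) return(pts[[k]])
  }
  0
}

# independent Cohen's kappa: 2x2 cell-count closed form
oracle_kappa <- function(x, y) {
  a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y); d <- sum(!x & !y)
  denom <- (a + b) * (b + d) + (a + c) * (c + d)
  if (denom == 0) return(0)
  2 * (a * d - b * c) / denom
}

# random valid panel drawn uniformly over wide label-realistic ranges
random_panel <- function() {
  total_fat <- runif(1, 0, 100)
  sat <- runif(1, 0, total_fat)
  trans <- runif(1, 0, min(2, total_fat - sat))
  sugars <- runif(1, 0, 80)
  nutrient_panel(
    energy_kj = runif(1, 0, 4000),
    total_fat_g = total_fat, sat_fat_g = sat, trans_fat_g = trans,
    total_sugars_g = sugars, added_sugars_g = runif(1, 0, sugars),
    salt_g = runif(1, 0, 4), fibre_g = runif(1, 0, 15),
    protein_g = runif(1, 0, 30), fvn_pct = runif(1, 0, 100),
    wholegrain_pct = runif(1, 0, 100),
    calcium_mg = if (runif(1) < 0.8) runif(1, 0, 1200) else NA_real_,
    sweetener = runif(1) < 0.1)
}

# product row (plain list; same fields as a supply-table row)
make_product <- function(panel, category, id = "P1", name = "product",
                         sales = NA_real_) {
  c(list(id = id, name = name, category = category),
    unclass(panel)[setdiff(names(unclass(panel)), "sodium_mg")],
    list(sales_units = sales))
}

product_healthier <- function(panel, category, model) {
  suppressWarnings(
    classify_product(make_product(panel, category), model, CONFIGS, MAPPING)$healthier)
}

# harm/benefit perturbations used by the monotonicity property;
# saturated fat stays capped at total fat to keep the panel valid
perturb_panel <- function(panel, what) {
  p <- unclass(panel)
  switch(what,
    energy = p$energy_kj <- p$energy_kj + 500,
    sat_fat = p$sat_fat_g <- min(p$sat_fat_g + 2, p$total_fat_g),
    sugars = p$total_sugars_g <- p$total_sugars_g + 5,
    salt = p$salt_g <- p$salt_g + 0.5,
    fibre = p$fibre_g <- p$fibre_g + 2,
    fvn = p$fvn_pct <- min(p$fvn_pct + 20, 100),
    wholegrain = p$wholegrain_pct <- min(p$wholegrain_pct + 20, 100))
  do.call(nutrient_panel, p[setdiff(names(p), "sodium_mg")])
}

# one full monotone-harm check; returns character() when clean
monotone_violations <- function(panel, category, models = fop_models()) {
  out <- character()
  for (m in models) {
    base <- product_healthier(panel, category, m)
    for (w in c("energy", "sat_fat", "sugars", "salt")) {
      worse <- product_healthier(perturb_panel(panel, w), category, m)
      if (worse && !base) out <- c(out, sprintf("%s: +%s flipped to healthier", m, w))
    }
    for (w in c("fibre", "fvn", "wholegrain")) {
      better <- product_healthier(perturb_panel(panel, w), category, m)
      if (!better && base) out <- c(out, sprintf("%s: +%s flipped to unhealthier", m, w))
    }
  }
  out
}

# score-model component points vs the independent ladder oracle;
# returns TRUE when every component matches
points_match_oracle <- function(panel) {
  ok <- TRUE
  # nutriscore over its three categories
  for (cat in c("general_food", "cheese", "added_fats")) {
    s <- suppressWarnings(score_nutriscore(panel, cat, CONFIGS$nutriscore))
    neg <- CONFIGS$nutriscore$negative
    exp_sat <- if (cat == "added_fats") {
      if (panel$total_fat_g <= 0) 0 else
        oracle_points(100 * panel$sat_fat_g / panel$total_fat_g, neg$sat_fat_ratio)
    } else oracle_points(panel$sat_fat_g, neg$sat_fat)
    ok <- ok &&
      s$points$energy == oracle_points(panel$energy_kj, neg$energy) &&
      s$points$sat_fat == exp_sat &&
      s$points$sugars == oracle_points(panel$total_sugars_g, neg$sugars) &&
      s$points$sodium == oracle_points(panel$sodium_mg, neg$sodium) &&
      s$points$fvn == oracle_points(panel$fvn_pct, CONFIGS$nutriscore$positive$fvn) &&
      s$points$fibre == oracle_points(panel$fibre_g, CONFIGS$nutriscore$positive$fibre) &&
      s$points$protein == oracle_points(panel$protein_g, CONFIGS$nutriscore$positive$protein)
  }
  # ofcom
  s <- score_ofcom(panel, "food", CONFIGS$ofcom)
  neg <- CONFIGS$ofcom$negative
  ok <- ok &&
    s$points$energy == oracle_points(panel$energy_kj, neg$energy) &&
    s$points$sat_fat == oracle_points(panel$sat_fat_g, neg$sat_fat) &&
    s$points$sugars == oracle_points(panel$total_sugars_g, neg$sugars) &&
    s$points$sodium == oracle_points(panel$sodium_mg, neg$sodium)
  # fsanz standard and extended ladders
  for (cat in c("npsc_2", "npsc_3")) {
    s <- score_fsanz(panel, cat, CONFIGS$fsanz)
    neg <- CONFIGS$fsanz$negative
    sat_comp <- if (cat == "npsc_3") neg$sat_fat_extended else neg$sat_fat
    ok <- ok &&
      s$points$sat_fat == oracle_points(panel$sat_fat_g, sat_comp) &&
      s$points$energy == oracle_points(panel$energy_kj, neg$energy)
  }
  # hsr standard and extended ladders, extended fibre/protein
  for (cat in c("food", "dairy_cheese")) {
    s <- score_hsr(panel, cat, CONFIGS$hsr)
    neg <- CONFIGS$hsr$negative
    sat_comp <- if (cat == "dairy_cheese") neg$sat_fat_extended else neg$sat_fat
    ok <- ok &&
      s$points$sat_fat == oracle_points(panel$sat_fat_g, sat_comp) &&
      s$points$sugars == oracle_points(panel$total_sugars_g, neg$sugars) &&
      s$points$fibre == oracle_points(panel$fibre_g, CONFIGS$hsr$positive$fibre) &&
      s$points$protein == oracle_points(panel$protein_g, CONFIGS$hsr$positive$protein) &&
      s$points$fvn == oracle_points(panel$fvn_pct, CONFIGS$hsr$positive$fvn)
  }
  ok
}

# seeded 50-oil set matching the oils branch of the shipped supply spec
acceptance_oils <- function(seed) {
  spec <- default_supply_spec(seed = seed, n = c(cooking_oil = 50), only = TRUE)
  suppressMessages(suppressWarnings(generate_supply(spec)))
}
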