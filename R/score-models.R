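#' Nutri-Score (2017 foods algorithm)
#'
#' Negative points from energy, saturated fat (for added fats, the
#' percentage of fat that is saturated), total sugars and sodium;
#' positive points from fruit/vegetable/nut content, fibre and protein.
#' When negative points reach 11 and the FVN points are below 5, protein
#' is excluded — except in the cheese category, where protein always
#' counts. The final score (N minus P) maps to letters A-E; the
#' harmonised "healthier" verdict is a grade of A or B.
#'
#' @param panel A [nutrient_panel()].
#' @param category Internal category: `general_food`, `cheese` or
#'   `added_fats` (see [resolve_category()]).
#' @param tables Point tables from [load_model_config()].
#' @return A `fop_score` breakdown (components, totals, grade,
#'   `healthier` flag).
#' @export
#' @examples
#' p <- nutrient_panel(energy_kj = 260, total_fat_g = 3.5, sat_fat_g = 2.4,
#'                     total_sugars_g = 4.7, salt_g = 0.1, protein_g = 4)
#' score_nutriscore(p, "general_food")
score_nutriscore <- function(panel, category,
                             tables = load_model_config("nutriscore")) {
  if (!category %in% tables$categories) {
    stop_config(sprintf("unknown Nutri-Score category '%s'", category))
  }
  neg <- tables$negative
  p_energy <- component_points(panel$energy_kj, neg$energy)
  if (identical(category, "added_fats")) {
    if (panel$total_fat_g <= 0) {
      fop_warn("added fat with zero total fat: saturated-fat ratio points set to 0")
      p_sat <- 0
    } else {
      ratio <- 100 * panel$sat_fat_g / panel$total_fat_g
      p_sat <- component_points(ratio, neg$sat_fat_ratio)
    }
  } else {
    p_sat <- component_points(panel$sat_fat_g, neg$sat_fat)
  }
  p_sug <- component_points(panel$total_sugars_g, neg$sugars)
  p_sod <- component_points(panel$sodium_mg, neg$sodium)
  n_total <- p_energy + p_sat + p_sug + p_sod

  pos <- tables$positive
  p_fvn <- component_points(panel$fvn_pct, pos$fvn)
  p_fib <- component_points(panel$fibre_g, pos$fibre)
  p_pro <- component_points(panel$protein_g, pos$protein)

  rule <- tables$protein_rule
  suppressed <- n_total >= rule$negative_min &&
    p_fvn < rule$fvn_full_points &&
    !category %in% (rule$exempt_categories %||% character())
  p_total <- p_fvn + p_fib + (if (suppressed) 0 else p_pro)

  score <- n_total - p_total
  grade <- grade_from_bounds(score, tables$grades$labels, tables$grades$upper)
  new_score_breakdown(
    "nutriscore", tables$version, category,
    points = list(energy = p_energy, sat_fat = p_sat, sugars = p_sug,
                  sodium = p_sod, fvn = p_fvn, fibre = p_fib,
                  protein = p_pro),
    negative_total = n_total, positive_total = p_total,
    protein_suppressed = suppressed, final_score = score, grade = grade,
    healthier = grade %in% tables$healthier_grades)
}

#' Ofcom nutrient profile model (UK FSA 2004/2005)
#'
#' A-points (energy, saturated fat, sugars, sodium) minus C-points
#' (fruit/veg/nuts, fibre, protein), with protein excluded when A-points
#' reach 11 unless FVN scores the full 5 points. A food is "less healthy"
#' (not permitted for marketing to children) at a score of 4 or more;
#' drinks at 1 or more.
#'
#' @inheritParams score_nutriscore
#' @param category `"food"` or `"drink"`.
#' @return A `fop_score`; `grade` is `"permitted"`/`"not_permitted"`.
#' @export
score_ofcom <- function(panel, category = "food",
                        tables = load_model_config("ofcom")) {
  if (!category %in% tables$categories) {
    stop_config(sprintf("unknown Ofcom category '%s'", category))
  }
  neg <- tables$negative
  p_energy <- component_points(panel$energy_kj, neg$energy)
  p_sat <- component_points(panel$sat_fat_g, neg$sat_fat)
  p_sug <- component_points(panel$total_sugars_g, neg$sugars)
  p_sod <- component_points(panel$sodium_mg, neg$sodium)
  a_total <- p_energy + p_sat + p_sug + p_sod

  pos <- tables$positive
  p_fvn <- component_points(panel$fvn_pct, pos$fvn)
  p_fib <- component_points(panel$fibre_g, pos$fibre)
  p_pro <- component_points(panel$protein_g, pos$protein)

  rule <- tables$protein_rule
  suppressed <- a_total >= rule$negative_min && p_fvn < rule$fvn_full_points
  c_total <- p_fvn + p_fib + (if (suppressed) 0 else p_pro)

  score <- a_total - c_total
  healthier <- score < tables$cutoffs[[category]]
  new_score_breakdown(
    "ofcom", tables$version, category,
    points = list(energy = p_energy, sat_fat = p_sat, sugars = p_sug,
                  sodium = p_sod, fvn = p_fvn, fibre = p_fib,
                  protein = p_pro),
    negative_total = a_total, positive_total = c_total,
    protein_suppressed = suppressed, final_score = score,
    grade = if (healthier) "permitted" else "not_permitted",
    healthier = healthier)
}

#' FSANZ Nutrient Profiling Scoring Criterion
#'
#' Baseline points minus modifying points; category 3 (oils/spreads and
#' high-calcium cheese) uses the extended saturated-fat ladder and a
#' cut-off of 28, category 2 foods 4, category 1 beverages 1. Protein is
#' excluded when baseline points reach 13 unless FVNL scores 5 or more.
#' "Healthier" means eligible to carry health claims (score strictly
#' below the category cut-off).
#'
#' @inheritParams score_nutriscore
#' @param category `"npsc_1"`, `"npsc_2"` or `"npsc_3"`.
#' @return A `fop_score`; `grade` is `"eligible"`/`"not_eligible"`.
#' @export
score_fsanz <- function(panel, category = "npsc_2",
                        tables = load_model_config("fsanz")) {
  if (!category %in% tables$categories) {
    stop_config(sprintf("unknown FSANZ category '%s'", category))
  }
  neg <- tables$negative
  sat_comp <- if (category %in% tables$extended_sat_fat_categories) {
    neg$sat_fat_extended
  } else {
    neg$sat_fat
  }
  p_energy <- component_points(panel$energy_kj, neg$energy)
  p_sat <- component_points(panel$sat_fat_g, sat_comp)
  p_sug <- component_points(panel$total_sugars_g, neg$sugars)
  p_sod <- component_points(panel$sodium_mg, neg$sodium)
  baseline <- p_energy + p_sat + p_sug + p_sod

  pos <- tables$positive
  p_fvn <- component_points(panel$fvn_pct, pos$fvn)
  p_fib <- component_points(panel$fibre_g, pos$fibre)
  p_pro <- component_points(panel$protein_g, pos$protein)

  rule <- tables$protein_rule
  suppressed <- baseline >= rule$negative_min && p_fvn < rule$fvn_full_points
  modifying <- p_fvn + p_fib + (if (suppressed) 0 else p_pro)

  score <- baseline - modifying
  healthier <- score < tables$cutoffs[[category]]
  new_score_breakdown(
    "fsanz", tables$version, category,
    points = list(energy = p_energy, sat_fat = p_sat, sugars = p_sug,
                  sodium = p_sod, fvn = p_fvn, fibre = p_fib,
                  protein = p_pro),
    negative_total = baseline, positive_total = modifying,
    protein_suppressed = suppressed, final_score = score,
    grade = if (healthier) "eligible" else "not_eligible",
    healthier = healthier)
}

#' Health Star Rating (2016 calculator)
#'
#' Baseline points minus modifying points, mapped to 0.5-5.0 stars in 0.5
#' steps through the category's score-to-star breakpoint table. Oils and
#' cheese use the extended saturated-fat ladder. "Healthier" means 3.5
#' stars or more.
#'
#' @inheritParams score_nutriscore
#' @param category `"food"`, `"dairy_food"`, `"oils"` or `"dairy_cheese"`.
#' @return A `fop_score`; `grade` is the star rating as character and the
#'   numeric stars are in `$stars`.
#' @export
score_hsr <- function(panel, category = "food",
                      tables = load_model_config("hsr")) {
  if (!category %in% tables$categories) {
    stop_config(sprintf("unknown HSR category '%s'", category))
  }
  neg <- tables$negative
  sat_comp <- if (category %in% tables$extended_sat_fat_categories) {
    neg$sat_fat_extended
  } else {
    neg$sat_fat
  }
  p_energy <- component_points(panel$energy_kj, neg$energy)
  p_sat <- component_points(panel$sat_fat_g, sat_comp)
  p_sug <- component_points(panel$total_sugars_g, neg$sugars)
  p_sod <- component_points(panel$sodium_mg, neg$sodium)
  baseline <- p_energy + p_sat + p_sug + p_sod

  pos <- tables$positive
  p_fvn <- component_points(panel$fvn_pct, pos$fvn)
  p_fib <- component_points(panel$fibre_g, pos$fibre)
  p_pro <- component_points(panel$protein_g, pos$protein)

  rule <- tables$protein_rule
  suppressed <- baseline >= rule$negative_min && p_fvn < rule$fvn_full_points
  modifying <- p_fvn + p_fib + (if (suppressed) 0 else p_pro)

  score <- baseline - modifying
  sm <- tables$star_map[[category]]
  if (is.null(sm)) {
    stop_config(sprintf("no star map for HSR category '%s'", category))
  }
  idx <- which(score <= as.numeric(sm$upper))
  stars <- if (length(idx) == 0) 0.5 else as.numeric(sm$stars)[[min(idx)]]
  out <- new_score_breakdown(
    "hsr", tables$version, category,
    points = list(energy = p_energy, sat_fat = p_sat, sugars = p_sug,
                  sodium = p_sod, fvn = p_fvn, fibre = p_fib,
                  protein = p_pro),
    negative_total = baseline, positive_total = modifying,
    protein_suppressed = suppressed, final_score = score,
    grade = format(stars, nsmall = 1),
    healthier = stars >= tables$healthier_min_stars)
  out$stars <- stars
  out
}
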