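#' UK FSA traffic-light banding
#'
#' Per-100 g colour banding of total fat, saturated fat, total sugars and
#' salt: green at or below the green bound, red strictly above the red
#' bound, amber between. Applied to all categories, cooking oils
#' included. The harmonised "healthier" verdict is the absence of any
#' red light.
#'
#' @param panel A [nutrient_panel()].
#' @param config Band configuration (see
#'   `load_model_config("traffic_light")`).
#' @return List of class `traffic_light` with `colours` (named character
#'   vector over the four nutrients), `healthier` and `version`.
#' @export
#' @examples
#' oil <- nutrient_panel(energy_kj = 3700, total_fat_g = 100, sat_fat_g = 14,
#'                       total_sugars_g = 0, salt_g = 0, protein_g = 0)
#' traffic_light(oil)$colours[["total_fat"]]  # "red"
traffic_light <- function(panel, config = load_model_config("traffic_light")) {
  band_of <- function(value, band) {
    if (value <= band$green) "green" else if (value > band$red) "red" else "amber"
  }
  colours <- vapply(
    config$bands,
    function(band) band_of(panel[[band$field]], band),
    character(1))
  structure(
    list(colours = colours, healthier = !any(colours == "red"),
         version = config$version),
    class = "traffic_light")
}

#' Evaluate a conjunctive threshold rule set
#'
#' A rule set is a list of threshold rules (nutrient or derived quantity,
#' comparator, limit) plus optional boolean requirements; a product is
#' eligible iff every rule holds. Categories a scheme does not cover
#' carry a `never_eligible` marker instead of borrowed limits.
#'
#' @param panel A [nutrient_panel()].
#' @param ruleset A per-category config block with elements `rules`
#'   (list of `nutrient`/`comparator`/`limit`), optional
#'   `forbid_sweetener`, or `never_eligible: true`.
#' @return List with `eligible` (logical) and `failed` (character vector
#'   describing each violated rule; empty when eligible).
#' @export
evaluate_ruleset <- function(panel, ruleset) {
  if (isTRUE(ruleset$never_eligible)) {
    return(list(eligible = FALSE, failed = "category never eligible under this scheme"))
  }
  failed <- character()
  for (rule in ruleset$rules %||% list()) {
    value <- panel_quantity(panel, rule$nutrient)
    ok <- switch(rule$comparator,
                 le = value <= rule$limit,
                 lt = value <  rule$limit,
                 ge = value >= rule$limit,
                 gt = value >  rule$limit,
                 stop_config(sprintf("unknown comparator '%s'", rule$comparator)))
    if (!ok) {
      failed <- c(failed, sprintf("%s %s %s violated (value %.4g)",
                                  rule$nutrient, rule$comparator, rule$limit,
                                  value))
    }
  }
  if (isTRUE(ruleset$forbid_sweetener) && isTRUE(panel$sweetener)) {
    failed <- c(failed, "contains sweetener")
  }
  list(eligible = length(failed) == 0, failed = failed)
}

#' High-unsaturated-fat claim predicate for cooking oils
#'
#' Operationalises eligibility of an oil to carry an authorised
#' nutrition/health claim: unsaturated fat (total minus saturated minus
#' trans) must make up at least 70% of total fat and supply more than
#' 20% of the product's energy, at 37 kJ per g of fat. The parameters
#' are configuration-replaceable.
#'
#' @param panel A [nutrient_panel()].
#' @param params Claim parameters (`min_unsat_share`, `min_energy_share`,
#'   `kj_per_g_fat`).
#' @return Logical scalar.
#' @export
#' @examples
#' olive <- nutrient_panel(energy_kj = 3700, total_fat_g = 100, sat_fat_g = 14,
#'                         total_sugars_g = 0, salt_g = 0, protein_g = 0)
#' claim_high_unsaturated(olive)  # TRUE
claim_high_unsaturated <- function(panel,
                                   params = load_model_config("protective_food")$oil_claim) {
  if (panel$total_fat_g <= 0) {
    fop_warn("claim predicate on a product with zero total fat")
    return(FALSE)
  }
  unsat <- unsaturated_fat_g(panel)
  share_ok <- unsat / panel$total_fat_g >= params$min_unsat_share
  energy_ok <- if (panel$energy_kj <= 0) {
    unsat > 0
  } else {
    unsat * params$kj_per_g_fat > params$min_energy_share * panel$energy_kj
  }
  share_ok && energy_ok
}

#' Protective Food symbol eligibility
#'
#' Traffic-light "no red light" screening for most categories, with two
#' overrides: dairy products (cheese and yoghurts) must contain strictly
#' less than 3 g total fat and 1.5 g saturated fat per 100 g; cooking
#' oils must satisfy the authorised-claim predicate
#' ([claim_high_unsaturated()]).
#'
#' @param panel A [nutrient_panel()].
#' @param category Leaf category code.
#' @param config Scheme configuration.
#' @return List with `eligible`, `failed` and `version`.
#' @export
protective_food <- function(panel, category,
                            config = load_model_config("protective_food")) {
  if (category %in% config$dairy_categories) {
    failed <- character()
    if (!(panel$total_fat_g < config$dairy_rules$total_fat_max)) {
      failed <- c(failed, sprintf("total fat %.3g not < %.3g g/100g",
                                  panel$total_fat_g, config$dairy_rules$total_fat_max))
    }
    if (!(panel$sat_fat_g < config$dairy_rules$sat_fat_max)) {
      failed <- c(failed, sprintf("saturated fat %.3g not < %.3g g/100g",
                                  panel$sat_fat_g, config$dairy_rules$sat_fat_max))
    }
    res <- list(eligible = length(failed) == 0, failed = failed)
  } else if (identical(category, "cooking_oil")) {
    ok <- claim_high_unsaturated(panel, config$oil_claim)
    res <- list(eligible = ok,
                failed = if (ok) character() else "no authorised claim eligibility")
  } else {
    tl <- traffic_light(panel, load_model_config("traffic_light"))
    reds <- names(tl$colours)[tl$colours == "red"]
    res <- list(eligible = tl$healthier,
                failed = if (length(reds)) paste("red light:", reds) else character())
  }
  res$version <- config$version
  res
}

#' Health-symbol and limit-scheme eligibility
#'
#' Evaluates one of the config-driven threshold schemes (Keyhole,
#' Choices, Finnish Heart, WHO-Europe) for a product by delegating to
#' [evaluate_ruleset()] with the scheme's per-category rule block.
#'
#' @param panel A [nutrient_panel()].
#' @param category Leaf category code.
#' @param scheme One of `"keyhole"`, `"choices"`, `"finnish_heart"`,
#'   `"whoe"`.
#' @param config Scheme configuration (defaults to the shipped version).
#' @return List with `eligible`, `failed` and `version`.
#' @export
symbol_scheme <- function(panel, category,
                          scheme = c("keyhole", "choices", "finnish_heart", "whoe"),
                          config = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(config)) config <- load_model_config(scheme)
  block <- config$categories[[category]]
  if (is.null(block)) {
    stop_config(sprintf("scheme '%s' has no rule set or never-eligible marker for category '%s'",
                        scheme, category))
  }
  if (isTRUE(config$forbid_sweetener_all)) block$forbid_sweetener <- TRUE
  res <- evaluate_ruleset(panel, block)
  res$version <- config$version
  res
}
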