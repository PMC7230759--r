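SALT_TO_SODIUM_MG <- 400  # mg sodium per g salt (EU labelling convention)

#' Construct a per-100 g nutrient panel
#'
#' A nutrient panel is the declared composition of one product per 100 g.
#' Mandatory nutrients are energy, total fat, saturated fat, total
#' sugars, salt and protein; fibre and the remaining nutrients are
#' optional and default to zero (absent positives being the conservative
#' reading of a label that does not declare them). Sodium is derived from
#' salt at 400 mg/g.
#'
#' @param energy_kj Energy, kJ/100 g.
#' @param total_fat_g,sat_fat_g,total_sugars_g,salt_g,protein_g Mandatory
#'   declared nutrients, g/100 g.
#' @param fibre_g Fibre (AOAC), g/100 g; defaults to 0.
#' @param trans_fat_g,added_sugars_g Optional, g/100 g; default 0.
#' @param fvn_pct Fruit/vegetable/nut/legume content, % of product.
#' @param wholegrain_pct Wholegrain, % of cereal dry matter.
#' @param calcium_mg Calcium, mg/100 g; `NA` when undeclared.
#' @param sweetener Logical; whether the product contains sweeteners.
#' @return A list of class `nutrient_panel` including the derived
#'   `sodium_mg`.
#' @export
#' @examples
#' p <- nutrient_panel(energy_kj = 260, total_fat_g = 3.5, sat_fat_g = 2.4,
#'                     total_sugars_g = 4.7, salt_g = 0.1, protein_g = 4)
#' p$sodium_mg  # 40
nutrient_panel <- function(energy_kj, total_fat_g, sat_fat_g, total_sugars_g,
                           salt_g, protein_g, fibre_g = 0, trans_fat_g = 0,
                           added_sugars_g = 0, fvn_pct = 0, wholegrain_pct = 0,
                           calcium_mg = NA_real_, sweetener = FALSE) {
  panel <- list(
    energy_kj = as.numeric(energy_kj),
    total_fat_g = as.numeric(total_fat_g),
    sat_fat_g = as.numeric(sat_fat_g),
    trans_fat_g = as.numeric(trans_fat_g),
    total_sugars_g = as.numeric(total_sugars_g),
    added_sugars_g = as.numeric(added_sugars_g),
    fibre_g = as.numeric(fibre_g),
    protein_g = as.numeric(protein_g),
    salt_g = as.numeric(salt_g),
    sodium_mg = as.numeric(salt_g) * SALT_TO_SODIUM_MG,
    fvn_pct = as.numeric(fvn_pct),
    wholegrain_pct = as.numeric(wholegrain_pct),
    calcium_mg = as.numeric(calcium_mg),
    sweetener = isTRUE(as.logical(sweetener))
  )
  class(panel) <- "nutrient_panel"
  panel
}

#' Validate a nutrient panel
#'
#' Checks the panel invariants: non-negative quantities, saturated and
#' trans fat bounded by total fat, added sugars bounded by total sugars,
#' percentage fields within 0-100, and the salt/sodium derivation.
#'
#' @param panel A [nutrient_panel()] (or any named list with its fields).
#' @return Character vector of violation reasons; empty when valid.
#' @export
validate_panel <- function(panel) {
  reasons <- character()
  mandatory <- c("energy_kj", "total_fat_g", "sat_fat_g", "total_sugars_g",
                 "salt_g", "protein_g")
  for (f in mandatory) {
    v <- panel[[f]]
    if (is.null(v) || is.na(v)) {
      reasons <- c(reasons, sprintf("missing mandatory nutrient %s", f))
    }
  }
  if (length(reasons) > 0) return(reasons)

  nonneg <- c(mandatory, "fibre_g", "trans_fat_g", "added_sugars_g",
              "fvn_pct", "wholegrain_pct", "calcium_mg")
  for (f in nonneg) {
    v <- panel[[f]]
    if (!is.null(v) && !is.na(v) && v < 0) {
      reasons <- c(reasons, sprintf("%s is negative", f))
    }
  }
  if (panel$sat_fat_g > panel$total_fat_g) {
    reasons <- c(reasons, "sat_fat exceeds total_fat")
  }
  if (!is.na(panel$trans_fat_g) && panel$trans_fat_g > panel$total_fat_g) {
    reasons <- c(reasons, "trans_fat exceeds total_fat")
  }
  if (!is.na(panel$added_sugars_g) && panel$added_sugars_g > panel$total_sugars_g) {
    reasons <- c(reasons, "added_sugars exceeds total_sugars")
  }
  for (f in c("fvn_pct", "wholegrain_pct")) {
    v <- panel[[f]]
    if (!is.null(v) && !is.na(v) && v > 100) {
      reasons <- c(reasons, sprintf("%s exceeds 100", f))
    }
  }
  if (!is.null(panel$sodium_mg) && !is.na(panel$sodium_mg) &&
      abs(panel$sodium_mg - panel$salt_g * SALT_TO_SODIUM_MG) > 0.5) {
    reasons <- c(reasons, "sodium inconsistent with salt")
  }
  reasons
}

# resolve a nutrient or derived quantity used by threshold rules
panel_quantity <- function(panel, nutrient) {
  switch(nutrient,
    sat_fat_ratio_pct = {
      if (panel$total_fat_g <= 0) 0 else 100 * panel$sat_fat_g / panel$total_fat_g
    },
    unsat_fat_ratio_pct = {
      if (panel$total_fat_g <= 0) 0 else
        100 * unsaturated_fat_g(panel) / panel$total_fat_g
    },
    {
      v <- panel[[nutrient]]
      if (is.null(v)) {
        stop_config(sprintf("rule references unknown nutrient '%s'", nutrient))
      }
      if (is.na(v)) {
        stop_config(sprintf(
          "rule references nutrient '%s' absent from the panel and not defaultable",
          nutrient))
      }
      v
    }
  )
}

unsaturated_fat_g <- function(panel) {
  tf <- if (is.na(panel$trans_fat_g)) 0 else panel$trans_fat_g
  max(0, panel$total_fat_g - panel$sat_fat_g - tf)
}
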