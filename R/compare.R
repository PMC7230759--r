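#' Proportion of healthier products in a category under one scheme
#'
#' @param matrix Long classification matrix from [classify_all()].
#' @param category Leaf category code.
#' @param model Scheme identifier.
#' @return List with `n`, `n_healthier` and `proportion`.
#' @export
proportion_healthier <- function(matrix, category, model) {
  flags <- matrix$healthier[matrix$category == category & matrix$model == model]
  if (length(flags) == 0) {
    stop_input(sprintf("no products for category '%s' under model '%s': proportion undefined",
                       category, model))
  }
  list(n = length(flags), n_healthier = sum(flags),
       proportion = mean(flags))
}

#' Sales-weighted proportion of healthier products
#'
#' Weights each product's healthier flag by its 12-month sales units
#' (unitless relative weights). Products without recorded sales are
#' excluded from both sums and counted in the log.
#'
#' @inheritParams proportion_healthier
#' @param products Product tibble carrying `sales_units`.
#' @return List with `n_with_sales`, `total_sales`, `healthier_sales`
#'   and `proportion`.
#' @export
sales_weighted_proportion <- function(matrix, products, category, model) {
  sub <- matrix[matrix$category == category & matrix$model == model, ]
  if (nrow(sub) == 0) {
    stop_input(sprintf("no products for category '%s' under model '%s'",
                       category, model))
  }
  sales <- products$sales_units[match(sub$id, products$id)]
  keep <- !is.na(sales)
  if (sum(keep) < nrow(sub)) {
    rlang::inform(sprintf(
      "sales weighting for %s/%s: %d product(s) without sales excluded",
      category, model, sum(!keep)))
  }
  total <- sum(sales[keep])
  if (!any(keep) || total <= 0) {
    stop_input(sprintf("total sales are zero for category '%s': weighted proportion undefined",
                       category))
  }
  healthier_sales <- sum(sales[keep][sub$healthier[keep]])
  list(n_with_sales = sum(keep), total_sales = total,
       healthier_sales = healthier_sales,
       proportion = healthier_sales / total)
}

#' Cohen's kappa for two binary classifications
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e), with p_o
#' the observed agreement fraction and p_e the expected agreement from
#' the marginal positive rates. When both raters are constant the
#' expected agreement is 1 and the statistic is undefined (0/0); the
#' convention here reports 0 with `degenerate = TRUE`, since agreement
#' under zero variation is indistinguishable from chance.
#'
#' @param flags_x,flags_y Logical vectors of equal length >= 2.
#' @return List with `kappa`, `degenerate`, `p_observed`, `p_expected`.
#' @export
#' @examples
#' cohens_kappa(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))$kappa
cohens_kappa <- function(flags_x, flags_y) {
  if (length(flags_x) != length(flags_y)) {
    stop_input("flag vectors differ in length")
  }
  if (length(flags_x) < 2) stop_input("need at least 2 paired ratings")
  if (any(is.na(flags_x)) || any(is.na(flags_y))) {
    stop_input("flags must not contain NA")
  }
  n <- length(flags_x)
  p_o <- mean(flags_x == flags_y)
  px <- mean(flags_x); py <- mean(flags_y)
  p_e <- px * py + (1 - px) * (1 - py)
  if (p_e >= 1) {
    return(list(kappa = 0, degenerate = TRUE, p_observed = p_o, p_expected = p_e))
  }
  list(kappa = (p_o - p_e) / (1 - p_e), degenerate = FALSE,
       p_observed = p_o, p_expected = p_e)
}

#' Agreement band for a kappa value
#'
#' Interprets kappa on the conventional ranges 0.01-0.20 (slight),
#' 0.21-0.40 (fair), 0.41-0.60 (moderate), 0.61-0.80 (substantial),
#' 0.81-0.99 (near perfect). Values at or below 0 fold into
#' "none-to-slight" and 1.0 into "near perfect"; the raw value should be
#' reported alongside the label.
#'
#' @param kappa Numeric in \[-1, 1\].
#' @return Character band label.
#' @export
#' @examples
#' band_label(0.625)  # "substantial"
band_label <- function(kappa) {
  if (is.na(kappa) || kappa < -1 || kappa > 1) {
    stop_input("kappa must lie in [-1, 1]")
  }
  if (kappa <= 0.20) "none-to-slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "near perfect"
}

#' Kappa agreement of one reference scheme against the others
#'
#' Per category, Cohen's kappa between the reference scheme's healthier
#' flags and each other scheme's, with interpretation bands.
#'
#' @param matrix Classification matrix from [classify_all()].
#' @param reference Reference scheme identifier.
#' @param others Schemes to compare against (default: all others in the
#'   matrix).
#' @return Tibble with `category`, `model`, `kappa`, `band`,
#'   `degenerate`.
#' @export
kappa_report <- function(matrix, reference = "nutriscore", others = NULL) {
  models <- unique(matrix$model)
  if (!reference %in% models) {
    stop_input(sprintf("reference model '%s' not in matrix", reference))
  }
  others <- others %||% setdiff(models, reference)
  rows <- list()
  for (cat in unique(matrix$category)) {
    ref <- matrix[matrix$category == cat & matrix$model == reference, ]
    ref_flags <- ref$healthier[order(ref$id)]
    for (m in others) {
      oth <- matrix[matrix$category == cat & matrix$model == m, ]
      k <- cohens_kappa(ref_flags, oth$healthier[order(oth$id)])
      rows[[length(rows) + 1]] <- tibble::tibble(
        category = cat, reference = reference, model = m,
        kappa = k$kappa, band = band_label(k$kappa),
        degenerate = k$degenerate)
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-category proportion report for all schemes
#'
#' The headline result shape: for every (category, model) pair, the
#' number of products, the healthier count and proportion, and — when
#' sales are recorded — the sales totals and sales-weighted proportion.
#'
#' @param matrix Classification matrix.
#' @param products Product tibble (needed for sales weighting; optional).
#' @return Tibble, one row per (category, model).
#' @export
proportion_report <- function(matrix, products = NULL) {
  combos <- unique(matrix[, c("category", "model")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cat <- combos$category[[i]]; m <- combos$model[[i]]
    p <- proportion_healthier(matrix, cat, m)
    row <- tibble::tibble(category = cat, model = m, n = p$n,
                          n_healthier = p$n_healthier,
                          proportion = p$proportion,
                          total_sales = NA_real_,
                          healthier_sales = NA_real_,
                          sw_proportion = NA_real_)
    if (!is.null(products) && "sales_units" %in% names(products) &&
        any(!is.na(products$sales_units[products$category == cat]))) {
      sw <- sales_weighted_proportion(matrix, products, cat, m)
      row$total_sales <- sw$total_sales
      row$healthier_sales <- sw$healthier_sales
      row$sw_proportion <- sw$proportion
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Symbol-versus-rating conflict scenarios
#'
#' Cross-tabulates eligibility for a health symbol against a "green"
#' verdict from an interpretive rating scheme into four scenarios:
#' A (green and symbol), B (green, no symbol), C (non-green but symbol —
#' the conflicting case), D (neither). Reports counts and percentages of
#' all products; the C percentage is the headline conflict rate.
#'
#' @param matrix Classification matrix containing both models.
#' @param symbol_model A binary symbol scheme (e.g. `protective_food`,
#'   `finnish_heart`).
#' @param rating_model A rating scheme with a green notion
#'   (`nutriscore` A/B, `hsr` >= 3.5 stars, `traffic_light` no red).
#' @return List with `counts` (named A-D), `percentages`, `n` and
#'   `scenario_c_pct`.
#' @export
scenario_table <- function(matrix, symbol_model = "protective_food",
                           rating_model = "nutriscore") {
  if (!rating_model %in% rating_models()) {
    stop_input(sprintf("model '%s' exposes no green rating notion", rating_model))
  }
  for (m in c(symbol_model, rating_model)) {
    if (!m %in% matrix$model) {
      stop_input(sprintf("model '%s' not present in classification matrix", m))
    }
  }
  sym <- matrix[matrix$model == symbol_model, ]
  rat <- matrix[matrix$model == rating_model, ]
  sym <- sym[order(sym$id), ]
  rat <- rat[order(rat$id), ]
  stopifnot(identical(sym$id, rat$id))
  symbol <- sym$healthier
  green <- rat$healthier
  counts <- c(A = sum(green & symbol),
              B = sum(green & !symbol),
              C = sum(!green & symbol),
              D = sum(!green & !symbol))
  n <- length(symbol)
  list(counts = counts, percentages = 100 * counts / n, n = n,
       scenario_c_pct = 100 * counts[["C"]] / n,
       symbol_model = symbol_model, rating_model = rating_model)
}
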