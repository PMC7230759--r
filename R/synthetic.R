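#' Default synthetic supply specification
#'
#' Loads the shipped supply spec (category counts, truncated nutrient
#' distributions, sales parameters) and optionally overrides the seed
#' and per-category product counts.
#'
#' @param seed Integer seed (mandatory before generation).
#' @param n Optional named integer vector of per-category counts, e.g.
#'   `c(cooking_oil = 50)`; categories set to 0 are dropped. When `n` is
#'   given, categories not named in it keep their default counts unless
#'   `only = TRUE`.
#' @param only If `TRUE`, generate only the categories named in `n`.
#' @param file Optional alternative spec YAML.
#' @return A `supply_spec` list.
#' @export
#' @examples
#' spec <- default_supply_spec(seed = 1, n = c(cooking_oil = 50), only = TRUE)
default_supply_spec <- function(seed = NULL, n = NULL, only = FALSE,
                                file = NULL) {
  if (is.null(file)) file <- fop_config_path("supply-default")
  spec <- yaml::read_yaml(file)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  if (!is.null(n)) {
    unknown <- setdiff(names(n), leaf_categories())
    if (length(unknown) > 0) {
      stop_input(sprintf("unknown category in count override: %s",
                         paste(unknown, collapse = ", ")))
    }
    if (only) spec$categories <- spec$categories[names(spec$categories) %in% names(n)]
    for (cat in names(n)) spec$categories[[cat]]$count <- as.integer(n[[cat]])
  }
  class(spec) <- c("supply_spec", class(spec))
  spec
}

# truncated draws by inverse-CDF; infeasible bounds are a spec error
draw_dist <- function(n, d, what = "nutrient") {
  if (is.null(d$dist)) stop_input(sprintf("%s distribution lacks 'dist'", what))
  switch(d$dist,
    constant = rep(d$value, n),
    uniform = {
      if (d$min > d$max) stop_input(sprintf("%s: min > max", what))
      runif(n, d$min, d$max)
    },
    normal = {
      lo <- stats::pnorm(d$min, d$mean, d$sd)
      hi <- stats::pnorm(d$max, d$mean, d$sd)
      if (d$min > d$max || hi <= lo) {
        stop_input(sprintf("%s: infeasible truncation bounds", what))
      }
      stats::qnorm(runif(n, lo, hi), d$mean, d$sd)
    },
    lognormal = {
      lo <- stats::plnorm(max(d$min, 0), d$meanlog, d$sdlog)
      hi <- stats::plnorm(d$max, d$meanlog, d$sdlog)
      if (hi <= lo) stop_input(sprintf("%s: infeasible truncation bounds", what))
      stats::qlnorm(runif(n, lo, hi), d$meanlog, d$sdlog)
    },
    stop_input(sprintf("%s: unknown distribution '%s'", what, d$dist))
  )
}

generate_category <- function(cat, cfg, cat_idx) {
  n <- cfg$count
  if (is.null(n) || n < 0) stop_input(sprintf("%s: invalid product count", cat))
  if (n == 0) return(NULL)
  nd <- cfg$nutrients
  draw <- function(field) {
    if (is.null(nd[[field]])) return(rep(0, n))
    draw_dist(n, nd[[field]], paste(cat, field))
  }

  total_fat <- draw("total_fat_g")
  if (!is.null(nd$sat_fat_g)) {
    sat_fat <- pmin(draw("sat_fat_g"), total_fat)
  } else if (!is.null(nd$sat_fat_share)) {
    sat_fat <- total_fat * draw_dist(n, nd$sat_fat_share, paste(cat, "sat share"))
  } else {
    sat_fat <- rep(0, n)
  }
  energy <- if (!is.null(cfg$energy_from_fat_kj_per_g)) {
    cfg$energy_from_fat_kj_per_g * total_fat
  } else {
    draw("energy_kj")
  }
  sugars <- draw("total_sugars_g")
  added <- if (!is.null(cfg$lactose_g)) pmax(0, sugars - cfg$lactose_g) else rep(0, n)
  salt <- draw("salt_g")
  fibre <- draw("fibre_g")
  protein <- draw("protein_g")
  calcium <- if (!is.null(nd$calcium_mg)) draw("calcium_mg") else rep(NA_real_, n)

  fvn <- rep(0, n)
  if (!is.null(cfg$fvn)) {
    has <- runif(n) < cfg$fvn$prob
    fvn[has] <- runif(sum(has), cfg$fvn$min, cfg$fvn$max)
  }
  wholegrain <- rep(0, n)
  if (!is.null(cfg$wholegrain)) {
    has <- runif(n) < cfg$wholegrain$prob
    wholegrain[has] <- runif(sum(has), cfg$wholegrain$min, cfg$wholegrain$max)
    # wholegrain subpopulation carries its own (higher) fibre level
    if (!is.null(cfg$wholegrain$fibre_mean) && any(has)) {
      fibre[has] <- pmax(0, rnorm(sum(has), cfg$wholegrain$fibre_mean,
                                  cfg$wholegrain$fibre_sd %||% 1))
    }
  }
  sweetener <- runif(n) < (cfg$sweetener_prob %||% 0)

  tibble::tibble(
    id = sprintf("383%02d%06d", cat_idx, seq_len(n)),
    name = sprintf("%s %03d", gsub("_", " ", cat), seq_len(n)),
    category = cat,
    energy_kj = round(energy, 0),
    total_fat_g = round(total_fat, 2),
    sat_fat_g = round(pmin(sat_fat, total_fat), 2),
    trans_fat_g = 0,
    total_sugars_g = round(sugars, 2),
    added_sugars_g = round(pmin(added, sugars), 2),
    fibre_g = round(fibre, 2),
    protein_g = round(protein, 2),
    salt_g = round(salt, 3),
    fvn_pct = round(fvn, 1),
    wholegrain_pct = round(wholegrain, 1),
    calcium_mg = round(calcium, 0),
    sweetener = sweetener,
    sales_units = NA_real_
  )
}

#' Generate a synthetic food-supply table
#'
#' Seeded generator emulating category-typical nutrient distributions of
#' the five studied categories: oils are near-pure fat (energy derived
#' at 37 kJ/g fat), cheese fat- and salt-rich, plain yoghurts lower in
#' sugar than flavoured ones, pasta mostly low fat/salt with a
#' wholegrain subpopulation. Every generated product passes panel
#' validation; identical spec and seed give identical tables.
#'
#' @param spec A [default_supply_spec()] (seed mandatory).
#' @param sales If `TRUE` (default), attach heavy-tailed sales via
#'   [attach_sales()] within the same seeded stream.
#' @return Product tibble in [supply_columns()] order.
#' @export
generate_supply <- function(spec, sales = TRUE) {
  if (is.null(spec$seed)) stop_input("supply spec must carry a seed")
  set.seed(spec$seed)
  cats <- names(spec$categories)
  parts <- lapply(seq_along(cats), function(i) {
    generate_category(cats[[i]], spec$categories[[cats[[i]]]], i)
  })
  products <- dplyr::bind_rows(parts)
  if (nrow(products) == 0) {
    fop_warn("supply spec generated zero products")
    return(products)
  }
  if (sales) products <- attach_sales(products, spec)
  products
}

#' Attach synthetic 12-month sales
#'
#' Draws log-normal (heavy-tailed) sales per category. A non-zero bias
#' coefficient `b` tilts expected sales along a continuous
#' nutritional-quality index (the negative Ofcom score, standardised
#' within category): `b < 0` makes the market leaders less healthy, as
#' observed for breakfast cereals; `b > 0` the reverse, as for cheese.
#' Uses the current RNG stream (call after seeding, or within
#' [generate_supply()]).
#'
#' @param products Product tibble.
#' @param spec Supply spec carrying per-category `sales` blocks
#'   (`meanlog`, `sdlog`, `bias`).
#' @return `products` with `sales_units` filled (positive integers).
#' @export
attach_sales <- function(products, spec) {
  ofcom_cfg <- load_model_config("ofcom")
  mapping <- load_category_mapping()
  sales <- numeric(nrow(products))
  for (cat in unique(products$category)) {
    idx <- which(products$category == cat)
    scfg <- spec$categories[[cat]]$sales %||%
      list(meanlog = 7.6, sdlog = 1.2, bias = 0)
    quality <- vapply(idx, function(i) {
      panel <- panel_from_row(products[i, ])
      internal <- resolve_category(cat, "ofcom", panel, mapping)
      -score_ofcom(panel, internal, ofcom_cfg)$final_score
    }, numeric(1))
    z <- if (length(idx) > 1 && stats::sd(quality) > 0) {
      (quality - mean(quality)) / stats::sd(quality)
    } else {
      rep(0, length(idx))
    }
    b <- scfg$bias %||% 0
    sales[idx] <- pmax(1, round(exp(
      scfg$meanlog + b * z + scfg$sdlog * rnorm(length(idx)))))
  }
  products$sales_units <- sales
  products
}
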