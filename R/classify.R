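#' Classify one product under one scheme
#'
#' Dispatches to the appropriate scoring or threshold model, resolving
#' the model's internal category where needed, and returns the raw
#' verdict together with the harmonised binary "healthier" flag
#' (Nutri-Score A/B; HSR >= 3.5 stars; traffic light no red; symbols and
#' regulatory models: permitted/eligible).
#'
#' @param product One-row tibble (or named list) with supply columns.
#' @param model One of [fop_models()].
#' @param configs Optional named list of pre-loaded configurations
#'   (avoids re-reading YAML in a loop).
#' @param mapping Category mapping from [load_category_mapping()].
#' @return List with `healthier`, `raw` (character), `score` (numeric or
#'   `NA`) and `version`.
#' @export
classify_product <- function(product, model, configs = NULL,
                             mapping = load_category_mapping()) {
  cfg <- configs[[model]] %||% load_model_config(model)
  panel <- panel_from_row(product)
  category <- product$category
  switch(
    model,
    nutriscore = {
      s <- score_nutriscore(panel, resolve_category(category, "nutriscore", panel, mapping), cfg)
      list(healthier = s$healthier, raw = s$grade, score = s$final_score,
           version = s$version)
    },
    hsr = {
      s <- score_hsr(panel, resolve_category(category, "hsr", panel, mapping), cfg)
      list(healthier = s$healthier, raw = s$grade, score = s$stars,
           version = s$version)
    },
    ofcom = {
      s <- score_ofcom(panel, resolve_category(category, "ofcom", panel, mapping), cfg)
      list(healthier = s$healthier, raw = s$grade, score = s$final_score,
           version = s$version)
    },
    fsanz = {
      s <- score_fsanz(panel, resolve_category(category, "fsanz", panel, mapping), cfg)
      list(healthier = s$healthier, raw = s$grade, score = s$final_score,
           version = s$version)
    },
    traffic_light = {
      tl <- traffic_light(panel, cfg)
      list(healthier = tl$healthier,
           raw = paste(tl$colours, collapse = "/"), score = NA_real_,
           version = tl$version)
    },
    protective_food = {
      r <- protective_food(panel, category, cfg)
      list(healthier = r$eligible,
           raw = if (r$eligible) "eligible" else "not_eligible",
           score = NA_real_, version = r$version)
    },
    keyhole = ,
    choices = ,
    finnish_heart = ,
    whoe = {
      r <- symbol_scheme(panel, category, scheme = model, config = cfg)
      list(healthier = r$eligible,
           raw = if (r$eligible) "eligible" else "not_eligible",
           score = NA_real_, version = r$version)
    },
    stop_config(sprintf("unknown model '%s'", model))
  )
}

#' Classify all products under a set of schemes
#'
#' Builds the complete products-by-models classification matrix in long
#' form. Deterministic; records the configuration version of every
#' scheme used. Any model failing on any product aborts with the product
#' id and cause.
#'
#' @param products Validated product tibble ([read_supply()] or
#'   [generate_supply()]).
#' @param models Character vector of scheme identifiers (default: all
#'   ten).
#' @param configs Optional named list of configuration overrides per
#'   model.
#' @param mapping Category mapping.
#' @param quiet Suppress the per-model count messages.
#' @return Tibble with columns `id`, `category`, `model`, `model_version`,
#'   `raw`, `score`, `healthier`.
#' @export
classify_all <- function(products, models = fop_models(), configs = NULL,
                         mapping = load_category_mapping(), quiet = FALSE) {
  unknown <- setdiff(models, fop_models())
  if (length(unknown) > 0) {
    stop_config(sprintf("unknown model(s): %s", paste(unknown, collapse = ", ")))
  }
  loaded <- lapply(setNames(models, models), function(m) {
    configs[[m]] %||% load_model_config(m)
  })
  n <- nrow(products)
  out <- vector("list", length(models))
  for (j in seq_along(models)) {
    m <- models[[j]]
    healthier <- logical(n)
    raw <- character(n)
    score <- numeric(n)
    for (i in seq_len(n)) {
      res <- tryCatch(
        classify_product(products[i, ], m, loaded, mapping),
        error = function(e) {
          stop_compute(sprintf("model '%s' failed on product '%s': %s",
                               m, products$id[[i]], conditionMessage(e)))
        })
      healthier[[i]] <- res$healthier
      raw[[i]] <- res$raw
      score[[i]] <- res$score
    }
    if (!quiet) {
      rlang::inform(sprintf("%-16s (%s): %d/%d healthier", m,
                            loaded[[m]]$version, sum(healthier), n))
    }
    out[[j]] <- tibble::tibble(
      id = products$id, category = products$category, model = m,
      model_version = loaded[[m]]$version, raw = raw, score = score,
      healthier = healthier)
  }
  dplyr::bind_rows(out)
}
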