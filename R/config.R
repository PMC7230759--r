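#' Scheme identifiers
#'
#' The ten front-of-package profiling schemes implemented by the package,
#' in the order used throughout reports. Four are point-scoring models
#' (`nutriscore`, `hsr`, `ofcom`, `fsanz`), the rest are threshold/limit
#' schemes (`traffic_light`, `protective_food`, `keyhole`, `choices`,
#' `finnish_heart`, `whoe`).
#'
#' @return Character vector of model identifiers.
#' @export
#' @examples
#' fop_models()
fop_models <- function() {
  c("nutriscore", "hsr", "traffic_light", "protective_food",
    "keyhole", "choices", "finnish_heart", "whoe", "ofcom", "fsanz")
}

# rating schemes expose a graded verdict with a "green" notion; symbol
# schemes are binary endorsements
rating_models <- function() c("nutriscore", "hsr", "traffic_light")
symbol_models <- function() c("protective_food", "keyhole", "choices", "finnish_heart")

default_config_files <- function() {
  c(nutriscore      = "nutriscore-2017",
    ofcom           = "ofcom-2005",
    fsanz           = "fsanz-npsc-2016",
    hsr             = "hsr-2016",
    traffic_light   = "traffic-light-fsa-2007",
    protective_food = "protective-food-1992",
    keyhole         = "keyhole-2015",
    choices         = "choices-2015",
    finnish_heart   = "finnish-heart-2000",
    whoe            = "whoe-2015")
}

fop_config_path <- function(name) {
  path <- system.file("extdata", "config", paste0(name, ".yaml"),
                      package = "fopcompare")
  if (!nzchar(path)) {
    stop_config(sprintf("no shipped configuration named '%s'", name))
  }
  path
}

#' Load a scheme configuration
#'
#' Point tables, class boundaries and threshold rule sets ship as
#' versioned YAML files under `inst/extdata/config`. Every configuration
#' carries a `version` tag that is surfaced in all classification output.
#'
#' @param model One of [fop_models()].
#' @param file Optional path to an alternative configuration file
#'   (overrides the shipped default for that model).
#' @return A named list with at least elements `model` and `version`.
#' @export
#' @examples
#' cfg <- load_model_config("nutriscore")
#' cfg$version
load_model_config <- function(model, file = NULL) {
  if (is.null(file)) {
    files <- default_config_files()
    if (!model %in% names(files)) {
      stop_config(sprintf("unknown model identifier '%s'", model))
    }
    file <- fop_config_path(files[[model]])
  }
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$version)) {
    stop_config(sprintf("configuration '%s' lacks a version tag", file))
  }
  if (!is.null(cfg$model) && !identical(cfg$model, model)) {
    stop_config(sprintf("configuration '%s' is for model '%s', not '%s'",
                        file, cfg$model, model))
  }
  validate_point_tables(cfg)
  cfg
}

# threshold ladders must be strictly increasing and point vectors
# non-decreasing; enforced at load so scoring can assume it
validate_point_tables <- function(cfg) {
  for (side in c("negative", "positive")) {
    for (nm in names(cfg[[side]])) {
      comp <- cfg[[side]][[nm]]
      thr <- as.numeric(comp$thresholds)
      if (any(diff(thr) <= 0)) {
        stop_config(sprintf("thresholds for %s component '%s' not strictly increasing",
                            cfg$model, nm))
      }
      if (!is.null(comp$points)) {
        pts <- as.numeric(comp$points)
        if (length(pts) != length(thr) || any(diff(pts) < 0)) {
          stop_config(sprintf("points for %s component '%s' malformed", cfg$model, nm))
        }
      }
    }
  }
  invisible(cfg)
}

#' Load the leaf-to-internal category mapping
#'
#' Each scoring model groups the seven leaf food categories into its own
#' internal categories (e.g. Ofcom only distinguishes foods from drinks;
#' Nutri-Score adds cheese and added fats). The mapping is configuration
#' data, not code.
#'
#' @param file Optional alternative YAML mapping file.
#' @return Named list with `models` (per-model lookup) and the FSANZ
#'   calcium limit used for conditional cheese routing.
#' @export
load_category_mapping <- function(file = NULL) {
  if (is.null(file)) file <- fop_config_path("category-mapping")
  yaml::read_yaml(file)
}

#' Leaf food-category codes
#'
#' @return Character vector of the seven leaf category codes in scope.
#' @export
leaf_categories <- function() {
  c("breakfast_cereals", "pasta", "cheese", "yoghurt_plain",
    "yoghurt_flavoured", "yoghurt_drink_flavoured", "cooking_oil")
}
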