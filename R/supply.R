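#' Canonical supply-table columns
#'
#' Documented CSV header for food-supply tables: one row per product with
#' identifier, name, leaf category, the per-100 g nutrient declaration
#' and optional 12-month sales units. Comma-separated, UTF-8, dot decimal
#' separator, header mandatory.
#'
#' @return Character vector of column names in canonical order.
#' @export
supply_columns <- function() {
  c("id", "name", "category", "energy_kj", "total_fat_g", "sat_fat_g",
    "trans_fat_g", "total_sugars_g", "added_sugars_g", "fibre_g",
    "protein_g", "salt_g", "fvn_pct", "wholegrain_pct", "calcium_mg",
    "sweetener", "sales_units")
}

supply_col_types <- function() {
  readr::cols(
    id = readr::col_character(),
    name = readr::col_character(),
    category = readr::col_character(),
    energy_kj = readr::col_double(),
    total_fat_g = readr::col_double(),
    sat_fat_g = readr::col_double(),
    trans_fat_g = readr::col_double(),
    total_sugars_g = readr::col_double(),
    added_sugars_g = readr::col_double(),
    fibre_g = readr::col_double(),
    protein_g = readr::col_double(),
    salt_g = readr::col_double(),
    fvn_pct = readr::col_double(),
    wholegrain_pct = readr::col_double(),
    calcium_mg = readr::col_double(),
    sweetener = readr::col_logical(),
    sales_units = readr::col_double()
  )
}

# nutrients that default to zero when undeclared (logged), vs mandatory
optional_zero_default <- function() {
  c("trans_fat_g", "added_sugars_g", "fibre_g", "fvn_pct", "wholegrain_pct")
}

panel_from_row <- function(row) {
  nutrient_panel(
    energy_kj = row$energy_kj, total_fat_g = row$total_fat_g,
    sat_fat_g = row$sat_fat_g, total_sugars_g = row$total_sugars_g,
    salt_g = row$salt_g, protein_g = row$protein_g, fibre_g = row$fibre_g,
    trans_fat_g = row$trans_fat_g, added_sugars_g = row$added_sugars_g,
    fvn_pct = row$fvn_pct, wholegrain_pct = row$wholegrain_pct,
    calcium_mg = row$calcium_mg, sweetener = isTRUE(row$sweetener)
  )
}

#' Read a food-supply table
#'
#' Reads and validates a product CSV (header per [supply_columns()]).
#' Validation is total: every row is either accepted or attributed a
#' machine-readable rejection reason. In `permissive` mode invalid rows
#' are dropped with a warning and recorded in the `rejected` attribute of
#' the result; in `strict` mode the first violation aborts.
#'
#' @param path Path to a CSV file.
#' @param strictness `"permissive"` (default) or `"strict"`.
#' @return A tibble of validated products. Attributes: `rejected`, a
#'   tibble with columns `id`, `row` and `reason` (permissive mode).
#' @export
read_supply <- function(path, strictness = c("permissive", "strict")) {
  strictness <- match.arg(strictness)
  if (!file.exists(path)) stop_input(sprintf("input file '%s' not found", path))
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = supply_col_types(),
                    show_col_types = FALSE)
  )
  missing_cols <- setdiff(supply_columns(), names(raw))
  mandatory_cols <- setdiff(supply_columns(),
                            c("name", "sales_units", "calcium_mg", "sweetener",
                              optional_zero_default()))
  missing_mandatory <- intersect(missing_cols, mandatory_cols)
  if (length(missing_mandatory) > 0) {
    stop_input(sprintf("missing mandatory column(s): %s",
                       paste(missing_mandatory, collapse = ", ")))
  }
  for (col in missing_cols) raw[[col]] <- NA
  raw <- raw[supply_columns()]
  validate_supply(raw, strictness = strictness)
}

#' Validate a raw supply table
#'
#' Applies the panel invariants row by row, fills optional-nutrient
#' defaults (zero, with a warning naming the affected columns), derives
#' nothing beyond what [nutrient_panel()] derives, and checks id
#' uniqueness and category codes.
#'
#' @param raw A tibble with the columns of [supply_columns()].
#' @inheritParams read_supply
#' @return A validated tibble with a `rejected` attribute (see
#'   [read_supply()]).
#' @export
validate_supply <- function(raw, strictness = c("permissive", "strict")) {
  strictness <- match.arg(strictness)
  n <- nrow(raw)

  defaulted <- character()
  for (col in optional_zero_default()) {
    if (any(is.na(raw[[col]]))) {
      defaulted <- c(defaulted, col)
      raw[[col]][is.na(raw[[col]])] <- 0
    }
  }
  if (length(defaulted) > 0) {
    fop_warn(sprintf("missing optional nutrient(s) defaulted to 0: %s",
                     paste(defaulted, collapse = ", ")))
  }
  raw$sweetener[is.na(raw$sweetener)] <- FALSE

  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    row <- raw[i, ]
    r <- character()
    if (is.na(row$id) || !nzchar(row$id)) r <- c(r, "missing id")
    if (is.na(row$category) || !row$category %in% leaf_categories()) {
      r <- c(r, sprintf("unknown category code '%s'", row$category))
    }
    if (!is.na(row$sales_units) && row$sales_units < 0) {
      r <- c(r, "sales_units is negative")
    }
    mandatory_na <- any(is.na(c(row$energy_kj, row$total_fat_g, row$sat_fat_g,
                                row$total_sugars_g, row$salt_g, row$protein_g)))
    if (mandatory_na) {
      miss <- c("energy_kj", "total_fat_g", "sat_fat_g", "total_sugars_g",
                "salt_g", "protein_g")
      miss <- miss[is.na(unlist(row[miss]))]
      r <- c(r, sprintf("missing mandatory nutrient %s", miss))
    } else {
      r <- c(r, validate_panel(panel_from_row(row)))
    }
    if (length(r) > 0 && strictness == "strict") {
      stop_input(sprintf("row %d (id '%s'): %s", i, row$id, r[[1]]))
    }
    reasons[[i]] <- r
  }

  dup <- duplicated(raw$id) & !is.na(raw$id)
  if (any(dup)) {
    for (i in which(dup)) {
      reasons[[i]] <- c(reasons[[i]], "duplicate id")
      if (strictness == "strict") {
        stop_input(sprintf("row %d (id '%s'): duplicate id", i, raw$id[[i]]))
      }
    }
  }

  bad <- vapply(reasons, function(r) length(r) > 0, logical(1))
  rejected <- tibble::tibble(
    row = which(bad),
    id = raw$id[bad],
    reason = vapply(reasons[bad], function(r) paste(r, collapse = "; "),
                    character(1))
  )
  if (nrow(rejected) > 0) {
    fop_warn(sprintf("dropped %d invalid row(s): %s", nrow(rejected),
                     paste(utils::head(rejected$reason, 5), collapse = " | ")))
  }
  out <- raw[!bad, ]
  attr(out, "rejected") <- rejected
  out
}

#' Write a food-supply table
#'
#' Writes products as CSV such that `read_supply(write_supply(x))`
#' reproduces `x` field for field.
#'
#' @param products Validated product tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_supply <- function(products, path) {
  cols <- intersect(supply_columns(), names(products))
  readr::write_csv(products[cols], path, na = "")
  invisible(path)
}

#' Resolve a product's internal category for a scoring model
#'
#' Pure function of the leaf code, the panel (FSANZ cheese routing uses
#' calcium) and the mapping configuration.
#'
#' @param category Leaf category code.
#' @param model One of `nutriscore`, `ofcom`, `hsr`, `fsanz`.
#' @param panel Optional [nutrient_panel()]; needed for FSANZ cheese.
#' @param mapping Mapping list from [load_category_mapping()].
#' @return The model's internal category code (character scalar).
#' @export
#' @examples
#' resolve_category("cooking_oil", "nutriscore")  # "added_fats"
#' resolve_category("yoghurt_drink_flavoured", "ofcom")  # "drink"
resolve_category <- function(category, model, panel = NULL,
                             mapping = load_category_mapping()) {
  if (!model %in% names(mapping$models)) {
    stop_config(sprintf("no category mapping for model '%s'", model))
  }
  m <- mapping$models[[model]]
  internal <- m[[category]] %||% m[["default"]]
  if (is.null(internal)) {
    stop_config(sprintf("leaf category '%s' unmapped for model '%s'",
                        category, model))
  }
  if (identical(internal, "conditional_calcium")) {
    limit <- mapping$fsanz_calcium_limit_mg %||% 320
    ca <- if (!is.null(panel)) panel$calcium_mg else NA_real_
    if (is.null(ca) || is.na(ca)) {
      fop_warn(sprintf(
        "calcium unrecorded for a '%s' product; FSANZ falls back to npsc_2",
        category))
      internal <- "npsc_2"
    } else if (ca >= limit) {
      internal <- "npsc_3"
    } else {
      internal <- "npsc_2"
    }
  }
  internal
}
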