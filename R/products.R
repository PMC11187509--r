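#' Product reference table
#'
#' Each dispensed product is described by an opioid flag, an oral morphine
#' equivalence (OME) conversion factor per dispensed unit, a flag for regular
#' (long-acting) opioids — preparations used on a continuing basis to control
#' pain, as opposed to breakthrough-pain preparations and injections — and the
#' expected daily OME when the product is taken as directed. The daily OME is
#' what classifies a regular opioid as high dose (>= 120 mg OME per day).
#'
#' `ome_reference()` loads the reference table shipped with the package, which
#' covers a set of common opioid products; `read_product_ref()` reads any CSV
#' with the same columns.
#'
#' @param path path to a product-reference CSV with columns `bnf_code`,
#'   `name`, `is_opioid`, `ome_per_unit_mg`, `is_regular`, `ome_per_day_mg`.
#' @return A tibble with one row per product.
#' @examples
#' ref <- ome_reference()
#' ref[ref$is_regular, c("name", "ome_per_day_mg")]
#' @export
ome_reference <- function() {
  read_product_ref(system.file("extdata", "ome_reference.csv",
    package = "opioidtrends", mustWork = TRUE
  ))
}

#' @rdname ome_reference
#' @export
read_product_ref <- function(path) {
  ref <- readr::read_csv(path,
    col_types = readr::cols(
      bnf_code = readr::col_character(),
      name = readr::col_character(),
      is_opioid = readr::col_logical(),
      ome_per_unit_mg = readr::col_double(),
      is_regular = readr::col_logical(),
      ome_per_day_mg = readr::col_double()
    )
  )
  validate_product_ref(ref)
  ref
}

validate_product_ref <- function(ref) {
  required <- c(
    "bnf_code", "name", "is_opioid", "ome_per_unit_mg", "is_regular",
    "ome_per_day_mg"
  )
  missing <- setdiff(required, names(ref))
  if (length(missing) > 0) {
    abort(paste0(
      "Product reference is missing columns: ",
      paste(missing, collapse = ", ")
    ))
  }
  if (any(ref$ome_per_unit_mg < 0, na.rm = TRUE) ||
    any(ref$ome_per_day_mg < 0, na.rm = TRUE)) {
    abort("OME values in the product reference must be nonnegative.")
  }
  if (any(!ref$is_opioid & ref$is_regular)) {
    abort("Non-opioid products cannot be flagged as regular opioids.")
  }
  if (anyDuplicated(ref$bnf_code)) {
    abort("Duplicated bnf_code in product reference.")
  }
  invisible(ref)
}

#' Oral morphine equivalence of a dispensed quantity
#'
#' Converts a dispensed quantity (units: tablets, patches, doses) of an opioid
#' product into milligrams of oral morphine equivalent, using the product's
#' per-unit conversion factor.
#'
#' @param quantity number of dispensed units (nonnegative).
#' @param product a one-row product reference (data frame row or named list)
#'   with at least `is_opioid` and `ome_per_unit_mg`.
#' @return OME in mg.
#' @examples
#' ref <- ome_reference()
#' morphine30 <- ref[ref$name == "Morphine sulfate MR 30mg tablets", ]
#' item_ome(60, morphine30) # 1800 mg
#' @export
item_ome <- function(quantity, product) {
  if (!isTRUE(all(as.logical(product$is_opioid)))) {
    abort("`item_ome()` is defined for opioid products only.")
  }
  if (any(quantity < 0)) {
    abort("`quantity` must be nonnegative.")
  }
  quantity * product$ome_per_unit_mg
}

#' Classify a regular opioid as high dose
#'
#' A regular (long-acting) opioid is high dose when its expected daily intake,
#' taken as directed, is at least `threshold` mg OME per day (default 120,
#' boundary inclusive). Products that are not regular opioids are not
#' classifiable and are excluded from the regular-opioid measures; for those
#' the function returns `NA`.
#'
#' @param product product reference rows (data frame or named list with
#'   `is_opioid`, `is_regular`, `ome_per_day_mg`).
#' @param threshold daily OME threshold in mg.
#' @return logical vector: `TRUE`/`FALSE` for regular opioids, `NA` otherwise.
#' @examples
#' classify_high_dose(list(is_opioid = TRUE, is_regular = TRUE, ome_per_day_mg = 120))
#' @export
classify_high_dose <- function(product, threshold = 120) {
  regular <- as.logical(product$is_opioid) & as.logical(product$is_regular)
  out <- ifelse(regular, product$ome_per_day_mg >= threshold, NA)
  as.logical(out)
}
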