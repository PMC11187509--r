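#' Opioid prescribing measure identifiers
#'
#' Three monthly measures are supported, and for all of them higher values
#' mean more opioid prescribing:
#'
#' * `ome_per_1000` — total oral morphine equivalence (mg) of all opioid
#'   prescriptions per 1000 registered patients.
#' * `high_dose_pct_regular` — items of high-dose regular opioids as a
#'   percentage of items of all regular (long-acting) opioids.
#' * `high_dose_per_1000` — items of high-dose regular opioids per 1000
#'   registered patients.
#'
#' @return character vector of the three measure ids.
#' @export
measure_ids <- function() {
  c("ome_per_1000", "high_dose_pct_regular", "high_dose_per_1000")
}

#' Build monthly measure series for every organization
#'
#' Converts product-level dispensing records into one monthly series of the
#' chosen measure per organization, at practice or region level. Region
#' series are aggregated by summing member practices' numerators and
#' denominators before dividing (population-rate aggregation), never by
#' averaging practice ratios. Months with a zero denominator yield a missing
#' value, not zero: a 0/0 ratio carries no information, and the screening
#' stage counts those months.
#'
#' @param records prescribing records: `practice_code` (or `org_id`),
#'   `period`, `bnf_code`, `items`, `quantity`.
#' @param list_sizes monthly registered populations: `practice_code`,
#'   `period`, `list_size`. Every practice/month in the study window must
#'   have a row; the study window is taken from the distinct periods here.
#' @param products product reference (see [ome_reference()]).
#' @param measure_id one of [measure_ids()].
#' @param level `"practice"` or `"region"`.
#' @param region_map tibble `practice_code`, `region_code`; required for
#'   `level = "region"`.
#' @param high_dose_threshold daily OME threshold (mg) for the high-dose
#'   classification.
#' @return A tibble with columns `org_id`, `measure_id`, `period`,
#'   `month_index`, `numerator`, `denominator`, `value` (`NA` where the
#'   denominator is zero), one row per organization and month.
#' @examples
#' panel <- generate_panel(panel_config(n_practices = 2, n_months = 12,
#'                                      noise_dispersion = 0))
#' series <- build_measure_series(panel$records, panel$list_sizes,
#'                                panel$products, "ome_per_1000")
#' head(series)
#' @export
build_measure_series <- function(records, list_sizes, products,
                                 measure_id = measure_ids(),
                                 level = c("practice", "region"),
                                 region_map = NULL,
                                 high_dose_threshold = 120) {
  measure_id <- match.arg(measure_id)
  level <- match.arg(level)
  validate_product_ref(products)
  if (level == "region" && is.null(region_map)) {
    abort("`region_map` is required for region-level series.")
  }
  if (!"practice_code" %in% names(records) && "org_id" %in% names(records)) {
    records <- dplyr::rename(records, practice_code = org_id)
  }

  unknown <- setdiff(unique(records$bnf_code), products$bnf_code)
  if (length(unknown) > 0) {
    abort(paste0(
      "Prescribing records contain bnf_codes absent from the product ",
      "reference: ", paste(sort(unknown), collapse = ", ")
    ))
  }

  periods <- sort(unique(list_sizes$period))
  rec <- dplyr::left_join(records, products, by = "bnf_code")
  rec$high_dose <- dplyr::coalesce(
    classify_high_dose(rec, threshold = high_dose_threshold), FALSE
  )

  num <- switch(measure_id,
    ome_per_1000 = rec |>
      dplyr::filter(is_opioid) |>
      dplyr::group_by(practice_code, period) |>
      dplyr::summarise(
        numerator = sum(quantity * ome_per_unit_mg), .groups = "drop"
      ),
    high_dose_pct_regular = ,
    high_dose_per_1000 = rec |>
      dplyr::filter(is_opioid, is_regular, high_dose) |>
      dplyr::group_by(practice_code, period) |>
      dplyr::summarise(numerator = sum(items), .groups = "drop")
  )

  den <- if (measure_id == "high_dose_pct_regular") {
    rec |>
      dplyr::filter(is_opioid, is_regular) |>
      dplyr::group_by(practice_code, period) |>
      dplyr::summarise(denominator = sum(items), .groups = "drop")
  } else {
    dplyr::select(list_sizes, practice_code, period, denominator = list_size)
  }

  grid <- tidyr::expand_grid(
    practice_code = sort(unique(list_sizes$practice_code)),
    period = periods
  )
  out <- grid |>
    dplyr::left_join(num, by = c("practice_code", "period")) |>
    dplyr::left_join(den, by = c("practice_code", "period")) |>
    dplyr::mutate(
      numerator = dplyr::coalesce(numerator, 0),
      denominator = dplyr::coalesce(denominator, 0)
    )

  if (level == "region") {
    missing_map <- setdiff(out$practice_code, region_map$practice_code)
    if (length(missing_map) > 0) {
      abort(paste0(
        "Practices without a region mapping: ",
        paste(head(sort(missing_map), 10), collapse = ", ")
      ))
    }
    out <- out |>
      dplyr::left_join(region_map, by = "practice_code") |>
      dplyr::group_by(org_id = region_code, period) |>
      dplyr::summarise(
        numerator = sum(numerator), denominator = sum(denominator),
        .groups = "drop"
      )
  } else {
    out <- dplyr::rename(out, org_id = practice_code)
  }

  scale <- if (measure_id == "high_dose_pct_regular") 100 else 1000
  mid <- measure_id
  out |>
    dplyr::mutate(
      measure_id = mid,
      month_index = match(period, periods),
      value = dplyr::if_else(
        denominator > 0, numerator / denominator * scale, NA_real_
      )
    ) |>
    dplyr::select(org_id, measure_id, period, month_index, numerator,
                  denominator, value) |>
    dplyr::arrange(org_id, period)
}
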