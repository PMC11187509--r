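#' Screen organizations before change detection
#'
#' Applies the screening cascade in a fixed order: (1) remove closed or
#' dormant practices; (2) remove practices with a registered list size below
#' `min_list_size` (2000 by default), evaluated at the latest available month
#' (configurable to the minimum or mean over the window); (3) remove
#' organizations where more than `zero_denom_frac` of the monthly denominator
#' values of the measure are zero — either no registered population or no
#' prescribing in the measure's denominator. Regions are exempt from the
#' closed and list-size stages, which are practice-level administrative
#' facts. Each organization receives exactly one disposition, so the stage
#' counts always sum to the input count.
#'
#' @param statuses practice metadata: `practice_code`, `status` (`active`,
#'   `closed`, `dormant`), `close_period`. Required for practice level.
#' @param list_sizes monthly list sizes: `practice_code`, `period`,
#'   `list_size`. Required for practice level.
#' @param series the measure series of the organizations to screen, from
#'   [build_measure_series()].
#' @param level `"practice"` or `"region"`.
#' @param min_list_size list-size threshold (default 2000, exclusive: a
#'   practice is removed when its evaluated list size is `< min_list_size`).
#' @param zero_denom_frac zero-denominator threshold (default 0.5, strict:
#'   an organization is removed only when *more than* this fraction of its
#'   monthly denominators is zero).
#' @param list_size_month which month's list size to test: `"last"` (latest
#'   available), `"min"` or `"mean"` over the window.
#' @return An object of class `screening_report`: a list with the stage
#'   counts (`n_input`, `n_removed_closed`, `n_removed_small_list`,
#'   `n_removed_zero_denominator`, `n_analyzable`) and a `disposition`
#'   tibble (`org_id`, `disposition`, `reason`).
#' @examples
#' panel <- generate_panel(panel_config(n_practices = 10, n_months = 24,
#'                                      frac_closed = 0.2, seed = 7))
#' series <- build_measure_series(panel$records, panel$list_sizes,
#'                                panel$products, "ome_per_1000")
#' screen_organizations(panel$statuses, panel$list_sizes, series)
#' @export
screen_organizations <- function(statuses, list_sizes, series,
                                 level = c("practice", "region"),
                                 min_list_size = 2000,
                                 zero_denom_frac = 0.5,
                                 list_size_month = c("last", "min", "mean")) {
  level <- match.arg(level)
  list_size_month <- match.arg(list_size_month)
  if (min_list_size <= 0) abort("`min_list_size` must be positive.")
  check_fraction(zero_denom_frac, "zero_denom_frac")

  orgs <- sort(unique(series$org_id))
  disposition <- tibble::tibble(
    org_id = orgs,
    disposition = rep("analyzable", length(orgs)),
    reason = rep(NA_character_, length(orgs))
  )

  if (level == "practice") {
    missing_meta <- setdiff(orgs, statuses$practice_code)
    if (length(missing_meta) > 0) {
      abort(paste0(
        "Organizations present in the series but absent from `statuses`: ",
        paste(head(missing_meta, 10), collapse = ", ")
      ))
    }
    # stage 1: closed or dormant
    closed <- statuses$practice_code[statuses$status %in% c("closed", "dormant")]
    hit <- disposition$org_id %in% closed
    disposition$disposition[hit] <- "removed"
    disposition$reason[hit] <- "closed_or_dormant"

    # stage 2: small list among the remainder
    eval_list <- list_sizes |>
      dplyr::filter(practice_code %in% disposition$org_id[
        disposition$disposition == "analyzable"
      ]) |>
      dplyr::group_by(practice_code) |>
      dplyr::summarise(
        eval_size = switch(list_size_month,
          last = list_size[which.max(period)],
          min = min(list_size),
          mean = mean(list_size)
        ),
        .groups = "drop"
      )
    small <- eval_list$practice_code[eval_list$eval_size < min_list_size]
    hit <- disposition$org_id %in% small
    disposition$disposition[hit] <- "removed"
    disposition$reason[hit] <- "small_list"
  }

  # stage 3: more than half of monthly denominators are zero
  zero_frac <- series |>
    dplyr::filter(org_id %in% disposition$org_id[
      disposition$disposition == "analyzable"
    ]) |>
    dplyr::group_by(org_id) |>
    dplyr::summarise(frac0 = mean(denominator == 0), .groups = "drop")
  zero <- zero_frac$org_id[zero_frac$frac0 > zero_denom_frac]
  hit <- disposition$org_id %in% zero
  disposition$disposition[hit] <- "removed"
  disposition$reason[hit] <- "zero_denominator"

  structure(
    list(
      level = level,
      n_input = length(orgs),
      n_removed_closed = sum(disposition$reason %in% "closed_or_dormant"),
      n_removed_small_list = sum(disposition$reason %in% "small_list"),
      n_removed_zero_denominator = sum(disposition$reason %in% "zero_denominator"),
      n_analyzable = sum(disposition$disposition == "analyzable"),
      disposition = disposition
    ),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %s level\n", x$level))
  cat(sprintf("  input organizations:   %d\n", x$n_input))
  cat(sprintf("  closed or dormant:    -%d\n", x$n_removed_closed))
  cat(sprintf("  small list (<2000):   -%d\n", x$n_removed_small_list))
  cat(sprintf("  >50%% zero denominators: -%d\n", x$n_removed_zero_denominator))
  cat(sprintf("  analyzable:            %d\n", x$n_analyzable))
  invisible(x)
}

#' Analyzable organizations from a screening report
#'
#' @param report a [screen_organizations()] result.
#' @return character vector of analyzable organization ids.
#' @export
analyzable_orgs <- function(report) {
  stopifnot(inherits(report, "screening_report"))
  report$disposition$org_id[report$disposition$disposition == "analyzable"]
}

#' Keep reductions that started from a top-fraction prescribing level
#'
#' Organizations with consistently low prescribing are not interesting
#' candidates for intervention discovery, so a detected reduction is kept
#' only when the organization's level immediately before the drop was in the
#' top `fraction` (default 20%) of its peers. The reference distribution is
#' the cross-section of all analyzable organizations' observed measure values
#' in the candidate's pre-drop month; the cutoff is the k-th largest value in
#' that cross-section with `k = floor(fraction * N)` (so 191 regions give a
#' top-38 cut), and ties at the cutoff are all retained.
#'
#' @param changes detected reductions from [detect_changes()] (must carry
#'   `predrop_period` and `predrop_value`).
#' @param series the measure series of all analyzable organizations.
#' @param fraction top fraction kept, in (0, 1).
#' @return The qualifying subset of `changes`.
#' @export
select_top_starting <- function(changes, series, fraction = 0.2) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be a single number in (0, 1).")
  }
  if (nrow(changes) == 0) return(changes)
  keep <- vapply(seq_len(nrow(changes)), function(i) {
    ref <- series$value[series$period == changes$predrop_period[i]]
    ref <- ref[!is.na(ref)]
    if (length(ref) == 0) return(FALSE)
    k <- top_cut_count(length(ref), fraction)
    cutoff <- sort(ref, decreasing = TRUE)[k]
    # small relative tolerance so a fitted pre-drop level numerically equal
    # to the cutoff counts as a tie and is retained
    changes$predrop_value[i] >= cutoff - 1e-9 * (abs(cutoff) + 1)
  }, logical(1))
  changes[keep, , drop = FALSE]
}

#' Rank organizations by proportional reduction
#'
#' Sorts detected reductions by proportional change (the percentage
#' reduction between the pre-drop and end-drop values) in decreasing order;
#' ties are broken by absolute change (decreasing) and then organization id,
#' so the table is invariant to input order.
#'
#' @param changes detected (and usually top-starting-filtered) reductions.
#' @return A tibble with a leading `rank` column (consecutive from 1); empty
#'   input yields an empty table.
#' @export
rank_reductions <- function(changes) {
  out <- changes[order(-changes$proportional_change,
                       -changes$absolute_change,
                       changes$org_id), , drop = FALSE]
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' Summarize detected reductions
#'
#' Count, median, quartile-based IQR and range of the proportional
#' reductions in a set of detected changes (conventionally computed on all
#' detected reductions, before the top-starting-level filter). An empty set
#' yields a count of zero with missing statistics.
#'
#' @param changes detected reductions.
#' @param n_organizations number of organizations analyzed (optional,
#'   reported alongside the count).
#' @return A one-row tibble: `n_organizations`, `count`, `median`,
#'   `iqr_low`, `iqr_high`, `range_low`, `range_high`.
#' @examples
#' summarize_reductions(tibble::tibble(proportional_change = c(10, 15, 20)))
#' @export
summarize_reductions <- function(changes, n_organizations = NA_integer_) {
  x <- changes$proportional_change
  if (length(x) == 0) {
    return(tibble::tibble(
      n_organizations = n_organizations, count = 0L,
      median = NA_real_, iqr_low = NA_real_, iqr_high = NA_real_,
      range_low = NA_real_, range_high = NA_real_
    ))
  }
  if (any(x <= 0 | x > 100)) {
    abort("Proportional changes must lie in (0, 100].")
  }
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    n_organizations = n_organizations,
    count = length(x),
    median = q[2], iqr_low = q[1], iqr_high = q[3],
    range_low = min(x), range_high = max(x)
  )
}
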