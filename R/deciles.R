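#' Monthly deciles of a measure across peer organizations
#'
#' For every month of the study window, computes the nine deciles (10th to
#' 90th percentile, linear-interpolation convention) of the measure across
#' all organizations with a defined value that month. Months with fewer than
#' two defined values get missing deciles.
#'
#' @param series a measure series table from [build_measure_series()].
#' @return A tibble with `period`, `month_index`, `n_defined` and decile
#'   columns `d10` ... `d90` (nondecreasing within each month).
#' @examples
#' panel <- generate_panel(panel_config(n_practices = 20, n_months = 12))
#' series <- build_measure_series(panel$records, panel$list_sizes,
#'                                panel$products, "ome_per_1000")
#' monthly_deciles(series)
#' @export
monthly_deciles <- function(series) {
  stopifnot(all(c("org_id", "period", "value") %in% names(series)))
  probs <- seq(0.1, 0.9, by = 0.1)
  out <- series |>
    dplyr::group_by(period, month_index) |>
    dplyr::summarise(
      n_defined = sum(!is.na(value)),
      dplyr::bind_cols(setNames(
        as.list(if (sum(!is.na(value)) >= 2) {
          quantile(value, probs, na.rm = TRUE, type = 7, names = FALSE)
        } else {
          rep(NA_real_, 9)
        }),
        paste0("d", seq(10, 90, by = 10))
      )),
      .groups = "drop"
    ) |>
    dplyr::arrange(period)
  if (max(out$n_defined) < 10) {
    warn("Fewer than 10 organizations have defined values in every month; deciles will be coarse.")
  }
  out
}

#' Decile chart for one organization against its peers
#'
#' Plots the organization's monthly trace (thick red line) over the peer
#' deciles (dotted blue lines, median emphasized as a thick dashed blue
#' line), optionally marking the start month of a detected change. Besides
#' the rendered figure, the plotted arrays are returned and can be written
#' to a sidecar CSV so downstream checks can assert on data rather than
#' pixels.
#'
#' @param series measure series of all peer organizations (including `org`
#'   by default, matching a peer comparison that includes everyone; set
#'   `include_org = FALSE` to exclude it from the decile computation).
#' @param org organization id to highlight.
#' @param deciles optional precomputed [monthly_deciles()] table.
#' @param change optional one-row reduction (from [extract_reduction()]);
#'   its `start_period` is marked with a vertical line.
#' @param out_path optional figure path; the extension selects the graphics
#'   device (`.png`, `.pdf` or `.svg`). A sidecar CSV of the plotted arrays
#'   is written next to it.
#' @param include_org whether the highlighted organization contributes to
#'   the decile computation.
#' @return Invisibly, a list with `plot` (a ggplot), `data` (the plotted
#'   arrays) and the paths written (if any).
#' @export
org_chart <- function(series, org, deciles = NULL, change = NULL,
                      out_path = NULL, include_org = TRUE) {
  if (!org %in% series$org_id) {
    abort(sprintf("Organization '%s' has no series to plot.", org))
  }
  peer <- if (include_org) series else series[series$org_id != org, ]
  if (is.null(deciles)) deciles <- suppressWarnings(monthly_deciles(peer))
  org_series <- series[series$org_id == org, c("period", "month_index", "value")]
  names(org_series)[3] <- "org_value"
  data <- dplyr::left_join(deciles, org_series,
                           by = c("period", "month_index")) |>
    dplyr::arrange(period)
  marker <- if (!is.null(change) && nrow(change) == 1) {
    change$start_period
  } else {
    NA_integer_
  }
  data$change_start <- data$period == marker & !is.na(marker)

  long <- tidyr::pivot_longer(
    data, dplyr::starts_with("d"),
    names_to = "decile", values_to = "decile_value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = month_index)) +
    ggplot2::geom_line(
      ggplot2::aes(y = decile_value, group = decile),
      colour = "steelblue", linetype = "dotted", na.rm = TRUE
    ) +
    ggplot2::geom_line(
      data = data, ggplot2::aes(y = d50),
      colour = "steelblue", linetype = "dashed", linewidth = 1, na.rm = TRUE
    ) +
    ggplot2::geom_line(
      data = data, ggplot2::aes(y = org_value),
      colour = "red", linewidth = 1.2, na.rm = TRUE
    ) +
    ggplot2::labs(
      x = "Month of study window", y = series$measure_id[1] %||% "value",
      title = sprintf("%s against peer deciles", org)
    ) +
    ggplot2::theme_minimal()
  if (!is.na(marker)) {
    p <- p + ggplot2::geom_vline(
      xintercept = data$month_index[data$change_start],
      colour = "grey30", linetype = "longdash"
    )
  }

  paths <- character(0)
  if (!is.null(out_path)) {
    dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
    ggplot2::ggsave(out_path, p, width = 8, height = 5, dpi = 150)
    sidecar <- paste0(tools::file_path_sans_ext(out_path), ".csv")
    readr::write_csv(data, sidecar)
    paths <- c(figure = out_path, data = sidecar)
  }
  invisible(list(plot = p, data = data, paths = paths))
}
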