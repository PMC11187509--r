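#' Calendar period helpers
#'
#' Monthly periods are carried as `YYYYMM` integers (the NHSBSA file
#' convention) and mapped to a 1-based month index over the study window.
#' The default window is December 2014 to November 2019 (60 months).
#'
#' @param period integer vector of `YYYYMM` periods.
#' @param index integer vector of 1-based month indices.
#' @param start_period first `YYYYMM` month of the study window.
#' @param n number of consecutive months.
#'
#' @return `period_to_index()` returns integer indices, `index_to_period()`
#'   returns `YYYYMM` integers, and `period_seq()` returns the `n` consecutive
#'   `YYYYMM` periods starting at `start_period`.
#' @examples
#' period_seq(201412, 3)
#' period_to_index(201501, start_period = 201412)
#' index_to_period(60, start_period = 201412)
#' @export
period_to_index <- function(period, start_period = 201412L) {
  stopifnot(is.numeric(period), is.numeric(start_period))
  as.integer(month_number(period) - month_number(start_period) + 1L)
}

#' @rdname period_to_index
#' @export
index_to_period <- function(index, start_period = 201412L) {
  m <- month_number(start_period) + as.integer(index) - 1L
  as.integer((m %/% 12L) * 100L + (m %% 12L) + 1L)
}

#' @rdname period_to_index
#' @export
period_seq <- function(start_period = 201412L, n = 60L) {
  index_to_period(seq_len(n), start_period = start_period)
}

# absolute month count since year 0 for YYYYMM arithmetic
month_number <- function(period) {
  period <- as.integer(period)
  yr <- period %/% 100L
  mo <- period %% 100L
  if (any(mo < 1L | mo > 12L)) {
    abort("`period` must be YYYYMM with a month between 01 and 12.")
  }
  yr * 12L + (mo - 1L)
}

#' Number of organizations kept by a top-fraction cut
#'
#' The screening stage keeps organizations whose pre-reduction level is in the
#' top `fraction` of peers; with `n` peers that is `floor(fraction * n)`
#' organizations (for example the top 38 of 191 regions at 20%).
#'
#' @param n number of organizations in the reference cross-section.
#' @param fraction top fraction kept, in (0, 1).
#' @return integer count, at least 1.
#' @examples
#' top_cut_count(191, 0.2)
#' @export
top_cut_count <- function(n, fraction = 0.2) {
  stopifnot(is.numeric(n), n >= 1)
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be a single number in (0, 1).")
  }
  max(1L, as.integer(floor(fraction * n)))
}

# internal: checked fraction in [0,1]
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name))
  }
  x
}
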