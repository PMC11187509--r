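test_that("the screening cascade removes closed, small and zero-denominator organizations in order", {
  panel <- generate_panel(panel_config(
    n_practices = 16, n_months = 24, frac_closed = 0.25, frac_small = 0.125,
    frac_zero_denominator = 0.125, seed = 31
  ))
  series <- ome_series(panel)
  report <- screen_organizations(panel$statuses, panel$list_sizes, series)
  expect_s3_class(report, "screening_report")
  expect_equal(report$n_input, 16L)
  expect_equal(report$n_removed_closed, 4L)
  expect_equal(report$n_removed_small_list, 2L)
  expect_equal(report$n_removed_zero_denominator, 2L)
  expect_equal(report$n_analyzable, 8L)
  # conservation: one disposition per organization, counts sum to input
  expect_equal(nrow(report$disposition), 16L)
  expect_equal(
    report$n_analyzable + report$n_removed_closed +
      report$n_removed_small_list + report$n_removed_zero_denominator,
    report$n_input
  )
  expect_length(analyzable_orgs(report), 8L)

  # organizations in the series but missing from metadata are an error
  expect_error(
    screen_organizations(panel$statuses[-1, ], panel$list_sizes, series),
    "absent"
  )

  # regions are exempt from the closed and list-size stages
  rg <- ome_series(panel, level = "region")
  rep_rg <- screen_organizations(panel$statuses, panel$list_sizes, rg,
                                 level = "region")
  expect_equal(rep_rg$n_removed_closed, 0L)
  expect_equal(rep_rg$n_removed_small_list, 0L)
})

test_that("the zero-denominator rule is strictly more than half", {
  make_series <- function(n_zero) {
    tibble::tibble(
      org_id = "A", measure_id = "ome_per_1000",
      period = period_seq(201412, 60), month_index = 1:60,
      numerator = 100,
      denominator = c(rep(0, n_zero), rep(5000, 60 - n_zero)),
      value = ifelse(c(rep(TRUE, n_zero), rep(FALSE, 60 - n_zero)),
                     NA_real_, 20)
    )
  }
  statuses <- tibble::tibble(practice_code = "A", status = "active",
                             close_period = NA_integer_)
  list_sizes <- tibble::tibble(practice_code = "A",
                               period = period_seq(201412, 60),
                               list_size = 5000)
  removed <- screen_organizations(statuses, list_sizes, make_series(31))
  expect_equal(removed$n_removed_zero_denominator, 1L)
  expect_equal(removed$n_analyzable, 0L)
  kept <- screen_organizations(statuses, list_sizes, make_series(30))
  expect_equal(kept$n_removed_zero_denominator, 0L)
  expect_equal(kept$n_analyzable, 1L)
})

test_that("the top-starting filter keeps the top fraction with ties retained", {
  n <- 191
  series <- tibble::tibble(
    org_id = sprintf("R%03d", 1:n), measure_id = "ome_per_1000",
    period = 201601, month_index = 14,
    numerator = 1:n, denominator = 1, value = as.numeric(1:n)
  )
  changes <- tibble::tibble(
    org_id = series$org_id,
    predrop_period = 201601,
    predrop_value = series$value,
    absolute_change = 1, proportional_change = 10
  )
  kept <- select_top_starting(changes, series, fraction = 0.2)
  expect_equal(nrow(kept), 38L) # top 38 of 191 at 20%
  expect_equal(sort(kept$predrop_value), as.numeric(154:191))
  expect_equal(top_cut_count(191, 0.2), 38L)

  # an organization at the cross-sectional median is excluded
  median_org <- changes[changes$predrop_value == 96, ]
  expect_equal(nrow(select_top_starting(median_org, series)), 0L)

  # degenerate tie: when every organization is identical, all qualify
  tied <- series
  tied$value <- 50
  tied_changes <- changes
  tied_changes$predrop_value <- 50
  expect_equal(nrow(select_top_starting(tied_changes, tied)), n)

  expect_error(select_top_starting(changes, series, fraction = 1.2),
               "fraction")
  expect_error(top_cut_count(191, 0), "fraction")
})

test_that("ranking sorts by proportional then absolute change, deterministically", {
  changes <- tibble::tibble(
    org_id = c("North", "GreatY", "Heywood"),
    absolute_change = c(8.9, 8.7, 8.9),
    proportional_change = c(40, 33, 33)
  )
  rk <- rank_reductions(changes)
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$org_id, c("North", "Heywood", "GreatY"))
  # invariant to input order
  rk2 <- rank_reductions(changes[c(3, 1, 2), ])
  expect_equal(as.data.frame(rk2), as.data.frame(rk))
  # single entry and empty input
  expect_equal(rank_reductions(changes[2, ])$rank, 1L)
  empty <- rank_reductions(changes[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true("rank" %in% names(empty))
})

test_that("reduction summaries report count, median, IQR and range", {
  s <- summarize_reductions(
    tibble::tibble(proportional_change = c(10, 15, 20))
  )
  expect_equal(s$count, 3L)
  expect_equal(s$median, 15)
  expect_equal(s$range_low, 10)
  expect_equal(s$range_high, 20)
  expect_true(s$iqr_low >= s$range_low && s$iqr_high <= s$range_high)
  expect_true(s$median >= s$iqr_low && s$median <= s$iqr_high)

  single <- summarize_reductions(tibble::tibble(proportional_change = 42))
  expect_equal(c(single$median, single$range_low, single$range_high),
               c(42, 42, 42))

  none <- summarize_reductions(tibble::tibble(proportional_change = numeric(0)),
                               n_organizations = 7L)
  expect_equal(none$count, 0L)
  expect_true(is.na(none$median))

  expect_error(
    summarize_reductions(tibble::tibble(proportional_change = c(10, 120))),
    "100"
  )

  # Monte-Carlo: the sample median of a known distribution stays within
  # three standard errors of the true median (uniform on (0, 100])
  set.seed(123)
  draws <- runif(1000, 0, 100)
  s_mc <- summarize_reductions(tibble::tibble(proportional_change = draws))
  se_median <- 1 / (2 * 0.01 * sqrt(1000))
  expect_lt(abs(s_mc$median - 50), 3 * se_median)
})
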