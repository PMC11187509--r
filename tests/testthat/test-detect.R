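test_that("noiseless flat and piecewise-linear series are fitted exactly", {
  flat <- fit_broken_trend(rep(10, 40))
  expect_length(flat$breaks, 0)
  expect_equal(flat$fitted, rep(10, 40))
  expect_null(extract_reduction(flat))

  # 100 until month 29, linear decline to 70 at month 40, then flat
  y <- c(rep(100, 29), seq(100, 70, length.out = 12)[-1], rep(70, 20))
  path <- fit_broken_trend(y)
  expect_equal(path$fitted, y, tolerance = 1e-8)
  expect_equal(path$breaks, c(30, 41))
  red <- extract_reduction(path)
  expect_equal(red$start_month, 30)
  expect_equal(red$predrop_value, 100)
  expect_equal(red$end_drop_value, 70)
  expect_equal(red$proportional_change, 30)
})

test_that("noiseless injected step and ramp are recovered exactly end to end", {
  stepped <- generate_panel(
    noiseless_config(),
    changes = list(P00001 = change_spec("step", 30,
                                        proportional_reduction = 0.3))
  )
  red <- extract_reduction(fit_broken_trend(ome_series(stepped)))
  expect_equal(red$start_month, 30)
  expect_equal(red$proportional_change, 30, tolerance = 1e-6)

  ramped <- generate_panel(
    noiseless_config(),
    changes = list(P00001 = change_spec("ramp", 24, duration_months = 12,
                                        proportional_reduction = 0.3))
  )
  path <- fit_broken_trend(ome_series(ramped))
  expect_equal(path$breaks, c(24, 36))
  red <- extract_reduction(path)
  expect_equal(red$start_month, 24)
  expect_equal(red$proportional_change, 30, tolerance = 1e-6)
})

test_that("short-series selection agrees with the brute-force BIC oracle", {
  cfg <- detection_config(min_months = 12)
  cases <- list(
    flat = rep(10, 12),
    slope_change = c(rep(10, 5), 10 - (1:7)),
    step = c(rep(10, 6), rep(7, 6)),
    two_kinks = c(rep(10, 4), 10 - (1:4), rep(6, 4))
  )
  for (nm in names(cases)) {
    y <- cases[[nm]]
    fit <- fit_broken_trend(y, cfg)
    expect_equal(fit$breaks, oracle_breaks(y, 4:9), info = nm)
    expect_equal(fit$fitted, y, tolerance = 1e-6, info = nm)
  }
})

test_that("reduction extraction reports pre-drop to end-drop change", {
  # constant and strictly increasing paths yield no reduction
  expect_null(extract_reduction(make_path(rep(5, 30))))
  up <- make_path(c(rep(10, 10), rep(14, 20)), breaks = c(11, 12))
  expect_null(extract_reduction(up))

  # pre-drop 22.25 declining to 13.35: absolute 8.9, proportional 40%
  fitted <- c(rep(22.25, 10), seq(22.25, 13.35, length.out = 6)[-1],
              rep(13.35, 10))
  red <- extract_reduction(make_path(fitted, breaks = c(11, 16)))
  expect_equal(red$absolute_change, 8.9)
  expect_equal(red$proportional_change, 40)
  expect_equal(red$predrop_value, 22.25)
  expect_equal(red$end_drop_value, 13.35)

  # a non-positive pre-drop level has no defined proportional change
  neg <- make_path(c(rep(-2, 10), rep(-6, 10)), breaks = c(11, 12))
  expect_null(extract_reduction(neg))

  # with several episodes the largest absolute change wins
  two <- make_path(
    c(rep(20, 8), rep(18, 8), rep(8, 14)),
    breaks = c(9, 10, 17, 18)
  )
  red2 <- extract_reduction(two)
  expect_equal(red2$start_month, 17)
  expect_equal(red2$absolute_change, 10)
})

test_that("proportional change is scale invariant and monotone in depth", {
  panel <- generate_panel(
    panel_config(n_practices = 1, n_months = 60, seed = 2),
    changes = list(P00001 = change_spec("step", 30,
                                        proportional_reduction = 0.3))
  )
  s <- ome_series(panel)
  red <- extract_reduction(fit_broken_trend(s))
  scaled <- s
  scaled$value <- scaled$value * 3.7
  red_scaled <- extract_reduction(fit_broken_trend(scaled))
  expect_equal(red_scaled$proportional_change, red$proportional_change)
  expect_equal(red_scaled$absolute_change, 3.7 * red$absolute_change)

  props <- vapply(c(0.2, 0.35, 0.5, 0.8), function(depth) {
    p <- generate_panel(
      noiseless_config(),
      changes = list(P00001 = change_spec("step", 30,
                                          proportional_reduction = depth))
    )
    extract_reduction(fit_broken_trend(ome_series(p)))$proportional_change
  }, numeric(1))
  expect_equal(props, c(20, 35, 50, 80), tolerance = 1e-6)
  expect_true(all(diff(props) > 0))
})

test_that("series with too few observed months are skipped with a reason", {
  expect_error(fit_broken_trend(rep(10, 20)),
               class = "opioidtrends_too_few_months")
  # missing months are excluded from the fit
  s <- tibble::tibble(
    org_id = "A", month_index = 1:60,
    value = c(rep(10, 30), rep(NA, 25), rep(10, 5))
  )
  expect_error(fit_broken_trend(s, detection_config(min_months = 36)),
               class = "opioidtrends_too_few_months")

  panel <- generate_panel(noiseless_config(n_practices = 10, n_months = 60))
  series <- ome_series(panel)
  short <- series[series$org_id != "P00001" | series$month_index <= 20, ]
  res <- detect_changes(short)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "n_series"), 10L)
  expect_equal(attr(res, "n_no_reduction"), 9L)
  expect_equal(attr(res, "skipped")$org_id, "P00001")
})

test_that("a panel of flat noiseless series yields no change results", {
  panel <- generate_panel(noiseless_config(n_practices = 10))
  res <- detect_changes(ome_series(panel))
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "n_no_reduction"), 10L)
})
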