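test_that("configuration and change specifications are validated", {
  expect_error(panel_config(frac_closed = 1.2), "frac_closed")
  expect_error(panel_config(n_months = 6), "n_months")
  expect_error(panel_config(noise_dispersion = -1), "noise_dispersion")
  expect_error(change_spec("step", start_month = 0), "start_month")
  expect_error(change_spec("ramp", 10, duration_months = 1), "ramp")
  expect_error(change_spec("step", 10, proportional_reduction = 1.5),
               "proportional_reduction")
  # change running past the window is rejected with a message
  expect_error(
    generate_panel(
      noiseless_config(n_months = 24),
      changes = list(P00001 = change_spec("step", 24,
                                          proportional_reduction = 0.3))
    ),
    "window"
  )
  expect_error(
    generate_panel(noiseless_config(),
                   changes = list(P99999 = change_spec("step", 10,
                                                       proportional_reduction = 0.1))),
    "unknown practice"
  )
})

test_that("change multipliers follow the closed-form step and ramp curves", {
  step <- change_spec("step", 5, proportional_reduction = 0.3)
  expect_equal(change_multiplier(step, 8), c(1, 1, 1, 1, 0.7, 0.7, 0.7, 0.7))
  ramp <- change_spec("ramp", 3, duration_months = 4,
                      proportional_reduction = 0.4)
  expect_equal(change_multiplier(ramp, 8),
               c(1, 1, 0.9, 0.8, 0.7, 0.6, 0.6, 0.6))
  expect_equal(change_multiplier(change_spec("none"), 5), rep(1, 5))
})

test_that("identical configuration and seed give identical panels", {
  cfg <- panel_config(n_practices = 8, n_months = 24, frac_closed = 0.25,
                      frac_zero_denominator = 0.125, seed = 42)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1$records, p2$records)
  expect_identical(p1$list_sizes, p2$list_sizes)
  expect_identical(p1$statuses, p2$statuses)
  p3 <- generate_panel(panel_config(n_practices = 8, n_months = 24,
                                    frac_closed = 0.25,
                                    frac_zero_denominator = 0.125, seed = 43))
  expect_false(identical(p1$records, p3$records))
})

test_that("noiseless trajectories reproduce the injected change exactly", {
  base <- 50000
  # flat: every month equals the configured baseline
  flat <- generate_panel(noiseless_config(baseline_ome_per_1000 = base))
  s <- ome_series(flat)
  expect_equal(s$value, rep(base, 60))
  # measure 2 equals 100 * high-dose share, measure 3 the high-dose item rate
  expect_equal(ome_series(flat, "high_dose_pct_regular")$value, rep(10, 60))
  expect_equal(ome_series(flat, "high_dose_per_1000")$value, rep(5, 60))
  # step: baseline before, (1 - r) * baseline from the start month on
  stepped <- generate_panel(
    noiseless_config(baseline_ome_per_1000 = base),
    changes = list(P00001 = change_spec("step", 30,
                                        proportional_reduction = 0.3))
  )
  sv <- ome_series(stepped)$value
  expect_equal(sv[1:29], rep(base, 29))
  expect_equal(sv[30:60], rep(0.7 * base, 31))
})

test_that("closed and zero-denominator practices produce the expected gaps", {
  cfg <- panel_config(n_practices = 8, n_months = 24, frac_closed = 0.25,
                      frac_zero_denominator = 0.25, seed = 11)
  panel <- generate_panel(cfg)
  closed <- panel$statuses$practice_code[panel$statuses$status != "active"]
  expect_length(closed, 2L)
  for (pc in closed) {
    ls <- panel$list_sizes[panel$list_sizes$practice_code == pc, ]
    after <- ls$period > panel$statuses$close_period[
      panel$statuses$practice_code == pc
    ]
    expect_true(all(ls$list_size[after] == 0))
    expect_true(all(ls$list_size[!after] > 0))
  }
  active <- panel$statuses$practice_code[panel$statuses$status == "active"]
  ls_active <- panel$list_sizes[panel$list_sizes$practice_code %in% active, ]
  zero_frac <- tapply(ls_active$list_size == 0,
                      ls_active$practice_code, mean)
  expect_equal(sum(zero_frac > 0.5), 2L)
})

test_that("fixtures round-trip losslessly and empty panels give headers only", {
  dir <- withr::local_tempdir()
  panel <- generate_panel(panel_config(n_practices = 3, n_months = 18,
                                       frac_closed = 1 / 3, seed = 7),
                          changes = list(P00002 = change_spec(
                            "ramp", 6, duration_months = 4,
                            proportional_reduction = 0.5
                          )))
  write_panel_fixture(panel, dir)
  back <- read_panel_fixture(dir)
  expect_equal(as.data.frame(back$records), as.data.frame(panel$records))
  expect_equal(as.data.frame(back$list_sizes), as.data.frame(panel$list_sizes))
  expect_equal(as.data.frame(back$statuses), as.data.frame(panel$statuses))
  expect_equal(as.data.frame(back$region_map), as.data.frame(panel$region_map))
  expect_equal(as.data.frame(back$products), as.data.frame(panel$products))
  expect_equal(as.data.frame(back$truth), as.data.frame(panel$truth))

  empty_dir <- withr::local_tempdir()
  empty <- generate_panel(panel_config(n_practices = 0, n_months = 12))
  write_panel_fixture(empty, empty_dir)
  back0 <- read_panel_fixture(empty_dir)
  expect_equal(nrow(back0$records), 0L)
  expect_equal(nrow(back0$list_sizes), 0L)
  expect_named(back0$records,
               c("practice_code", "region_code", "period", "bnf_code",
                 "bnf_name", "items", "quantity"))
})

test_that("noisy item counts are unbiased around the deterministic trajectory", {
  # a panel of many identical practices gives independent draws of the same
  # negative-binomial month; the sample mean must sit within 3 standard
  # errors of the deterministic expectation
  cfg <- panel_config(n_practices = 1000, n_months = 12,
                      noise_dispersion = 0.1,
                      list_size_log_mean = log(7000),
                      list_size_log_sd = 1e-9, seed = 314)
  panel <- generate_panel(cfg)
  std <- panel$records[panel$records$bnf_code == "SYN0401", ]
  expect_gt(nrow(std), 11000)
  expected <- 0.9 * 50 * 7000 / 1000 # items of the standard regular opioid
  se <- stats::sd(std$items) / sqrt(nrow(std))
  expect_lt(abs(mean(std$items) - expected), 3 * se)
})
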