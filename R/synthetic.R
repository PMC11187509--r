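#' Configuration of a synthetic prescribing panel
#'
#' Describes a panel of general practices nested in regions, observed monthly
#' over a study window, in the shape of the published NHSBSA dispensing files
#' (one row per product per organization per month, with item and quantity
#' counts). The defaults emulate a 60-month window (December 2014 to November
#' 2019) of practice-level opioid prescribing: list sizes are lognormal,
#' dispensing counts are overdispersed (negative binomial) around a
#' deterministic trajectory, and a configurable share of practices is closed
#' or dormant, below the 2000-patient list-size threshold, or has zero
#' population denominators in more than half of the months.
#'
#' The bulk list-size distribution is truncated below at 2000 patients so the
#' share of small practices is controlled by `frac_small` alone.
#'
#' @param n_practices number of practices (may be 0 for an empty panel).
#' @param n_regions number of regions (practices are assigned round-robin).
#' @param n_months study window length in months (>= 12, default 60).
#' @param start_period first calendar month of the window as `YYYYMM`.
#' @param baseline_ome_per_1000 baseline total oral morphine equivalence in mg
#'   per 1000 registered patients per month.
#' @param baseline_regular_items_rate baseline regular (long-acting) opioid
#'   items per 1000 patients per month.
#' @param high_dose_share fraction of regular opioid items that are high dose.
#' @param noise_dispersion negative-binomial overdispersion of item counts
#'   (variance = mu + dispersion * mu^2); 0 gives the noiseless deterministic
#'   trajectory (non-integer counts).
#' @param list_size_log_mean,list_size_log_sd parameters of the lognormal
#'   list-size distribution.
#' @param frac_closed fraction of practices closed or dormant part-way
#'   through the window.
#' @param frac_small fraction of practices with list size below 2000.
#' @param frac_zero_denominator fraction of practices given zero list size in
#'   more than half of the months.
#' @param seed integer random seed; identical configuration and seed give
#'   identical panels.
#' @return An object of class `panel_config` (a validated list).
#' @examples
#' cfg <- panel_config(n_practices = 5, n_months = 24, seed = 42)
#' @export
panel_config <- function(n_practices = 100,
                         n_regions = 10,
                         n_months = 60,
                         start_period = 201412L,
                         baseline_ome_per_1000 = 50000,
                         baseline_regular_items_rate = 50,
                         high_dose_share = 0.1,
                         noise_dispersion = 0.02,
                         list_size_log_mean = log(7000),
                         list_size_log_sd = 0.45,
                         frac_closed = 0,
                         frac_small = 0,
                         frac_zero_denominator = 0,
                         seed = 1L) {
  cfg <- list(
    n_practices = as.integer(n_practices),
    n_regions = as.integer(n_regions),
    n_months = as.integer(n_months),
    start_period = as.integer(start_period),
    baseline_ome_per_1000 = baseline_ome_per_1000,
    baseline_regular_items_rate = baseline_regular_items_rate,
    high_dose_share = check_fraction(high_dose_share, "high_dose_share"),
    noise_dispersion = noise_dispersion,
    list_size_log_mean = list_size_log_mean,
    list_size_log_sd = list_size_log_sd,
    frac_closed = check_fraction(frac_closed, "frac_closed"),
    frac_small = check_fraction(frac_small, "frac_small"),
    frac_zero_denominator = check_fraction(
      frac_zero_denominator, "frac_zero_denominator"
    ),
    seed = as.integer(seed)
  )
  if (cfg$n_practices < 0) abort("`n_practices` must be >= 0.")
  if (cfg$n_regions < 1) abort("`n_regions` must be >= 1.")
  if (cfg$n_months < 12) abort("`n_months` must be >= 12.")
  if (cfg$baseline_ome_per_1000 <= 0 || cfg$baseline_regular_items_rate <= 0) {
    abort("Baseline rates must be positive.")
  }
  if (cfg$noise_dispersion < 0) abort("`noise_dispersion` must be >= 0.")
  structure(cfg, class = "panel_config")
}

#' Specify an injected prescribing change
#'
#' A change is `"none"`, a `"step"` (a sudden drop completed within one
#' month), or a `"ramp"` (a gradual, smooth transition interpolated linearly
#' over several months). The change multiplies all of a practice's opioid
#' prescribing, so its total OME per 1000 patients falls from the baseline to
#' `(1 - proportional_reduction)` times the baseline.
#'
#' @param kind `"none"`, `"step"` or `"ramp"`.
#' @param start_month 1-based month index at which the change begins.
#' @param duration_months months over which the change completes (1 for a
#'   step, > 1 for a ramp).
#' @param proportional_reduction fraction of baseline removed, in \[0, 1\].
#' @return An object of class `change_spec`.
#' @examples
#' change_spec("step", start_month = 30, proportional_reduction = 0.3)
#' change_spec("ramp", start_month = 24, duration_months = 12,
#'             proportional_reduction = 0.5)
#' @export
change_spec <- function(kind = c("none", "step", "ramp"),
                        start_month = NA_integer_,
                        duration_months = if (kind == "step") 1L else NA_integer_,
                        proportional_reduction = 0) {
  kind <- match.arg(kind)
  if (kind == "none") {
    return(structure(
      list(kind = "none", start_month = NA_integer_,
           duration_months = NA_integer_, proportional_reduction = 0),
      class = "change_spec"
    ))
  }
  start_month <- as.integer(start_month)
  duration_months <- as.integer(duration_months)
  if (is.na(start_month) || start_month < 1) {
    abort("`start_month` must be a positive month index.")
  }
  if (is.na(duration_months) || duration_months < 1) {
    abort("`duration_months` must be >= 1.")
  }
  if (kind == "step" && duration_months != 1L) {
    abort("A step change has `duration_months = 1`.")
  }
  if (kind == "ramp" && duration_months < 2L) {
    abort("A ramp change has `duration_months > 1`.")
  }
  check_fraction(proportional_reduction, "proportional_reduction")
  structure(
    list(kind = kind, start_month = start_month,
         duration_months = duration_months,
         proportional_reduction = proportional_reduction),
    class = "change_spec"
  )
}

#' Deterministic change multiplier over the study window
#'
#' Returns the month-by-month multiplier implied by a [change_spec()]: 1
#' before the change starts, `1 - proportional_reduction` after it completes,
#' and a linear interpolation in between (a step completes in its first
#' month).
#'
#' @param spec a [change_spec()].
#' @param n_months window length.
#' @return numeric vector of length `n_months`.
#' @examples
#' change_multiplier(change_spec("step", 5, proportional_reduction = 0.3), 8)
#' @export
change_multiplier <- function(spec, n_months) {
  stopifnot(inherits(spec, "change_spec"))
  t <- seq_len(n_months)
  if (spec$kind == "none") {
    return(rep(1, n_months))
  }
  if (spec$start_month + spec$duration_months > n_months) {
    abort(sprintf(
      "Change runs past the window: start %d + duration %d > %d months.",
      spec$start_month, spec$duration_months, n_months
    ))
  }
  r <- spec$proportional_reduction
  frac_done <- pmin(pmax((t - spec$start_month + 1) / spec$duration_months, 0), 1)
  1 - r * frac_done
}

# Synthetic product book: one product per (opioid class x high-dose flag x
# regular flag). The standard-product OME factor is solved so that the
# noiseless total OME per 1000 patients equals the configured baseline.
synthetic_products <- function(config) {
  rate <- config$baseline_regular_items_rate
  h <- config$high_dose_share
  hd <- list(units = 56, ome_unit = 60) # e.g. 60 mg MR morphine tds
  std <- list(units = 56)
  bt <- list(units = 30, ome_unit = 5, rate_mult = 0.3)
  non <- list(units = 28, rate = 100)
  residual_ome <- config$baseline_ome_per_1000 -
    h * rate * hd$units * hd$ome_unit -
    bt$rate_mult * rate * bt$units * bt$ome_unit
  if (h < 1 && residual_ome <= 0) {
    abort(paste0(
      "Infeasible baseline: high-dose and breakthrough products alone exceed ",
      "`baseline_ome_per_1000`; raise the baseline or lower the rates."
    ))
  }
  std_ome_unit <- if (h < 1) residual_ome / ((1 - h) * rate * std$units) else 0
  tibble::tibble(
    bnf_code = c("SYN0401", "SYN0402", "SYN0403", "SYN0901"),
    name = c(
      "Synthetic regular opioid (standard dose)",
      "Synthetic regular opioid (high dose)",
      "Synthetic breakthrough opioid",
      "Synthetic non-opioid"
    ),
    is_opioid = c(TRUE, TRUE, TRUE, FALSE),
    ome_per_unit_mg = c(std_ome_unit, hd$ome_unit, bt$ome_unit, 0),
    is_regular = c(TRUE, TRUE, FALSE, FALSE),
    ome_per_day_mg = c(60, 180, 0, 0),
    units_per_item = c(std$units, hd$units, bt$units, non$units),
    items_per_1000 = c(
      (1 - h) * rate, h * rate, bt$rate_mult * rate, non$rate
    ),
    scales_with_change = c(TRUE, TRUE, TRUE, FALSE)
  )
}

#' Generate a synthetic prescribing panel with known injected changes
#'
#' Simulates a monthly dispensing panel for `config$n_practices` practices
#' over `config$n_months` months and returns the prescribing records, list
#' sizes, practice statuses, practice-to-region map, product reference and
#' the per-practice ground truth of injected changes.
#'
#' For each practice and month the deterministic trajectory is the baseline
#' scaled by the practice's [change_multiplier()]; observed item counts are
#' negative-binomial draws around it (or the trajectory itself when
#' `noise_dispersion = 0`, in which case counts may be non-integer so that
#' the noiseless trajectory is exact). Closed or dormant practices emit zero
#' items and zero list size after their closure month; zero-denominator
#' practices are given zero list size in 60% of months.
#'
#' @param config a [panel_config()].
#' @param changes named list of [change_spec()] objects keyed by practice
#'   code (codes are `P00001`, `P00002`, ...). Practices not named get
#'   `kind = "none"`.
#' @return A list of class `prescribing_panel` with elements `records`,
#'   `list_sizes`, `statuses`, `region_map`, `products`, `truth`, `config`.
#' @examples
#' panel <- generate_panel(
#'   panel_config(n_practices = 2, n_months = 24, noise_dispersion = 0),
#'   changes = list(P00001 = change_spec("step", 12, proportional_reduction = 0.3))
#' )
#' panel$truth
#' @export
generate_panel <- function(config, changes = list()) {
  stopifnot(inherits(config, "panel_config"))
  n <- config$n_practices
  m <- config$n_months
  codes <- if (n > 0) sprintf("P%05d", seq_len(n)) else character(0)
  bad <- setdiff(names(changes), codes)
  if (length(bad) > 0) {
    abort(paste0(
      "Changes assigned to unknown practices: ", paste(bad, collapse = ", ")
    ))
  }
  for (cs in changes) {
    stopifnot(inherits(cs, "change_spec"))
    if (cs$kind != "none" && cs$start_month + cs$duration_months > m) {
      abort(sprintf(
        "Invalid change: start %d + duration %d exceeds the %d-month window.",
        cs$start_month, cs$duration_months, m
      ))
    }
  }

  set.seed(config$seed)
  products <- synthetic_products(config)
  periods <- period_seq(config$start_period, m)

  # practice roles: closed/dormant first, then small, then zero-denominator,
  # mutually exclusive so composition counts are exact
  n_closed <- round(config$frac_closed * n)
  n_small <- round(config$frac_small * n)
  n_zero <- round(config$frac_zero_denominator * n)
  if (n_closed + n_small + n_zero > n) {
    abort("frac_closed + frac_small + frac_zero_denominator exceed the panel.")
  }
  role <- rep("typical", n)
  idx <- if (n > 0) sample.int(n) else integer(0)
  role[idx[seq_len(n_closed)]] <- "closed"
  role[idx[n_closed + seq_len(n_small)]] <- "small"
  role[idx[n_closed + n_small + seq_len(n_zero)]] <- "zero_denom"

  # list sizes: bulk lognormal truncated below the 2000-patient threshold
  p0 <- plnorm(2000, config$list_size_log_mean, config$list_size_log_sd)
  base_list <- round(qlnorm(
    runif(n, p0, 1), config$list_size_log_mean, config$list_size_log_sd
  ))
  base_list[role == "small"] <- round(runif(sum(role == "small"), 800, 1999))

  close_lo <- max(2L, ceiling(m / 5))
  close_hi <- max(close_lo, m - ceiling(m / 5))
  close_month <- rep(NA_integer_, n)
  close_month[role == "closed"] <- sample(
    seq(close_lo, close_hi), sum(role == "closed"), replace = TRUE
  )
  status <- rep("active", n)
  status[role == "closed"] <- sample(
    c("closed", "dormant"), sum(role == "closed"), replace = TRUE
  )

  # zero-denominator practices: 60% of months (> half) with no registered
  # population; the final month is kept nonzero so the list-size screen uses
  # a real value
  n_zero_months <- floor(0.6 * m)
  zero_month_sets <- lapply(seq_len(n), function(i) {
    if (role[i] == "zero_denom") {
      sort(sample(seq_len(m - 1), n_zero_months))
    } else {
      integer(0)
    }
  })

  practices <- tibble::tibble(
    practice_code = codes,
    region_code = if (n > 0) {
      sprintf("R%03d", ((seq_len(n) - 1L) %% config$n_regions) + 1L)
    } else {
      character(0)
    },
    status = status,
    close_month = close_month,
    base_list = base_list
  )

  # month-level grid with list size and change multiplier
  mult <- matrix(1, nrow = n, ncol = m)
  for (code in names(changes)) {
    i <- match(code, codes)
    mult[i, ] <- change_multiplier(changes[[code]], m)
  }
  grid <- tidyr::expand_grid(
    practice_code = codes,
    month_index = seq_len(m)
  )
  if (n > 0) {
    i <- match(grid$practice_code, codes)
    grid$list_size <- practices$base_list[i]
    closed_now <- !is.na(practices$close_month[i]) &
      grid$month_index > practices$close_month[i]
    grid$list_size[closed_now] <- 0
    zero_now <- mapply(
      function(j, t) t %in% zero_month_sets[[j]], i, grid$month_index
    )
    grid$list_size[zero_now] <- 0
    grid$mult <- mult[cbind(i, grid$month_index)]
  } else {
    grid$list_size <- integer(0)
    grid$mult <- numeric(0)
  }
  grid$period <- periods[grid$month_index]
  grid$region_code <- practices$region_code[match(grid$practice_code, codes)]

  # expected items per product, then overdispersed draws
  records <- purrr::map_dfr(seq_len(nrow(products)), function(k) {
    p <- products[k, ]
    mu <- p$items_per_1000 * grid$list_size / 1000 *
      (if (p$scales_with_change) grid$mult else 1)
    items <- if (config$noise_dispersion > 0) {
      as.numeric(rnbinom(length(mu), size = 1 / config$noise_dispersion, mu = mu))
    } else {
      mu
    }
    tibble::tibble(
      practice_code = grid$practice_code,
      region_code = grid$region_code,
      period = grid$period,
      bnf_code = p$bnf_code,
      bnf_name = p$name,
      items = items,
      quantity = items * p$units_per_item
    )
  })
  records <- dplyr::filter(records, items > 0)
  records <- dplyr::arrange(records, practice_code, period, bnf_code)

  list_sizes <- tibble::tibble(
    practice_code = grid$practice_code,
    period = grid$period,
    list_size = grid$list_size
  )

  statuses <- tibble::tibble(
    practice_code = codes,
    status = practices$status,
    close_period = ifelse(
      is.na(practices$close_month), NA_integer_,
      periods[pmin(practices$close_month, m)]
    )
  )

  truth <- purrr::map_dfr(codes, function(code) {
    cs <- changes[[code]] %||% change_spec("none")
    tibble::tibble(
      org_id = code,
      kind = cs$kind,
      start_month = cs$start_month,
      duration_months = cs$duration_months,
      proportional_reduction = cs$proportional_reduction,
      true_predrop_level = config$baseline_ome_per_1000,
      true_end_level = config$baseline_ome_per_1000 *
        (1 - cs$proportional_reduction)
    )
  })
  if (n == 0) {
    truth <- tibble::tibble(
      org_id = character(0), kind = character(0), start_month = integer(0),
      duration_months = integer(0), proportional_reduction = numeric(0),
      true_predrop_level = numeric(0), true_end_level = numeric(0)
    )
  }

  structure(
    list(
      records = records,
      list_sizes = list_sizes,
      statuses = statuses,
      region_map = practices[, c("practice_code", "region_code")],
      products = products[, c(
        "bnf_code", "name", "is_opioid", "ome_per_unit_mg", "is_regular",
        "ome_per_day_mg"
      )],
      truth = truth,
      config = config
    ),
    class = "prescribing_panel"
  )
}

#' @export
print.prescribing_panel <- function(x, ...) {
  cat(sprintf(
    "<prescribing_panel> %d practices x %d months, %d prescribing rows\n",
    x$config$n_practices, x$config$n_months, nrow(x$records)
  ))
  invisible(x)
}

#' Write and read a panel fixture as a set of CSV files
#'
#' `write_panel_fixture()` writes the NHSBSA-dialect prescribing CSV together
#' with the list-size, status, region-map, product-reference and ground-truth
#' CSVs; `read_panel_fixture()` reads them back. The round trip is lossless.
#'
#' @param panel a `prescribing_panel` from [generate_panel()].
#' @param dir output directory (created if needed).
#' @return `write_panel_fixture()` returns the written file paths invisibly;
#'   `read_panel_fixture()` returns a list with the same tabular elements as
#'   [generate_panel()] (without the generating `config`).
#' @export
write_panel_fixture <- function(panel, dir) {
  stopifnot(inherits(panel, "prescribing_panel") || is.list(panel))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("Cannot create directory '%s'.", dir))
  paths <- c(
    prescribing = file.path(dir, "prescribing.csv"),
    list_sizes = file.path(dir, "list_sizes.csv"),
    statuses = file.path(dir, "statuses.csv"),
    region_map = file.path(dir, "region_map.csv"),
    products = file.path(dir, "products.csv"),
    ground_truth = file.path(dir, "ground_truth.csv")
  )
  readr::write_csv(panel$records, paths[["prescribing"]], na = "")
  readr::write_csv(panel$list_sizes, paths[["list_sizes"]], na = "")
  readr::write_csv(panel$statuses, paths[["statuses"]], na = "")
  readr::write_csv(panel$region_map, paths[["region_map"]], na = "")
  readr::write_csv(panel$products, paths[["products"]], na = "")
  readr::write_csv(panel$truth, paths[["ground_truth"]], na = "")
  invisible(paths)
}

#' @rdname write_panel_fixture
#' @export
read_panel_fixture <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("No such fixture directory '%s'.", dir))
  list(
    records = readr::read_csv(
      file.path(dir, "prescribing.csv"),
      col_types = readr::cols(
        practice_code = readr::col_character(),
        region_code = readr::col_character(),
        period = readr::col_integer(),
        bnf_code = readr::col_character(),
        bnf_name = readr::col_character(),
        items = readr::col_double(),
        quantity = readr::col_double()
      )
    ),
    list_sizes = readr::read_csv(
      file.path(dir, "list_sizes.csv"),
      col_types = readr::cols(
        practice_code = readr::col_character(),
        period = readr::col_integer(),
        list_size = readr::col_double()
      )
    ),
    statuses = readr::read_csv(
      file.path(dir, "statuses.csv"),
      col_types = readr::cols(
        practice_code = readr::col_character(),
        status = readr::col_character(),
        close_period = readr::col_integer()
      )
    ),
    region_map = readr::read_csv(
      file.path(dir, "region_map.csv"),
      col_types = readr::cols(
        practice_code = readr::col_character(),
        region_code = readr::col_character()
      )
    ),
    products = read_product_ref(file.path(dir, "products.csv")),
    truth = readr::read_csv(
      file.path(dir, "ground_truth.csv"),
      col_types = readr::cols(
        org_id = readr::col_character(),
        kind = readr::col_character(),
        start_month = readr::col_integer(),
        duration_months = readr::col_integer(),
        proportional_reduction = readr::col_double(),
        true_predrop_level = readr::col_double(),
        true_end_level = readr::col_double()
      )
    )
  )
}
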