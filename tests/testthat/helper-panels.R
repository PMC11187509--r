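# shared builders for synthetic fixtures; everything is generated in code

noiseless_config <- function(n_practices = 1, n_months = 60, seed = 1, ...) {
  panel_config(
    n_practices = n_practices, n_months = n_months,
    noise_dispersion = 0, seed = seed, ...
  )
}

ome_series <- function(panel, measure_id = "ome_per_1000",
                       level = "practice") {
  build_measure_series(
    panel$records, panel$list_sizes, panel$products,
    measure_id = measure_id, level = level, region_map = panel$region_map
  )
}

# hand-built fitted path for extraction tests
make_path <- function(fitted, breaks = integer(0), beta = 0) {
  list(
    org_id = "ORG1", measure_id = "ome_per_1000",
    months = seq_along(fitted),
    periods = index_to_period(seq_along(fitted)),
    values = fitted, fitted = fitted, breaks = breaks,
    coefficients = c(mu = fitted[1], beta = beta),
    n_obs = length(fitted)
  )
}

# brute-force best-subset (up to two breaks) minimizing BIC over the same
# trimmed candidate range the fitting procedure uses; independent oracle for
# short-series model selection
oracle_breaks <- function(y, cand) {
  tt <- seq_along(y)
  n <- length(y)
  basis <- function(set) {
    vapply(set, function(j) ifelse(tt >= j, tt - j + 1, 0), numeric(n))
  }
  sets <- c(
    list(integer(0)), as.list(cand),
    utils::combn(cand, 2, simplify = FALSE)
  )
  best <- integer(0)
  best_bic <- Inf
  for (set in sets) {
    X <- cbind(1, tt, if (length(set) > 0) basis(set))
    rss <- sum(stats::lm.fit(X, y)$residuals^2)
    bic <- n * log(max(rss, 1e-12) / n) + (2 + length(set)) * log(n)
    if (bic < best_bic - 1e-9) {
      best <- set
      best_bic <- bic
    }
  }
  sort(best)
}
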