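#' Change-detection configuration
#'
#' Settings for the broken-linear-trend (trend-indicator-saturation) fit. A
#' candidate slope-change indicator is placed at every observed month at
#' least three months from either end of the series; candidates are
#' partitioned into `n_blocks` contiguous blocks and pruned by backward
#' elimination at significance `alpha` within each block, after which a
#' final joint selection over the pooled survivors (and over all one-event
#' models) picks the break set by an event-penalized BIC; see
#' [fit_broken_trend()] for the full procedure.
#'
#' @param alpha two-sided significance level for retaining an indicator
#'   (default 0.01).
#' @param n_blocks number of contiguous candidate blocks (default 4).
#' @param min_episode_months minimum length of a reduction episode in
#'   calendar months spanned, from the pre-drop month to the end-drop month
#'   inclusive (default 2, so a one-month step — which spans two calendar
#'   months — qualifies).
#' @param max_candidates optional cap on the number of candidate break
#'   months; when exceeded, candidates are thinned evenly. `NULL` (default)
#'   keeps all interior months.
#' @param min_months minimum number of non-missing months a series needs to
#'   be fitted (default 24); shorter series are skipped.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(alpha = 0.01, n_blocks = 4,
                             min_episode_months = 2,
                             max_candidates = NULL,
                             min_months = 24) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  if (n_blocks < 1) abort("`n_blocks` must be >= 1.")
  if (min_episode_months < 2) abort("`min_episode_months` must be >= 2.")
  structure(
    list(
      alpha = alpha,
      n_blocks = as.integer(n_blocks),
      min_episode_months = as.integer(min_episode_months),
      max_candidates = if (is.null(max_candidates)) NULL else as.integer(max_candidates),
      min_months = as.integer(min_months)
    ),
    class = "detection_config"
  )
}

# sloped break indicators: column j is (t - j + 1) * 1[t >= j], which changes
# the trend slope from month j onward (with an immediate unit effect at j,
# so a one-month level shift is the sum of two adjacent indicators)
trend_basis <- function(tt, breaks) {
  vapply(breaks, function(j) ifelse(tt >= j, tt - j + 1, 0),
         numeric(length(tt)))
}

# least squares with rank handling; se is NA for aliased columns
ols_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  p <- ncol(X)
  res <- fit$residuals
  df <- length(y) - r
  rss <- sum(res^2)
  sigma <- if (df > 0) sqrt(rss / df) else 0
  se <- rep(NA_real_, p)
  if (r > 0) {
    piv <- fit$qr$pivot[seq_len(r)]
    R <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
    R[lower.tri(R)] <- 0
    xtx_inv <- chol2inv(R)
    se[piv] <- sqrt(pmax(diag(xtx_inv), 0)) * sigma
  }
  list(coef = fit$coefficients, se = se, sigma = sigma, df = df,
       fitted = y - res)
}

# two-sided p-values for the break coefficients, with a guard for (near-)
# exact fits: when the residual scale is numerically zero the usual t
# statistics are undefined, so indicators with a numerically zero
# coefficient are removable (p = 1) and the rest are kept (p = 0).
# Aliased (collinear) columns get p > 1 so they are removed first.
break_pvalues <- function(fit, idx, y_scale) {
  coef <- fit$coef[idx]
  se <- fit$se[idx]
  sigma_eps <- 1e-8 + 1e-7 * y_scale
  coef_eps <- 1e-8 + 1e-6 * y_scale
  if (fit$sigma < sigma_eps || fit$df == 0) {
    p <- ifelse(abs(coef) > coef_eps, 0, 1)
  } else {
    tstat <- coef / se
    p <- 2 * pt(-abs(tstat), fit$df)
  }
  p[is.na(coef) | (!is.finite(se) & fit$sigma >= sigma_eps)] <- 1.5
  p[is.na(p)] <- 1.5
  p
}

# backward elimination of break indicators at level alpha, keeping the
# intercept and base trend throughout
eliminate_breaks <- function(y, tt, cand, alpha, y_scale) {
  cand <- sort(cand)
  while (length(cand) > 0) {
    X <- cbind(1, tt, trend_basis(tt, cand))
    fit <- ols_fit(X, y)
    p <- break_pvalues(fit, idx = 2 + seq_along(cand), y_scale = y_scale)
    worst <- which.max(p)
    if (p[worst] < alpha) break
    cand <- cand[-worst]
  }
  cand
}

# number of distinct change events in a break set: a run of indicators at
# consecutive months acts as one event (a level step is the sum of two
# adjacent slope indicators)
n_break_events <- function(breaks) {
  if (length(breaks) == 0) return(0L)
  sum(diff(sort(breaks)) > 1L) + 1L
}

# largest run of adjacent indicators in a break set
max_event_size <- function(breaks) {
  if (length(breaks) == 0) return(0L)
  event <- cumsum(c(TRUE, diff(sort(breaks)) > 1L))
  max(tabulate(event))
}

# final joint selection among the pooled block survivors: candidate models
# are the backward-deletion path (dropping the least significant indicator
# each step, down to the no-break model) plus, when the survivor set is
# small, all subsets of up to four indicators. The selected model minimizes
# a BIC penalized per change event, log(n) + 2 log(m) for each event (m =
# number of candidate months; the 2 log m term is the extreme-value scaling
# of the best chance break over m candidate positions), among models whose
# indicators are all individually significant at alpha. Chance wiggles and
# mutually offsetting indicator clusters fail the event penalty, while a
# genuine break -- even a level step whose collinear indicator pair has only
# moderate partial t-values -- pays it easily. On an exact (noise-free) fit
# the residual floor makes the sparsest interpolating model win.
select_breaks_bic <- function(y, tt, survivors, alpha, y_scale, candidates) {
  n <- length(y)
  rss_floor <- n * (1e-10 * y_scale)^2
  event_penalty <- log(n) + 2 * log(max(length(candidates), 2))
  cand <- sort(survivors)

  score <- function(set) {
    X <- cbind(1, tt, if (length(set) > 0) trend_basis(tt, set))
    fit <- ols_fit(X, y)
    rss <- sum((y - fit$fitted)^2)
    p <- if (length(set) > 0) {
      break_pvalues(fit, idx = 2 + seq_along(set), y_scale = y_scale)
    } else {
      numeric(0)
    }
    list(
      bic = n * log(max(rss, rss_floor) / n) + 2 * log(n) +
        n_break_events(set) * event_penalty,
      p = p,
      # an admissible change event is a slope change (one indicator) or a
      # level step (two adjacent indicators); longer contiguous runs add
      # flexibility that mostly fits one- or two-month noise blips
      eligible = all(p < alpha) && max_event_size(set) <= 2L
    )
  }

  best <- integer(0)
  best_bic <- score(integer(0))$bic
  consider <- function(set) {
    sc <- score(set)
    if (sc$eligible && sc$bic < best_bic) {
      best <<- set
      best_bic <<- sc$bic
    }
    sc
  }

  # backward-deletion path
  cur <- cand
  while (length(cur) > 0) {
    sc <- consider(cur)
    cur <- cur[-which.max(sc$p)]
  }
  # exhaustive small subsets: of every candidate when the series is short,
  # otherwise of the block survivors
  pool <- if (length(candidates) <= 12) sort(candidates) else cand
  if (length(pool) >= 1 && length(pool) <= 12) {
    for (k in seq_len(min(4L, length(pool)))) {
      sets <- utils::combn(pool, k, simplify = FALSE)
      for (set in sets) consider(set)
    }
  }
  # single-event scan: every admissible one-event model (a lone slope
  # change or an adjacent step pair) over the full candidate range, not
  # limited to what survived the block stage
  for (j in candidates) {
    consider(j)
    if ((j + 1L) %in% candidates) consider(c(j, j + 1L))
  }
  sort(best)
}

#' Fit a broken linear trend to one organization's measure series
#'
#' Fits `y_t = mu + beta t + sum_j gamma_j (t - j + 1) 1[t >= j]` by least
#' squares over the organization's non-missing months, where a candidate
#' break `j` sits at every interior observed month. Candidates are pruned in
#' contiguous blocks by backward elimination (drop the least significant
#' indicator until all retained have two-sided p < `alpha`), the survivors
#' of all blocks are pooled, and a final joint backward-elimination path is
#' walked down to the no-break model; the retained break set is the path
#' model with the smallest BIC among those whose indicators are all
#' individually significant at `alpha`. The BIC comparison guards against
#' mutually offsetting clusters of collinear indicators that chance noise
#' patterns would otherwise keep. The result is a piecewise-linear
#' fitted path able to track both steep, sudden drops and gradual, smooth
#' transitions over several months.
#'
#' Missing months are dropped from the design matrix (not imputed); the
#' fitted path and any episode found in it are reported in terms of the
#' observed calendar months.
#'
#' @param series one organization's series: a tibble with columns `value`
#'   and optionally `month_index`, `period`, `org_id`, `measure_id` (as
#'   produced by [build_measure_series()]), or a plain numeric vector.
#' @param config a [detection_config()].
#' @return An object of class `fitted_path`: a list with `org_id`,
#'   `measure_id`, `months`, `periods`, `values`, `fitted`, `breaks`
#'   (retained break months, in observed-month positions), `break_months`
#'   (the same in `month_index` terms), and `coefficients`.
#' @examples
#' y <- c(rep(10, 15), seq(10, 6, length.out = 6), rep(6, 9))
#' path <- fit_broken_trend(y, detection_config())
#' path$break_months
#' @export
fit_broken_trend <- function(series, config = detection_config()) {
  stopifnot(inherits(config, "detection_config"))
  if (is.numeric(series)) {
    series <- tibble::tibble(month_index = seq_along(series), value = series)
  }
  if (!"month_index" %in% names(series)) {
    series$month_index <- seq_len(nrow(series))
  }
  if (!"period" %in% names(series)) series$period <- NA_integer_
  obs <- series[!is.na(series$value), , drop = FALSE]
  obs <- obs[order(obs$month_index), , drop = FALSE]
  m <- nrow(obs)
  if (m < config$min_months) {
    abort(
      sprintf("Series has %d non-missing months; at least %d are required.",
              m, config$min_months),
      class = "opioidtrends_too_few_months"
    )
  }
  y <- obs$value
  tt <- seq_len(m)
  y_scale <- max(abs(y)) + stats::sd(y)

  # candidates are trimmed three months from either end: a break closer to
  # the boundary leaves the baseline trend essentially unidentified (its
  # outer segment has fewer than three observations), a standard trimming
  # device in structural-break estimation
  cand <- if (m >= 7) seq(4L, m - 3L) else integer(0)
  if (!is.null(config$max_candidates) &&
      length(cand) > config$max_candidates) {
    cand <- cand[unique(round(seq(1, length(cand),
                                  length.out = config$max_candidates)))]
  }
  if (length(cand) > 0) {
    nb <- min(config$n_blocks, length(cand))
    block_id <- as.integer(cut(seq_along(cand), nb, labels = FALSE))
    # second pass with half-shifted block boundaries, so that break shapes
    # needing adjacent indicators (e.g. a level step) are never split
    # between blocks in both passes
    shift <- max(1L, floor(length(cand) / nb / 2))
    block_id2 <- as.integer(cut(
      (seq_along(cand) + shift - 1L) %% length(cand), nb, labels = FALSE
    ))
    survivors <- unlist(lapply(
      c(split(cand, block_id), split(cand, block_id2)),
      function(b) eliminate_breaks(y, tt, b, config$alpha, y_scale)
    ), use.names = FALSE)
    breaks <- select_breaks_bic(y, tt, sort(unique(survivors)),
                                config$alpha, y_scale, candidates = cand)
  } else {
    breaks <- integer(0)
  }

  X <- cbind(1, tt, if (length(breaks) > 0) trend_basis(tt, breaks))
  fit <- ols_fit(X, y)
  coefs <- fit$coef
  coefs[is.na(coefs)] <- 0
  names(coefs) <- c("mu", "beta",
                    if (length(breaks) > 0) paste0("gamma_", breaks))

  structure(
    list(
      org_id = if ("org_id" %in% names(obs)) obs$org_id[[1]] else NA_character_,
      measure_id = if ("measure_id" %in% names(obs)) obs$measure_id[[1]] else NA_character_,
      months = obs$month_index,
      periods = obs$period,
      values = y,
      fitted = as.numeric(fit$fitted),
      breaks = breaks,
      break_months = obs$month_index[breaks],
      coefficients = coefs,
      sigma = fit$sigma,
      n_obs = m
    ),
    class = "fitted_path"
  )
}

#' @export
print.fitted_path <- function(x, ...) {
  cat(sprintf(
    "<fitted_path> %s: %d months, %d retained break(s)%s\n",
    x$org_id %||% "?", x$n_obs, length(x$breaks),
    if (length(x$breaks) > 0) {
      paste0(" at month(s) ", paste(x$break_months, collapse = ", "))
    } else ""
  ))
  invisible(x)
}

#' Extract the dominant sustained reduction from a fitted path
#'
#' Scans the fitted path's month-to-month slopes for reduction episodes:
#' maximal runs of negative slopes spanning at least
#' `config$min_episode_months` calendar months (from the pre-drop month to
#' the end-drop month inclusive). The pre-drop value is the fitted (not raw)
#' level immediately before the first declining month, for robustness to
#' single-month spikes; the end-drop value is the fitted level where the
#' decline ends. If several episodes qualify, the one with the largest
#' absolute change is reported (earliest wins a tie). Increases are never
#' reported — a flat or rising path yields `NULL` — and an episode whose
#' pre-drop value is not positive is discarded because its proportional
#' change is undefined.
#'
#' @param path a [fit_broken_trend()] result (or any list with `fitted`,
#'   `months`, `periods`, and optionally `org_id`, `measure_id`, `breaks`).
#' @param config a [detection_config()].
#' @return A one-row tibble with `org_id`, `measure_id`, `start_month`,
#'   `start_period`, `predrop_period`, `predrop_value`, `end_drop_value`,
#'   `absolute_change` and `proportional_change` (in percent of the pre-drop
#'   value), plus `n_breaks_retained` — or `NULL` when no qualifying
#'   reduction exists.
#' @examples
#' y <- c(rep(20, 20), rep(12, 16))
#' extract_reduction(fit_broken_trend(y, detection_config()))
#' @export
extract_reduction <- function(path, config = detection_config()) {
  fitted <- path$fitted
  if (length(fitted) < 2) return(NULL)
  months <- path$months %||% seq_along(fitted)
  periods <- path$periods %||% rep(NA_integer_, length(fitted))
  # episodes live in the break-induced component: removing the estimated
  # baseline linear trend means a path with no retained breaks has no
  # episode (a chance tilt of the base trend is not a detected change),
  # while noiseless piecewise-linear input is unaffected
  beta <- unname(path$coefficients["beta"] %||% 0)
  if (is.na(beta)) beta <- 0
  component <- fitted - beta * seq_along(fitted)
  slopes <- diff(component)
  # slopes below 5% of the steepest fitted slope are treated as flat, so a
  # statistically negligible tilt between two distinct break events cannot
  # chain them into one long episode
  tol <- 1e-8 * (1 + max(abs(fitted))) + 0.05 * max(abs(slopes))
  neg <- slopes < -tol
  if (!any(neg)) return(NULL)

  runs <- rle(neg)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  # first indicator position of each retained break event: a declining run
  # that spans several events is split at each interior event start, so the
  # drift between two events stays with the earlier episode and a later
  # event's episode begins at its own month
  breaks <- sort(path$breaks %||% integer(0))
  event_starts <- breaks[c(TRUE, diff(breaks) > 1L)]
  episodes <- purrr::map_dfr(which(runs$values), function(k) {
    p0 <- starts[k]         # first negative slope index: decline p -> p + 1
    q0 <- ends[k]           # last negative slope index
    cuts <- event_starts[event_starts - 1L > p0 & event_starts - 1L <= q0]
    seg_p <- c(p0, cuts - 1L)
    seg_q <- c(cuts - 2L, q0)
    keep <- seg_q >= seg_p
    tibble::tibble(
      p = seg_p[keep], q = seg_q[keep],
      span_months = seg_q[keep] - seg_p[keep] + 2L,
      predrop_value = fitted[seg_p[keep]],
      end_drop_value = fitted[seg_q[keep] + 1L]
    )
  })
  episodes$absolute_change <- episodes$predrop_value - episodes$end_drop_value
  episodes <- episodes[
    episodes$span_months >= config$min_episode_months &
      episodes$predrop_value > 0 &
      episodes$absolute_change > 0, , drop = FALSE
  ]
  if (nrow(episodes) == 0) return(NULL)
  best <- episodes[order(-episodes$absolute_change, episodes$p), ][1, ]

  tibble::tibble(
    org_id = path$org_id %||% NA_character_,
    measure_id = path$measure_id %||% NA_character_,
    start_month = months[best$p + 1],
    start_period = periods[best$p + 1],
    predrop_period = periods[best$p],
    predrop_value = best$predrop_value,
    end_drop_value = best$end_drop_value,
    absolute_change = best$absolute_change,
    proportional_change = 100 * best$absolute_change / best$predrop_value,
    n_breaks_retained = length(path$breaks %||% integer(0))
  )
}

#' Detect sustained reductions across a panel of organizations
#'
#' Applies [fit_broken_trend()] and [extract_reduction()] to every
#' organization in a measure series table. Organizations with too few
#' non-missing months are skipped with a logged reason; organizations whose
#' fitted path shows no qualifying reduction contribute no row but are
#' counted. The result is deterministic given the input.
#'
#' @param series a measure series table from [build_measure_series()] (one
#'   measure, one organizational level).
#' @param config a [detection_config()].
#' @return A tibble of detected reductions (see [extract_reduction()]),
#'   with attributes `skipped` (tibble of `org_id`, `reason`), `n_series`,
#'   and `n_no_reduction`.
#' @export
detect_changes <- function(series, config = detection_config()) {
  stopifnot(all(c("org_id", "value") %in% names(series)))
  orgs <- unique(series$org_id)
  skipped <- list()
  results <- list()
  n_none <- 0L
  for (org in orgs) {
    one <- series[series$org_id == org, , drop = FALSE]
    path <- tryCatch(
      fit_broken_trend(one, config),
      opioidtrends_too_few_months = function(e) e
    )
    if (inherits(path, "condition")) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(org_id = org, reason = conditionMessage(path))
      next
    }
    res <- extract_reduction(path, config)
    if (is.null(res)) {
      n_none <- n_none + 1L
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  out <- if (length(results) > 0) {
    dplyr::bind_rows(results)
  } else {
    tibble::tibble(
      org_id = character(0), measure_id = character(0),
      start_month = integer(0), start_period = integer(0),
      predrop_period = integer(0), predrop_value = numeric(0),
      end_drop_value = numeric(0), absolute_change = numeric(0),
      proportional_change = numeric(0), n_breaks_retained = integer(0)
    )
  }
  attr(out, "skipped") <- if (length(skipped) > 0) {
    dplyr::bind_rows(skipped)
  } else {
    tibble::tibble(org_id = character(0), reason = character(0))
  }
  attr(out, "n_series") <- length(orgs)
  attr(out, "n_no_reduction") <- n_none
  out
}
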