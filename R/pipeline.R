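#' Configure a full surveillance pipeline run
#'
#' Bundles everything a reproducible run needs: the input (a synthetic
#' [panel_config()] plus injected changes, or a fixture directory written by
#' [write_panel_fixture()]), the [detection_config()], and the screening
#' thresholds (2000-patient list size, 0.5 zero-denominator fraction, 0.2
#' top-starting fraction, 120 mg/day high-dose threshold). All thresholds
#' are configuration, not constants in the stage logic.
#'
#' @param panel a [panel_config()] for synthetic input (ignored when
#'   `input_dir` is given).
#' @param changes named list of [change_spec()] objects for synthetic input.
#' @param input_dir optional fixture directory to read instead of simulating.
#' @param detection a [detection_config()].
#' @param levels organizational levels to analyze.
#' @param measures measure ids to analyze (see [measure_ids()]).
#' @param min_list_size,zero_denom_frac,top_fraction,high_dose_threshold
#'   screening and measure thresholds.
#' @param seed integer seed overriding the panel config's seed (optional).
#' @param write_fixture also write the generated panel as a CSV fixture.
#' @param charts render a decile chart for the top-ranked organization of
#'   each measure and level.
#' @return An object of class `run_config`.
#' @export
run_config <- function(panel = panel_config(),
                       changes = list(),
                       input_dir = NULL,
                       detection = detection_config(),
                       levels = c("practice", "region"),
                       measures = measure_ids(),
                       min_list_size = 2000,
                       zero_denom_frac = 0.5,
                       top_fraction = 0.2,
                       high_dose_threshold = 120,
                       seed = NULL,
                       write_fixture = FALSE,
                       charts = FALSE) {
  stopifnot(inherits(panel, "panel_config"), inherits(detection, "detection_config"))
  levels <- match.arg(levels, several.ok = TRUE)
  measures <- match.arg(measures, measure_ids(), several.ok = TRUE)
  if (min_list_size <= 0 || high_dose_threshold <= 0) {
    abort("Thresholds must be positive.")
  }
  if (!is.null(seed)) panel$seed <- as.integer(seed)
  structure(
    list(
      panel = panel, changes = changes, input_dir = input_dir,
      detection = detection, levels = levels, measures = measures,
      min_list_size = min_list_size, zero_denom_frac = zero_denom_frac,
      top_fraction = top_fraction, high_dose_threshold = high_dose_threshold,
      write_fixture = isTRUE(write_fixture), charts = isTRUE(charts)
    ),
    class = "run_config"
  )
}

#' Run the full surveillance pipeline
#'
#' Executes generate (or load) -> measures -> screen -> detect -> summarize
#' -> top-starting filter -> rank -> deciles (-> charts) for every requested
#' measure and organizational level, and writes a CSV bundle plus a JSON run
#' manifest to `out_dir`. Reduction summaries cover all detected reductions
#' among analyzable organizations, before the top-starting filter; ranking
#' tables are computed after it. Outputs are staged and only moved into
#' `out_dir` when every stage succeeds, so a failing stage leaves no partial
#' bundle; identical configuration and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the `panel`, per-measure/level `results`
#'   (series, screening report, changes, summary, ranking, deciles) and the
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  staging <- tempfile("opioidtrends_run_")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  panel <- stage("input", {
    if (!is.null(config$input_dir)) {
      read_panel_fixture(config$input_dir)
    } else {
      generate_panel(config$panel, config$changes)
    }
  })
  if (config$write_fixture) {
    stage("fixture", write_panel_fixture(panel, file.path(staging, "fixture")))
  }

  results <- list()
  summary_rows <- list()
  counts <- list()
  for (level in config$levels) {
    for (measure in config$measures) {
      key <- paste(measure, level, sep = "_")
      series <- stage(paste0("measures:", key), build_measure_series(
        panel$records, panel$list_sizes, panel$products,
        measure_id = measure, level = level, region_map = panel$region_map,
        high_dose_threshold = config$high_dose_threshold
      ))
      screening <- stage(paste0("screen:", key), screen_organizations(
        panel$statuses, panel$list_sizes, series, level = level,
        min_list_size = config$min_list_size,
        zero_denom_frac = config$zero_denom_frac
      ))
      analyzable <- series[series$org_id %in% analyzable_orgs(screening), ]
      changes <- stage(paste0("detect:", key),
                       detect_changes(analyzable, config$detection))
      summary <- stage(paste0("summarize:", key), dplyr::bind_cols(
        tibble::tibble(level = level, measure_id = measure),
        summarize_reductions(changes, n_organizations = screening$n_analyzable)
      ))
      top <- stage(paste0("top_starting:", key), select_top_starting(
        changes, analyzable, fraction = config$top_fraction
      ))
      ranking <- stage(paste0("rank:", key), rank_reductions(top))
      deciles <- stage(paste0("deciles:", key),
                       suppressWarnings(monthly_deciles(analyzable)))

      readr::write_csv(series, file.path(staging, sprintf("measures_%s.csv", key)))
      readr::write_csv(screening$disposition,
                       file.path(staging, sprintf("screening_%s.csv", key)))
      readr::write_csv(changes, file.path(staging, sprintf("changes_%s.csv", key)))
      readr::write_csv(ranking, file.path(staging, sprintf("ranking_%s.csv", key)))
      readr::write_csv(deciles, file.path(staging, sprintf("deciles_%s.csv", key)))

      if (config$charts && nrow(ranking) > 0) {
        stage(paste0("chart:", key), org_chart(
          analyzable, ranking$org_id[1], change = ranking[1, ],
          out_path = file.path(
            staging,
            sprintf("chart_%s_%s.%s", key, ranking$org_id[1],
                    if (capabilities("png")) "png" else "pdf")
          )
        ))
      }

      skipped <- attr(changes, "skipped")
      counts[[key]] <- list(
        level = level, measure = measure,
        n_input = screening$n_input,
        n_removed_closed = screening$n_removed_closed,
        n_removed_small_list = screening$n_removed_small_list,
        n_removed_zero_denominator = screening$n_removed_zero_denominator,
        n_analyzable = screening$n_analyzable,
        n_skipped_short_series = nrow(skipped),
        n_with_reduction = nrow(changes),
        n_without_reduction = attr(changes, "n_no_reduction"),
        n_top_starting = nrow(top)
      )
      summary_rows[[key]] <- summary
      results[[key]] <- list(
        series = series, screening = screening, changes = changes,
        summary = summary, ranking = ranking, deciles = deciles
      )
    }
  }

  summary_stats <- dplyr::bind_rows(summary_rows)
  readr::write_csv(summary_stats, file.path(staging, "summary_stats.csv"))

  manifest <- list(
    package = "opioidtrends",
    version = as.character(utils::packageVersion("opioidtrends")),
    seed = config$panel$seed,
    panel_config = unclass(config$panel),
    detection_config = unclass(config$detection),
    thresholds = list(
      min_list_size = config$min_list_size,
      zero_denom_frac = config$zero_denom_frac,
      top_fraction = config$top_fraction,
      high_dose_threshold = config$high_dose_threshold
    ),
    stage_counts = counts
  )
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list.files(staging, recursive = TRUE)
  for (f in files) {
    dir.create(dirname(file.path(out_dir, f)), showWarnings = FALSE,
               recursive = TRUE)
    file.copy(file.path(staging, f), file.path(out_dir, f), overwrite = TRUE)
  }

  invisible(list(panel = panel, results = results,
                 summary_stats = summary_stats, manifest = manifest))
}
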