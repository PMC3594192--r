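#' Run the full in-silico study
#'
#' Orchestrates the whole analysis for both experimental conditions:
#' simulate pulling experiments, extract rupture events, apply the
#' multiple-tether discard correction, fit the two-Gaussian rupture-force
#' model, summarise and compare the conditions, and quantify the aggregate
#' morphology time course on synthetic topographs. A single seed is expanded
#' into fixed per-stage sub-seeds so stages are independently reproducible.
#'
#' @param seed Master integer seed.
#' @param n_curves Curves per condition.
#' @param control_config,copper_config Optional [simulation_config()]
#'   overrides; defaults [config_control()] / [config_copper()] with
#'   `n_curves`.
#' @param image_times Incubation time labels for the image series (hours).
#' @param image_noise_sd Pixel noise for the synthetic topographs, nm.
#' @param image_size Topograph size in pixels (10 nm pixels).
#' @return A list of class `"afs_study"`: `force_summary` (one row per
#'   condition), `comparison`, `tether` (yield / lambda / p_multi /
#'   discarded per condition), `events` (all extracted events),
#'   `timecourse` and `features` (image morphometrics), and `seed`.
#' @examples
#' \donttest{
#' st <- run_study(seed = 1, n_curves = 150)
#' st$force_summary
#' }
#' @export
run_study <- function(seed = 1, n_curves = 1000,
                      control_config = NULL, copper_config = NULL,
                      image_times = c(1, 6, 24), image_noise_sd = 0.3,
                      image_size = c(500, 500)) {
  seed <- as.integer(seed)
  if (is.null(control_config)) {
    control_config <- config_control(seed = seed + 101L,
                                     n_curves = n_curves)
  }
  if (is.null(copper_config)) {
    copper_config <- config_copper(seed = seed + 202L, n_curves = n_curves)
  }

  conditions <- list(control = control_config, copper = copper_config)
  events <- list()
  summaries <- list()
  tether <- list()
  for (nm in names(conditions)) {
    cfg <- conditions[[nm]]
    ex <- simulate_experiment(cfg)
    ev <- analyze_curves(ex)
    ev$condition <- nm
    events[[nm]] <- ev
    res <- condition_statistics(ev, n_curves = cfg$n_curves, condition = nm)
    summaries[[nm]] <- res$summary
    tether[[nm]] <- res$tether
  }

  force_summary <- dplyr::bind_rows(summaries)
  comparison <- compare_conditions(summaries$control, summaries$copper)

  features <- list()
  img_seed <- seed + 303L
  for (nm in names(conditions)) {
    for (t in image_times) {
      img_seed <- img_seed + 1L
      spec <- aggregation_stage_spec(nm, t, seed = img_seed)
      topo <- simulate_topograph(spec, image_size = image_size,
                                 pixel_size = 10,
                                 noise_sd = image_noise_sd,
                                 seed = img_seed + 5000L)
      ft <- analyze_topograph(topo)
      if (nrow(ft)) {
        ft$condition <- nm
        ft$time_h <- t
        features[[length(features) + 1]] <- ft
      }
    }
  }
  features <- dplyr::bind_rows(features)
  timecourse <- if (nrow(features)) {
    timecourse_summary(features)
  } else {
    tibble::tibble(condition = character(), time_h = numeric())
  }

  structure(
    list(
      force_summary = force_summary,
      comparison = comparison,
      tether = dplyr::bind_rows(tether),
      events = dplyr::bind_rows(events),
      features = features,
      timecourse = timecourse,
      seed = seed
    ),
    class = "afs_study"
  )
}

#' Rupture-force statistics for one condition
#'
#' The statistical chain applied to an extracted events table: specific
#' single-event forces, yield, Poisson multiple-tether probability, discard
#' of the `p * n` highest forces, double-Gaussian fit and summary row.
#'
#' @param events Events tibble from [analyze_curves()].
#' @param n_curves Total curves recorded.
#' @param condition Row label.
#' @param bin_width Histogram bin width, pN.
#' @return List with `summary` (one row), `tether` (one row: `condition`,
#'   `n_curves`, `n_specific`, `yield_pct`, `lambda`, `p_multi`,
#'   `n_discarded`), `fit` and `forces` (retained).
#' @export
condition_statistics <- function(events, n_curves, condition = "condition",
                                 bin_width = 10) {
  spec_ev <- events[events$specific, ]
  n_specific <- length(unique(spec_ev$curve_id))
  yield <- compute_yield(n_curves, n_specific)
  mt <- multi_tether_probability(yield / 100)
  forces <- spec_ev$rupture_force_pN
  retained <- discard_highest(forces, mt$p_multi)
  fit <- fit_double_gaussian(retained, bin_width = bin_width)
  list(
    summary = summarize_condition(retained, fit, n_curves = n_curves,
                                  n_specific = n_specific,
                                  condition = condition),
    tether = tibble::tibble(
      condition = condition, n_curves = n_curves, n_specific = n_specific,
      yield_pct = yield, lambda = mt$lambda, p_multi = mt$p_multi,
      n_discarded = length(forces) - length(retained)
    ),
    fit = fit,
    forces = retained
  )
}

#' @export
print.afs_study <- function(x, ...) {
  cat("<afs_study> seed", x$seed, "\n\nForce summary:\n")
  print(as.data.frame(x$force_summary), digits = 4)
  cat("\nCondition comparison:\n")
  print(as.data.frame(x$comparison), digits = 4)
  cat("\nMorphology time course:\n")
  print(as.data.frame(x$timecourse), digits = 3)
  invisible(x)
}

#' Write a study report bundle
#'
#' Plain-text outputs: `force_summary.tsv`, `comparison.tsv`,
#' `tether_correction.tsv`, `events.tsv`, `timecourse.tsv` and a
#' `provenance.txt` with package and R versions, seed and timestamp.
#'
#' @param study An `"afs_study"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
report_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(study$force_summary, file.path(dir, "force_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$comparison, file.path(dir, "comparison.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$tether, file.path(dir, "tether_correction.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$events, file.path(dir, "events.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$timecourse, file.path(dir, "timecourse.tsv"),
                   progress = FALSE)
  writeLines(c(
    sprintf("package: smforce %s",
            as.character(utils::packageVersion("smforce"))),
    sprintf("R: %s", R.version.string),
    sprintf("seed: %d", study$seed),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), file.path(dir, "provenance.txt"))
  invisible(dir)
}
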