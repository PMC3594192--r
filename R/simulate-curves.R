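#' Simulate one force-distance cycle
#'
#' Builds a synthetic approach/retract force curve on a regular piezo grid.
#' The approach shows a hard-contact region of slope equal to the spring
#' constant below the contact point (z = 0). The retract carries a linear
#' baseline tilt plus Gaussian force noise and, for every tether event, a
#' worm-like-chain force branch. Each branch is computed against true tether
#' extension: at piezo position `z` the cantilever deflects by `F/k` toward
#' the surface, so the branch satisfies `F = wlc(z - F/k)`, solved by
#' parameterising in extension and interpolating onto the piezo grid. The
#' branch is truncated the moment it reaches the event's rupture force and
#' returns to baseline within one sample; multiple tethers superpose.
#'
#' @param config A [simulation_config()].
#' @param events A data frame with columns `force_pN` and `Lc_nm`, one row
#'   per tether attached during this cycle; zero rows (or `NULL`) simulates a
#'   non-specific cycle.
#' @param curve_id Identifier stored in the output.
#' @return A tibble with columns `curve_id`, `z_nm`, `f_approach_pN`,
#'   `f_retract_pN` (positive force = repulsive contact on approach, tether
#'   pull on retract). Acquisition metadata travels in attributes
#'   `velocity_nm_s`, `dwell_s`, `spring_constant_pN_nm`.
#' @examples
#' cfg <- simulation_config(force_noise_sd = 0, baseline_tilt = 0)
#' fc <- simulate_force_curve(cfg, data.frame(force_pN = 132, Lc_nm = 35))
#' max(fc$f_retract_pN) # ~132 pN
#' @export
simulate_force_curve <- function(config, events = NULL, curve_id = 1L) {
  dz <- config$retract_velocity / config$sample_rate
  z <- seq(config$z_min, config$z_max, by = dz)
  n <- length(z)
  contact <- pmax(0, -z) * config$spring_constant

  f_app <- contact
  if (config$force_noise_sd > 0) {
    f_app <- f_app + rnorm(n, 0, config$force_noise_sd)
  }

  f_ret <- contact + config$baseline_tilt * z
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      f_ret <- f_ret + tether_branch(
        z, events$force_pN[[i]], events$Lc_nm[[i]],
        Lp = config$persistence_length, k = config$spring_constant,
        temperature = config$temperature
      )
    }
  }
  if (config$force_noise_sd > 0) {
    f_ret <- f_ret + rnorm(n, 0, config$force_noise_sd)
  }

  out <- tibble::tibble(
    curve_id = as.integer(curve_id),
    z_nm = z,
    f_approach_pN = f_app,
    f_retract_pN = f_ret
  )
  attr(out, "velocity_nm_s") <- config$retract_velocity
  attr(out, "dwell_s") <- 0.5
  attr(out, "spring_constant_pN_nm") <- config$spring_constant
  out
}

## WLC force branch of one tether evaluated on the piezo grid; zero beyond
## the rupture point and on the surface side of the contact point
tether_branch <- function(z, rupture_force, Lc, Lp, k, temperature) {
  x_rupt <- wlc_extension(rupture_force, Lp, Lc, temperature)
  x_grid <- seq(0, x_rupt, length.out = 512)
  f_grid <- wlc_force(x_grid, Lp, Lc, temperature)
  z_grid <- x_grid + f_grid / k # piezo position including deflection
  f <- approx(z_grid, f_grid, xout = z, rule = 1)$y
  f[is.na(f)] <- 0
  f
}

#' Simulate a full pulling experiment with ground truth
#'
#' Draws a Poisson number of tether attachments for each of `n_curves`
#' approach cycles (rate `attachment_rate`), assigns each tether a rupture
#' force from the two-Gaussian mixture and a contour length from the tether
#' length distribution, and renders every cycle with
#' [simulate_force_curve()]. Contour lengths whose rupture point would fall
#' outside the scanned piezo range (or below the worm-like-chain's reach for
#' the drawn force) are resampled.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to `config$seed`. The whole experiment
#'   is bit-reproducible given the seed.
#' @return An object of class `"afs_experiment"`: a list with
#'   \describe{
#'     \item{curves}{tibble of all cycles (`curve_id`, `z_nm`,
#'       `f_approach_pN`, `f_retract_pN`)}
#'     \item{events}{ground-truth tibble, one row per tether
#'       (`curve_id`, `event`, `force_pN`, `Lc_nm`)}
#'     \item{config}{the configuration used}
#'   }
#' @examples
#' ex <- simulate_experiment(simulation_config(n_curves = 5), seed = 1)
#' ex$events
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  set.seed(seed)
  n_curves <- config$n_curves
  n_events <- rpois(n_curves, config$attachment_rate)

  max_z_rupt <- 0.9 * config$z_max
  draw_event <- function() {
    force <- simulate_rupture_forces(config, 1)
    for (try in 1:100) {
      Lc <- rnorm(1, config$tether_contour_mean, config$tether_contour_sd)
      if (Lc < 5 * config$persistence_length) next
      x_rupt <- tryCatch(
        wlc_extension(force, config$persistence_length, Lc,
                      config$temperature),
        smforce_unreachable = function(e) NULL
      )
      if (is.null(x_rupt)) next
      if (x_rupt + force / config$spring_constant < max_z_rupt) {
        return(c(force = force, Lc = Lc))
      }
    }
    abort("could not place a tether event within the scan range.",
          class = "smforce_error")
  }

  truth <- vector("list", n_curves)
  curves <- vector("list", n_curves)
  for (i in seq_len(n_curves)) {
    k <- n_events[[i]]
    if (k > 0) {
      ev <- t(vapply(seq_len(k), function(j) draw_event(), numeric(2)))
      ev_df <- tibble::tibble(
        curve_id = i, event = seq_len(k),
        force_pN = ev[, "force"], Lc_nm = ev[, "Lc"]
      )
    } else {
      ev_df <- NULL
    }
    truth[[i]] <- ev_df
    curves[[i]] <- simulate_force_curve(
      config,
      if (is.null(ev_df)) NULL else
        data.frame(force_pN = ev_df$force_pN, Lc_nm = ev_df$Lc_nm),
      curve_id = i
    )
  }

  structure(
    list(
      curves = dplyr::bind_rows(curves),
      events = if (all(vapply(truth, is.null, logical(1)))) {
        tibble::tibble(curve_id = integer(), event = integer(),
                       force_pN = numeric(), Lc_nm = numeric())
      } else {
        dplyr::bind_rows(truth)
      },
      config = config,
      seed = as.integer(seed)
    ),
    class = "afs_experiment"
  )
}

#' @export
print.afs_experiment <- function(x, ...) {
  cat(sprintf(
    "<afs_experiment> %d curves, %d tether events on %d curves (seed %d)\n",
    x$config$n_curves, nrow(x$events),
    length(unique(x$events$curve_id)), x$seed
  ))
  invisible(x)
}
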