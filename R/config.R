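#' Simulation configuration for synthetic pulling experiments
#'
#' Bundles every parameter the force-curve generator needs: the two-component
#' Gaussian rupture-force mixture, the Poisson tether-attachment rate, the
#' PEG-tether geometry, acquisition settings and noise. Defaults reproduce the
#' control condition of the study design this package models: peaks at 66 and
#' 132 pN, an attachment rate giving a ~14% specific-event yield, a 400 nm/s
#' retraction at 20 kHz sampling, and PEG(3400)+peptide tethers of ~35 nm
#' contour length.
#'
#' The mixture weights and component SDs are fixture constants (the component
#' means are the experimentally reported quantities; widths and weights are
#' plausible stand-ins chosen once), see the package vignette.
#'
#' @param seed Integer seed recorded in the config; generators use it when the
#'   caller does not override.
#' @param n_curves Number of approach/retract cycles per simulated experiment.
#' @param attachment_rate Poisson rate \eqn{\lambda} of tether attachment per
#'   approach. The default 0.155 gives an expected specific-event yield
#'   \eqn{1 - e^{-\lambda} \approx 14.4\%}.
#' @param mixture Named numeric vector `c(w1, mu1, sigma1, mu2, sigma2)`
#'   describing the rupture-force mixture in pN; `w1` is the weight of the
#'   low-force component and the components must satisfy `mu1 < mu2`.
#' @param tether_contour_mean,tether_contour_sd Mean and SD (nm) of the
#'   Gaussian contour-length distribution of the PEG+peptide tether.
#' @param persistence_length Worm-like-chain persistence length in nm.
#' @param retract_velocity Piezo approach/retract speed, nm/s.
#' @param sample_rate Acquisition rate, Hz. Together with `retract_velocity`
#'   this sets the spatial sampling (0.02 nm at the defaults), fine enough
#'   that the last sample before a rupture carries essentially the full
#'   rupture force.
#' @param force_noise_sd Additive Gaussian force noise, pN.
#' @param baseline_tilt Linear baseline slope on the retract, pN/nm.
#' @param spring_constant Cantilever spring constant, pN/nm.
#' @param temperature Bath temperature, K.
#' @param z_min,z_max Piezo range simulated, nm (contact at z = 0).
#'
#' @return A list of class `"sim_config"`.
#' @seealso [config_control()], [config_copper()], [simulate_experiment()]
#' @examples
#' cfg <- simulation_config(n_curves = 10, force_noise_sd = 0)
#' cfg$mixture
#' @export
simulation_config <- function(seed = 1L,
                              n_curves = 1000L,
                              attachment_rate = 0.155,
                              mixture = c(w1 = 0.5, mu1 = 66, sigma1 = 20,
                                          mu2 = 132, sigma2 = 30),
                              tether_contour_mean = 35,
                              tether_contour_sd = 5,
                              persistence_length = 0.38,
                              retract_velocity = 400,
                              sample_rate = 20000,
                              force_noise_sd = 3,
                              baseline_tilt = 0.05,
                              spring_constant = 30,
                              temperature = 298,
                              z_min = -10,
                              z_max = 80) {
  mixture <- as.numeric(mixture[c("w1", "mu1", "sigma1", "mu2", "sigma2")])
  names(mixture) <- c("w1", "mu1", "sigma1", "mu2", "sigma2")
  cfg <- list(
    seed = as.integer(seed),
    n_curves = as.integer(n_curves),
    attachment_rate = attachment_rate,
    mixture = mixture,
    tether_contour_mean = tether_contour_mean,
    tether_contour_sd = tether_contour_sd,
    persistence_length = persistence_length,
    retract_velocity = retract_velocity,
    sample_rate = sample_rate,
    force_noise_sd = force_noise_sd,
    baseline_tilt = baseline_tilt,
    spring_constant = spring_constant,
    temperature = temperature,
    z_min = z_min,
    z_max = z_max
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  m <- cfg$mixture
  if (anyNA(m)) abort("mixture must supply w1, mu1, sigma1, mu2, sigma2.",
                      class = "smforce_error")
  if (m[["w1"]] < 0 || m[["w1"]] > 1) {
    abort("mixture weight w1 must lie in [0, 1].", class = "smforce_error")
  }
  if (m[["sigma1"]] < 0 || m[["sigma2"]] < 0 || cfg$tether_contour_sd < 0 ||
      cfg$force_noise_sd < 0) {
    abort("standard deviations must be non-negative.", class = "smforce_error")
  }
  if (m[["mu2"]] <= m[["mu1"]]) {
    abort("mixture components must be ordered: mu2 > mu1.",
          class = "smforce_error")
  }
  if (cfg$attachment_rate < 0) {
    abort("attachment_rate (Poisson lambda) must be >= 0.",
          class = "smforce_error")
  }
  if (cfg$tether_contour_mean <= 0) {
    abort("tether_contour_mean must be positive.", class = "smforce_error")
  }
  if (cfg$spring_constant <= 0 || cfg$persistence_length <= 0) {
    abort("spring_constant and persistence_length must be positive.",
          class = "smforce_error")
  }
  if (cfg$temperature <= 0) {
    abort("temperature must be positive.", class = "smforce_error")
  }
  invisible(cfg)
}

#' Preset configurations for the two experimental conditions
#'
#' `config_control()` is the metal-free condition (rupture-force peaks at 66
#' and 132 pN, equal weights); `config_copper()` is the Cu2+ condition (peaks
#' shifted up to 83 and 164 pN, with the low-force weight reduced to 0.35,
#' reflecting the redistribution of events toward the high-force peak).
#'
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `"sim_config"` object.
#' @examples
#' config_copper(n_curves = 50)$mixture
#' @export
config_control <- function(...) {
  simulation_config(...)
}

#' @rdname config_control
#' @export
config_copper <- function(...) {
  args <- list(...)
  if (is.null(args$mixture)) {
    args$mixture <- c(w1 = 0.35, mu1 = 83, sigma1 = 20, mu2 = 164, sigma2 = 30)
  }
  do.call(simulation_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  m <- x$mixture
  cat("<sim_config>\n")
  cat(sprintf("  curves: %d  lambda: %.3f (expected yield %.1f%%)\n",
              x$n_curves, x$attachment_rate,
              100 * (1 - exp(-x$attachment_rate))))
  cat(sprintf("  mixture: %.2f N(%g, %g) + %.2f N(%g, %g) pN\n",
              m[["w1"]], m[["mu1"]], m[["sigma1"]],
              1 - m[["w1"]], m[["mu2"]], m[["sigma2"]]))
  cat(sprintf("  tether: Lc ~ N(%g, %g) nm, Lp %g nm\n",
              x$tether_contour_mean, x$tether_contour_sd,
              x$persistence_length))
  cat(sprintf("  acquisition: %g nm/s @ %g Hz, k %g pN/nm, noise %g pN\n",
              x$retract_velocity, x$sample_rate, x$spring_constant,
              x$force_noise_sd))
  invisible(x)
}
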