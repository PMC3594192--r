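#' Draw rupture forces from the two-component Gaussian mixture
#'
#' Samples i.i.d. rupture forces from
#' \eqn{w_1 N(\mu_1, \sigma_1^2) + (1 - w_1) N(\mu_2, \sigma_2^2)}, the model
#' used throughout for specific unbinding forces. Non-positive draws (possible
#' only in the far lower tail of the low-force component) are resampled so
#' that every returned force is physical.
#'
#' @param config A [simulation_config()] object; its `mixture` element defines
#'   the components.
#' @param n Number of forces to draw (>= 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of `n` forces in pN.
#' @examples
#' f <- simulate_rupture_forces(config_control(), 5, seed = 1)
#' @export
simulate_rupture_forces <- function(config, n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a positive count.", class = "smforce_error")
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  m <- config$mixture
  draw <- function(k) {
    comp <- runif(k) >= m[["w1"]] # FALSE -> component 1
    mu <- ifelse(comp, m[["mu2"]], m[["mu1"]])
    sig <- ifelse(comp, m[["sigma2"]], m[["sigma1"]])
    rnorm(k, mu, sig)
  }
  forces <- draw(n)
  bad <- forces <= 0
  while (any(bad)) {
    forces[bad] <- draw(sum(bad))
    bad <- forces <= 0
  }
  forces
}

#' Simulate a cantilever thermal deflection series
#'
#' Generates the stationary Gaussian deflection record that the thermal-tune
#' calibration consumes. By equipartition a harmonic cantilever of stiffness
#' `k` in a bath at temperature `T` fluctuates with variance
#' \eqn{\langle d^2 \rangle = k_B T / k}.
#'
#' @param spring_constant Cantilever spring constant, pN/nm (> 0).
#' @param temperature Bath temperature, K (> 0).
#' @param n_samples Length of the series.
#' @param seed Optional integer seed.
#' @return Numeric vector of deflections in nm.
#' @examples
#' d <- simulate_thermal_spectrum(30, 298, 1e4, seed = 7)
#' var(d) * 30 # ~ kBT(298)
#' @export
simulate_thermal_spectrum <- function(spring_constant, temperature = 298,
                                      n_samples = 1e5, seed = NULL) {
  if (spring_constant <= 0) {
    abort("`spring_constant` must be positive.", class = "smforce_error")
  }
  if (temperature <= 0) {
    abort("`temperature` must be positive.", class = "smforce_error")
  }
  if (!is.null(seed)) set.seed(seed)
  rnorm(n_samples, 0, sqrt(kBT(temperature) / spring_constant))
}
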