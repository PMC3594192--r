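#' Worm-like-chain force (Marko-Siggia interpolation)
#'
#' Entropic restoring force of a semi-flexible polymer stretched to extension
#' `x`, in the widely used interpolation
#' \deqn{F(x) = \frac{k_B T}{L_p}\left[\frac{1}{4(1 - x/L_c)^2} - \frac14 +
#'   \frac{x}{L_c}\right]}
#' which is exact at both the low-force and the divergent high-force limits.
#' `F` is strictly increasing in `x` and diverges as `x` approaches the
#' contour length `Lc`.
#'
#' @param x Extension, nm. Vectorised; each value must satisfy
#'   `0 <= x < Lc`.
#' @param Lp Persistence length, nm (> 0).
#' @param Lc Contour length, nm (> 0).
#' @param temperature Temperature in K (default 298, i.e. kBT ~ 4.11 pN nm).
#' @return Force in pN, same length as `x`.
#' @examples
#' wlc_force(15, Lp = 0.38, Lc = 30) # ~13.5 pN
#' @export
wlc_force <- function(x, Lp, Lc, temperature = 298) {
  if (Lp <= 0 || Lc <= 0) {
    abort("`Lp` and `Lc` must be positive.", class = "smforce_error")
  }
  if (any(x < 0) || any(x >= Lc)) {
    abort("extension must satisfy 0 <= x < Lc.", class = "smforce_error")
  }
  t <- x / Lc
  (kBT(temperature) / Lp) * (1 / (4 * (1 - t)^2) - 0.25 + t)
}

## inverse of wlc_force in x for a single force value (root solve on (0, Lc))
wlc_extension <- function(force, Lp, Lc, temperature = 298) {
  if (force <= 0) return(0)
  upper <- Lc * (1 - 1e-7)
  f_hi <- wlc_force(upper, Lp, Lc, temperature)
  if (force >= f_hi) {
    abort("rupture force not reachable below the contour length.",
          class = "smforce_unreachable")
  }
  stats::uniroot(function(x) wlc_force(x, Lp, Lc, temperature) - force,
                 lower = 0, upper = upper, tol = 1e-10)$root
}

## tether force at piezo position z, solving F = wlc(z - z0 - F/k) for the
## cantilever-deflection-corrected extension
wlc_force_at_z <- function(z, z0, Lp, Lc, spring_constant, temperature = 298) {
  x0 <- z - z0
  if (!is.finite(Lp) || !is.finite(Lc) || x0 <= 0) return(NA_real_)
  x0 <- min(x0, Lc * (1 - 1e-7))
  f_up <- wlc_force(x0, Lp, Lc, temperature)
  if (f_up <= 0) return(0)
  g <- function(F) {
    x <- min(max(z - z0 - F / spring_constant, 0), Lc * (1 - 1e-7))
    wlc_force(x, Lp, Lc, temperature) - F
  }
  stats::uniroot(g, lower = 0, upper = f_up, tol = 1e-8)$root
}

#' Fit the worm-like-chain model to a tether-stretch segment
#'
#' Least-squares fit of [wlc_force()] to an (extension, force) segment taken
#' from the contact point up to a rupture, with both the persistence length
#' and the contour length free. Minimisation uses Levenberg-Marquardt
#' ([minpack.lm::nls.lm]) with a small ladder of restarts from perturbed
#' contour-length guesses; the best residual wins.
#'
#' @param extension Tip-sample separation, nm (piezo displacement corrected
#'   for cantilever deflection by the caller).
#' @param force Tether force, pN (positive = pulling).
#' @param temperature Temperature, K.
#' @param Lp_init Initial persistence length guess, nm.
#' @param min_points Minimum number of points required in the segment.
#' @return A list with elements `Lp` (nm), `Lc` (nm), `residual` (RMS, pN)
#'   and `converged` (logical).
#' @examples
#' x <- seq(1, 28, length.out = 60)
#' f <- wlc_force(x, Lp = 0.38, Lc = 35)
#' fit_wlc(x, f)
#' @export
fit_wlc <- function(extension, force, temperature = 298, Lp_init = 0.38,
                    min_points = 15) {
  keep <- is.finite(extension) & is.finite(force) & extension >= 0
  extension <- extension[keep]
  force <- force[keep]
  if (length(extension) < min_points) {
    abort(sprintf("WLC fit needs at least %d points.", min_points),
          class = "smforce_error")
  }
  xmax <- max(extension)
  resid_fun <- function(par) {
    Lp <- par[[1]]
    Lc <- par[[2]]
    t <- pmin(extension / Lc, 1 - 1e-8)
    model <- (kBT(temperature) / Lp) * (1 / (4 * (1 - t)^2) - 0.25 + t)
    model - force
  }
  lower <- c(0.02, xmax * 1.001)
  upper <- c(10, xmax * 20)
  ## restarts: Lc initialised at a few fractions of full extension at rupture
  starts <- lapply(c(0.85, 0.75, 0.92, 0.65, 0.95), function(frac) {
    c(Lp_init, max(xmax / frac, lower[[2]] * 1.01))
  })
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, lower = lower, upper = upper, fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(list(Lp = NA_real_, Lc = NA_real_, residual = Inf,
                converged = FALSE))
  }
  list(
    Lp = best$par[[1]],
    Lc = best$par[[2]],
    residual = sqrt(best$deviance / length(force)),
    converged = best$info %in% 1:4
  )
}
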