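#' Experimental yield
#'
#' Percentage of approach cycles that produced a specific unbinding event.
#'
#' @param n_curves Total number of force curves recorded (> 0).
#' @param n_specific Number of curves with a specific event
#'   (`<= n_curves`).
#' @return Yield in percent.
#' @examples
#' compute_yield(1000, 143) # 14.3
#' @export
compute_yield <- function(n_curves, n_specific) {
  if (n_curves <= 0) {
    abort("`n_curves` must be positive.", class = "smforce_error")
  }
  if (n_specific > n_curves || n_specific < 0) {
    abort("`n_specific` must lie in [0, n_curves].", class = "smforce_error")
  }
  100 * n_specific / n_curves
}

#' Multiple-tether probability under Poisson attachment
#'
#' If tether attachments per approach are Poisson with rate \eqn{\lambda},
#' the observed yield fixes \eqn{\lambda = -\ln(1 - \mathrm{yield})}, and the
#' probability that an observed event involves two or more simultaneous
#' tethers is the conditional
#' \deqn{p = \frac{1 - e^{-\lambda}(1 + \lambda)}{1 - e^{-\lambda}}.}
#' This is the basis of the discard correction: the `p * n` highest rupture
#' forces are removed before histogramming ([discard_highest()]).
#'
#' @param yield_fraction Specific-event yield as a fraction in `[0, 1)`.
#' @return A tibble with columns `lambda` and `p_multi`.
#' @examples
#' multi_tether_probability(0.143)$p_multi # ~0.075
#' multi_tether_probability(0.221)$p_multi # ~0.12
#' @export
multi_tether_probability <- function(yield_fraction) {
  if (any(yield_fraction < 0) || any(yield_fraction >= 1)) {
    abort("`yield_fraction` must lie in [0, 1).", class = "smforce_error")
  }
  lambda <- -log(1 - yield_fraction)
  p <- ifelse(lambda == 0, 0,
              (1 - exp(-lambda) * (1 + lambda)) / (1 - exp(-lambda)))
  tibble::tibble(lambda = lambda, p_multi = p)
}

#' Discard the highest rupture forces
#'
#' Removes exactly `floor(p_multi * length(forces))` largest values — the
#' events most likely to be simultaneous multiple-tether ruptures — keeping
#' the remaining values in their original order.
#'
#' @param forces Numeric vector of rupture forces, pN (non-empty).
#' @param p_multi Multiple-tether probability in `[0, 1)`.
#' @return The retained forces.
#' @examples
#' discard_highest(1:10, 0.25) # drops 9 and 10
#' @export
discard_highest <- function(forces, p_multi) {
  if (!length(forces)) {
    abort("`forces` must be non-empty.", class = "smforce_error")
  }
  if (p_multi < 0 || p_multi >= 1) {
    abort("`p_multi` must lie in [0, 1).", class = "smforce_error")
  }
  k <- floor(p_multi * length(forces))
  if (k == 0) return(forces)
  drop_idx <- order(forces, decreasing = TRUE)[seq_len(k)]
  forces[-drop_idx]
}

#' Effective counts and standard errors of the mixture components
#'
#' The standard error quoted for each most-probable rupture force is the
#' component standard deviation divided by the square root of the effective
#' number of counts, where the effective count of a component is the total
#' number of data points multiplied by that component's area fraction.
#'
#' @param fit A [fit_double_gaussian()] result.
#' @param n Total number of data points (defaults to the fit's `n`).
#' @return A tibble with one row per component: `component`, `n_eff`, `se_pN`.
#' @examples
#' \dontrun{effective_counts_se(fit)}
#' @export
effective_counts_se <- function(fit, n = fit$n) {
  if (n <= 0) abort("`n` must be positive.", class = "smforce_error")
  af <- fit$area_fraction
  if (any(af <= 0)) {
    abort("zero area fraction: standard error undefined for an empty component.",
          class = "smforce_error")
  }
  n_eff <- n * af
  tibble::tibble(component = seq_along(af), n_eff = n_eff,
                 se_pN = fit$sd / sqrt(n_eff))
}

#' Summarise one experimental condition
#'
#' Combines the retained rupture forces and their double-Gaussian fit into a
#' one-row table shaped like the published per-condition summary: the two
#' most probable rupture forces with effective-counts standard errors, the
#' arithmetic mean rupture force (computed on the forces given, i.e. after
#' any discard step), the low-force area fraction and, when the curve count
#' is supplied, the experimental yield.
#'
#' @param forces Retained rupture forces, pN.
#' @param fit The [fit_double_gaussian()] of these forces.
#' @param n_curves Optional total number of force curves, for the yield.
#' @param n_specific Optional number of specific curves (defaults to
#'   `length(forces)`).
#' @param condition Label for the row.
#' @return A one-row tibble.
#' @export
summarize_condition <- function(forces, fit, n_curves = NULL,
                                n_specific = length(forces),
                                condition = "condition") {
  se <- effective_counts_se(fit)
  tibble::tibble(
    condition = condition,
    n_forces = length(forces),
    peak1_pN = fit$mean[[1]], se1_pN = se$se_pN[[1]],
    peak2_pN = fit$mean[[2]], se2_pN = se$se_pN[[2]],
    mean_force_pN = mean(forces),
    area_fraction1 = fit$area_fraction[[1]],
    yield_pct = if (is.null(n_curves)) NA_real_ else
      compute_yield(n_curves, n_specific)
  )
}

#' Compare two condition summaries
#'
#' Reports the shift of each most-probable rupture force and of the
#' low-force area fraction between two conditions, with standard errors
#' combined in quadrature. For the area fraction a binomial standard error
#' `sqrt(f (1 - f) / n)` per condition is used.
#'
#' @param summary_a,summary_b One-row tibbles from [summarize_condition()]
#'   (`a` is the reference, e.g. the control).
#' @return A tibble with one row per compared quantity: `quantity`, `value_a`,
#'   `value_b`, `delta`, `se_delta`.
#' @export
compare_conditions <- function(summary_a, summary_b) {
  af_se <- function(s) sqrt(s$area_fraction1 * (1 - s$area_fraction1) /
                              s$n_forces)
  tibble::tibble(
    quantity = c("peak1_pN", "peak2_pN", "area_fraction1"),
    value_a = c(summary_a$peak1_pN, summary_a$peak2_pN,
                summary_a$area_fraction1),
    value_b = c(summary_b$peak1_pN, summary_b$peak2_pN,
                summary_b$area_fraction1),
    delta = .data$value_b - .data$value_a,
    se_delta = c(
      sqrt(summary_a$se1_pN^2 + summary_b$se1_pN^2),
      sqrt(summary_a$se2_pN^2 + summary_b$se2_pN^2),
      sqrt(af_se(summary_a)^2 + af_se(summary_b)^2)
    )
  )
}
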