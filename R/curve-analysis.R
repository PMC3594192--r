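#' Remove the linear baseline from a retract curve
#'
#' Fits a straight line to the far-from-surface tail of the retract (where no
#' tether can still be attached) and subtracts it from the whole retract
#' segment, removing baseline offset and tilt.
#'
#' @param curve Tibble with columns `z_nm` and `f_retract_pN` (one curve).
#' @param tail_fraction Fraction of the z range, taken from the free end,
#'   used to fit the baseline (default 0.25; at least 20 samples required).
#' @return The curve with `f_retract_pN` corrected; the fitted intercept and
#'   slope are stored in attribute `baseline`.
#' @examples
#' cfg <- simulation_config(force_noise_sd = 0, baseline_tilt = 0.05)
#' fc <- simulate_force_curve(cfg, NULL)
#' mean(correct_baseline(fc)$f_retract_pN[fc$z_nm > 60]) # ~0
#' @export
correct_baseline <- function(curve, tail_fraction = 0.25) {
  z <- curve$z_nm
  f <- curve$f_retract_pN
  cut <- max(z) - tail_fraction * diff(range(z))
  tail_idx <- which(z >= cut)
  if (length(tail_idx) < 20) {
    abort("baseline tail too short (< 20 samples).", class = "smforce_error")
  }
  co <- coef(lm(f[tail_idx] ~ z[tail_idx]))
  curve$f_retract_pN <- f - (co[[1]] + co[[2]] * z)
  attr(curve, "baseline") <- c(intercept = co[[1]], slope = co[[2]])
  curve
}

#' Locate the contact point on the approach curve
#'
#' Walks from the free end of the approach toward the surface until the
#' repulsive force exceeds a noise threshold for several consecutive samples,
#' then refines the estimate by intersecting the least-squares contact line
#' with zero force. All rupture distances are referenced to this point.
#'
#' @param curve Tibble with `z_nm` and `f_approach_pN`.
#' @param noise_sd Baseline force noise SD, pN; estimated from the free-end
#'   tail when `NULL`.
#' @param threshold_factor Detection threshold in units of `noise_sd`.
#' @return Contact position z0 in nm.
#' @export
find_contact_point <- function(curve, noise_sd = NULL, threshold_factor = 3) {
  z <- curve$z_nm
  f <- curve$f_approach_pN
  ord <- order(z)
  z <- z[ord]
  f <- f[ord]
  n <- length(z)
  if (is.null(noise_sd)) {
    tail_idx <- which(z >= max(z) - 0.25 * diff(range(z)))
    noise_sd <- sd(f[tail_idx])
  }
  thr <- max(threshold_factor * noise_sd, 1e-9)
  run <- if (noise_sd < 1e-6) 1L else 5L
  above <- f > thr
  ## sustained run of `run` samples above threshold, nearest to the free end
  idx <- NA_integer_
  count <- 0L
  for (i in seq(n, 1)) {
    if (above[[i]]) {
      count <- count + 1L
      if (count >= run) {
        idx <- i + run - 1L # free-end edge of the run
        break
      }
    } else {
      count <- 0L # isolated noise spikes do not count as contact
    }
  }
  if (is.na(idx)) {
    abort("no contact region found on the approach.",
          class = "smforce_error")
  }
  ## refine with the contact line (deep-contact samples)
  deep <- which(z <= z[[idx]] & f >= max(10 * noise_sd, thr))
  if (length(deep) >= 10) {
    co <- coef(lm(f[deep] ~ z[deep]))
    z0 <- -co[[1]] / co[[2]]
    if (is.finite(z0) && abs(z0 - z[[idx]]) < 5) return(z0)
  }
  z[[idx]]
}

#' Detect rupture events on a baseline-corrected retract
#'
#' A rupture is a force drop of at least `drop_factor` times the noise SD
#' completed within at most `drop_window` samples, preceded by a stretch of
#' rising tether force (strictly monotone in the noiseless case; a
#' significantly positive fitted slope otherwise) and a peak force above the
#' noise floor. Nearby candidates from the same drop are merged, keeping the
#' largest. The reported rupture force is the drop magnitude: peak force
#' minus the median post-rupture level.
#'
#' @param curve Tibble with `z_nm` and baseline-corrected `f_retract_pN`.
#' @param noise_sd Force noise SD, pN; estimated from the free-end tail when
#'   `NULL`.
#' @param drop_factor,drop_window Detection threshold (units of noise SD) and
#'   maximum drop extent in samples.
#' @param rise_window Samples of preceding rise examined.
#' @param z_min Only events at `z_nm > z_min` are kept (pass the contact
#'   point to exclude contact unloading).
#' @return Tibble of candidate events ordered by z: `z_nm`,
#'   `rupture_force_pN`, `peak_force_pN`, `index`.
#' @export
detect_ruptures <- function(curve, noise_sd = NULL, drop_factor = 5,
                            drop_window = 3L, rise_window = 50L,
                            z_min = -Inf) {
  z <- curve$z_nm
  f <- curve$f_retract_pN
  ord <- order(z)
  z <- z[ord]
  f <- f[ord]
  n <- length(f)
  if (is.null(noise_sd)) {
    tail_idx <- which(z >= max(z) - 0.25 * diff(range(z)))
    noise_sd <- mad(diff(f[tail_idx])) / sqrt(2)
  }
  sigma <- max(noise_sd, 1e-6)
  thr <- drop_factor * sigma

  ## forward minimum over the next `drop_window` samples (sharpness)
  fwd_min <- rep(Inf, n)
  for (j in seq_len(drop_window)) {
    shifted <- c(f[-seq_len(j)], rep(Inf, j))
    fwd_min <- pmin(fwd_min, shifted)
  }
  drop <- f - fwd_min
  ## sustained level after the drop: a transient noise dip on a rising
  ## tether branch recovers immediately; a rupture stays down
  rm11 <- stats::runmed(f, 11, endrule = "median")
  after_med <- rm11[pmin(seq_len(n) + 7L, n)] # median of f[(i+2)..(i+12)]
  sustained <- f - after_med
  cand <- which(drop >= thr & sustained >= thr & f >= drop_factor * sigma &
                  z > z_min)
  cand <- cand[cand > 10 & cand < n]
  if (!length(cand)) {
    return(tibble::tibble(z_nm = numeric(), rupture_force_pN = numeric(),
                          peak_force_pN = numeric(), index = integer()))
  }

  rising <- vapply(cand, function(i) {
    lo <- max(1L, i - rise_window)
    seg <- f[lo:(i - 1L)]
    if (noise_sd < 1e-6) {
      all(diff(f[max(1L, i - 10L):i]) >= -1e-9)
    } else {
      if (length(seg) < 10) return(FALSE)
      sm <- summary(lm(seg ~ seq_along(seg)))$coefficients
      sm[2, 1] > 0 && sm[2, 3] > 2 # positive slope, t > 2
    }
  }, logical(1))
  cand <- cand[rising]
  if (!length(cand)) {
    return(tibble::tibble(z_nm = numeric(), rupture_force_pN = numeric(),
                          peak_force_pN = numeric(), index = integer()))
  }

  ## merge candidates belonging to the same drop (gap <= 5 samples)
  groups <- cumsum(c(1, diff(cand) > 5))
  keep <- vapply(split(seq_along(cand), groups), function(ix) {
    ix[which.max(drop[cand[ix]])]
  }, integer(1))
  cand <- cand[keep]

  tibble::tibble(
    z_nm = z[cand],
    rupture_force_pN = f[cand] - after_med[cand],
    peak_force_pN = f[cand],
    index = cand
  )
}

#' Flag events as specific tether ruptures
#'
#' An event is a specific single-tether unbinding when its rupture distance
#' falls inside the window expected for the PEG(3400)+peptide tether and its
#' worm-like-chain fit residual is acceptable. Events at very small distances
#' are surface adhesion, not tether ruptures.
#'
#' @param events Events tibble with `rupture_distance_nm` and `residual_pN`.
#' @param window Length-2 numeric, admissible rupture distance in nm.
#' @param residual_max Maximum WLC RMS residual, pN.
#' @return The tibble with a logical `specific` column (re)computed.
#' @export
classify_specificity <- function(events, window = c(10, 60),
                                 residual_max = 10) {
  events$specific <- events$rupture_distance_nm > window[[1]] &
    events$rupture_distance_nm < window[[2]] &
    events$rupture_force_pN > 0 &
    !is.na(events$residual_pN) & events$residual_pN <= residual_max
  events
}

#' Extract rupture events from force curves
#'
#' Full per-curve analysis: baseline correction, contact-point location,
#' rupture detection, worm-like-chain fit of each tether stretch (against
#' tip-sample separation, i.e. piezo displacement corrected by the
#' cantilever deflection `F/k`), and specificity classification.
#'
#' @param x An `"afs_experiment"` from [simulate_experiment()], or a tibble
#'   of curves (`curve_id`, `z_nm`, `f_approach_pN`, `f_retract_pN`).
#' @param ... Passed to methods.
#' @return A tibble with one row per detected event: `curve_id`,
#'   `rupture_force_pN`, `rupture_distance_nm`, `Lc_nm`, `Lp_nm`,
#'   `residual_pN`, `specific`, `multiplicity`.
#' @examples
#' ex <- simulate_experiment(
#'   simulation_config(n_curves = 4, attachment_rate = 1, force_noise_sd = 0,
#'                     baseline_tilt = 0),
#'   seed = 2)
#' analyze_curves(ex)
#' @export
analyze_curves <- function(x, ...) UseMethod("analyze_curves")

#' @rdname analyze_curves
#' @export
analyze_curves.afs_experiment <- function(x, ...) {
  analyze_curves(x$curves, spring_constant = x$config$spring_constant,
                 temperature = x$config$temperature,
                 noise_sd = x$config$force_noise_sd, ...)
}

#' @rdname analyze_curves
#' @param spring_constant Cantilever spring constant, pN/nm.
#' @param temperature Temperature, K.
#' @param noise_sd Force noise SD, pN (`NULL` to estimate per curve).
#' @param window,residual_max Specificity rule, see [classify_specificity()].
#' @export
analyze_curves.data.frame <- function(x, spring_constant, temperature = 298,
                                      noise_sd = NULL, window = c(10, 60),
                                      residual_max = 10, ...) {
  out <- lapply(split(x, x$curve_id), function(cv) {
    analyze_one_curve(cv, spring_constant = spring_constant,
                      temperature = temperature, noise_sd = noise_sd,
                      window = window, residual_max = residual_max)
  })
  dplyr::bind_rows(out)
}

analyze_one_curve <- function(curve, spring_constant, temperature, noise_sd,
                              window, residual_max) {
  empty <- tibble::tibble(
    curve_id = integer(), rupture_force_pN = numeric(),
    rupture_distance_nm = numeric(), Lc_nm = numeric(), Lp_nm = numeric(),
    residual_pN = numeric(), specific = logical(), multiplicity = integer()
  )
  curve <- curve[order(curve$z_nm), ]
  corrected <- tryCatch(correct_baseline(curve),
                        smforce_error = function(e) NULL)
  if (is.null(corrected)) return(empty)
  z0 <- tryCatch(find_contact_point(corrected, noise_sd = noise_sd),
                 smforce_error = function(e) NA_real_)
  if (is.na(z0)) z0 <- min(curve$z_nm)
  ev <- detect_ruptures(corrected, noise_sd = noise_sd,
                        z_min = z0 + 1e-9)
  if (nrow(ev) == 0) return(empty)

  z <- corrected$z_nm
  f <- corrected$f_retract_pN
  dz <- median(diff(z))
  sigma <- if (is.null(noise_sd)) mad(diff(f)) / sqrt(2) else noise_sd
  ## deflection correction of the extension uses a smoothed force: noise in
  ## the regressor would otherwise attenuate the steep part of the branch
  f_smooth <- if (length(f) > 11) stats::runmed(f, 11) else f
  fits <- vector("list", nrow(ev))
  force_refined <- ev$rupture_force_pN
  prev_z <- z0
  for (j in seq_len(nrow(ev))) {
    seg <- which(z > prev_z & z <= ev$z_nm[[j]] &
                   f > max(3 * sigma, 0.5))
    fits[[j]] <- if (length(seg) >= 15) {
      ext <- z[seg] - z0 - f_smooth[seg] / spring_constant
      tryCatch(fit_wlc(ext, f[seg], temperature = temperature),
               smforce_error = function(e)
                 list(Lp = NA_real_, Lc = NA_real_, residual = Inf))
    } else {
      list(Lp = NA_real_, Lc = NA_real_, residual = Inf)
    }
    ## the drop magnitude carries the full noise of one sample; when the WLC
    ## fit succeeded, read the rupture force off the fitted branch at the
    ## rupture position (midway between the last attached and the first
    ## detached sample), which averages the noise over the whole stretch
    ft <- fits[[j]]
    if (is.finite(ft$residual) && ft$residual < 5 * max(sigma, 1e-3)) {
      fr <- tryCatch(
        wlc_force_at_z(ev$z_nm[[j]] + dz / 2, z0, ft$Lp, ft$Lc,
                       spring_constant, temperature),
        error = function(e) NA_real_
      )
      if (is.finite(fr) && abs(fr - ev$rupture_force_pN[[j]]) < 6 * sigma) {
        force_refined[[j]] <- fr
      }
    }
    prev_z <- ev$z_nm[[j]]
  }

  out <- tibble::tibble(
    curve_id = curve$curve_id[[1]],
    rupture_force_pN = force_refined,
    rupture_distance_nm = ev$z_nm - z0,
    Lc_nm = vapply(fits, `[[`, numeric(1), "Lc"),
    Lp_nm = vapply(fits, `[[`, numeric(1), "Lp"),
    residual_pN = vapply(fits, `[[`, numeric(1), "residual"),
    multiplicity = nrow(ev)
  )
  out <- classify_specificity(out, window = window,
                              residual_max = residual_max)
  out[, c("curve_id", "rupture_force_pN", "rupture_distance_nm", "Lc_nm",
          "Lp_nm", "residual_pN", "specific", "multiplicity")]
}
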