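#' Photodiode sensitivity from the hard-contact slope
#'
#' On an incompressible surface the cantilever deflection equals the piezo
#' displacement, so the slope of the deflection signal against z in the
#' contact region converts photodiode units to nanometres. The slope of the
#' least-squares line is inverted to give nm per signal unit.
#'
#' @param data Data frame with the contact-region samples.
#' @param z,signal Column names (strings) holding piezo displacement (nm) and
#'   raw deflection signal (V or other photodiode units).
#' @return Sensitivity in nm per signal unit (positive scalar).
#' @examples
#' seg <- data.frame(z_nm = 0:20, v = 0.02 * (20:0))
#' fit_sensitivity(seg, z = "z_nm", signal = "v") # 50 nm/V
#' @export
fit_sensitivity <- function(data, z = "z_nm", signal = "signal") {
  zz <- data[[z]]
  ss <- data[[signal]]
  if (length(zz) < 10) {
    abort("contact segment needs at least 10 points.",
          class = "smforce_error")
  }
  slope <- coef(lm(ss ~ zz))[[2]]
  if (!is.finite(slope) || abs(slope) < 1e-10) {
    abort("contact slope is degenerate; no contact region found.",
          class = "smforce_error")
  }
  1 / abs(slope)
}

#' Spring constant by the thermal-tune (equipartition) method
#'
#' A cantilever in thermal equilibrium fluctuates with mean-square deflection
#' \eqn{\langle d^2 \rangle = k_B T / k}; inverting gives the spring constant
#' from a calibrated deflection record. The variance is computed after mean
#' removal, which is the time-domain equivalent of integrating the thermal
#' resonance spectrum.
#'
#' @param deflection Deflection time series in nm (>= 1e4 samples advised).
#' @param temperature Bath temperature, K.
#' @return Spring constant in pN/nm.
#' @examples
#' d <- simulate_thermal_spectrum(30, n_samples = 1e5, seed = 1)
#' fit_spring_constant(d) # ~30 pN/nm
#' @export
fit_spring_constant <- function(deflection, temperature = 298) {
  v <- var(deflection - mean(deflection)) * (length(deflection) - 1) /
    length(deflection)
  if (!is.finite(v) || v <= 0) {
    abort("deflection series has zero variance.", class = "smforce_error")
  }
  kBT(temperature) / v
}

#' Assemble a calibration
#'
#' @param sensitivity nm per photodiode unit (> 0).
#' @param spring_constant pN/nm (> 0).
#' @param temperature K.
#' @return A list of class `"afs_calibration"`.
#' @export
calibration <- function(sensitivity, spring_constant, temperature = 298) {
  if (sensitivity <= 0 || spring_constant <= 0) {
    abort("sensitivity and spring_constant must be positive.",
          class = "smforce_error")
  }
  structure(list(sensitivity = sensitivity,
                 spring_constant = spring_constant,
                 temperature = temperature),
            class = "afs_calibration")
}

#' @export
print.afs_calibration <- function(x, ...) {
  cat(sprintf(
    "<afs_calibration> sensitivity %.4g nm/V, k %.4g pN/nm, T %.4g K\n",
    x$sensitivity, x$spring_constant, x$temperature))
  invisible(x)
}

#' Convert a raw deflection-signal curve to force
#'
#' Multiplies the photodiode signal by the sensitivity (signal to nm) and the
#' spring constant (nm to pN). Any numeric signal columns named in `cols` are
#' converted in place; the calibration used is recorded in an attribute.
#'
#' @param data Data frame holding raw signal columns.
#' @param calibration An [calibration()] object.
#' @param cols Character vector of signal column names to convert; converted
#'   columns are renamed by swapping a trailing `"_signal"` for `"_pN"` (or
#'   suffixed `"_pN"`).
#' @return The data frame with forces in pN and attribute `calibration`.
#' @examples
#' raw <- data.frame(z_nm = 1:5, defl_signal = rep(0.1, 5))
#' cal <- calibration(sensitivity = 50, spring_constant = 30)
#' to_force(raw, cal)$defl_pN # 150 pN
#' @export
to_force <- function(data, calibration, cols = grep("_signal$", names(data),
                                                    value = TRUE)) {
  if (!inherits(calibration, "afs_calibration")) {
    abort("`calibration` must be an afs_calibration object.",
          class = "smforce_error")
  }
  if (length(cols) == 0) {
    abort("no signal columns to convert.", class = "smforce_error")
  }
  scale <- calibration$sensitivity * calibration$spring_constant
  for (cl in cols) {
    data[[cl]] <- data[[cl]] * scale
    new <- if (grepl("_signal$", cl)) sub("_signal$", "_pN", cl) else
      paste0(cl, "_pN")
    names(data)[names(data) == cl] <- new
  }
  attr(data, "calibration") <- calibration
  data
}
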