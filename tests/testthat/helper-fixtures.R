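## noise-free configuration used by the deterministic round-trip tests
quiet_config <- function(...) {
  simulation_config(force_noise_sd = 0, baseline_tilt = 0, ...)
}

## a bare retract baseline (no curve structure) for false-positive tests
baseline_only_curve <- function(n = 1500, noise_sd = 5, dz = 0.05) {
  tibble::tibble(
    curve_id = 1L,
    z_nm = seq_len(n) * dz,
    f_retract_pN = rnorm(n, 0, noise_sd)
  )
}

## brute-force sum-of-squares of the two-Gaussian histogram model on a
## parameter lattice, profiling amplitudes by exact linear least squares
grid_two_gaussian_ssr <- function(centers, counts, mu1, mu2, s1, s2) {
  g1 <- exp(-(centers - mu1)^2 / (2 * s1^2))
  g2 <- exp(-(centers - mu2)^2 / (2 * s2^2))
  X <- cbind(g1, g2)
  a <- tryCatch(qr.coef(qr(X), counts), error = function(e) c(NA, NA))
  if (anyNA(a)) return(Inf)
  a <- pmax(a, 0)
  sum((X %*% a - counts)^2)
}
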