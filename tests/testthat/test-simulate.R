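test_that("simulation_config enforces its invariants", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(mixture = c(w1 = 1.2, mu1 = 66, sigma1 = 20,
                                             mu2 = 132, sigma2 = 30)),
               class = "smforce_error")
  expect_error(simulation_config(mixture = c(w1 = 0.5, mu1 = 132, sigma1 = 20,
                                             mu2 = 66, sigma2 = 30)),
               class = "smforce_error")
  expect_error(simulation_config(attachment_rate = -1),
               class = "smforce_error")
  expect_error(simulation_config(tether_contour_mean = 0),
               class = "smforce_error")
  expect_error(simulation_config(temperature = -5), class = "smforce_error")
})

test_that("rupture-force draws follow the two-component mixture", {
  ## degenerate mixture collapses to a point mass
  cfg <- simulation_config(mixture = c(w1 = 1, mu1 = 66, sigma1 = 0,
                                       mu2 = 67, sigma2 = 0))
  expect_equal(simulate_rupture_forces(cfg, 5, seed = 1), rep(66, 5))

  expect_error(simulate_rupture_forces(config_control(), 0),
               class = "smforce_error")

  ## moments converge to the analytic mixture moments (3 sigma band)
  set.seed(42)
  n <- 2000
  f <- simulate_rupture_forces(config_control(), n)
  m <- config_control()$mixture
  mix_mean <- m[["w1"]] * m[["mu1"]] + (1 - m[["w1"]]) * m[["mu2"]]
  mix_var <- m[["w1"]] * (m[["sigma1"]]^2 + m[["mu1"]]^2) +
    (1 - m[["w1"]]) * (m[["sigma2"]]^2 + m[["mu2"]]^2) - mix_mean^2
  expect_lt(abs(mean(f) - mix_mean), 3 * sqrt(mix_var / n))
  expect_lt(abs(sd(f) - sqrt(mix_var)), 3 * sqrt(mix_var / (2 * n)))

  ## bit-reproducible under a fixed seed
  expect_identical(simulate_rupture_forces(config_control(), 50, seed = 7),
                   simulate_rupture_forces(config_control(), 50, seed = 7))
})

test_that("thermal deflection series obeys equipartition", {
  d <- simulate_thermal_spectrum(30, 298, 1e5, seed = 42)
  expect_lt(abs(var(d) - kBT(298) / 30) / (kBT(298) / 30), 0.05)
  ## stiff limit: fluctuations vanish
  d_stiff <- simulate_thermal_spectrum(3e7, 298, 1000, seed = 42)
  expect_lt(var(d_stiff), 1e-6)
  expect_identical(simulate_thermal_spectrum(30, 298, 100, seed = 9),
                   simulate_thermal_spectrum(30, 298, 100, seed = 9))
  expect_error(simulate_thermal_spectrum(-1), class = "smforce_error")
  expect_error(simulate_thermal_spectrum(30, temperature = 0),
               class = "smforce_error")
})

test_that("force-curve generator builds the intended geometry", {
  cfg <- quiet_config()
  ## no tether, no noise, no tilt: retract identically baseline
  fc0 <- simulate_force_curve(cfg, NULL)
  expect_equal(fc0$f_retract_pN[fc0$z_nm > 0], rep(0, sum(fc0$z_nm > 0)))
  ## contact region has slope = spring constant on the approach
  contact <- fc0[fc0$z_nm < -1, ]
  expect_equal(unname(coef(lm(f_approach_pN ~ z_nm, contact))[2]),
               -cfg$spring_constant, tolerance = 1e-8)

  ## single tether: retract maximum equals the rupture force at the rupture
  fc1 <- simulate_force_curve(cfg, data.frame(force_pN = 132, Lc_nm = 35))
  ret <- fc1[fc1$z_nm > 0, ]
  expect_equal(max(ret$f_retract_pN), 132, tolerance = 0.01)
  ## instantaneous return to baseline after the rupture
  i_max <- which.max(ret$f_retract_pN)
  expect_lt(max(ret$f_retract_pN[(i_max + 2):nrow(ret)]), 1)

  ## two tethers with distinct contour lengths: two separated force drops
  fc2 <- simulate_force_curve(cfg, data.frame(force_pN = c(66, 132),
                                              Lc_nm = c(28, 40)))
  drops <- sum(diff(fc2$f_retract_pN[fc2$z_nm > 0]) < -5)
  expect_equal(drops, 2)

  ## a force the chain cannot reach below its contour length is rejected
  expect_error(simulate_force_curve(cfg, data.frame(force_pN = 1e18,
                                                    Lc_nm = 35)),
               class = "smforce_unreachable")
})

test_that("attachment counts are Poisson and the experiment is reproducible", {
  cfg <- simulation_config(n_curves = 1500, sample_rate = 2000,
                           force_noise_sd = 0, baseline_tilt = 0)
  ex <- simulate_experiment(cfg, seed = 42)
  frac <- length(unique(ex$events$curve_id)) / cfg$n_curves
  p <- 1 - exp(-cfg$attachment_rate)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / cfg$n_curves))

  cfg_small <- simulation_config(n_curves = 5, sample_rate = 2000)
  ex1 <- simulate_experiment(cfg_small, seed = 3)
  ex2 <- simulate_experiment(cfg_small, seed = 3)
  expect_identical(ex1$curves, ex2$curves)
  expect_identical(ex1$events, ex2$events)
})

test_that("topograph generator renders caps, ridges and blobs as specified", {
  ## one cap, no noise or tilt: image max equals the cap height
  topo <- simulate_topograph(feature_spec("cap", 3.13, radius_nm = 50),
                             image_size = c(120, 120), pixel_size = 10,
                             noise_sd = 0, tilt = 0, seed = 42)
  expect_lt(abs(max(topo) - 3.13), 0.05)
  expect_equal(attr(topo, "pixel_size_nm"), 10)

  ## long thin ridge: segmented aspect ratio far above 10
  ridge <- simulate_topograph(
    feature_spec("ridge", 7.2, length_nm = 3000, width_nm = 20),
    image_size = c(400, 400), pixel_size = 10, noise_sd = 0, tilt = 0,
    seed = 42)
  ft <- analyze_topograph(ridge)
  expect_equal(nrow(ft), 1)
  expect_gt(ft$aspect_ratio, 10)
  expect_lt(abs(ft$length_nm - 3000) / 3000, 0.06)

  ## empty spec: the image is exactly the background plane
  bg <- simulate_topograph(NULL, c(50, 80), pixel_size = 10, noise_sd = 0,
                           tilt = 0.5, seed = 1)
  expect_equal(dim(bg), c(50, 80))
  xs <- (seq_len(80) - 0.5) * 10
  expect_equal(unclass(bg)[1, ], xs * 0.5 / 1000, tolerance = 1e-12,
               ignore_attr = TRUE)

  ## determinism
  t1 <- simulate_topograph(feature_spec("blob", 9.3, diameter_nm = 300),
                           c(100, 100), seed = 5)
  t2 <- simulate_topograph(feature_spec("blob", 9.3, diameter_nm = 300),
                           c(100, 100), seed = 5)
  expect_identical(unclass(t1), unclass(t2))

  ## an oversized feature cannot be placed
  expect_error(
    simulate_topograph(feature_spec("cap", 3, radius_nm = 900),
                       image_size = c(100, 100), pixel_size = 10, seed = 1),
    class = "smforce_error")
})
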