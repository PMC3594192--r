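test_that("baseline correction removes its own model and is idempotent", {
  cfg <- simulation_config(force_noise_sd = 0, baseline_tilt = 0.05)
  fc <- simulate_force_curve(cfg, NULL)
  corr <- correct_baseline(fc)
  tail_idx <- fc$z_nm > max(fc$z_nm) - 10
  expect_lt(abs(mean(corr$f_retract_pN[tail_idx])), 0.1)

  ## an already-flat curve is unchanged
  again <- correct_baseline(corr)
  expect_equal(again$f_retract_pN, corr$f_retract_pN, tolerance = 1e-10)

  expect_error(correct_baseline(fc[1:30, ], tail_fraction = 0.2),
               class = "smforce_error")
})

test_that("tilted curves with an event still yield the true rupture force", {
  cfg <- simulation_config(force_noise_sd = 0, baseline_tilt = 0.08)
  fc <- simulate_force_curve(cfg, data.frame(force_pN = 132, Lc_nm = 35))
  ev <- analyze_curves(fc, spring_constant = cfg$spring_constant,
                       noise_sd = 0)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$rupture_force_pN - 132), 0.5)
})

test_that("contact point is found at the generator's surface position", {
  cfg <- quiet_config()
  fc <- simulate_force_curve(cfg, NULL)
  dz <- cfg$retract_velocity / cfg$sample_rate
  expect_lt(abs(find_contact_point(fc, noise_sd = 0)), dz + 1e-9)

  flat <- tibble::tibble(z_nm = seq(-10, 80, by = 0.1),
                         f_approach_pN = 0)
  expect_error(find_contact_point(flat, noise_sd = 0),
               class = "smforce_error")
})

test_that("contact point is stable under force noise", {
  cfg <- simulation_config(force_noise_sd = 2, baseline_tilt = 0)
  set.seed(42)
  z0 <- vapply(1:30, function(i) {
    fc <- simulate_force_curve(cfg, NULL)
    find_contact_point(fc, noise_sd = 2)
  }, numeric(1))
  expect_lt(max(abs(z0)), 0.5) # true contact at z = 0
})

test_that("rupture detection finds constructed events and nothing else", {
  cfg <- quiet_config()
  fc <- simulate_force_curve(cfg, data.frame(force_pN = 66, Lc_nm = 35))
  corr <- correct_baseline(fc)
  ev <- detect_ruptures(corr, noise_sd = 0, z_min = 0)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$rupture_force_pN - 66), 0.5)

  ## two tethers, distinct contour lengths: two events at distinct z
  fc2 <- simulate_force_curve(cfg, data.frame(force_pN = c(66, 132),
                                              Lc_nm = c(28, 40)))
  ev2 <- detect_ruptures(correct_baseline(fc2), noise_sd = 0, z_min = 0)
  expect_equal(nrow(ev2), 2)
  expect_gt(diff(ev2$z_nm), 1)
})

test_that("flat noisy baselines rarely trigger false detections", {
  set.seed(42)
  n_events <- vapply(1:1000, function(i) {
    nrow(detect_ruptures(baseline_only_curve(noise_sd = 5), noise_sd = 5))
  }, numeric(1))
  expect_gte(mean(n_events == 0), 0.95)
})

test_that("noiseless full pipeline round-trips every single-tether force", {
  cfg <- simulation_config(n_curves = 80, attachment_rate = 0.4,
                           force_noise_sd = 0, baseline_tilt = 0.05)
  ex <- simulate_experiment(cfg, seed = 42)
  ev <- analyze_curves(ex)
  truth <- ex$events
  singles <- names(which(table(truth$curve_id) == 1))
  m <- merge(ev[ev$multiplicity == 1, ], truth,
             by = "curve_id", suffixes = c("_fit", "_true"))
  m <- m[m$curve_id %in% as.integer(singles), ]
  expect_equal(nrow(m), length(singles)) # every single-tether event found
  expect_lt(max(abs(m$rupture_force_pN - m$force_pN)), 0.5)
  ## the WLC fit recovers the tether geometry too
  expect_lt(max(abs(m$Lc_nm_fit - m$Lc_nm_true) / m$Lc_nm_true), 0.05)
})

test_that("detection count equals the generator event count without noise", {
  cfg <- quiet_config()
  counts <- vapply(1:20, function(i) {
    fc <- simulate_force_curve(cfg, data.frame(force_pN = c(70, 140),
                                               Lc_nm = c(29, 41)))
    nrow(detect_ruptures(correct_baseline(fc), noise_sd = 0, z_min = 0))
  }, numeric(1))
  expect_true(all(counts == 2))
})

test_that("mean rupture-force error stays small under 5 pN noise", {
  cfg <- simulation_config(n_curves = 500, attachment_rate = 0.3,
                           force_noise_sd = 5)
  ex <- simulate_experiment(cfg, seed = 42)
  ev <- analyze_curves(ex)
  truth <- ex$events
  singles <- as.integer(names(which(table(truth$curve_id) == 1)))
  m <- merge(ev[ev$multiplicity == 1 & ev$curve_id %in% singles, ],
             truth, by = "curve_id")
  expect_gt(nrow(m), 80)
  expect_lt(mean(abs(m$rupture_force_pN - m$force_pN)), 2)
})

test_that("specificity follows the tether-distance window", {
  ev <- tibble::tibble(rupture_force_pN = c(80, 80, 80),
                       rupture_distance_nm = c(35, 2, 75),
                       residual_pN = c(1, 1, 1))
  out <- classify_specificity(ev)
  expect_equal(out$specific, c(TRUE, FALSE, FALSE))

  ## permissive limit: everything passes
  all_in <- classify_specificity(ev, window = c(0, Inf), residual_max = Inf)
  expect_true(all(all_in$specific))

  ## a bad WLC fit disqualifies an event
  bad <- classify_specificity(dplyr::mutate(ev[1, ], residual_pN = 99))
  expect_false(bad$specific)
})
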