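test_that("yield is the specific-event percentage", {
  expect_equal(compute_yield(1000, 143), 14.3)
  expect_equal(compute_yield(1000, 0), 0)
  expect_equal(compute_yield(512, 512), 100)
  expect_error(compute_yield(0, 0), class = "smforce_error")
  expect_error(compute_yield(10, 11), class = "smforce_error")
})

test_that("multiple-tether probability matches the Poisson conditional", {
  ## direct evaluations of the formula
  expect_lt(abs(multi_tether_probability(0.143)$p_multi - 0.075), 0.001)
  ## the highest-yield regime reproduces the published p = 0.12
  expect_lt(abs(multi_tether_probability(0.221)$p_multi - 0.12), 0.005)
  ## lambda is the Poisson rate implied by the yield
  expect_equal(multi_tether_probability(0.143)$lambda, -log(1 - 0.143))

  ## series limit: p -> lambda/2 -> 0 as yield -> 0
  tiny <- multi_tether_probability(1e-6)
  expect_lt(abs(tiny$p_multi / (tiny$lambda / 2) - 1), 1e-3)
  expect_equal(multi_tether_probability(0)$p_multi, 0)

  ## strictly increasing in yield
  grid <- multi_tether_probability(seq(0.01, 0.95, by = 0.01))$p_multi
  expect_true(all(diff(grid) > 0))

  expect_error(multi_tether_probability(1), class = "smforce_error")
})

test_that("discard_highest removes exactly the floor(p n) largest values", {
  expect_length(discard_highest(rnorm(1000, 100, 10), 0.12), 880)
  f <- c(5, 1, 9, 3, 10, 2, 8, 4, 7, 6)
  expect_identical(discard_highest(f, 0.25), c(5, 1, 3, 2, 8, 4, 7, 6))
  expect_identical(discard_highest(f, 0), f)

  ## property: retained = original with the k largest removed, order kept
  set.seed(42)
  x <- rnorm(333, 100, 25)
  p <- 0.1
  k <- floor(p * length(x))
  kept <- discard_highest(x, p)
  expect_identical(kept, x[!seq_along(x) %in%
                             order(x, decreasing = TRUE)[1:k]])
  expect_error(discard_highest(numeric(0), 0.1), class = "smforce_error")
})

test_that("a noise-free two-Gaussian histogram is recovered exactly", {
  centers <- seq(5, 255, by = 10)
  truth <- c(A1 = 50, mu1 = 66, s1 = 20, A2 = 50, mu2 = 132, s2 = 30)
  counts <- truth[["A1"]] * exp(-(centers - truth[["mu1"]])^2 /
                                  (2 * truth[["s1"]]^2)) +
    truth[["A2"]] * exp(-(centers - truth[["mu2"]])^2 / (2 * truth[["s2"]]^2))
  fit <- smforce:::fit_two_gaussians_counts(centers, counts, bin_width = 10,
                                            mu_init = c(60, 140))
  expect_equal(fit$mean, c(66, 132), tolerance = 1e-6)
  expect_equal(fit$sd, c(20, 30), tolerance = 1e-6)
  expect_equal(fit$amplitude, c(50, 50), tolerance = 1e-6)
})

test_that("components are reported ordered by mean whatever the starts", {
  centers <- seq(5, 255, by = 10)
  counts <- 50 * exp(-(centers - 66)^2 / 800) +
    50 * exp(-(centers - 132)^2 / 1800)
  swapped <- smforce:::fit_two_gaussians_counts(centers, counts,
                                                bin_width = 10,
                                                mu_init = c(140, 60))
  expect_lt(swapped$mean[1], swapped$mean[2])
  expect_equal(swapped$mean, c(66, 132), tolerance = 1e-4)
})

test_that("mixture fit on draws recovers the generating parameters", {
  set.seed(42)
  f <- simulate_rupture_forces(config_control(), 2000)
  fit <- fit_double_gaussian(f)
  expect_s3_class(fit, "double_gaussian_fit")
  expect_lt(abs(fit$mean[1] - 66), 5)
  expect_lt(abs(fit$mean[2] - 132), 8)
  expect_equal(sum(fit$area_fraction), 1)
  expect_equal(sum(fit$n_eff), fit$n, tolerance = 1e-6)
  ## the histogram is a faithful, unmodified binning of the input
  expect_equal(sum(fit$histogram$count), length(f))

  ## broom-style accessors
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(td$mean_pN, fit$mean)
  gl <- glance(fit)
  expect_equal(gl$n, 2000)
  expect_error(fit_double_gaussian(f[1:10]), class = "smforce_error")
})

test_that("the fitted means are unbiased over replicates", {
  set.seed(42)
  mu <- t(vapply(1:50, function(i) {
    fit_double_gaussian(simulate_rupture_forces(config_control(), 2000))$mean
  }, numeric(2)))
  expect_lt(abs(mean(mu[, 1]) - 66), 1)
  expect_lt(abs(mean(mu[, 2]) - 132), 1)
})

test_that("LM fit agrees with a profiled grid search on a fixed sample", {
  set.seed(42)
  f <- simulate_rupture_forces(config_control(), 200)
  fit <- fit_double_gaussian(f)
  h <- fit$histogram
  mu1_grid <- seq(46, 86, by = 2)
  mu2_grid <- seq(112, 152, by = 2)
  s_grid <- seq(12.5, 40, by = 2.5)
  best <- c(Inf, NA, NA)
  for (m1 in mu1_grid) for (m2 in mu2_grid) {
    ssr <- min(vapply(s_grid, function(s1) {
      min(vapply(s_grid, function(s2) {
        grid_two_gaussian_ssr(h$center_pN, h$count, m1, m2, s1, s2)
      }, numeric(1)))
    }, numeric(1)))
    if (ssr < best[1]) best <- c(ssr, m1, m2)
  }
  expect_lt(abs(fit$mean[1] - best[2]), 2 + 1e-9)
  expect_lt(abs(fit$mean[2] - best[3]), 2 + 1e-9)
})

test_that("effective counts and standard errors follow the area fractions", {
  fake <- structure(list(area_fraction = c(0.25, 0.75), sd = c(10, 10),
                         n = 400), class = "double_gaussian_fit")
  se <- effective_counts_se(fake)
  expect_equal(se$n_eff, c(100, 300))
  expect_equal(se$se_pN[1], 1.0)

  degenerate <- structure(list(area_fraction = c(1, 0), sd = c(10, 10),
                               n = 400), class = "double_gaussian_fit")
  expect_error(effective_counts_se(degenerate), class = "smforce_error")
})

test_that("condition summaries report mean force and Table-style columns", {
  fake_fit <- structure(
    list(mean = c(66, 132), sd = c(20, 30), area_fraction = c(0.5, 0.5),
         n = 2, amplitude = c(1, 1)),
    class = "double_gaussian_fit")
  s <- summarize_condition(c(100, 150), fake_fit, n_curves = 1000,
                           n_specific = 143, condition = "control")
  expect_equal(s$mean_force_pN, 125)
  expect_equal(s$yield_pct, 14.3)

  ## a heavy high-force tail pulls the arithmetic mean above the upper peak
  set.seed(42)
  tail_forces <- c(rnorm(300, 83, 15), rnorm(500, 164, 20),
                   runif(140, 320, 520))
  fit_tail <- fit_double_gaussian(tail_forces)
  s_tail <- summarize_condition(tail_forces, fit_tail)
  expect_gt(s_tail$mean_force_pN, fit_tail$mean[2])
})

test_that("condition comparison propagates standard errors in quadrature", {
  mk <- function(p1, se1, p2, se2, af) {
    tibble::tibble(condition = "x", n_forces = 100, peak1_pN = p1,
                   se1_pN = se1, peak2_pN = p2, se2_pN = se2,
                   mean_force_pN = 0, area_fraction1 = af,
                   yield_pct = NA_real_)
  }
  a <- mk(66, 3, 132, 3, 0.5)
  b <- mk(83, 4, 164, 4, 0.35)
  cmp <- compare_conditions(a, b)
  expect_equal(cmp$delta[cmp$quantity == "peak1_pN"], 17)
  expect_equal(cmp$delta[cmp$quantity == "peak2_pN"], 32)
  expect_equal(cmp$se_delta[cmp$quantity == "peak1_pN"], 5) # 3-4-5
  same <- compare_conditions(a, a)
  expect_true(all(same$delta == 0))
})
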