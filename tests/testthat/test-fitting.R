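test_that("profiles validate their sampling design", {
  expect_error(sampling_profile("s", c(0, 3, 6), c(1, 2, 3)), "at least 5")
  expect_error(sampling_profile("s", seq(0, 21, 3), rep(-1, 8)), "nonnegative")
  expect_error(sampling_profile("s", c(0, 3, 6, 9, 24), 1:5), "distinct")
  # times in [24, 48) are folded onto the same clock day
  p <- sampling_profile("s", c(25, 3, 6, 9, 12), c(10, 2, 3, 4, 5))
  expect_equal(p$times, c(1, 3, 6, 9, 12))
  expect_equal(p$concentrations[1], 10)
})

test_that("starting values are read deterministically off the data", {
  tt <- seq(0, 21, by = 3)
  cc <- c(20, 150, 80, 30, 6, 7, 8, 10)
  init <- initialize_params(sampling_profile("s", tt, cc))
  expect_equal(init$b1, 6)
  expect_equal(init$b2, 144)
  expect_equal(init$b3, 3)
  expect_gte(init$b4, 0.5); expect_lte(init$b4, 11.5)

  const <- initialize_params(sampling_profile("s", tt, rep(10, 8)))
  expect_equal(const$b1, 10)
  expect_equal(const$b2, 0)
  expect_equal(const$b3, 0)   # earliest time on a flat profile
  expect_equal(const$b4, 0.5)

  truth <- secretion_params(6, 140, 2, 8)
  init2 <- initialize_params(profile_from_params(truth))
  expect_equal(init2$b3, 3)   # nearest sampled time to the true peak at 2
})

test_that("noiseless profiles are recovered to high relative accuracy", {
  truth <- secretion_params(6, 140, 2, 8)
  f <- fit_profile(profile_from_params(truth))
  expect_true(f$converged)
  b <- as.numeric(f$params)
  expect_equal(b[["b1"]], 6, tolerance = 1e-3)
  expect_equal(b[["b2"]], 140, tolerance = 1e-3)
  expect_lt(circ_dist(b[["b3"]], 2), 2e-3)
  expect_equal(b[["b4"]], 8, tolerance = 1e-3)
  expect_gt(f$explained_variance, 0.999)
  expect_gt(f$r_value, 0.999)
  expect_true(f$bell_shaped)
  expect_true(f$quality_pass)
})

test_that("a peak wrapping midnight is recovered with circular accuracy", {
  truth <- secretion_params(0, 1, 23.8, 7)
  f <- fit_profile(profile_from_params(truth))
  expect_true(f$converged)
  expect_lt(circ_dist(f$params$b3, 23.8), 1e-2)
})

test_that("recovery is invariant to shifting all sample times by 24 h", {
  truth <- secretion_params(4, 90, 21, 6)
  f1 <- fit_profile(profile_from_params(truth, times = seq(0, 21, 3)))
  f2 <- fit_profile(profile_from_params(truth, times = seq(0, 21, 3) + 24))
  expect_lt(circ_dist(f1$params$b3, f2$params$b3), 1e-6)
  expect_equal(f1$params$b2, f2$params$b2, tolerance = 1e-8)
})

test_that("returned parameters always respect the physiological box", {
  set.seed(7)
  for (i in 1:40) {
    truth <- random_valid_params(b4 = runif(1, 4, 10))
    f <- fit_profile(profile_from_params(truth, noise_cv = 0.05))
    b <- as.numeric(f$params)
    expect_gte(b[["b1"]], 0); expect_gte(b[["b2"]], 0)
    expect_gte(b[["b3"]], 0); expect_lt(b[["b3"]], 24)
    expect_gt(b[["b4"]], 0); expect_lt(b[["b4"]], 12)
  }
})

test_that("accepted objective values never increase along the LM iterations", {
  set.seed(8)
  for (i in 1:20) {
    truth <- random_valid_params(b4 = runif(1, 4, 10))
    f <- fit_profile(profile_from_params(truth, noise_cv = 0.05))
    expect_true(all(diff(f$rss_trace) <= 1e-8 * (1 + f$rss_trace[-length(f$rss_trace)])))
  }
})

test_that("simulated noisy profiles are recovered within 10% median error", {
  set.seed(9)
  relerr <- matrix(NA_real_, 60, 4)
  for (i in 1:60) {
    b <- c(runif(1, 0, 20), runif(1, 40, 250), runif(1, 0, 24), runif(1, 4, 10))
    truth <- secretion_params(b[1], b[2], b[3], b[4])
    f <- fit_profile(profile_from_params(truth, noise_cv = 0.05))
    est <- as.numeric(f$params)
    relerr[i, ] <- c(abs(est[["b1"]] - b[1]) / max(b[1], 1e-8),
                     abs(est[["b2"]] - b[2]) / b[2],
                     circ_dist(est[["b3"]], b[3]) / max(b[3], 1e-8),
                     abs(est[["b4"]] - b[4]) / b[4])
  }
  expect_true(all(apply(relerr, 2, median) < 0.10))
})

test_that("goodness of fit follows its definitions", {
  truth <- secretion_params(6, 140, 2, 8)
  prof <- profile_from_params(truth)
  g <- goodness_of_fit(prof, truth)
  expect_equal(g$r_value, 1)
  expect_equal(g$explained_variance, 1)
  expect_true(g$degenerate)       # all-zero residuals: normality meaningless
  expect_true(is.na(g$residual_normality_p))

  # residuals orthogonal to the fitted curve (and the intercept), scaled so
  # SS_res / SS_tot = 0.05 exactly => explained variance 0.95
  tt <- prof$times
  fitted <- evaluate_model(truth, tt)
  set.seed(123)
  res <- stats::residuals(stats::lm(rnorm(length(tt)) ~ fitted))
  ssfit <- sum((fitted - mean(fitted))^2)
  res <- res * sqrt((0.05 / 0.95) * ssfit / sum(res^2))
  g2 <- goodness_of_fit(sampling_profile("s", tt, fitted + res), truth)
  expect_equal(g2$explained_variance, 0.95, tolerance = 1e-10)

  expect_warning(
    g3 <- goodness_of_fit(sampling_profile("s", tt, rep(10, 8)), truth),
    "constant")
  expect_equal(g3$explained_variance, 0)
})

test_that("non-bell-shaped profiles are screened out", {
  tt <- seq(0, 21, by = 3)
  expect_warning(fc <- fit_profile(sampling_profile("flat", tt, rep(10, 8))),
                 "constant")
  expect_false(fc$bell_shaped)
  expect_false(fc$quality_pass)

  # double release 12 h apart with equal amplitudes
  p1 <- secretion_params(6, 140, 2, 8)
  p2 <- secretion_params(0, 140, 14, 8)
  dbl <- sampling_profile("dbl", tt, evaluate_model(p1, tt) + evaluate_model(p2, tt))
  fd <- fit_profile(dbl)
  expect_false(fd$bell_shaped)

  fb <- fit_profile(profile_from_params(secretion_params(6, 140, 2, 8)))
  expect_true(fb$bell_shaped)
})

test_that("fit tables round-trip all diagnostics", {
  set.seed(10)
  fits <- lapply(1:3, function(i)
    fit_profile(profile_from_params(random_valid_params(b4 = 7),
                                    id = paste0("S", i), noise_cv = 0.05)))
  tab <- fits_to_table(fits)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$b_max, tab$b1 + tab$b2)
  expect_true(all(c("r_value", "explained_variance", "residual_normality_p",
                    "converged", "bell_shaped", "quality_pass") %in% names(tab)))
})
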