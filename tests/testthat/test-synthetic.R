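test_that("configuration rejects impossible designs", {
  expect_error(generator_config(n_eg = 0), "group sizes")
  expect_error(generator_config(n_cg = -1), "group sizes")
  expect_error(generator_config(noise_cv = -0.1), "noise_cv")
  expect_error(generator_config(prop_non_bell = 1.5), "prop_non_bell")
  expect_error(generate_cohort(list(n_eg = 5)), "generator_config")
})

test_that("zero effects and zero spread reproduce the group locations exactly", {
  cfg <- generator_config(sigma = c(log_b1 = 0, log_b2 = 0, b3 = 0, b4 = 0),
                          effects = list(EG = list(), CG = list()),
                          noise_cv = 0)
  co <- generate_cohort(cfg, seed = 1)
  for (g in c("EG", "CG")) {
    loc <- cfg$group_params[[g]]
    tp <- co$true_params[co$true_params$group == g, ]
    expect_equal(unique(tp$b1), unname(loc[["b1"]]), tolerance = 1e-12)
    expect_equal(unique(tp$b2), unname(loc[["b2"]]), tolerance = 1e-12)
    expect_equal(unique(tp$b3), unname(loc[["b3"]]), tolerance = 1e-12)
    expect_equal(unique(tp$b4), unname(loc[["b4"]]), tolerance = 1e-12)
  }
})

test_that("the same seed reproduces the cohort byte for byte", {
  cfg <- generator_config(n_eg = 10, n_cg = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg, seed = 77), d1)
  write_cohort(generate_cohort(cfg, seed = 77), d2)
  for (f in c("profiles.csv", "clinical.csv", "params_true.csv", "manifest.yaml"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  co3 <- generate_cohort(cfg, seed = 78)
  expect_false(identical(generate_cohort(cfg, seed = 77)$true_params$b2,
                         co3$true_params$b2))
})

test_that("noiseless synthesis reproduces the model exactly and noise floors at zero", {
  p <- secretion_params(6, 140, 2, 8)
  cfg0 <- generator_config(noise_cv = 0)
  prof <- synthesize_profile(p, cfg0, "s")
  expect_equal(prof$concentrations, evaluate_model(p, cfg0$sampling_times))
  set.seed(30)
  cfg_big <- generator_config(noise_cv = 2)   # absurd noise: exercises the floor
  prof2 <- synthesize_profile(secretion_params(0.1, 1, 2, 8), cfg_big, "s")
  expect_true(all(prof2$concentrations >= 0))
})

test_that("a noisy profile round-trips through the fitter within 10%", {
  set.seed(31)
  truth <- secretion_params(6, 140, 2, 8)
  f <- fit_profile(synthesize_profile(truth, generator_config(), "s"))
  est <- as.numeric(f$params)
  expect_lt(abs(est[["b1"]] - 6) / 6, 0.25)
  expect_lt(abs(est[["b2"]] - 140) / 140, 0.10)
  expect_lt(circ_dist(est[["b3"]], 2), 0.5)
  expect_lt(abs(est[["b4"]] - 8) / 8, 0.10)
})

test_that("cohorts carry the study structure", {
  co <- generate_cohort(generator_config(), seed = 5)
  expect_equal(sum(co$clinical$group == "EG"), 52)
  expect_equal(sum(co$clinical$group == "CG"), 30)
  expect_equal(length(co$profiles), 82)
  expect_true(all(vapply(co$profiles, function(p) length(p$times), 1L) == 8L))
  eg <- co$clinical[co$clinical$group == "EG", ]
  cg <- co$clinical[co$clinical$group == "CG", ]
  expect_true(all(is.na(cg$n_aeds)))
  expect_true(all(eg$n_aeds %in% 1:4))
  expect_true(all(eg$disease_duration >= 11 & eg$disease_duration <= 200))
  expect_true(all(eg$hours_since_last_seizure >= 1 &
                    eg$hours_since_last_seizure <= 42))
  expect_true(all(cg$sleep_disorder == 0) && all(cg$generalized_seizures == 0))
  # age-matched by construction: same distribution in both groups
  expect_gt(mann_whitney_u(eg$age, cg$age)$p_value, 0.001)
})

test_that("configured covariate effects reproduce their correlation signs", {
  signs <- list(
    c(feature = "age", param = "b2", group = "EG", sign = -1),
    c(feature = "avg_seizures_per_day", param = "b3", group = "EG", sign = 1),
    c(feature = "hours_since_last_seizure", param = "b3", group = "EG", sign = -1),
    c(feature = "disease_duration", param = "b2", group = "EG", sign = -1),
    c(feature = "age", param = "b3", group = "CG", sign = 1))
  nrep <- 60
  hits <- numeric(length(signs))
  iq_rho <- numeric(nrep)
  for (r in seq_len(nrep)) {
    co <- generate_cohort(generator_config(), seed = 400 + r)
    m <- merge(co$true_params, co$clinical, by = c("subject_id", "group"))
    m$b3 <- align_phase(m$b3)
    for (k in seq_along(signs)) {
      s <- signs[[k]]
      sub <- m[m$group == s[["group"]], ]
      rho <- spearman_rho(sub[[s[["feature"]]]], sub[[s[["param"]]]])$rho
      hits[k] <- hits[k] + (sign(rho) == as.numeric(s[["sign"]]))
    }
    eg <- m[m$group == "EG", ]
    iq_rho[r] <- abs(spearman_rho(eg$iq_quotient, eg$b2)$rho)
  }
  grp <- vapply(signs, function(s) s[["group"]], character(1))
  # at the EG size (n = 52) sign recovery is near-certain; the smaller CG
  # (n = 30) carries proportionally more sampling noise on its rho ~ 0.3
  expect_true(all(hits[grp == "EG"] / nrep >= 0.95))
  expect_true(all(hits[grp == "CG"] / nrep >= 0.85))
  # null fidelity: zero-effect covariates stay near zero correlation
  expect_lt(median(iq_rho), 0.15)
})

test_that("large-sample draws confirm the age-amplitude direction", {
  set.seed(33)
  cfg <- generator_config()
  recs <- lapply(1:2000, function(i)
    list(group = "EG", age = runif(1, 1, 14), avg_seizures_per_day = 2,
         seizures_day_before = 1, seizures_sampling_day = 1, n_aeds = 2,
         disease_duration = 100, hours_since_last_seizure = 20))
  b2 <- vapply(recs, function(r) draw_subject_params(r, cfg)$b2, numeric(1))
  age <- vapply(recs, function(r) r$age, numeric(1))
  expect_lt(spearman_rho(age, b2)$rho, 0)
})
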