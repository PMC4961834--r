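# Standardisation constants for covariates: fixed (not per-cohort empirical)
# so that a single subject can be simulated without cohort context.
.cov_center <- c(age = 6.8, iq_quotient = 100, avg_seizures_per_day = 2.2,
                 seizures_day_before = 1.5, seizures_sampling_day = 1.3,
                 n_aeds = 2.1, disease_duration = 105.5,
                 hours_since_last_seizure = 21.5)
.cov_scale <- c(age = 2.6, iq_quotient = 15, avg_seizures_per_day = 1.1,
                seizures_day_before = 0.67, seizures_sampling_day = 0.55,
                n_aeds = 0.95, disease_duration = 54.6,
                hours_since_last_seizure = 11.8)

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study design the package targets: an epilepsy group
#' (EG, n = 52) and a comparison group (CG, n = 30) of children sampled every
#' 3 hours over one day, with group-level secretion parameters centred on the
#' published group medians and clinical covariates whose correlations with
#' the parameters carry the published signs.
#'
#' Parameter distributions are log-normal for `b1` and `b2` (medians at the
#' group locations), wrapped-normal for the phase `b3`, and truncated-normal
#' for the width `b4`. Covariates act linearly on the latent (log or
#' identity) scale through the signed `effects` coefficients, expressed per
#' standard deviation of the covariate.
#'
#' @param n_eg,n_cg Group sizes.
#' @param sampling_times Blood-draw clock times in hours.
#' @param noise_cv Multiplicative assay noise, as a coefficient of variation.
#' @param prop_non_bell Fraction of EG subjects generated with a
#'   non-bell-shaped (flat or double-peaked) profile, to exercise the
#'   exclusion path. Off by default.
#' @param seed Default seed used by [generate_cohort()].
#' @param group_params Per-group locations for `b1`, `b2` \[pg/mL\] and
#'   `b3`, `b4` \[h\].
#' @param sigma Latent-scale spreads: `log_b1`, `log_b2` (log pg/mL),
#'   `b3`, `b4` (hours).
#' @param effects Per-group, per-parameter named coefficient vectors linking
#'   standardised covariates to the latent parameter scale.
#' @param fitter List of fitter settings (`max_iter`, `tol`).
#' @param stats List of statistics switches (`adjust`: `"none"` or `"holm"`).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_eg = 52L, n_cg = 30L,
                             sampling_times = seq(0, 21, by = 3),
                             noise_cv = 0.05,
                             prop_non_bell = 0,
                             seed = 20160713L,
                             group_params = list(
                               EG = c(b1 = 5.9933, b2 = 117.9186,
                                      b3 = 2.3851, b4 = 7.2894),
                               CG = c(b1 = 6.4645, b2 = 142.7516,
                                      b3 = 1.4843, b4 = 7.1835)),
                             sigma = c(log_b1 = 0.4, log_b2 = 0.5,
                                       b3 = 1.0, b4 = 1.0),
                             effects = list(
                               EG = list(
                                 log_b2 = c(age = -0.20,
                                            avg_seizures_per_day = 0.18,
                                            seizures_day_before = 0.15,
                                            disease_duration = -0.18,
                                            hours_since_last_seizure = -0.15),
                                 b3 = c(avg_seizures_per_day = 0.35,
                                        seizures_day_before = 0.30,
                                        seizures_sampling_day = 0.35,
                                        n_aeds = 0.25,
                                        hours_since_last_seizure = -0.50)),
                               CG = list(
                                 log_b2 = c(age = -0.20),
                                 b3 = c(age = 0.30))),
                             fitter = list(max_iter = 200L, tol = 1e-10),
                             stats = list(adjust = "none")) {
  if (n_eg <= 0L || n_cg <= 0L)
    stop("group sizes must be positive")
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  if (prop_non_bell < 0 || prop_non_bell > 1)
    stop("prop_non_bell must lie in [0, 1]")
  structure(list(n_eg = as.integer(n_eg), n_cg = as.integer(n_cg),
                 sampling_times = as.numeric(sampling_times),
                 noise_cv = noise_cv, prop_non_bell = prop_non_bell,
                 seed = as.integer(seed), group_params = group_params,
                 sigma = sigma, effects = effects,
                 fitter = fitter, stats = stats),
            class = "generator_config")
}

.rtrunc_norm <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:1000) {
    x <- stats::rnorm(1L, mean, sd)
    if (x > lo && x < hi) return(x)
  }
  min(max(mean, lo), hi)  # pathological configuration; truncate
}

.effect_shift <- function(betas, record) {
  if (is.null(betas) || !length(betas)) return(0)
  z <- vapply(names(betas), function(nm) {
    v <- record[[nm]]
    if (is.null(v) || is.na(v)) 0
    else (v - .cov_center[[nm]]) / .cov_scale[[nm]]
  }, numeric(1L))
  sum(betas * z)
}

.resid_sd <- function(sigma, betas) {
  sqrt(max(sigma^2 - sum(betas^2), 0.05 * sigma^2))
}

#' Draw one subject's secretion parameters
#'
#' Samples `(b1, b2, b3, b4)` from the group-specific distributions in
#' `config`, with the configured covariate effects applied on the latent
#' scale. The total latent spread per parameter is held at `config$sigma`
#' by shrinking the residual component as effects are added. Out-of-range
#' widths are resampled within `(0.5, 11.5)` h; the phase is wrapped.
#'
#' @param record One subject's clinical record (named list or one-row
#'   data frame, with a `group` field of `"EG"` or `"CG"`).
#' @param config A [generator_config()].
#' @return A [secretion_params()] object. Uses the global RNG stream.
#' @export
draw_subject_params <- function(record, config) {
  grp <- as.character(record[["group"]])
  if (!grp %in% c("EG", "CG")) stop("record group must be 'EG' or 'CG'")
  loc <- config$group_params[[grp]]
  eff <- config$effects[[grp]]
  sg <- config$sigma

  b1 <- exp(log(loc[["b1"]]) +
              .effect_shift(eff$log_b1, record) +
              .resid_sd(sg[["log_b1"]], eff$log_b1) * stats::rnorm(1L))
  b2 <- exp(log(loc[["b2"]]) +
              .effect_shift(eff$log_b2, record) +
              .resid_sd(sg[["log_b2"]], eff$log_b2) * stats::rnorm(1L))
  b3 <- (loc[["b3"]] +
           .effect_shift(eff$b3, record) +
           .resid_sd(sg[["b3"]], eff$b3) * stats::rnorm(1L)) %% 24
  b4 <- .rtrunc_norm(loc[["b4"]] + .effect_shift(eff$b4, record),
                     if (is.null(eff$b4)) sg[["b4"]] else
                       .resid_sd(sg[["b4"]], eff$b4),
                     0.5, 11.5)
  secretion_params(b1, b2, b3, b4)
}

#' Simulate a sampling profile from known parameters
#'
#' Evaluates the secretion model at the configured blood-draw times and
#' applies multiplicative Gaussian assay noise
#' (`concentration * (1 + eps)`, `eps ~ N(0, noise_cv)`), floored at zero.
#'
#' @param params A [secretion_params()] object.
#' @param config A [generator_config()].
#' @param subject_id Label for the resulting profile.
#' @return A [sampling_profile()]. Uses the global RNG stream.
#' @export
synthesize_profile <- function(params, config, subject_id = "S1") {
  tt <- config$sampling_times
  mu <- evaluate_model(params, tt)
  eps <- if (config$noise_cv > 0)
    stats::rnorm(length(tt), 0, config$noise_cv) else numeric(length(tt))
  sampling_profile(subject_id, tt, pmax(mu * (1 + eps), 0))
}

# Non-bell-shaped profiles for the exclusion path: a flat tracing or a
# double release 12 h apart with equal amplitudes.
.synthesize_non_bell <- function(params, config, subject_id, kind) {
  tt <- config$sampling_times
  mu <- switch(kind,
    flat = rep(params$b1 + 0.05 * params$b2, length(tt)),
    double = {
      p2 <- secretion_params(0, params$b2, (params$b3 + 12) %% 24, params$b4)
      evaluate_model(params, tt) + evaluate_model(p2, tt)
    },
    stop("unknown non-bell kind: ", kind))
  eps <- if (config$noise_cv > 0)
    stats::rnorm(length(tt), 0, config$noise_cv) else numeric(length(tt))
  sampling_profile(subject_id, tt, pmax(mu * (1 + eps), 0))
}

.draw_clinical <- function(n, group, id_prefix) {
  age <- round(vapply(seq_len(n), function(i) .rtrunc_norm(6.8, 3, 1, 16),
                      numeric(1L)), 1L)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  iq <- round(pmin(pmax(stats::rnorm(n, 100, 15), 40), 145))
  df <- data.frame(
    subject_id = sprintf("%s%02d", id_prefix, seq_len(n)),
    group = group, sex = sex, age = age, iq_quotient = iq,
    avg_seizures_per_day = NA_real_, seizures_day_before = NA_real_,
    seizures_sampling_day = NA_real_, n_aeds = NA_real_,
    disease_duration = NA_real_, hours_since_last_seizure = NA_real_,
    sleep_disorder = 0L, sleep_associated_seizures = 0L,
    generalized_seizures = 0L, stringsAsFactors = FALSE)
  if (group == "EG") {
    df$avg_seizures_per_day <- pmin(1L + stats::rpois(n, 1.2), 9L)
    df$seizures_day_before <- sample(1:3, n, replace = TRUE,
                                     prob = c(0.6, 0.3, 0.1))
    df$seizures_sampling_day <- pmin(1L + stats::rpois(n, 0.3), 3L)
    df$n_aeds <- sample(1:4, n, replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1))
    df$disease_duration <- round(stats::runif(n, 11, 200))
    df$hours_since_last_seizure <- round(stats::runif(n, 1, 42), 1L)
    df$sleep_disorder <- stats::rbinom(n, 1L, 0.35)
    df$sleep_associated_seizures <- stats::rbinom(n, 1L, 0.30)
    df$generalized_seizures <- sample(rep(0:1, length.out = n))
  }
  df
}

#' Generate a full synthetic cohort
#'
#' Draws clinical covariates for both groups (age-matched by construction:
#' both groups share one age distribution), subject-level secretion
#' parameters via [draw_subject_params()], and noisy sampling profiles via
#' [synthesize_profile()]. Fully reproducible from the seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `melatonin_cohort` with elements `profiles`
#'   (list of [sampling_profile()]), `clinical` (data frame), `true_params`
#'   (data frame of the generating parameters and profile shapes), `config`,
#'   `seed`.
#' @export
generate_cohort <- function(config = generator_config(), seed = config$seed) {
  if (!inherits(config, "generator_config")) stop("config must be a generator_config")
  if (config$n_eg + config$n_cg <= 0L) stop("empty cohort configuration")
  set.seed(as.integer(seed))
  clinical <- rbind(.draw_clinical(config$n_eg, "EG", "EG"),
                    .draw_clinical(config$n_cg, "CG", "CG"))
  n <- nrow(clinical)
  n_nb <- floor(config$prop_non_bell * config$n_eg)
  nb_ids <- if (n_nb > 0L)
    sample(clinical$subject_id[clinical$group == "EG"], n_nb) else character(0L)

  profiles <- vector("list", n)
  tp <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- clinical[i, ]
    params <- draw_subject_params(rec, config)
    sid <- rec$subject_id
    shape <- if (sid %in% nb_ids) {
      if (match(sid, nb_ids) %% 2L == 1L) "flat" else "double"
    } else "bell"
    profiles[[i]] <- if (shape == "bell")
      synthesize_profile(params, config, sid)
    else
      .synthesize_non_bell(params, config, sid, shape)
    b <- as.numeric(params)
    tp[[i]] <- data.frame(subject_id = sid, group = rec$group,
                          b1 = b[["b1"]], b2 = b[["b2"]],
                          b3 = b[["b3"]], b4 = b[["b4"]],
                          shape = shape, stringsAsFactors = FALSE)
  }
  names(profiles) <- clinical$subject_id
  structure(list(profiles = profiles, clinical = clinical,
                 true_params = do.call(rbind, tp),
                 config = config, seed = as.integer(seed)),
            class = "melatonin_cohort")
}

#' @export
print.melatonin_cohort <- function(x, ...) {
  cat(sprintf("Synthetic melatonin cohort: %d EG + %d CG subjects, %d samples each (seed %d)\n",
              sum(x$clinical$group == "EG"), sum(x$clinical$group == "CG"),
              length(x$config$sampling_times), x$seed))
  invisible(x)
}

#' Write a cohort to delimited text files
#'
#' Writes `profiles.csv` (the format [read_profiles()] ingests),
#' `clinical.csv`, `params_true.csv` (the synthetic generating truth), and a
#' `manifest.yaml` recording the configuration and seed.
#'
#' @param cohort A `melatonin_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "melatonin_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_profiles(cohort$profiles, file.path(dir, "profiles.csv"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$true_params, file.path(dir, "params_true.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  manifest <- list(seed = cohort$seed,
                   n_eg = cfg$n_eg, n_cg = cfg$n_cg,
                   sampling_times = cfg$sampling_times,
                   noise_cv = cfg$noise_cv,
                   prop_non_bell = cfg$prop_non_bell,
                   group_params = lapply(cfg$group_params, as.list),
                   sigma = as.list(cfg$sigma),
                   fitter = cfg$fitter, stats = cfg$stats)
  writeLines(yaml::as.yaml(manifest), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
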