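#' Read a pipeline configuration file
#'
#' A YAML file overriding any subset of the [generator_config()] fields
#' (including nested `group_params`, `sigma`, `fitter`, `stats`); unspecified
#' fields keep their defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A [generator_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- generator_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  for (nm in names(user)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    if (nm %in% c("group_params", "sigma", "fitter", "stats", "effects")) {
      cur <- cfg[[nm]]
      for (k in names(user[[nm]])) {
        v <- user[[nm]][[k]]
        cur[[k]] <- if (is.list(v) && !is.null(names(unlist(v)))) {
          u <- unlist(v)
          if (nm %in% c("group_params")) u else v
        } else v
      }
      cfg[[nm]] <- cur
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg2 <- generator_config(n_eg = cfg$n_eg, n_cg = cfg$n_cg,
                           sampling_times = cfg$sampling_times,
                           noise_cv = cfg$noise_cv,
                           prop_non_bell = cfg$prop_non_bell,
                           seed = cfg$seed, group_params = cfg$group_params,
                           sigma = unlist(cfg$sigma), effects = cfg$effects,
                           fitter = cfg$fitter, stats = cfg$stats)
  cfg2
}

#' Fit stage: estimate the secretion model for every subject in a file
#'
#' Reads a profile table, fits each subject with [fit_profile()], applies
#' the bell-shape exclusion flags, and writes one diagnostics row per
#' subject (`excluded`, `exclusion_reason` appended to the
#' [fits_to_table()] layout).
#'
#' @param profiles_path Input CSV of profiles (see [read_profiles()]).
#' @param output_path Output CSV of fit results.
#' @param config A [generator_config()] (fitter settings are honoured).
#' @param verbose Log one line per subject.
#' @return The fits data frame, invisibly.
#' @export
run_fit_stage <- function(profiles_path, output_path = NULL,
                          config = generator_config(), verbose = FALSE) {
  profiles <- read_profiles(profiles_path)
  fits <- lapply(profiles, function(p) {
    f <- fit_profile(p, max_iter = config$fitter$max_iter,
                     tol = config$fitter$tol)
    if (verbose)
      message(sprintf("subject %s: converged=%s ev=%.4f bell=%s",
                      p$subject_id, f$converged, f$explained_variance,
                      f$bell_shaped))
    f
  })
  tab <- fits_to_table(fits)
  tab$excluded <- !tab$bell_shaped
  tab$exclusion_reason <- ifelse(tab$excluded, "not bell shaped", "")
  if (!is.null(output_path))
    utils::write.csv(tab, output_path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Align circular phase values for linear ranking
#'
#' The phase shift is a clock time, i.e. a circular quantity: values just
#' below midnight (23.9 h) and just after (0.1 h) are 0.2 h apart, yet a
#' linear rank treats them as extremes. Before any rank-based statistic the
#' phases are therefore mapped into the half-open 24-h window centred on
#' their circular mean, `(center - 12, center + 12]`.
#'
#' @param x Phase values in hours.
#' @param center Optional window centre; defaults to the circular mean of `x`.
#' @return Aligned values, congruent to `x` modulo 24.
#' @export
align_phase <- function(x, center = NULL) {
  if (is.null(center)) {
    center <- atan2(mean(sin(2 * pi * x / 24)),
                    mean(cos(2 * pi * x / 24))) * 12 / pi
  }
  center + ((x - center + 12) %% 24) - 12
}

.report_group_table <- function(fits, clinical) {
  merged <- merge(fits, clinical[, c("subject_id", "group")], by = "subject_id")
  merged$b3 <- align_phase(merged$b3)
  params <- c("b1", "b2", "b3", "b4", "b_max")
  rows <- lapply(params, function(pn) {
    a <- merged[[pn]][merged$group == "EG"]
    b <- merged[[pn]][merged$group == "CG"]
    mw <- mann_whitney_u(a, b)
    med_a <- mw$median_a; med_b <- mw$median_b
    if (pn == "b3") { med_a <- med_a %% 24; med_b <- med_b %% 24 }
    data.frame(parameter = pn, median_eg = med_a,
               median_cg = med_b, u_statistic = mw$u_statistic,
               p_value = mw$p_value, significant = mw$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.report_corr_table <- function(fits, clinical, group, features, adjust = "none") {
  ids <- clinical$subject_id[clinical$group == group]
  merged <- merge(fits[fits$subject_id %in% ids, ],
                  clinical, by = "subject_id")
  merged$b3 <- align_phase(merged$b3)
  params <- c("b1", "b2", "b3", "b4", "b_max")
  rows <- list()
  for (ft in features) for (pn in params) {
    # a covariate can be constant in a small group; its correlation row is NA
    sp <- tryCatch(spearman_rho(merged[[ft]], merged[[pn]]),
                   error = function(e) list(rho = NA_real_, p_value = NA_real_))
    rows[[length(rows) + 1L]] <- data.frame(
      feature = ft, parameter = pn, rho = sp$rho, p_value = sp$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (identical(adjust, "holm")) out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out
}

.report_logit <- function(fits, clinical) {
  eg <- merge(fits, clinical[clinical$group == "EG", ], by = "subject_id")
  eg$b3 <- align_phase(eg$b3)
  outcomes <- c("sleep_disorder", "sleep_associated_seizures",
                "generalized_seizures")
  lapply(outcomes, function(oc) {
    tryCatch(logit_fit(eg[, c("b1", "b2", "b3", "b4")], eg[[oc]], oc),
             error = function(e)
               structure(list(outcome = oc, n = nrow(eg), coefficients = NULL,
                              converged = FALSE, separation_detected = FALSE,
                              error = conditionMessage(e)),
                         class = "logit_summary"))
  })
}

.logit_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    if (is.null(s$coefficients))
      return(data.frame(outcome = s$outcome, term = NA, estimate = NA,
                        std_error = NA, z = NA, p_value = NA,
                        converged = s$converged,
                        separation_detected = s$separation_detected,
                        stringsAsFactors = FALSE))
    cbind(outcome = s$outcome, s$coefficients, converged = s$converged,
          separation_detected = s$separation_detected)
  }))
}

#' Compare stage: cohort statistics over fitted parameters
#'
#' Consumes the fit-stage table and the clinical covariates (never the raw
#' concentrations), drops excluded subjects, and produces the cohort report:
#' per-parameter group comparisons (Mann-Whitney U over `b1`, `b2`, `b3`,
#' `b4` and the per-subject `b_max = b1 + b2`), Spearman correlation tables
#' for each group (disease-associated covariates for EG only), logistic
#' regressions of the EG binary flags on `b1..b4`, and group-homogeneity
#' checks (age, intellectual-development quotient, sex).
#'
#' @param fits_path CSV written by [run_fit_stage()] (or its data frame).
#' @param clinical_path Clinical covariates CSV (or data frame).
#' @param output_dir If non-NULL, writes `report_group.csv`,
#'   `report_corr_eg.csv`, `report_corr_cg.csv`, `report_logit.csv` there.
#' @param config A [generator_config()] (`stats$adjust` honoured).
#' @return A `cohort_report` object.
#' @export
run_compare_stage <- function(fits_path, clinical_path, output_dir = NULL,
                              config = generator_config()) {
  fits <- if (is.data.frame(fits_path)) fits_path
          else utils::read.csv(fits_path, stringsAsFactors = FALSE)
  clinical <- if (is.data.frame(clinical_path)) clinical_path
              else utils::read.csv(clinical_path, stringsAsFactors = FALSE)
  orphans_f <- setdiff(fits$subject_id, clinical$subject_id)
  orphans_c <- setdiff(clinical$subject_id, fits$subject_id)
  if (length(orphans_f) || length(orphans_c))
    stop("subject id mismatch between fits and clinical tables; orphans: ",
         paste(c(orphans_f, orphans_c), collapse = ", "))

  if (!"excluded" %in% names(fits)) fits$excluded <- !fits$bell_shaped
  n_input <- nrow(fits)
  exclusions <- data.frame(
    subject_id = fits$subject_id[fits$excluded],
    reason = if ("exclusion_reason" %in% names(fits))
      fits$exclusion_reason[fits$excluded] else "not bell shaped",
    stringsAsFactors = FALSE)
  kept <- fits[!fits$excluded, ]
  kept$b_max <- kept$b1 + kept$b2
  clin_kept <- clinical[clinical$subject_id %in% kept$subject_id, ]

  adjust <- if (!is.null(config$stats$adjust)) config$stats$adjust else "none"
  eg_features <- c("age", "iq_quotient", "avg_seizures_per_day",
                   "seizures_day_before", "seizures_sampling_day", "n_aeds",
                   "disease_duration", "hours_since_last_seizure")
  cg_features <- c("age", "iq_quotient")

  homog <- list(
    age = mann_whitney_u(clin_kept$age[clin_kept$group == "EG"],
                         clin_kept$age[clin_kept$group == "CG"]),
    iq = mann_whitney_u(clin_kept$iq_quotient[clin_kept$group == "EG"],
                        clin_kept$iq_quotient[clin_kept$group == "CG"]),
    sex = tryCatch(
      chi2_independence(table(clin_kept$group, clin_kept$sex)),
      error = function(e) NULL))

  report <- structure(list(
    group_comparisons = .report_group_table(kept, clin_kept),
    correlations_eg = .report_corr_table(kept, clin_kept, "EG", eg_features,
                                         adjust),
    correlations_cg = .report_corr_table(kept, clin_kept, "CG", cg_features,
                                         adjust),
    logit_summaries = .report_logit(kept, clin_kept),
    homogeneity = homog,
    exclusions = exclusions,
    fit_quality_summary = list(
      n_input = n_input,
      n_analyzed = nrow(kept),
      n_excluded = nrow(exclusions),
      n_quality_pass = sum(kept$quality_pass),
      explained_variance = stats::quantile(kept$explained_variance,
                                           c(0, 0.25, 0.5, 0.75, 1)))),
    class = "cohort_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$group_comparisons,
                     file.path(output_dir, "report_group.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(report$correlations_eg,
                     file.path(output_dir, "report_corr_eg.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(report$correlations_cg,
                     file.path(output_dir, "report_corr_cg.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(.logit_table(report$logit_summaries),
                     file.path(output_dir, "report_logit.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  fq <- x$fit_quality_summary
  cat("Cohort report\n")
  cat(sprintf("  subjects: %d analysed + %d excluded of %d (quality pass: %d)\n",
              fq$n_analyzed, fq$n_excluded, fq$n_input, fq$n_quality_pass))
  cat("\nGroup comparison (Mann-Whitney U, EG vs CG):\n")
  gc <- x$group_comparisons
  gc$p_value <- signif(gc$p_value, 4)
  print(gc, row.names = FALSE, digits = 4)
  cat("\nSignificant Spearman correlations (EG):\n")
  sig <- x$correlations_eg[x$correlations_eg$significant, ]
  if (nrow(sig)) print(sig, row.names = FALSE, digits = 3)
  else cat("  none\n")
  cat("\nSignificant Spearman correlations (CG):\n")
  sig <- x$correlations_cg[x$correlations_cg$significant, ]
  if (nrow(sig)) print(sig, row.names = FALSE, digits = 3)
  else cat("  none\n")
  cat("\nLogit regressions (EG binary outcomes on b1..b4):\n")
  for (s in x$logit_summaries) {
    if (!is.null(s$coefficients)) {
      sig <- s$coefficients[s$coefficients$p_value < 0.05 &
                              s$coefficients$term != "(Intercept)", ]
      cat(sprintf("  %s: %s\n", s$outcome,
                  if (nrow(sig)) paste(sig$term, collapse = ", ")
                  else "no significant parameters"))
    } else {
      cat(sprintf("  %s: withheld (%s)\n", s$outcome,
                  if (isTRUE(s$separation_detected)) "separation"
                  else "not estimable"))
    }
  }
  invisible(x)
}

#' Run the full simulate-fit-compare pipeline
#'
#' Generates a synthetic cohort, writes it to `out_dir`, fits every subject,
#' and produces the cohort report, all under a single seed recorded in the
#' run manifest.
#'
#' @param config A [generator_config()], or a path to a YAML config file.
#' @param out_dir Run directory for all artifacts.
#' @param seed Optional seed override.
#' @param verbose Log per-subject fit diagnostics.
#' @return The `cohort_report`, invisibly.
#' @export
run_end_to_end <- function(config = generator_config(),
                           out_dir = tempfile("melcirc_run"),
                           seed = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- tryCatch(generate_cohort(config, seed = seed),
                     error = function(e) stop("simulate stage: ",
                                              conditionMessage(e)))
  write_cohort(cohort, out_dir)
  fits <- tryCatch(
    run_fit_stage(file.path(out_dir, "profiles.csv"),
                  file.path(out_dir, "fits.csv"), config, verbose = verbose),
    error = function(e) stop("fit stage: ", conditionMessage(e)))
  report <- tryCatch(
    run_compare_stage(fits, file.path(out_dir, "clinical.csv"),
                      out_dir, config),
    error = function(e) stop("compare stage: ", conditionMessage(e)))
  invisible(report)
}
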