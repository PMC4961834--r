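#' Two-sided Mann-Whitney U test
#'
#' Compares two independent samples on the count-scale U statistic. When the
#' combined sample size is at most 12 and there are no ties the exact null
#' distribution of U is used; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 3.
#' @return List with `u_statistic`, `p_value`, `median_a`, `median_b`,
#'   `method` (`"exact"` or `"normal"`), `significant` (at alpha = 0.05).
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  stopifnot(is.numeric(sample_a), is.numeric(sample_b))
  if (length(sample_a) < 3L || length(sample_b) < 3L)
    stop("each sample must contain at least 3 values")
  if (anyNA(sample_a) || anyNA(sample_b))
    stop("missing values are not allowed")
  pooled <- c(sample_a, sample_b)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both samples; p = 1")
    return(list(u_statistic = length(sample_a) * length(sample_b) / 2,
                p_value = 1, median_a = stats::median(sample_a),
                median_b = stats::median(sample_b), method = "degenerate",
                significant = FALSE))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- (length(pooled) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
  p <- min(wt$p.value, 1)
  list(u_statistic = unname(wt$statistic), p_value = p,
       median_a = stats::median(sample_a), median_b = stats::median(sample_b),
       method = if (exact) "exact" else "normal",
       significant = p < 0.05)
}

# All permutations of 1..n (n <= 8 is the practical ceiling).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Computes rho as the Pearson correlation of mid-ranks (average ranks for
#' ties). The default two-sided p-value uses the t-approximation with n - 2
#' degrees of freedom, appropriate for cohort-sized samples; an exact
#' permutation p-value is available for tiny fixtures (`n <= 8`).
#'
#' @param x,y Paired numeric vectors, length >= 4.
#' @param exact Use the exact permutation null distribution of rho.
#' @return List with `rho`, `p_value`, `n`, `significant` (alpha = 0.05).
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("at least 4 paired observations are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: a ranked vector has zero variance")
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8L) stop("exact permutation mode is limited to n <= 8")
    perms <- .permutations(n)
    rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, significant = p < 0.05)
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' No continuity correction, 1 degree of freedom.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   row and column marginals.
#' @return List with `statistic`, `p_value`, `significant`.
#' @export
chi2_independence <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("a 2x2 count table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a row or column marginal is zero")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       significant = ct$p.value < 0.05)
}

#' Logistic regression of a binary outcome on the model parameters
#'
#' Maximum-likelihood logit fit (iteratively reweighted least squares) of a
#' binary flag on the four secretion parameters, with Wald p-values. The
#' maximum concentration is never included as a predictor since it is the
#' sum of b1 and b2. Complete or quasi-separation is detected and flagged;
#' coefficient estimates are withheld in that case rather than reporting
#' diverged values.
#'
#' @param predictors Data frame with numeric columns `b1`, `b2`, `b3`, `b4`,
#'   one row per subject.
#' @param outcome Binary (0/1 or logical) vector, one value per subject.
#' @param outcome_name Label carried into the summary.
#' @return An object of class `logit_summary`: `outcome`, `n`,
#'   `coefficients` (term/estimate/std_error/z/p_value data frame, or `NULL`
#'   when withheld), `converged`, `separation_detected`.
#' @export
logit_fit <- function(predictors, outcome, outcome_name = "outcome") {
  need <- c("b1", "b2", "b3", "b4")
  miss <- setdiff(need, names(predictors))
  if (length(miss))
    stop("predictors must contain columns: ", paste(miss, collapse = ", "))
  outcome <- as.integer(as.logical(outcome))
  n <- nrow(predictors)
  if (length(outcome) != n) stop("outcome length must match predictor rows")
  if (anyNA(outcome)) stop("missing outcome values are not allowed")
  if (length(unique(outcome)) < 2L)
    stop("no variation in the outcome: logistic regression is undefined")
  if (n < 10L * length(need))
    stop("too few subjects: the subjects-per-predictor ratio must exceed 10 (",
         n, " subjects for ", length(need), " predictors)")

  dat <- data.frame(predictors[need], .y = outcome)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ b1 + b2 + b3 + b4, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  eta <- stats::predict(fit, type = "link")
  separated <- sep_warn || !fit$converged || max(abs(eta)) > 30 ||
    max(abs(stats::coef(fit)[-1L])) > 50
  coefs <- NULL
  if (!separated) {
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                        std_error = sm[, 2L], z = sm[, 3L],
                        p_value = sm[, 4L], row.names = NULL,
                        stringsAsFactors = FALSE)
  }
  structure(list(outcome = outcome_name, n = n, coefficients = coefs,
                 converged = fit$converged, separation_detected = separated),
            class = "logit_summary")
}

#' @export
print.logit_summary <- function(x, ...) {
  cat("Logit regression for outcome:", x$outcome, sprintf("(n = %d)\n", x$n))
  if (x$separation_detected) {
    cat("  separation detected; coefficients withheld\n")
  } else {
    print(x$coefficients, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
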