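#' Secretion model parameters
#'
#' Constructs the parameter vector of the periodic melatonin secretion model:
#' a baseline-plus-pulse curve with an exact 24-hour period.
#'
#' @param b1 Minimum melatonin concentration \[pg/mL\]; must be >= 0.
#' @param b2 Melatonin release amplitude \[pg/mL\]; must be >= 0. The maximum
#'   modelled concentration is `b1 + b2`.
#' @param b3 Phase shift of melatonin release \[h\]: the clock time of the
#'   secretion peak. Phase is circular, so any finite value is accepted and
#'   wrapped into `[0, 24)`.
#' @param b4 Sleep duration \[h\]: the full width at half maximum (FWHM) of
#'   the secretion peak; must lie strictly inside `(0, 12)`.
#'
#' @return An object of class `secretion_params`: a list with elements
#'   `b1`, `b2`, `b3`, `b4`.
#' @seealso [evaluate_model()], [fwhm_numeric()], [max_concentration()]
#' @export
#' @examples
#' p <- secretion_params(b1 = 6, b2 = 140, b3 = 2, b4 = 8)
#' evaluate_model(p, t = 2)  # peak: 6 + 140
secretion_params <- function(b1, b2, b3, b4) {
  stopifnot(is.numeric(b1), is.numeric(b2), is.numeric(b3), is.numeric(b4),
            length(b1) == 1L, length(b2) == 1L, length(b3) == 1L, length(b4) == 1L)
  if (!is.finite(b1) || b1 < 0)
    stop("b1 (minimum concentration) must be finite and >= 0, got ", b1)
  if (!is.finite(b2) || b2 < 0)
    stop("b2 (release amplitude) must be finite and >= 0, got ", b2)
  if (!is.finite(b3))
    stop("b3 (phase shift) must be finite, got ", b3)
  if (!is.finite(b4) || b4 <= 0 || b4 >= 12)
    stop("b4 (FWHM / sleep duration) must lie in the open interval (0, 12), got ", b4)
  structure(list(b1 = unname(b1), b2 = unname(b2), b3 = unname(b3) %% 24,
                 b4 = unname(b4)),
            class = "secretion_params")
}

#' @export
print.secretion_params <- function(x, ...) {
  cat("Melatonin secretion parameters\n")
  cat(sprintf("  b1 (minimum concentration): %8.4f pg/mL\n", x$b1))
  cat(sprintf("  b2 (release amplitude)    : %8.4f pg/mL\n", x$b2))
  cat(sprintf("  b3 (phase shift)          : %8.4f h\n", x$b3))
  cat(sprintf("  b4 (FWHM, sleep duration) : %8.4f h\n", x$b4))
  cat(sprintf("  b_max = b1 + b2           : %8.4f pg/mL\n", x$b1 + x$b2))
  invisible(x)
}

#' @export
as.double.secretion_params <- function(x, ...) {
  c(b1 = x$b1, b2 = x$b2, b3 = x$b3, b4 = x$b4)
}

as_secretion_params <- function(x) {
  if (inherits(x, "secretion_params")) return(x)
  x <- unlist(x)
  secretion_params(x[["b1"]], x[["b2"]], x[["b3"]], x[["b4"]])
}

#' Maximum modelled concentration
#'
#' The peak of the secretion curve, `b_max = b1 + b2` \[pg/mL\].
#'
#' @param params A [secretion_params()] object.
#' @return Numeric scalar.
#' @export
max_concentration <- function(params) {
  params <- as_secretion_params(params)
  params$b1 + params$b2
}

#' Horizontal scale factor of the secretion kernel
#'
#' Converts the FWHM parameter `b4` into the horizontal scale
#' `s = (cos(pi * b4 / 24) - 1) / sqrt(ln 2)` that makes the full width at
#' half maximum of the periodic Gaussian kernel equal exactly `b4` hours.
#'
#' The returned value is negative for all `b4` in `(0, 12)` (this sign is
#' stable across versions); downstream it only ever enters squared.
#'
#' @param b4 FWHM in hours, strictly inside `(0, 12)`.
#' @return Dimensionless scalar, negative.
#' @export
#' @examples
#' scale_factor(8)  # (cos(pi/3) - 1)/sqrt(log(2)) = -0.6006
scale_factor <- function(b4) {
  stopifnot(is.numeric(b4), length(b4) == 1L)
  if (!is.finite(b4) || b4 <= 0)
    stop("b4 must be > 0 (open lower bound), got ", b4)
  if (b4 >= 12)
    stop("b4 must be < 12 (open upper bound), got ", b4)
  (cos(pi * b4 / 24) - 1) / sqrt(log(2))
}

#' Evaluate the melatonin secretion model
#'
#' Computes the modelled absolute melatonin concentration
#' `MLT(t) = b1 + b2 * exp(-((cos(pi*t/12 - pi*b3/12) - 1)/s)^2)` with
#' `s = scale_factor(b4)`. The curve is periodic with period exactly 24 h,
#' peaks at `t = b3` with value `b1 + b2`, passes through `b1 + b2/2` at
#' `b3 +/- b4/2`, and is bounded between `b1` and `b1 + b2`.
#'
#' @param params A [secretion_params()] object (or coercible list).
#' @param t Time of day in hours; any real vector (periodicity folds times
#'   outside one day).
#' @return Concentrations \[pg/mL\], same length as `t`.
#' @export
evaluate_model <- function(params, t) {
  params <- as_secretion_params(params)
  stopifnot(is.numeric(t), all(is.finite(t)))
  s <- scale_factor(params$b4)
  z <- (cos(pi * t / 12 - pi * params$b3 / 12) - 1) / s
  params$b1 + params$b2 * exp(-z^2)
}

#' Clock time of the secretion peak
#'
#' @param params A [secretion_params()] object.
#' @return `b3` reduced to `[0, 24)`; the argmax of [evaluate_model()] over
#'   one period.
#' @export
peak_time <- function(params) {
  params <- as_secretion_params(params)
  params$b3 %% 24
}

#' Numeric full width at half maximum
#'
#' Locates, by root bracketing around the peak, the two times where the
#' modelled concentration equals `b1 + b2/2`, and returns their difference.
#' Serves as a numerical self-check that the horizontal scaling yields
#' FWHM = `b4` exactly.
#'
#' @param params A [secretion_params()] object with `b2 > 0`.
#' @param tol Root-finding tolerance in hours.
#' @return Width in hours; equals `b4` to within `tol`.
#' @export
fwhm_numeric <- function(params, tol = 1e-9) {
  params <- as_secretion_params(params)
  if (params$b2 <= 0)
    stop("FWHM is undefined for a flat curve (b2 = 0)")
  half <- params$b1 + params$b2 / 2
  f <- function(t) evaluate_model(params, t) - half
  eps <- 1e-9
  left  <- stats::uniroot(f, c(params$b3 - 12 + eps, params$b3), tol = tol)$root
  right <- stats::uniroot(f, c(params$b3, params$b3 + 12 - eps), tol = tol)$root
  right - left
}

#' Gap between the model minimum and the baseline b1
#'
#' The model's minimum over one period is attained half a period from the
#' peak and exceeds `b1` by `b2 * exp(-(2/s)^2)`. For physiological widths
#' (`b4 <= 11`) this gap is a tiny fraction of the amplitude, which is why
#' the minimum of the curve is read clinically as "approximately b1".
#'
#' @param params A [secretion_params()] object.
#' @return Nonnegative concentration \[pg/mL\].
#' @export
min_concentration_gap <- function(params) {
  params <- as_secretion_params(params)
  s <- scale_factor(params$b4)
  params$b2 * exp(-(2 / s)^2)
}
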