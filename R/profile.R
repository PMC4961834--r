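#' A single subject's sampling profile
#'
#' Bundles the time-stamped melatonin concentrations drawn from one subject.
#' Sampling times are clock hours; times in `[24, 48)` are folded into
#' `[0, 24)` by the model's periodicity and the samples re-ordered by folded
#' time. At least 5 samples are required (the model has 4 free parameters).
#'
#' @param subject_id Opaque subject label.
#' @param times Sampling times in hours, `[0, 48)`, unique after folding.
#' @param concentrations Melatonin concentrations \[pg/mL\], nonnegative,
#'   no missing values, same length as `times`.
#' @return An object of class `sampling_profile`.
#' @export
sampling_profile <- function(subject_id, times, concentrations) {
  stopifnot(length(subject_id) == 1L)
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations))
    stop("times and concentrations must have the same length")
  if (anyNA(times) || anyNA(concentrations))
    stop("missing values are not allowed in a sampling profile")
  if (length(times) < 5L)
    stop("insufficient data: at least 5 samples are required (got ",
         length(times), ")")
  if (any(times < 0 | times >= 48))
    stop("sampling times must lie in [0, 48) hours")
  if (any(concentrations < 0))
    stop("concentrations must be nonnegative")
  folded <- times %% 24
  ord <- order(folded)
  folded <- folded[ord]
  concentrations <- concentrations[ord]
  if (anyDuplicated(folded))
    stop("sampling times must be distinct after folding modulo 24")
  structure(list(subject_id = as.character(subject_id),
                 times = folded,
                 concentrations = concentrations),
            class = "sampling_profile")
}

#' @export
print.sampling_profile <- function(x, ...) {
  cat("Sampling profile for subject", x$subject_id, "\n")
  print(data.frame(time_h = x$times, melatonin_pg_ml = x$concentrations),
        row.names = FALSE)
  invisible(x)
}

#' Read sampling profiles from a delimited text file
#'
#' Expects a UTF-8 CSV with header columns `subject_id`, `time_h`,
#' `melatonin_pg_ml`; one row per blood sample. Times in `[0, 48)` are
#' accepted and folded modulo 24.
#'
#' @param path Path to the CSV file.
#' @return Named list of [sampling_profile()] objects, one per subject.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_h", "melatonin_pg_ml")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("profile table ", path, " contains no rows")
  for (col in c("time_h", "melatonin_pg_ml")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric or missing value in column '", col, "' at row ",
           bad[1L], " of ", path)
    df[[col]] <- v
  }
  out <- lapply(split(df, df$subject_id), function(d)
    sampling_profile(d$subject_id[1L], d$time_h, d$melatonin_pg_ml))
  out[unique(df$subject_id)]
}

#' Write sampling profiles to a delimited text file
#'
#' @param profiles List of [sampling_profile()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, time_h = p$times,
               melatonin_pg_ml = p$concentrations)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
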