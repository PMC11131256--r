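#' The 11 feature-descriptor column names
#'
#' \code{var_<parameter>} for each of the 11 skeleton parameters, e.g.
#' \code{var_th_9_10} is the averaged variance of the thigh angle.
#'
#' @return Character vector of length 11.
#' @export
feature_names <- function() paste0("var_", parameter_names())

.unusable <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("skelvar_unusable", "error")))
}

#' Windowed averaged variance of a parameter series
#'
#' The series is partitioned into K = floor(T / R) disjoint windows of R
#' consecutive frames (window k covers frames (k-1)R+1 ... kR); within each
#' window the unbiased sample variance (denominator R - 1) is computed and
#' the window variances are averaged. Trailing frames beyond K * R are
#' discarded. Invalid frames are excluded from a window's mean and variance
#' with the denominator reduced accordingly; a window with fewer than two
#' valid frames is skipped and does not enter the average.
#'
#' @param values Numeric series of length T.
#' @param valid Logical validity mask (default: non-NA values).
#' @param window Window size R in frames, at least 2. Default 30 frames
#'   (1 s at 30 Hz): short enough to capture within-second fidgeting, long
#'   enough to leave 240 windows per 4-minute recording for stable averaging.
#' @return The averaged variance (same squared units as \code{values}).
#'   Signals an error of class \code{skelvar_unusable} when T < R or no
#'   window retains two valid frames.
#' @export
windowed_average_variance <- function(values, valid = NULL, window = 30L) {
  R <- as.integer(window)
  if (R < 2L) stop("window size must be at least 2 (sample variance needs R-1 >= 1)")
  Tn <- length(values)
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(length(valid) == Tn)
  if (Tn < R)
    .unusable(sprintf("series of length %d is shorter than one window (R = %d)", Tn, R))
  K <- Tn %/% R
  x <- values[seq_len(K * R)]
  x[!valid[seq_len(K * R)]] <- NA_real_
  dim(x) <- c(R, K)
  nv <- colSums(!is.na(x))
  keep <- nv >= 2L
  if (!any(keep))
    .unusable("no window retains at least two valid frames")
  m <- colMeans(x, na.rm = TRUE)
  ctr <- x - rep(m, each = R)
  vars <- colSums(ctr^2, na.rm = TRUE) / (nv - 1L)
  mean(vars[keep])
}

#' Extract the 11 averaged-variance descriptors for one subject
#'
#' @param pset A \code{parameter_series} (see
#'   \code{\link{compute_parameter_series}}).
#' @param window Window size R passed to
#'   \code{\link{windowed_average_variance}}.
#' @return A one-row data frame with the 11 \code{var_*} descriptor columns
#'   and a \code{label} column; the row name is the subject id. Signals an
#'   error of class \code{skelvar_unusable} naming the offending parameters
#'   when any descriptor cannot be computed.
#' @export
extract_feature_vector <- function(pset, window = 30L) {
  stopifnot(inherits(pset, "parameter_series"))
  pn <- parameter_names()
  vals <- vapply(pn, function(p) {
    tryCatch(
      windowed_average_variance(pset$values[, p], pset$valid[, p], window = window),
      skelvar_unusable = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(vals))
    .unusable(sprintf("subject %s: unusable descriptor(s): %s", pset$subject_id,
                      paste(pn[is.na(vals)], collapse = ", ")),
              subject = pset$subject_id, features = pn[is.na(vals)])
  out <- as.data.frame(as.list(vals))
  names(out) <- feature_names()
  out$label <- pset$label
  rownames(out) <- pset$subject_id
  out
}

#' Stack per-subject feature vectors into the cohort dataset matrix
#'
#' @param fvs List of one-row feature data frames from
#'   \code{\link{extract_feature_vector}}.
#' @return Data frame with one row per subject (row names = subject ids) and
#'   12 columns: the 11 \code{var_*} descriptors and a \code{label} factor
#'   with levels ADHD / non-ADHD. Subject order is the input order.
#' @export
build_dataset <- function(fvs) {
  if (length(fvs) < 1L) stop("no feature vectors supplied")
  ids <- vapply(fvs, rownames, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate subject id(s): ", paste(unique(dup), collapse = ", "))
  out <- do.call(rbind, fvs)
  out$label <- factor(out$label, levels = .group_levels)
  if (anyNA(out$label)) stop("labels must be 'ADHD' or 'non-ADHD'")
  out
}

#' Full cohort pipeline: skeleton sequences to dataset matrix
#'
#' Runs \code{\link{compute_parameter_series}} and
#' \code{\link{extract_feature_vector}} on every sequence and stacks the
#' results. Subjects with unusable descriptors are dropped with a warning
#' naming them and the reason.
#'
#' @param cohort List of \code{skeleton_sequence} objects.
#' @param window Averaging window size in frames.
#' @param truncate_min Recording minutes kept per subject.
#' @return Dataset matrix as from \code{\link{build_dataset}}.
#' @export
cohort_features <- function(cohort, window = 30L, truncate_min = 4) {
  fvs <- list()
  dropped <- character(0)
  for (seq in cohort) {
    fv <- tryCatch(
      extract_feature_vector(compute_parameter_series(seq, truncate_min), window),
      skelvar_unusable = function(e) conditionMessage(e))
    if (is.character(fv)) dropped <- c(dropped, fv) else fvs[[length(fvs) + 1L]] <- fv
  }
  if (length(dropped))
    warning("dropped unusable subject(s):\n  ", paste(dropped, collapse = "\n  "))
  build_dataset(fvs)
}
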