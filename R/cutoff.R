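#' Youden's J statistic
#'
#' @param sensitivity,specificity Proportions in [0, 1].
#' @return sensitivity + specificity - 1.
#' @export
youden <- function(sensitivity, specificity) sensitivity + specificity - 1

#' Rank-based (Mann-Whitney) AUC
#'
#' Threshold-free area under the ROC curve: the probability that a randomly
#' chosen positive scores higher than a randomly chosen negative, with ties
#' counted one half. Equals the trapezoidal ROC area for tie-free data and
#' stays well defined with ties. Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param is_positive Logical vector, TRUE for the positive class.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive))
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.check_labeled <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% .group_levels))
    stop("labels must be 'ADHD' or 'non-ADHD'")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  labels
}

#' Optimal cutpoint by Youden-index maximization
#'
#' Candidate cutpoints are the distinct observed values. The decision rule
#' is fixed: predict ADHD when value >= cutpoint (movement-variance
#' descriptors are systematically larger in the ADHD group, so high = ADHD).
#' Among candidates with maximal J the smallest is returned, which favors
#' sensitivity.
#'
#' @param values Numeric descriptor values.
#' @param labels Group labels (\code{"ADHD"} / \code{"non-ADHD"}).
#' @return List with \code{cutpoint}, \code{youden}, \code{sensitivity},
#'   \code{specificity} (the in-sample values at the chosen cutpoint).
#' @export
optimal_cutpoint <- function(values, labels) {
  labels <- .check_labeled(values, labels)
  pos <- values[labels == "ADHD"]
  neg <- values[labels != "ADHD"]
  cands <- sort(unique(values))
  sens <- vapply(cands, function(cc) mean(pos >= cc), numeric(1))
  spec <- vapply(cands, function(cc) mean(neg < cc), numeric(1))
  J <- youden(sens, spec)
  best <- which(J == max(J))[1L]   # cands ascending -> smallest maximizer
  list(cutpoint = cands[best], youden = J[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Evaluate a cutpoint on a labeled test set
#'
#' Applies the fixed rule (predict ADHD when value >= cutpoint) and returns
#' the four performance indices. AUC is threshold-free
#' (\code{\link{rank_auc}} of the raw values), independent of the cutpoint.
#'
#' @param cutpoint Numeric threshold.
#' @param values,labels Test-set descriptor values and group labels.
#' @return Named list: \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{auc}, all in [0, 1].
#' @export
evaluate_cutpoint <- function(cutpoint, values, labels) {
  labels <- .check_labeled(values, labels)
  truth <- labels == "ADHD"
  pred <- values >= cutpoint
  list(accuracy = mean(pred == truth),
       sensitivity = mean(pred[truth]),
       specificity = mean(!pred[!truth]),
       auc = rank_auc(values, truth))
}

#' Bootstrap optimal-cutpoint analysis of one descriptor
#'
#' Repeats, \code{reps} times: draw an in-bag sample of size N with
#' replacement, find the Youden-optimal cutpoint on it
#' (\code{\link{optimal_cutpoint}}), and evaluate that cutpoint on the
#' out-of-bag samples (\code{\link{evaluate_cutpoint}}). Degenerate draws
#' (in-bag or out-of-bag missing a class) are redrawn so exactly \code{reps}
#' valid repetitions contribute; more than \code{max_redraw} consecutive
#' degenerate draws aborts (pathological input). Reported values are the
#' means over repetitions.
#'
#' @param values,labels Descriptor values and group labels.
#' @param reps Number of bootstrap repetitions (default 100).
#' @param seed Optional integer seed for reproducibility.
#' @param feature Descriptor name carried into the result.
#' @param max_redraw Consecutive degenerate-draw limit (default 1000).
#' @return Object of class \code{cutoff_result}: list with \code{feature},
#'   \code{summary} (mean cutpoint and mean out-of-bag indices),
#'   \code{records} (one row per repetition, including the fraction of
#'   distinct subjects in each in-bag set), \code{n_degenerate} and
#'   \code{seed}.
#' @export
bootstrap_cutoff <- function(values, labels, reps = 100L, seed = NULL,
                             feature = "feature", max_redraw = 1000L) {
  labels <- .check_labeled(values, labels)
  N <- length(values)
  if (N < 4L) stop("at least 4 samples required")
  stopifnot(reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  rec <- matrix(NA_real_, reps, 6L,
                dimnames = list(NULL, c("cutpoint", "accuracy", "sensitivity",
                                        "specificity", "auc", "inbag_unique_frac")))
  n_degenerate <- 0L
  for (b in seq_len(reps)) {
    consecutive <- 0L
    repeat {
      idx <- sample.int(N, N, replace = TRUE)
      oob <- setdiff(seq_len(N), idx)
      if (length(unique(labels[idx])) == 2L && length(unique(labels[oob])) == 2L)
        break
      consecutive <- consecutive + 1L
      n_degenerate <- n_degenerate + 1L
      if (consecutive > max_redraw)
        stop("aborting: ", max_redraw,
             " consecutive degenerate bootstrap draws (pathological input)")
    }
    cp <- optimal_cutpoint(values[idx], labels[idx])
    perf <- evaluate_cutpoint(cp$cutpoint, values[oob], labels[oob])
    rec[b, ] <- c(cp$cutpoint, perf$accuracy, perf$sensitivity,
                  perf$specificity, perf$auc, length(unique(idx)) / N)
  }
  structure(
    list(feature = feature, reps = reps,
         summary = colMeans(rec)[1:5],
         records = as.data.frame(rec),
         n_degenerate = n_degenerate, seed = seed),
    class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cutoff_result> %s (%d bootstrap repetitions)\n", x$feature, x$reps))
  cat(sprintf("  mean optimal cutpoint: %.2f\n", s["cutpoint"]))
  cat(sprintf("  out-of-bag means: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.2f%%\n",
              100 * s["accuracy"], 100 * s["sensitivity"],
              100 * s["specificity"], 100 * s["auc"]))
  if (x$n_degenerate > 0)
    cat(sprintf("  (%d degenerate draws redrawn)\n", x$n_degenerate))
  invisible(x)
}

#' Bootstrap cutoff analysis of all 11 descriptors
#'
#' Runs \code{\link{bootstrap_cutoff}} on every \code{var_*} column of a
#' dataset matrix and tabulates the mean optimal cutpoint and the four mean
#' out-of-bag indices per descriptor (proportions in [0, 1]).
#'
#' @param dataset Dataset matrix from \code{\link{build_dataset}} or
#'   \code{\link{generate_feature_table}}.
#' @param reps Bootstrap repetitions per descriptor.
#' @param seed Optional integer seed (one stream for the whole table).
#' @return Data frame: \code{feature}, \code{optimal_cutpoint},
#'   \code{accuracy}, \code{sensitivity}, \code{specificity}, \code{auc}.
#' @export
cutoff_analysis <- function(dataset, reps = 100L, seed = NULL) {
  feats <- intersect(feature_names(), names(dataset))
  if (!length(feats)) stop("no var_* descriptor columns in dataset")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(feats, function(f) {
    res <- bootstrap_cutoff(dataset[[f]], dataset$label, reps = reps, feature = f)
    data.frame(feature = f, optimal_cutpoint = res$summary[["cutpoint"]],
               accuracy = res$summary[["accuracy"]],
               sensitivity = res$summary[["sensitivity"]],
               specificity = res$summary[["specificity"]],
               auc = res$summary[["auc"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
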