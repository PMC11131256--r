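#' Per-descriptor group comparison (mean +/- SD and two-sample t-test)
#'
#' For each \code{var_*} descriptor: group means and standard deviations and
#' a two-sided two-sample t-test between ADHD and non-ADHD. The default is
#' the Welch unequal-variance form, appropriate here because descriptor SDs
#' routinely differ several-fold between the groups; the pooled-variance
#' test is available by flag. Significance stars follow the conventional
#' thresholds: * p < 0.05, ** p < 0.01, *** p < 0.001. No multiplicity
#' adjustment is applied across the 11 tests.
#'
#' @param dataset Dataset matrix (\code{var_*} columns + \code{label}).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Data frame with one row per descriptor: \code{descriptor},
#'   \code{adhd_mean}, \code{adhd_sd}, \code{non_adhd_mean},
#'   \code{non_adhd_sd}, \code{p_value}, \code{significance}. A descriptor
#'   with zero variance in both groups gets \code{p_value = NA} and
#'   significance \code{"(undefined)"}.
#' @export
compare_groups <- function(dataset, var_equal = FALSE) {
  feats <- intersect(feature_names(), names(dataset))
  if (!length(feats)) stop("no var_* descriptor columns in dataset")
  lab <- as.character(dataset$label)
  if (sum(lab == "ADHD") < 2L || sum(lab == "non-ADHD") < 2L)
    stop("at least 2 subjects per group required")
  rows <- lapply(feats, function(f) {
    a <- dataset[[f]][lab == "ADHD"]
    b <- dataset[[f]][lab == "non-ADHD"]
    p <- tryCatch(stats::t.test(a, b, var.equal = var_equal)$p.value,
                  error = function(e) NA_real_)
    stars <- if (is.na(p)) "(undefined)"
             else if (p < 0.001) "***"
             else if (p < 0.01) "**"
             else if (p < 0.05) "*"
             else ""
    data.frame(descriptor = f,
               adhd_mean = mean(a), adhd_sd = stats::sd(a),
               non_adhd_mean = mean(b), non_adhd_sd = stats::sd(b),
               p_value = p, significance = stars)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
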