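# Independent oracles and fixture builders shared across the test files.
# Oracles are deliberately written as plain loops, independent of the
# vectorized implementation paths they check.

# Mean over windows of the plain sample variance of the valid frames.
oracle_windowed_var <- function(values, valid, R) {
  K <- length(values) %/% R
  vars <- numeric(0)
  for (k in seq_len(K)) {
    idx <- ((k - 1) * R + 1):(k * R)
    v <- values[idx][valid[idx]]
    if (length(v) >= 2) vars <- c(vars, stats::var(v))
  }
  if (!length(vars)) return(NA_real_)
  mean(vars)
}

# Exhaustive cutpoint scan over every candidate and both orientations of the
# decision rule (predict ADHD when value >= c, or when value < c).
oracle_best_cutpoint <- function(values, labels) {
  pos <- values[labels == "ADHD"]; neg <- values[labels != "ADHD"]
  best <- list(J = -Inf)
  for (cc in sort(unique(values))) {
    J_ge <- mean(pos >= cc) + mean(neg < cc) - 1
    J_lt <- mean(pos < cc) + mean(neg >= cc) - 1
    for (orient in c("ge", "lt")) {
      J <- if (orient == "ge") J_ge else J_lt
      if (J > best$J) best <- list(J = J, cutpoint = cc, orientation = orient)
    }
  }
  best
}

# A tiny sequence with hand-controlled joints. `coords` is a list of T
# matrices 25 x 2; confidence defaults to fully detected.
make_sequence <- function(coords, conf = NULL, subject_id = "S1",
                          label = "non-ADHD", fps = 30) {
  Tn <- length(coords)
  x <- t(vapply(coords, function(m) m[, 1], numeric(25)))
  y <- t(vapply(coords, function(m) m[, 2], numeric(25)))
  if (is.null(conf)) conf <- matrix(0.9, Tn, 25)
  skeleton_sequence(x, y, conf, subject_id = subject_id, label = label,
                    fps = fps, width = 1280, height = 720)
}

# Random fully detected posture-like frames.
random_coords <- function(Tn, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(Tn), function(t)
    cbind(runif(25, 100, 1100), runif(25, 100, 600)))
}

# A two-class 1-D labeled sample with the ADHD group shifted upward.
shifted_sample <- function(n_pos, n_neg, delta = 2.5) {
  values <- c(rnorm(n_pos, delta), rnorm(n_neg, 0))
  labels <- rep(c("ADHD", "non-ADHD"), c(n_pos, n_neg))
  list(values = values, labels = labels)
}

# Feature table in which only the thigh angle separates the groups; all
# other descriptors share one distribution across groups.
dominant_thigh_table <- function(n_per_group = 48, seed = 1) {
  params <- default_descriptor_params()
  dom <- params$feature == "var_th_9_10"
  params$adhd_mean[!dom] <- params$non_adhd_mean[!dom]
  params$adhd_sd[!dom] <- params$non_adhd_sd[!dom]
  generate_feature_table(n_per_group, params, seed = seed)
}
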