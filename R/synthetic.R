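#' Reference descriptor distributions for the two groups
#'
#' Per-descriptor mean and SD for each group, used as the defaults of
#' \code{\link{generate_feature_table}}. The values encode the package's
#' reference scenario: a seated pediatric outpatient contrast in which every
#' movement-variance descriptor is markedly larger in the ADHD group, with
#' the thigh angle (body spin on a swivel chair) the most discriminative.
#' Units: pixels^2 for lengths, degrees^2 for angles.
#'
#' @return Data frame: \code{feature}, \code{adhd_mean}, \code{adhd_sd},
#'   \code{non_adhd_mean}, \code{non_adhd_sd}.
#' @export
default_descriptor_params <- function() {
  data.frame(
    feature = feature_names(),
    adhd_mean     = c(39.78, 39.69, 18.29, 16.72, 164.99,
                      141.33, 123.39, 127.43, 99.21, 157.89, 50.60),
    adhd_sd       = c(7.22, 7.11, 3.13, 2.91, 41.86,
                      19.57, 17.35, 18.27, 14.22, 32.81, 17.65),
    non_adhd_mean = c(9.77, 10.15, 5.93, 5.49, 22.51,
                      73.57, 74.36, 75.74, 51.62, 15.37, 8.60),
    non_adhd_sd   = c(1.66, 1.70, 1.09, 1.14, 7.31,
                      21.37, 21.33, 19.27, 12.00, 6.62, 2.53))
}

#' Analytic AUC of two Gaussian classes
#'
#' For descriptor values N(mu1, sd1) in the positive and N(mu0, sd0) in the
#' negative class, the AUC of the "higher = positive" rule is
#' Phi((mu1 - mu0) / sqrt(sd1^2 + sd0^2)). Used as an independent oracle to
#' predict cutoff/classification performance on generated feature tables.
#'
#' @param mu1,sd1 Positive-class mean and SD.
#' @param mu0,sd0 Negative-class mean and SD.
#' @return AUC in (0, 1).
#' @export
expected_auc_gaussian <- function(mu1, sd1, mu0, sd0)
  stats::pnorm((mu1 - mu0) / sqrt(sd1^2 + sd0^2))

#' Generate a feature-table cohort with exact distributional control
#'
#' Draws each subject's 11 descriptors from per-group zero-truncated
#' Gaussians (negative draws are redrawn; with the default parameters the
#' truncation is negligible). Descriptors are independent by default -- a
#' simplification, since real movement descriptors correlate -- with an
#' optional common-factor knob: with \code{rho > 0} each subject's 11
#' standard-normal deviates share a latent factor giving pairwise
#' correlation rho before redrawing.
#'
#' @param n_per_group Subjects per group (default 48 + 48).
#' @param params Per-descriptor group means/SDs, as
#'   \code{\link{default_descriptor_params}}.
#' @param seed Optional integer seed.
#' @param rho Common-factor correlation in [0, 1).
#' @return Dataset matrix: one row per subject, 11 \code{var_*} columns and
#'   a \code{label} factor; ADHD rows first.
#' @export
generate_feature_table <- function(n_per_group = 48L,
                                   params = default_descriptor_params(),
                                   seed = NULL, rho = 0) {
  stopifnot(n_per_group >= 1L, rho >= 0, rho < 1,
            all(params$adhd_sd > 0), all(params$non_adhd_sd > 0),
            all(params$adhd_mean > 0), all(params$non_adhd_mean > 0))
  if (!is.null(seed)) set.seed(seed)
  draw_group <- function(n, means, sds) {
    p <- length(means)
    z <- matrix(stats::rnorm(n * p), n, p)
    if (rho > 0) {
      f <- stats::rnorm(n)
      z <- sqrt(rho) * matrix(f, n, p) + sqrt(1 - rho) * z
    }
    mm <- matrix(means, n, p, byrow = TRUE)
    ss <- matrix(sds, n, p, byrow = TRUE)
    x <- mm + ss * z
    while (any(bad <- x <= 0))
      x[bad] <- mm[bad] + ss[bad] * stats::rnorm(sum(bad))
    x
  }
  a <- draw_group(n_per_group, params$adhd_mean, params$adhd_sd)
  b <- draw_group(n_per_group, params$non_adhd_mean, params$non_adhd_sd)
  out <- as.data.frame(rbind(a, b))
  names(out) <- params$feature
  out$label <- factor(rep(.group_levels, each = n_per_group),
                      levels = .group_levels)
  rownames(out) <- c(sprintf("ADHD_%02d", seq_len(n_per_group)),
                     sprintf("CTRL_%02d", seq_len(n_per_group)))
  out
}

#' Configuration of the skeleton-level cohort generator
#'
#' Describes a two-group cohort of seated subjects filmed at a fixed camera:
#' a nominal seated BODY_25 posture in a 1280 x 720 frame, per-group
#' frame-to-frame Gaussian joint jitter, and intermittent "fidget events" --
#' smooth correlated displacement bouts of the hip/knee/shoulder joints
#' emulating body spin on a swivel chair, the dominant hyperactive movement
#' in a consulting room. The ADHD group must fidget at least as much as the
#' non-ADHD group in amplitude and rate. Nuisance structure: per-joint
#' missing detections, and (when exporting raw pose JSON with
#' \code{\link{write_openpose_json}}) an occasional spurious second person.
#'
#' @param n_adhd,n_non_adhd Subjects per group.
#' @param fps Frame rate (Hz). @param duration_s Recording length (s).
#' @param width,height Frame size (px).
#' @param jitter_sd Named per-group SD (px) of per-frame joint jitter.
#' @param event_rate_per_min Named per-group mean fidget events per minute.
#' @param event_amplitude Named per-group peak event displacement (px).
#' @param event_duration_s Nominal event length (s).
#' @param missing_prob Per joint-frame missing-detection probability.
#' @param spurious_person_prob Per-frame probability of a second person in
#'   exported pose JSON.
#' @return A \code{cohort_config} list.
#' @export
cohort_config <- function(n_adhd = 48L, n_non_adhd = 48L, fps = 30,
                          duration_s = 240,
                          width = 1280L, height = 720L,
                          jitter_sd = c(ADHD = 3, `non-ADHD` = 1),
                          event_rate_per_min = c(ADHD = 6, `non-ADHD` = 0.5),
                          event_amplitude = c(ADHD = 60, `non-ADHD` = 8),
                          event_duration_s = 2,
                          missing_prob = 0.005,
                          spurious_person_prob = 0.01) {
  pick <- function(v) if (is.null(names(v))) stats::setNames(rep_len(v, 2), .group_levels)
                      else v[.group_levels]
  jitter_sd <- pick(jitter_sd)
  event_rate_per_min <- pick(event_rate_per_min)
  event_amplitude <- pick(event_amplitude)
  stopifnot(n_adhd >= 1, n_non_adhd >= 1, fps > 0, duration_s > 0,
            all(jitter_sd >= 0), all(event_rate_per_min >= 0),
            all(event_amplitude >= 0),
            missing_prob >= 0, missing_prob <= 1,
            spurious_person_prob >= 0, spurious_person_prob <= 1)
  if (event_amplitude["ADHD"] < event_amplitude["non-ADHD"] ||
      event_rate_per_min["ADHD"] < event_rate_per_min["non-ADHD"])
    stop("ADHD fidget-event amplitude and rate must be >= the non-ADHD group's")
  structure(list(n_adhd = n_adhd, n_non_adhd = n_non_adhd, fps = fps,
                 duration_s = duration_s, width = width, height = height,
                 jitter_sd = jitter_sd, event_rate_per_min = event_rate_per_min,
                 event_amplitude = event_amplitude,
                 event_duration_s = event_duration_s,
                 missing_prob = missing_prob,
                 spurious_person_prob = spurious_person_prob),
            class = "cohort_config")
}

# Nominal seated posture (px) of a child facing the consulting-room camera.
.base_posture <- function() {
  m <- matrix(c(
    640, 200,   # 0 nose
    640, 260,   # 1 neck
    570, 265,   # 2 right shoulder
    545, 340,   # 3 right elbow
    540, 410,   # 4 right wrist
    710, 265,   # 5 left shoulder
    735, 340,   # 6 left elbow
    740, 410,   # 7 left wrist
    640, 430,   # 8 mid hip
    595, 430,   # 9 right hip
    570, 540,   # 10 right knee
    575, 650,   # 11 right ankle
    685, 430,   # 12 left hip
    710, 540,   # 13 left knee
    705, 650,   # 14 left ankle
    620, 185,   # 15 right eye
    660, 185,   # 16 left eye
    600, 195,   # 17 right ear
    680, 195,   # 18 left ear
    720, 700,   # 19 left big toe
    735, 700,   # 20 left small toe
    700, 670,   # 21 left heel
    560, 700,   # 22 right big toe
    545, 700,   # 23 right small toe
    580, 670    # 24 right heel
  ), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

# How strongly a swivel bout displaces each joint (legs most, head least).
.swivel_weights <- function() {
  w <- rep(0.3, 25)
  w[c(10, 13) + 1] <- 1.0          # knees
  w[c(11, 14, 19:24) + 1] <- 0.9   # ankles, feet
  w[c(9, 12) + 1] <- 0.7           # hips
  w[8 + 1] <- 0.6                  # mid hip
  w[c(2, 5) + 1] <- 0.35           # shoulders
  w[c(3, 4, 6, 7) + 1] <- 0.45    # arms
  w[c(0, 15:18) + 1] <- 0.25       # head
  w
}

.generate_subject <- function(cfg, label, subject_id) {
  Tn <- as.integer(round(cfg$duration_s * cfg$fps))
  base <- .base_posture()
  jit <- cfg$jitter_sd[[label]]
  x <- matrix(base[, 1], Tn, 25L, byrow = TRUE) +
       matrix(stats::rnorm(Tn * 25L, sd = jit), Tn, 25L)
  y <- matrix(base[, 2], Tn, 25L, byrow = TRUE) +
       matrix(stats::rnorm(Tn * 25L, sd = jit), Tn, 25L)
  n_events <- stats::rpois(1L, cfg$event_rate_per_min[[label]] * cfg$duration_s / 60)
  w <- .swivel_weights()
  amp <- cfg$event_amplitude[[label]]
  if (n_events > 0 && amp > 0) {
    for (e in seq_len(n_events)) {
      start <- sample.int(Tn, 1L)
      len <- max(2L, round(cfg$event_duration_s * cfg$fps * stats::runif(1, 0.5, 1.5)))
      idx <- start:min(Tn, start + len - 1L)
      u <- seq(0, 1, length.out = length(idx))
      disp <- amp * sin(pi * u) * sample(c(-1, 1), 1L)
      x[idx, ] <- x[idx, ] + disp %o% w
      y[idx, ] <- y[idx, ] + (0.3 * disp) %o% w
    }
  }
  x <- pmin(pmax(x, 0), cfg$width - 1L)
  y <- pmin(pmax(y, 0), cfg$height - 1L)
  conf <- matrix(stats::runif(Tn * 25L, 0.5, 0.95), Tn, 25L)
  conf[matrix(stats::runif(Tn * 25L) < cfg$missing_prob, Tn, 25L)] <- 0
  skeleton_sequence(x, y, conf, subject_id = subject_id, label = label,
                    fps = cfg$fps, width = cfg$width, height = cfg$height)
}

#' Generate a skeleton-level two-group cohort
#'
#' Simulates every subject's full skeleton sequence under the movement model
#' of \code{\link{cohort_config}}, exercising the whole pipeline
#' (kinematics, features, analyses) end to end. Deterministic given
#' \code{seed}. With zero jitter and zero events every subject is motionless
#' and all downstream descriptors are exactly zero.
#'
#' @param config A \code{cohort_config}.
#' @param seed Optional integer seed.
#' @return List of \code{skeleton_sequence} objects (ADHD subjects first).
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  ids <- c(sprintf("ADHD_%02d", seq_len(config$n_adhd)),
           sprintf("CTRL_%02d", seq_len(config$n_non_adhd)))
  labels <- rep(.group_levels, c(config$n_adhd, config$n_non_adhd))
  mapply(function(id, lab) .generate_subject(config, lab, id),
         ids, labels, SIMPLIFY = FALSE)
}

#' Export a skeleton sequence as per-frame pose-estimation JSON
#'
#' Writes one OpenPose-style BODY_25 JSON file per frame (a \code{people}
#' array of flat 75-number keypoint vectors; missing joints written as
#' 0,0,0). With \code{spurious_person_prob > 0} an occasional second person
#' (a bystander posture offset to the frame edge) is added, emulating a
#' parent or clinician entering the view -- input for testing person
#' tracking.
#'
#' @param seq A \code{skeleton_sequence}.
#' @param dir Output directory (created if needed).
#' @param spurious_person_prob Per-frame probability of a second person.
#' @param seed Optional integer seed.
#' @return Invisibly, the written file paths.
#' @export
write_openpose_json <- function(seq, dir, spurious_person_prob = 0, seed = NULL) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Tn <- n_frames(seq)
  base <- .base_posture()
  paths <- character(Tn)
  for (t in seq_len(Tn)) {
    fr <- get_frame(seq, t)
    fr[fr[, 3] == 0, 1:2] <- 0
    people <- list(list(person_id = -1L,
                        pose_keypoints_2d = as.vector(t(fr))))
    if (stats::runif(1) < spurious_person_prob) {
      bx <- pmin(pmax(base[, 1] - 400 + stats::rnorm(25, sd = 2), 0), seq$width - 1L)
      by <- pmin(pmax(base[, 2] + stats::rnorm(25, sd = 2), 0), seq$height - 1L)
      other <- cbind(bx, by, stats::runif(25, 0.3, 0.9))
      people[[2]] <- list(person_id = -1L, pose_keypoints_2d = as.vector(t(other)))
    }
    paths[t] <- file.path(dir, sprintf("%s_%012d_keypoints.json", seq$subject_id, t - 1L))
    jsonlite::write_json(list(version = 1.3, people = people), paths[t],
                         auto_unbox = TRUE, digits = 8)
  }
  invisible(paths)
}
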