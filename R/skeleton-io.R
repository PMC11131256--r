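#' BODY_25 joint names
#'
#' Names of the 25 keypoints of the BODY_25 skeleton model, in slot order
#' (slot 0 = nose, slot 1 = neck, ...). Throughout the package joints are
#' referred to by their 0-based slot index, matching the pose tool's output.
#'
#' @return Character vector of length 25.
#' @export
body25_joints <- function() {
  c("nose", "neck", "right_shoulder", "right_elbow", "right_wrist",
    "left_shoulder", "left_elbow", "left_wrist", "mid_hip", "right_hip",
    "right_knee", "right_ankle", "left_hip", "left_knee", "left_ankle",
    "right_eye", "left_eye", "right_ear", "left_ear", "left_big_toe",
    "left_small_toe", "left_heel", "right_big_toe", "right_small_toe",
    "right_heel")
}

.group_levels <- c("ADHD", "non-ADHD")

#' Construct a skeleton sequence
#'
#' A skeleton sequence holds one subject's ordered frames of 25 BODY_25
#' keypoints. Coordinates are pixels, origin top-left, x rightward,
#' y downward. A joint with detection confidence 0 is "missing"; its
#' coordinates carry no meaning and are stored as NA.
#'
#' @param x,y Numeric T x 25 matrices of pixel coordinates (frames in rows,
#'   joint slots 0-24 in columns).
#' @param confidence Numeric T x 25 matrix of detection confidences in [0, 1].
#' @param subject_id Subject identifier (scalar character).
#' @param label Group label, one of \code{"ADHD"}, \code{"non-ADHD"}.
#' @param fps Frame rate in frames per second (nominally 30).
#' @param width,height Frame size in pixels (nominally 1280 x 720).
#' @return An object of class \code{skeleton_sequence}.
#' @export
skeleton_sequence <- function(x, y, confidence, subject_id,
                              label = c("ADHD", "non-ADHD"),
                              fps = 30, width = 1280, height = 720) {
  label <- match.arg(label)
  x <- as.matrix(x); y <- as.matrix(y); confidence <- as.matrix(confidence)
  if (ncol(x) != 25L || !all(dim(x) == dim(y)) || !all(dim(x) == dim(confidence)))
    stop("x, y and confidence must be T x 25 matrices of equal dimension")
  if (nrow(x) < 1L) stop("a skeleton sequence needs at least one frame")
  if (anyNA(confidence) || any(confidence < 0) || any(confidence > 1))
    stop("confidences must lie in [0, 1] and contain no NA")
  if (fps <= 0) stop("fps must be positive")
  miss <- confidence == 0
  x[miss] <- NA_real_
  y[miss] <- NA_real_
  dimnames(x) <- dimnames(y) <- dimnames(confidence) <- NULL
  structure(
    list(subject_id = as.character(subject_id), label = label, fps = fps,
         width = as.integer(width), height = as.integer(height),
         x = x, y = y, confidence = confidence),
    class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  miss <- mean(x$confidence == 0)
  cat(sprintf("<skeleton_sequence> %s [%s]\n", x$subject_id, x$label))
  cat(sprintf("  %d frames @ %g Hz (%.1f s), %dx%d px, %.2f%% joints missing\n",
              nrow(x$x), x$fps, nrow(x$x) / x$fps, x$width, x$height, 100 * miss))
  invisible(x)
}

#' Number of frames in a skeleton sequence
#' @param seq A \code{skeleton_sequence}.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) nrow(seq$x)

#' Extract a single frame
#'
#' @param seq A \code{skeleton_sequence}.
#' @param t Frame position (1-based).
#' @return A 25 x 3 matrix with columns \code{x}, \code{y}, \code{confidence};
#'   rows are joint slots 0-24.
#' @export
get_frame <- function(seq, t) {
  stopifnot(t >= 1, t <= n_frames(seq))
  m <- cbind(x = seq$x[t, ], y = seq$y[t, ], confidence = seq$confidence[t, ])
  rownames(m) <- body25_joints()
  m
}

.empty_person <- function() {
  cbind(x = rep(NA_real_, 25), y = rep(NA_real_, 25), confidence = rep(0, 25))
}

.as_person <- function(v) {
  if (is.matrix(v)) {
    stopifnot(nrow(v) == 25L, ncol(v) == 3L)
    return(v)
  }
  v <- as.numeric(v)
  if (length(v) != 75L) stop("a detection must hold exactly 75 numbers (25 x 3)")
  matrix(v, ncol = 3L, byrow = TRUE, dimnames = list(NULL, c("x", "y", "confidence")))
}

#' Select the tracked person among several detections
#'
#' Pose estimation may detect several people in a frame (a parent, a
#' clinician). One person is selected deterministically: if a previous frame
#' with at least one detected joint is available, the candidate minimizing the
#' mean Euclidean distance over jointly detected joints is chosen (nearest
#' neighbor tracking, adequate for a seated subject); otherwise the candidate
#' with the largest total detection confidence. Ties go to the lowest
#' candidate index. Candidates sharing no detected joint with the previous
#' frame get infinite distance; if that holds for all candidates the
#' confidence rule is used as fallback.
#'
#' @param candidates List of detections, each a 25 x 3 matrix (or a flat
#'   75-vector) of (x, y, confidence).
#' @param previous The previously selected 25 x 3 detection, or NULL.
#' @return The selected 25 x 3 detection matrix.
#' @export
select_primary_person <- function(candidates, previous = NULL) {
  if (length(candidates) < 1L) stop("at least one candidate detection required")
  candidates <- lapply(candidates, .as_person)
  if (!is.null(previous) && any(previous[, 3] > 0)) {
    d <- vapply(candidates, function(cand) {
      both <- cand[, 3] > 0 & previous[, 3] > 0
      if (!any(both)) return(Inf)
      mean(sqrt((cand[both, 1] - previous[both, 1])^2 +
                (cand[both, 2] - previous[both, 2])^2))
    }, numeric(1))
    if (any(is.finite(d))) return(candidates[[which.min(d)]])
  }
  s <- vapply(candidates, function(cand) sum(cand[, 3]), numeric(1))
  candidates[[which.max(s)]]
}

.frame_number <- function(files) {
  m <- regexpr("[0-9]+(?=[^0-9]*\\.json$)", files, perl = TRUE)
  bad <- m < 0
  if (any(bad))
    stop("cannot extract a frame number from file name(s): ",
         paste(files[bad], collapse = ", "))
  as.numeric(regmatches(files, m))
}

#' Read a directory of per-frame pose-estimation JSON files
#'
#' Each file is an OpenPose BODY_25 output: a \code{people} array whose
#' entries carry \code{pose_keypoints_2d}, a flat vector of 75 numbers
#' (x1, y1, c1, ..., x25, y25, c25). Files are ordered by the last run of
#' digits before the \code{.json} extension. Frames with an empty
#' \code{people} array become frames of 25 missing joints; multi-person
#' frames are resolved with \code{\link{select_primary_person}}.
#'
#' @param path Directory of per-frame JSON files.
#' @param subject_id,label,fps,width,height Sequence metadata (see
#'   \code{\link{skeleton_sequence}}).
#' @return A \code{skeleton_sequence}.
#' @export
read_openpose_sequence <- function(path, subject_id, label, fps = 30,
                                   width = 1280, height = 720) {
  files <- list.files(path, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0L) stop("no .json files found under ", path)
  files <- files[order(.frame_number(basename(files)))]
  Tn <- length(files)
  x <- matrix(NA_real_, Tn, 25L)
  y <- matrix(NA_real_, Tn, 25L)
  conf <- matrix(0, Tn, 25L)
  previous <- NULL
  for (t in seq_len(Tn)) {
    parsed <- tryCatch(jsonlite::fromJSON(files[t], simplifyVector = FALSE),
                       error = function(e)
                         stop("malformed JSON in ", files[t], ": ",
                              conditionMessage(e), call. = FALSE))
    people <- parsed$people
    if (is.null(people) || length(people) == 0L) next
    cands <- lapply(people, function(p) {
      kp <- unlist(p$pose_keypoints_2d, use.names = FALSE)
      if (length(kp) != 75L)
        stop("keypoint list of length ", length(kp), " (expected 75) in ",
             files[t], call. = FALSE)
      .as_person(kp)
    })
    sel <- select_primary_person(cands, previous)
    x[t, ] <- sel[, 1]
    y[t, ] <- sel[, 2]
    conf[t, ] <- pmin(pmax(sel[, 3], 0), 1)
    previous <- sel
  }
  skeleton_sequence(x, y, conf, subject_id = subject_id, label = label,
                    fps = fps, width = width, height = height)
}

#' Fill short missing-joint gaps by linear interpolation
#'
#' For each joint slot, interior runs of missing frames no longer than
#' \code{max_gap} are filled by per-coordinate linear interpolation between
#' the flanking detections; the filled confidence is the smaller flank
#' confidence. Longer runs and runs touching either end of the sequence are
#' left missing. Detected joints are never altered.
#'
#' @param seq A \code{skeleton_sequence}.
#' @param max_gap Maximum gap length (frames) to fill; default 15 frames
#'   (0.5 s at 30 Hz) -- long enough for blink-length detection dropouts,
#'   short enough not to fabricate movement.
#' @return A list with elements \code{sequence} (the repaired
#'   \code{skeleton_sequence}) and \code{report} (data frame with per-joint
#'   counts of filled and unfilled missing frames).
#' @export
repair_missing_joints <- function(seq, max_gap = 15L) {
  stopifnot(inherits(seq, "skeleton_sequence"), max_gap >= 0)
  x <- seq$x; y <- seq$y; conf <- seq$confidence
  Tn <- nrow(x)
  filled <- unfilled <- integer(25L)
  for (j in seq_len(25L)) {
    miss <- conf[, j] == 0
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]; len <- e - s + 1L
      if (s == 1L || e == Tn || len > max_gap) {
        unfilled[j] <- unfilled[j] + len
        next
      }
      i0 <- s - 1L; i1 <- e + 1L
      w <- (s:e - i0) / (i1 - i0)
      x[s:e, j] <- x[i0, j] + w * (x[i1, j] - x[i0, j])
      y[s:e, j] <- y[i0, j] + w * (y[i1, j] - y[i0, j])
      conf[s:e, j] <- min(conf[i0, j], conf[i1, j])
      filled[j] <- filled[j] + len
    }
  }
  out <- skeleton_sequence(x, y, conf, subject_id = seq$subject_id,
                           label = seq$label, fps = seq$fps,
                           width = seq$width, height = seq$height)
  list(sequence = out,
       report = data.frame(joint = 0:24, name = body25_joints(),
                           filled = filled, unfilled = unfilled))
}

.seq_csv_cols <- c("subject_id", "frame", "joint", "x", "y", "confidence")

#' Write / read a skeleton sequence as long-format CSV
#'
#' One row per (frame, joint): columns \code{subject_id}, \code{frame}
#' (0-based), \code{joint} (0-24), \code{x}, \code{y}, \code{confidence},
#' plus constant metadata columns \code{label}, \code{fps}, \code{width},
#' \code{height} so the round trip is lossless. Missing joints have
#' confidence 0 and empty coordinates.
#'
#' @param seq A \code{skeleton_sequence}.
#' @param path CSV file path.
#' @return \code{write_sequence_csv} returns \code{path} invisibly;
#'   \code{read_sequence_csv} returns a \code{skeleton_sequence}.
#' @export
write_sequence_csv <- function(seq, path) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  Tn <- nrow(seq$x)
  df <- data.frame(
    subject_id = seq$subject_id,
    frame = rep(0:(Tn - 1L), each = 25L),
    joint = rep(0:24, times = Tn),
    x = as.vector(t(seq$x)),
    y = as.vector(t(seq$y)),
    confidence = as.vector(t(seq$confidence)),
    label = seq$label, fps = seq$fps, width = seq$width, height = seq$height)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequence_csv
#' @param label,fps,width,height Metadata overrides, used when the CSV lacks
#'   the corresponding optional columns.
#' @export
read_sequence_csv <- function(path, label = NULL, fps = NULL,
                              width = NULL, height = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.seq_csv_cols, names(df))
  if (length(missing_cols))
    stop("sequence CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("sequence CSV holds no rows")
  meta <- function(arg, col, default) {
    if (!is.null(arg)) return(arg)
    if (col %in% names(df)) return(df[[col]][1])
    default
  }
  label <- meta(label, "label",
                stop("no 'label' column in CSV and no label argument given"))
  fps <- meta(fps, "fps", 30)
  width <- meta(width, "width", 1280)
  height <- meta(height, "height", 720)
  frames <- sort(unique(df$frame))
  Tn <- length(frames)
  idx <- cbind(match(df$frame, frames), df$joint + 1L)
  x <- matrix(NA_real_, Tn, 25L); y <- matrix(NA_real_, Tn, 25L)
  conf <- matrix(0, Tn, 25L)
  x[idx] <- df$x; y[idx] <- df$y; conf[idx] <- df$confidence
  skeleton_sequence(x, y, conf, subject_id = df$subject_id[1], label = label,
                    fps = fps, width = width, height = height)
}
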