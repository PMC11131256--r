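#' The six tracked bones
#'
#' Bone vectors run from joint \code{from} to joint \code{to} (0-based
#' BODY_25 slots): right shoulder (1,2), left shoulder (1,5), right hip
#' (8,9), left hip (8,12), right thigh (9,10) and trunk (1,8). The right
#' thigh is used rather than the left because, with a seated subject filmed
#' from the camera side, the left thigh is usually partially occluded.
#' The trunk contributes an angle only, no length parameter.
#'
#' @return Data frame with columns \code{bone}, \code{from}, \code{to}.
#' @export
bone_table <- function() {
  data.frame(
    bone = c("right_shoulder", "left_shoulder", "right_hip", "left_hip",
             "right_thigh", "trunk"),
    from = c(1L, 1L, 8L, 8L, 9L, 1L),
    to   = c(2L, 5L, 9L, 12L, 10L, 8L))
}

#' The 11 skeleton parameter names
#'
#' Five bone lengths (pixels) and six bone angles (degrees): \code{l_i_j} is
#' the length of the bone from joint i to joint j, \code{th_i_j} its angle.
#' \code{th_8_1} is the trunk angle (computed from the neck-to-mid-hip
#' vector, reported on a [0, 180) scale).
#'
#' @return Character vector of length 11.
#' @export
parameter_names <- function() {
  c("l_1_2", "l_1_5", "l_8_9", "l_8_12", "l_9_10",
    "th_1_2", "th_1_5", "th_8_9", "th_8_12", "th_9_10", "th_8_1")
}

#' Bone vector of a single frame
#'
#' @param frame A 25 x 3 frame matrix as returned by \code{\link{get_frame}}.
#' @param from,to 0-based joint slots.
#' @return Numeric (dx, dy) displacement in pixels, or c(NA, NA) when either
#'   joint is missing.
#' @export
bone_vector <- function(frame, from, to) {
  a <- frame[from + 1L, ]; b <- frame[to + 1L, ]
  if (a[3] <= 0 || b[3] <= 0) return(c(dx = NA_real_, dy = NA_real_))
  c(dx = unname(b[1] - a[1]), dy = unname(b[2] - a[2]))
}

#' Bone length (Euclidean norm of a displacement)
#' @param v Numeric (dx, dy) displacement.
#' @return Length in pixels; NA for an invalid displacement.
#' @export
bone_length <- function(v) {
  if (anyNA(v)) return(NA_real_)
  sqrt(sum(v^2))
}

#' Bone angle in [0, 90] degrees
#'
#' The unsigned inclination |atan(dy/dx)| * 180 / pi of the displacement
#' against the image x-axis. A vertical bone (dx = 0) is defined as 90
#' degrees (the continuous limit). A zero-length displacement has no
#' direction and yields NA, so coincident-joint detection glitches cannot
#' inject spurious variance.
#'
#' @param v Numeric (dx, dy) displacement.
#' @return Angle in degrees, or NA.
#' @export
bone_angle <- function(v) {
  if (anyNA(v) || (v[1] == 0 && v[2] == 0)) return(NA_real_)
  if (v[1] == 0) return(90)
  abs(atan(v[2] / v[1]) * 180 / pi)
}

#' Trunk angle in [0, 180) degrees
#'
#' phi = atan(dy/dx) * 180 / pi, mapped to [0, 180) by adding 180 when
#' negative; dx = 0 is defined as 90 degrees. Unlike \code{\link{bone_angle}}
#' the sign of the inclination is kept (as a half-turn orientation), so
#' leaning left and leaning right are distinguished.
#'
#' @param v Numeric (dx, dy) displacement.
#' @return Angle in degrees, or NA for an invalid or zero displacement.
#' @export
trunk_angle <- function(v) {
  if (anyNA(v) || (v[1] == 0 && v[2] == 0)) return(NA_real_)
  if (v[1] == 0) return(90)
  phi <- atan(v[2] / v[1]) * 180 / pi
  if (phi < 0) phi + 180 else phi
}

#' Compute the 11 skeleton-parameter time series
#'
#' Applies the length and angle definitions to the six tracked bones in
#' every frame: lengths and [0, 90] angles for the five non-trunk bones and
#' the [0, 180) trunk angle, yielding 11 series. Only the initial
#' \code{truncate_min} minutes (floor(truncate_min * 60 * fps) frames) are
#' used, which minimizes comparison bias between recordings of different
#' durations. A frame is invalid for a parameter when either endpoint joint
#' is missing (or, for angles, when the displacement is zero).
#'
#' @param seq A \code{skeleton_sequence}.
#' @param truncate_min Recording minutes to keep (default 4); NULL keeps all
#'   frames.
#' @return An object of class \code{parameter_series}: list with
#'   \code{subject_id}, \code{label}, \code{fps}, a T x 11 \code{values}
#'   matrix (NA where invalid) and a T x 11 logical \code{valid} mask,
#'   columns named as in \code{\link{parameter_names}}.
#' @export
compute_parameter_series <- function(seq, truncate_min = 4) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  Tn <- n_frames(seq)
  keep <- if (is.null(truncate_min)) Tn else
    max(1L, min(Tn, floor(truncate_min * 60 * seq$fps)))
  bones <- bone_table()
  fi <- bones$from + 1L; ti <- bones$to + 1L
  dx <- seq$x[seq_len(keep), ti, drop = FALSE] - seq$x[seq_len(keep), fi, drop = FALSE]
  dy <- seq$y[seq_len(keep), ti, drop = FALSE] - seq$y[seq_len(keep), fi, drop = FALSE]
  pres <- (seq$confidence[seq_len(keep), ti, drop = FALSE] > 0) &
          (seq$confidence[seq_len(keep), fi, drop = FALSE] > 0)
  zero <- !is.na(dx) & !is.na(dy) & dx == 0 & dy == 0

  len <- sqrt(dx[, 1:5, drop = FALSE]^2 + dy[, 1:5, drop = FALSE]^2)
  ang <- ifelse(dx[, 1:5, drop = FALSE] == 0, 90,
                abs(atan(dy[, 1:5, drop = FALSE] / dx[, 1:5, drop = FALSE]) * 180 / pi))
  phi <- ifelse(dx[, 6] == 0, 90, atan(dy[, 6] / dx[, 6]) * 180 / pi)
  trunk <- ifelse(phi < 0, phi + 180, phi)

  values <- cbind(len, ang, trunk)
  valid <- cbind(pres[, 1:5, drop = FALSE],
                 pres[, 1:5, drop = FALSE] & !zero[, 1:5, drop = FALSE],
                 pres[, 6] & !zero[, 6])
  values[!valid] <- NA_real_
  colnames(values) <- colnames(valid) <- parameter_names()
  structure(
    list(subject_id = seq$subject_id, label = seq$label, fps = seq$fps,
         values = values, valid = valid),
    class = "parameter_series")
}

#' @export
print.parameter_series <- function(x, ...) {
  cat(sprintf("<parameter_series> %s [%s]: %d frames x 11 parameters, %.2f%% invalid\n",
              x$subject_id, x$label, nrow(x$values), 100 * mean(!x$valid)))
  invisible(x)
}
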