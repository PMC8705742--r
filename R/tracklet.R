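#' Construct a skeleton frame
#'
#' One detected person in one video frame: 17 COCO-ordered joints with
#' image coordinates (y-down pixel convention until normalization) and a
#' per-joint confidence in \[0, 1\].
#'
#' @param x,y Numeric vectors of length 17 (finite).
#' @param conf Numeric vector of length 17, values in \[0, 1\].
#' @return A 17 x 3 numeric matrix with columns `x`, `y`, `conf` and joint
#'   names as row names.
#' @export
skeleton_frame <- function(x, y, conf = rep(1, 17)) {
  m <- cbind(x = as.numeric(x), y = as.numeric(y), conf = as.numeric(conf))
  rownames(m) <- coco17_joints()
  validate_skeleton_frame(m)
  m
}

validate_skeleton_frame <- function(m) {
  if (!is.matrix(m) || nrow(m) != 17L || ncol(m) != 3L)
    stop("skeleton frame must be a 17 x 3 matrix (x, y, conf)")
  if (!all(is.finite(m[, 1:2])))
    stop("skeleton frame coordinates must be finite")
  if (any(m[, 3] < 0 | m[, 3] > 1 | !is.finite(m[, 3])))
    stop("skeleton frame confidences must lie in [0, 1]")
  invisible(m)
}

#' Construct a tracklet
#'
#' A contiguous sequence of skeletons of one tracked person from a single
#' camera, sampled uniformly at `fps`. Frame `k` (0-based) is at time
#' `k / fps` seconds.
#'
#' @param track_id Scalar identifier, unique within a dataset.
#' @param joints Numeric array of dimension `(frames, 17, 3)`, last axis
#'   ordered `x`, `y`, `conf`; or a list of skeleton frames.
#' @param fps Sampling rate in frames per second (> 0).
#' @param meta Named list of free-form source tags (camera, continent, ...).
#' @return An object of class `tracklet`.
#' @export
tracklet <- function(track_id, joints, fps = 24, meta = list()) {
  if (is.list(joints)) {
    joints <- aperm(simplify2array(joints), c(3L, 1L, 2L))
  }
  if (length(dim(joints)) != 3L || dim(joints)[2] != 17L || dim(joints)[3] != 3L)
    stop("joints must be a (frames x 17 x 3) array")
  if (dim(joints)[1] < 1L) stop("tracklet must contain at least one frame")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a positive scalar")
  dimnames(joints) <- list(NULL, coco17_joints(), c("x", "y", "conf"))
  if (!all(is.finite(joints[, , 1:2])))
    stop("tracklet coordinates must be finite")
  cf <- joints[, , 3]
  if (any(cf < 0 | cf > 1 | !is.finite(cf)))
    stop("tracklet confidences must lie in [0, 1]")
  structure(
    list(track_id = as.character(track_id), joints = joints,
         fps = as.numeric(fps), meta = meta),
    class = "tracklet")
}

#' Number of frames in a tracklet
#' @param t A `tracklet`.
#' @return Integer frame count.
#' @export
n_frames <- function(t) {
  stopifnot(inherits(t, "tracklet"))
  dim(t$joints)[1]
}

#' @export
print.tracklet <- function(x, ...) {
  cat(sprintf("<tracklet '%s'> %d frames @ %g fps (%.2f s)\n",
              x$track_id, n_frames(x), x$fps, n_frames(x) / x$fps))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Construct a tracklet dataset
#'
#' @param tracklets List of `tracklet` objects with pairwise distinct
#'   `track_id`s.
#' @param provenance Named list of dataset-level metadata.
#' @return An object of class `tracklet_dataset`.
#' @export
tracklet_dataset <- function(tracklets = list(), provenance = list()) {
  stopifnot(is.list(tracklets))
  for (t in tracklets)
    if (!inherits(t, "tracklet")) stop("all elements must be tracklets")
  ids <- vapply(tracklets, function(t) t$track_id, character(1))
  if (anyDuplicated(ids))
    stop("track ids must be pairwise distinct; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(tracklets) <- ids
  structure(list(tracklets = tracklets, provenance = provenance),
            class = "tracklet_dataset")
}

#' @export
print.tracklet_dataset <- function(x, ...) {
  n <- length(x$tracklets)
  cat(sprintf("<tracklet_dataset> %d tracklet%s\n", n, if (n == 1) "" else "s"))
  if (n) {
    len <- vapply(x$tracklets, n_frames, integer(1))
    cat(sprintf("  frames: min %d / median %g / max %d\n",
                min(len), stats::median(len), max(len)))
  }
  invisible(x)
}

#' @export
length.tracklet_dataset <- function(x) length(x$tracklets)

#' Temporally resample a tracklet
#'
#' Linearly interpolates every joint trajectory (and confidence) onto a new
#' uniform time grid at `target_fps`. The new length is
#' `round(frames * target_fps / fps)`; instants beyond the last original
#' frame take the last frame's values. Interpolated confidences are clamped
#' to \[0, 1\].
#'
#' @param t A `tracklet`.
#' @param target_fps Target sampling rate (> 0).
#' @return A `tracklet` at `target_fps`.
#' @export
resample_tracklet <- function(t, target_fps) {
  stopifnot(inherits(t, "tracklet"))
  if (!is.numeric(target_fps) || length(target_fps) != 1L || target_fps <= 0)
    stop("target_fps must be a positive scalar")
  if (target_fps == t$fps) return(t)
  n_old <- n_frames(t)
  n_new <- max(1L, as.integer(round(n_old * target_fps / t$fps)))
  t_old <- (seq_len(n_old) - 1) / t$fps
  t_new <- (seq_len(n_new) - 1) / target_fps
  flat <- matrix(t$joints, nrow = n_old)        # frames x 51, column-major
  if (n_old == 1L) {
    out <- flat[rep(1L, n_new), , drop = FALSE]
  } else {
    out <- apply(flat, 2L, function(v)
      stats::approx(t_old, v, xout = t_new, rule = 2)$y)
    out <- matrix(out, nrow = n_new)
  }
  joints <- array(out, dim = c(n_new, 17L, 3L))
  joints[, , 3] <- pmin(pmax(joints[, , 3], 0), 1)
  tracklet(t$track_id, joints, fps = target_fps, meta = t$meta)
}
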