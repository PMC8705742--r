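#' Tracklet quality-filter configuration
#'
#' Thresholds for the curation filters that separate well-tracked walking
#' people from noise, standers and broken tracks:
#' \describe{
#'   \item{min_mean_confidence}{keep tracklets whose mean joint confidence
#'     (all frames, all 17 joints) is strictly above this (default 0.60).}
#'   \item{feet_conf_threshold, max_consecutive_low_feet}{keep tracklets
#'     with at most `max_consecutive_low_feet` consecutive frames whose
#'     feet confidence (min of the two ankle confidences) is below
#'     `feet_conf_threshold` (defaults 3 frames, 0.50) — both feet must be
#'     visible essentially throughout.}
#'   \item{min_length}{minimum frame count, default 54 frames at 24 fps,
#'     about two full gait cycles.}
#'   \item{max_length}{maximum frame count; extremely long tracks are
#'     usually standers. Default 1000.}
#'   \item{min_mean_velocity}{minimum mean per-frame displacement of the
#'     leg joints in normalized units (default 0.01); slower tracks are
#'     treated as not walking.}
#'   \item{velocity_joints}{`"legs"` averages ankles and knees (default);
#'     `"feet"` uses the ankles only.}
#' }
#'
#' @param min_mean_confidence,feet_conf_threshold,max_consecutive_low_feet,min_length,max_length,min_mean_velocity,velocity_joints See above.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_mean_confidence = 0.60,
                          feet_conf_threshold = 0.50,
                          max_consecutive_low_feet = 3L,
                          min_length = 54L,
                          max_length = 1000L,
                          min_mean_velocity = 0.01,
                          velocity_joints = c("legs", "feet")) {
  cfg <- list(min_mean_confidence = min_mean_confidence,
              feet_conf_threshold = feet_conf_threshold,
              max_consecutive_low_feet = as.integer(max_consecutive_low_feet),
              min_length = as.integer(min_length),
              max_length = as.integer(max_length),
              min_mean_velocity = min_mean_velocity,
              velocity_joints = match.arg(velocity_joints))
  nums <- unlist(cfg[1:6])
  if (any(nums < 0)) stop("all filter thresholds must be >= 0")
  if (cfg$min_length > cfg$max_length)
    stop("min_length must not exceed max_length")
  structure(cfg, class = "filter_config")
}

#' Mean-confidence filter
#'
#' Passes iff the mean confidence over all frames and all 17 joints is
#' strictly greater than `cfg$min_mean_confidence`.
#'
#' @param t A `tracklet`.
#' @param cfg A `filter_config`.
#' @return `TRUE` (pass) or `FALSE`.
#' @export
mean_confidence_filter <- function(t, cfg = filter_config()) {
  mean(t$joints[, , 3]) > cfg$min_mean_confidence
}

#' Feet-visibility filter
#'
#' Per-frame feet confidence is the minimum of the two ankle confidences
#' (both feet must be visible). Passes iff the longest run of frames with
#' feet confidence below `cfg$feet_conf_threshold` has length at most
#' `cfg$max_consecutive_low_feet`.
#'
#' @inheritParams mean_confidence_filter
#' @return `TRUE` (pass) or `FALSE`.
#' @export
feet_visibility_filter <- function(t, cfg = filter_config()) {
  feet <- pmin(t$joints[, .coco$left_ankle, 3], t$joints[, .coco$right_ankle, 3])
  low <- feet < cfg$feet_conf_threshold
  longest_run(low) <= cfg$max_consecutive_low_feet
}

longest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Length filter
#'
#' Passes iff `cfg$min_length <= frames <= cfg$max_length`.
#'
#' @inheritParams mean_confidence_filter
#' @return `TRUE` (pass) or `FALSE`.
#' @export
length_filters <- function(t, cfg = filter_config()) {
  n <- n_frames(t)
  n >= cfg$min_length && n <= cfg$max_length
}

#' Leg-velocity (walking) filter
#'
#' Expects *normalized* coordinates. The velocity of a leg joint at frame
#' k is its Euclidean displacement from frame k-1 (normalized units per
#' frame); the filter averages over the selected leg joints (ankles and
#' knees by default) and all frame steps, and passes iff that mean is at
#' least `cfg$min_mean_velocity`. Static (standing) people fail.
#'
#' @inheritParams mean_confidence_filter
#' @return `TRUE` (pass) or `FALSE`.
#' @export
velocity_filter <- function(t, cfg = filter_config()) {
  if (n_frames(t) < 2L)
    stop("velocity undefined for a tracklet with fewer than 2 frames")
  mean_leg_velocity(t, cfg$velocity_joints) >= cfg$min_mean_velocity
}

#' Mean per-frame leg displacement of a tracklet
#'
#' @param t A normalized `tracklet` with at least two frames.
#' @param joints `"legs"` (ankles + knees) or `"feet"` (ankles only).
#' @return Mean displacement magnitude in normalized units per frame.
#' @export
mean_leg_velocity <- function(t, joints = c("legs", "feet")) {
  joints <- match.arg(joints)
  idx <- if (joints == "legs")
    c(.coco$left_knee, .coco$right_knee, .coco$left_ankle, .coco$right_ankle)
  else c(.coco$left_ankle, .coco$right_ankle)
  xy <- t$joints[, idx, 1:2, drop = FALSE]
  d <- xy[-1, , , drop = FALSE] - xy[-dim(xy)[1], , , drop = FALSE]
  mean(sqrt(d[, , 1]^2 + d[, , 2]^2))
}

#' Apply the full filter cascade to a dataset
#'
#' Filters run in a fixed order — length, mean confidence, feet
#' visibility, velocity — and each rejected tracklet is attributed to the
#' first filter it fails. The dataset must already be normalized (the
#' velocity threshold is in normalized units).
#'
#' @param ds A normalized `tracklet_dataset`.
#' @param cfg A `filter_config`.
#' @return List with `dataset` (the survivors, a `tracklet_dataset`) and
#'   `report` (a `filter_report`).
#' @export
apply_filters <- function(ds, cfg = filter_config()) {
  stopifnot(inherits(ds, "tracklet_dataset"))
  stages <- c("length", "mean_confidence", "feet_visibility", "velocity")
  verdict <- function(t) {
    if (!length_filters(t, cfg)) return("length")
    if (!mean_confidence_filter(t, cfg)) return("mean_confidence")
    if (!feet_visibility_filter(t, cfg)) return("feet_visibility")
    if (!velocity_filter(t, cfg)) return("velocity")
    "pass"
  }
  tl <- unname(ds$tracklets)
  failed <- vapply(tl, verdict, character(1))
  counts <- vapply(stages, function(s) sum(failed == s), integer(1))
  survivors <- tracklet_dataset(tl[failed == "pass"], provenance = ds$provenance)
  report <- structure(list(
    n_input = length(tl),
    n_survivors = sum(failed == "pass"),
    rejections = counts,
    verdicts = data.frame(
      track_id = vapply(tl, function(t) t$track_id, character(1)),
      pass = failed == "pass",
      failed_filter = ifelse(failed == "pass", NA_character_, failed),
      stringsAsFactors = FALSE)),
    class = "filter_report")
  list(dataset = survivors, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d in -> %d survivors\n",
              x$n_input, x$n_survivors))
  for (s in names(x$rejections))
    cat(sprintf("  rejected by %-16s %d\n", paste0(s, ":"), x$rejections[[s]]))
  invisible(x)
}

#' Export a filter report's per-tracklet verdicts as CSV
#'
#' @param report A `filter_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  utils::write.csv(report$verdicts, path, row.names = FALSE)
  invisible(path)
}
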