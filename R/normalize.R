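#' Derive the pelvis and neck virtual joints
#'
#' COCO-17 contains neither a pelvis nor a neck keypoint; they are derived
#' as the hip midpoint and the shoulder midpoint respectively, the only
#' construction consistent with the normalization equations on COCO input.
#'
#' @param frame A 17 x 3 skeleton frame matrix.
#' @return List with numeric `pelvis = c(x, y)` and `neck = c(x, y)`.
#' @export
derive_virtual_joints <- function(frame) {
  parents <- frame[c(.coco$left_hip, .coco$right_hip,
                     .coco$left_shoulder, .coco$right_shoulder), 1:2]
  if (!all(is.finite(parents)))
    stop("hip and shoulder joints must be finite to derive pelvis/neck")
  list(
    pelvis = c(x = mean(frame[c(.coco$left_hip, .coco$right_hip), 1]),
               y = mean(frame[c(.coco$left_hip, .coco$right_hip), 2])),
    neck   = c(x = mean(frame[c(.coco$left_shoulder, .coco$right_shoulder), 1]),
               y = mean(frame[c(.coco$left_shoulder, .coco$right_shoulder), 2])))
}

#' Stature-invariant normalization of one skeleton frame
#'
#' Zero-centers the skeleton at the pelvis and rescales each axis by a
#' body-size reference: for every joint
#' \deqn{x' = (x - x_{pelvis}) / |x_{R.shoulder} - x_{L.shoulder}|}
#' \deqn{y' = (y - y_{pelvis}) / |y_{neck} - y_{pelvis}|}
#' Confidences are unchanged. After normalization the pelvis sits at the
#' origin, the shoulder width is 1 and the torso length is 1, so all
#' absolute position and stature information is removed (the
#' anonymization step) and the map is idempotent. The y-down pixel
#' convention is preserved (no axis flip).
#'
#' @param frame A 17 x 3 skeleton frame matrix.
#' @param eps Degeneracy threshold on the shoulder-width and torso-length
#'   denominators, in source units.
#' @return The normalized 17 x 3 frame matrix.
#' @export
normalize_frame <- function(frame, eps = 1e-6) {
  validate_skeleton_frame(frame)
  vj <- derive_virtual_joints(frame)
  shoulder_w <- abs(frame[.coco$right_shoulder, 1] - frame[.coco$left_shoulder, 1])
  torso_l <- abs(vj$neck[["y"]] - vj$pelvis[["y"]])
  if (shoulder_w <= eps || torso_l <= eps)
    stop(sprintf(
      "degenerate frame: shoulder width %.3g, torso length %.3g (eps %.3g)",
      shoulder_w, torso_l, eps))
  out <- frame
  out[, 1] <- (frame[, 1] - vj$pelvis[["x"]]) / shoulder_w
  out[, 2] <- (frame[, 2] - vj$pelvis[["y"]]) / torso_l
  out
}

#' Normalize every frame of a tracklet
#'
#' Applies [normalize_frame()] per frame (denominators are per-frame, so
#' the output is invariant to global translation and uniform scaling of
#' the input). A frame with a degenerate shoulder width or torso length
#' either rejects the whole tracklet (default) or is dropped, per
#' `on_degenerate`; dropping frames breaks temporal contiguity, so
#' rejection is the default policy.
#'
#' @param t A `tracklet` in image coordinates.
#' @param on_degenerate `"reject"` (error) or `"drop"` (remove bad frames).
#' @param eps Degeneracy threshold passed to [normalize_frame()].
#' @return The normalized `tracklet`.
#' @export
normalize_tracklet <- function(t, on_degenerate = c("reject", "drop"),
                               eps = 1e-6) {
  stopifnot(inherits(t, "tracklet"))
  on_degenerate <- match.arg(on_degenerate)
  J <- t$joints
  px <- (J[, .coco$left_hip, 1] + J[, .coco$right_hip, 1]) / 2
  py <- (J[, .coco$left_hip, 2] + J[, .coco$right_hip, 2]) / 2
  ny <- (J[, .coco$left_shoulder, 2] + J[, .coco$right_shoulder, 2]) / 2
  sw <- abs(J[, .coco$right_shoulder, 1] - J[, .coco$left_shoulder, 1])
  tl <- abs(ny - py)
  bad <- sw <= eps | tl <= eps
  if (any(bad)) {
    if (on_degenerate == "reject")
      stop(sprintf(
        "tracklet '%s' rejected: %d degenerate frame(s) (first at frame %d)",
        t$track_id, sum(bad), which(bad)[1]))
    J <- J[!bad, , , drop = FALSE]
    if (dim(J)[1] == 0L)
      stop(sprintf("tracklet '%s': all frames degenerate", t$track_id))
    px <- px[!bad]; py <- py[!bad]; sw <- sw[!bad]; tl <- tl[!bad]
  }
  J[, , 1] <- (J[, , 1] - px) / sw
  J[, , 2] <- (J[, , 2] - py) / tl
  tracklet(t$track_id, J, fps = t$fps, meta = t$meta)
}

#' Normalize every tracklet of a dataset
#'
#' @param ds A `tracklet_dataset`.
#' @inheritParams normalize_tracklet
#' @return A `tracklet_dataset` of normalized tracklets.
#' @export
normalize_dataset <- function(ds, on_degenerate = c("reject", "drop"),
                              eps = 1e-6) {
  stopifnot(inherits(ds, "tracklet_dataset"))
  on_degenerate <- match.arg(on_degenerate)
  tracklet_dataset(
    lapply(unname(ds$tracklets), normalize_tracklet,
           on_degenerate = on_degenerate, eps = eps),
    provenance = ds$provenance)
}
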