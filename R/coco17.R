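#' COCO-17 joint names in canonical order
#'
#' The fixed 17-joint 2D pose convention used throughout the package:
#' nose, eyes, ears, shoulders, elbows, wrists, hips, knees, ankles.
#' All tracklets, samples and model tensors index joints in this order.
#'
#' @return Character vector of length 17.
#' @export
coco17_joints <- function() {
  c("nose",
    "left_eye", "right_eye",
    "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle")
}

# joint indices used repeatedly; kept as an internal lookup
.coco <- list(
  nose = 1L, left_eye = 2L, right_eye = 3L, left_ear = 4L, right_ear = 5L,
  left_shoulder = 6L, right_shoulder = 7L, left_elbow = 8L, right_elbow = 9L,
  left_wrist = 10L, right_wrist = 11L, left_hip = 12L, right_hip = 13L,
  left_knee = 14L, right_knee = 15L, left_ankle = 16L, right_ankle = 17L
)

#' Left/right joint index pairs
#'
#' Bilateral joint pairs (left index, right index) used when mirroring a
#' skeleton horizontally: eyes, ears, shoulders, elbows, wrists, hips,
#' knees, ankles.
#'
#' @return Integer matrix with columns `left` and `right`.
#' @export
coco17_lr_pairs <- function() {
  cbind(left  = c(2L, 4L, 6L, 8L, 10L, 12L, 14L, 16L),
        right = c(3L, 5L, 7L, 9L, 11L, 13L, 15L, 17L))
}

#' COCO-17 skeleton edges
#'
#' Bone connectivity of the COCO skeleton as an edge list (1-based joint
#' indices), including the ear-to-shoulder links.
#'
#' @return Two-column integer matrix, one edge per row.
#' @export
coco17_edges <- function() {
  e <- rbind(
    c(16L, 14L), c(14L, 12L),           # left ankle-knee-hip
    c(17L, 15L), c(15L, 13L),           # right ankle-knee-hip
    c(12L, 13L),                        # pelvis
    c(6L, 12L), c(7L, 13L),             # torso sides
    c(6L, 7L),                          # shoulders
    c(6L, 8L), c(8L, 10L),              # left arm
    c(7L, 9L), c(9L, 11L),              # right arm
    c(2L, 3L), c(1L, 2L), c(1L, 3L),    # face
    c(2L, 4L), c(3L, 5L),               # eye-ear
    c(4L, 6L), c(5L, 7L)                # ear-shoulder
  )
  colnames(e) <- c("from", "to")
  e
}
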