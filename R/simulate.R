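#' Sample a synthetic walker's gait signature
#'
#' Draws the per-identity kinematic parameters of the parametric 2D gait
#' simulator. Each identity is characterized by its cadence
#' (strides/second, Normal(0.9, 0.1) truncated above 0.5), ankle swing
#' half-range (Normal(0.35, 0.05) in torso-length units), knee and arm
#' swing amplitudes, per-limb phase offsets (left/right legs in antiphase
#' pi plus Normal(0, 0.1) identity jitter), relative bone lengths (torso
#' fixed at 1, other segments jittered by about 5%) and a vertical bounce
#' amplitude. Uses R's RNG stream; seed with [set.seed()].
#'
#' @param cadence_mean,cadence_sd,amplitude_mean,amplitude_sd Population
#'   parameters of the cadence and ankle-swing distributions.
#' @param proportion_jitter Relative sd of the bone-length jitter.
#' @return An object of class `gait_identity`.
#' @export
sample_identity <- function(cadence_mean = 0.9, cadence_sd = 0.1,
                            amplitude_mean = 0.35, amplitude_sd = 0.05,
                            proportion_jitter = 0.05) {
  rtrunc <- function(mean, sd, lower) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > lower) return(v)
    }
  }
  structure(list(
    cadence = rtrunc(cadence_mean, cadence_sd, 0.5),
    stride_amplitude = rtrunc(amplitude_mean, amplitude_sd, 0.05),
    knee_amplitude = rtrunc(0.18, 0.03, 0.03),
    arm_amplitude = rtrunc(0.15, 0.04, 0.02),
    phase_jitter = stats::rnorm(2, 0, 0.1),      # left leg, left arm
    bone_scale = stats::rnorm(5, 1, proportion_jitter),  # leg, shank, arm, shoulder, hip
    vertical_bounce_amplitude = rtrunc(0.03, 0.01, 0.005)),
    class = "gait_identity")
}

#' Scene and capture parameters for the gait simulator
#'
#' @param angle Viewpoint angle in degrees: body-local x-offsets are
#'   foreshortened by `cos(angle)` and a walking-direction drift is added
#'   along x proportional to `sin(angle)`.
#' @param fps Capture rate (default 24).
#' @param sigma Additive joint-noise scale in torso-length units
#'   (default 0.01). Noise is AR(1)-correlated over time (pose-estimator
#'   jitter is temporally smooth, not white).
#' @param mode `"walking"`, `"standing"` (all oscillation amplitudes
#'   zero) or `"low-confidence"` (walking, but with a contiguous block of
#'   at least 4 frames of ankle confidence below 0.5).
#' @param px_scale Pixels per torso length when rendering to image
#'   coordinates.
#' @param origin Pixel position of the pelvis at time 0.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(angle = 0, fps = 24, sigma = 0.01,
                         mode = c("walking", "standing", "low-confidence"),
                         px_scale = 140, origin = c(320, 360)) {
  if (fps <= 0) stop("fps must be positive")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(angle = angle, fps = fps, sigma = sigma,
                 mode = match.arg(mode), px_scale = px_scale,
                 origin = origin),
            class = "scene_params")
}

# AR(1) noise, frames x k columns, stationary sd = sigma
.ar1_noise <- function(n, k, sigma, rho = 0.95) {
  if (sigma == 0) return(matrix(0, n, k))
  e <- matrix(stats::rnorm(n * k, sd = sigma * sqrt(1 - rho^2)), n, k)
  e[1, ] <- stats::rnorm(k, sd = sigma)
  apply(e, 2L, function(v) stats::filter(v, rho, method = "recursive"))
}

#' Synthesize one tracklet
#'
#' Renders a COCO-17 tracklet of a synthetic walker: joint trajectories
#' are sinusoids at the identity's cadence (ankles and knees swing along
#' x with the stated amplitudes and phases, arms counter-swing, the whole
#' body bounces vertically at twice the cadence), the viewpoint
#' foreshortens body-local x by `cos(angle)` and adds a walking drift
#' along `sin(angle)`, temporally correlated Gaussian noise of scale
#' `sigma` is added, and confidences are drawn per joint around a high
#' base level. In standing mode all oscillation and drift amplitudes are
#' zero; in low-confidence mode a contiguous block of >= 4 frames gets
#' ankle confidences below 0.5.
#'
#' @param id A `gait_identity`.
#' @param scene A `scene_params`.
#' @param n_frames Number of frames (>= 2).
#' @param track_id Track identifier.
#' @return A `tracklet` in image (pixel) coordinates, y-down.
#' @export
synthesize_tracklet <- function(id, scene, n_frames = 108L,
                                track_id = "synth") {
  stopifnot(inherits(id, "gait_identity"), inherits(scene, "scene_params"))
  if (n_frames < 2L) stop("n_frames must be >= 2")
  walking <- scene$mode != "standing"
  tt <- (seq_len(n_frames) - 1) / scene$fps
  phi <- 2 * pi * id$cadence * tt + stats::runif(1, 0, 2 * pi)
  amp <- function(a) if (walking) a else 0
  bs <- id$bone_scale
  # static pose, torso-length units, y-down, pelvis at origin
  hip_w <- 0.18 * bs[5]; sho_w <- 0.22 * bs[4]
  knee_y <- 0.55 * bs[1]; ankle_y <- 1.10 * bs[1] * bs[2]
  elbow_y <- -0.55; wrist_y <- -0.15
  base <- rbind(
    nose = c(0, -1.25), left_eye = c(0.04, -1.30), right_eye = c(-0.04, -1.30),
    left_ear = c(0.09, -1.27), right_ear = c(-0.09, -1.27),
    left_shoulder = c(sho_w, -1), right_shoulder = c(-sho_w, -1),
    left_elbow = c(hip_w + 0.08, elbow_y), right_elbow = c(-hip_w - 0.08, elbow_y),
    left_wrist = c(hip_w + 0.10, wrist_y), right_wrist = c(-hip_w - 0.10, wrist_y),
    left_hip = c(hip_w, 0), right_hip = c(-hip_w, 0),
    left_knee = c(hip_w, knee_y), right_knee = c(-hip_w, knee_y),
    left_ankle = c(hip_w, ankle_y), right_ankle = c(-hip_w, ankle_y))
  X <- matrix(rep(base[, 1], each = n_frames), n_frames, 17L)
  Y <- matrix(rep(base[, 2], each = n_frames), n_frames, 17L)
  jL <- id$phase_jitter[1]; jA <- id$phase_jitter[2]
  # leg swing (left/right in antiphase), slight knee phase lead
  X[, .coco$left_ankle]  <- X[, .coco$left_ankle]  + amp(id$stride_amplitude) * sin(phi + pi + jL)
  X[, .coco$right_ankle] <- X[, .coco$right_ankle] + amp(id$stride_amplitude) * sin(phi)
  X[, .coco$left_knee]   <- X[, .coco$left_knee]   + amp(id$knee_amplitude) * sin(phi + pi + jL + 0.4)
  X[, .coco$right_knee]  <- X[, .coco$right_knee]  + amp(id$knee_amplitude) * sin(phi + 0.4)
  # ankles lift a little during swing
  Y[, .coco$left_ankle]  <- Y[, .coco$left_ankle]  - amp(0.06) * pmax(0, sin(phi + pi + jL))
  Y[, .coco$right_ankle] <- Y[, .coco$right_ankle] - amp(0.06) * pmax(0, sin(phi))
  # arms counter-swing their same-side leg
  X[, .coco$left_wrist]  <- X[, .coco$left_wrist]  + amp(id$arm_amplitude) * sin(phi + jA)
  X[, .coco$right_wrist] <- X[, .coco$right_wrist] + amp(id$arm_amplitude) * sin(phi + pi + jA)
  X[, .coco$left_elbow]  <- X[, .coco$left_elbow]  + amp(0.6 * id$arm_amplitude) * sin(phi + jA)
  X[, .coco$right_elbow] <- X[, .coco$right_elbow] + amp(0.6 * id$arm_amplitude) * sin(phi + pi + jA)
  # whole-body vertical bounce at twice the cadence
  Y <- Y + amp(id$vertical_bounce_amplitude) * sin(2 * phi)
  # viewpoint: foreshorten body-local x, then add walking-direction drift
  th <- scene$angle * pi / 180
  X <- X * cos(th)
  if (walking) {
    speed <- 2 * id$stride_amplitude * id$cadence * sin(th)  # units/second
    X <- X + speed * tt
  }
  # pose-estimator jitter; sigma is calibrated in *normalized* units, so
  # the x component scales with the (foreshortened) shoulder width and
  # the y component with the torso length, which is 1 in body units
  X <- X + .ar1_noise(n_frames, 17L, scene$sigma) * (2 * sho_w * abs(cos(th)))
  Y <- Y + .ar1_noise(n_frames, 17L, scene$sigma)
  # confidences: joint-type base profile (face/torso joints detect more
  # reliably than distal limbs) plus small temporal noise
  conf_base <- c(rep(0.93, 5),            # face
                 0.91, 0.91,              # shoulders
                 0.88, 0.88, 0.84, 0.84,  # elbows, wrists
                 0.91, 0.91,              # hips
                 0.88, 0.88, 0.84, 0.84)  # knees, ankles
  CF <- matrix(rep(conf_base, each = n_frames), n_frames, 17L) +
    matrix(stats::rnorm(n_frames * 17L, 0, 0.03), n_frames, 17L)
  CF <- pmin(pmax(CF, 0), 1)
  if (scene$mode == "low-confidence") {
    len <- sample(4:8, 1L)
    start <- sample.int(max(1L, n_frames - len + 1L), 1L)
    blk <- start:(start + len - 1L)
    CF[blk, c(.coco$left_ankle, .coco$right_ankle)] <-
      stats::runif(length(blk) * 2L, 0.15, 0.45)
  }
  joints <- array(0, dim = c(n_frames, 17L, 3L))
  joints[, , 1] <- scene$origin[1] + scene$px_scale * X
  joints[, , 2] <- scene$origin[2] + scene$px_scale * Y
  joints[, , 3] <- CF
  tracklet(track_id, joints, fps = scene$fps,
           meta = list(angle = as.character(scene$angle), mode = scene$mode))
}

#' Generate a synthetic gait benchmark
#'
#' Builds a full test corpus: `n_ids` identities, `runs_per_id` tracklets
#' each spread across the requested viewpoint angles, lengths drawn
#' around a mean of 108 frames, and optional fractions of contaminant
#' tracklets (standing people, who must fail the velocity filter, and
#' low-feet-confidence tracks, who must fail the feet-visibility filter).
#' The ground-truth table records each tracklet's identity, angle, run,
#' mode and the filter it is expected to fail (if any). Fully
#' reproducible under [set.seed()].
#'
#' @param n_ids Number of identities (>= 2).
#' @param runs_per_id Tracklets per identity.
#' @param angles Viewpoint angles in degrees, cycled over runs.
#' @param mean_length,sd_length Tracklet length distribution (frames);
#'   lengths are clamped to \[60, 400\] so clean tracklets pass the
#'   length filter.
#' @param contamination Named numeric vector with optional entries
#'   `standing` and `low_confidence`: fraction of tracklets converted to
#'   each contaminant type (assigned deterministically by count).
#' @param sigma Joint-noise scale passed to the scene.
#' @param fps Capture rate.
#' @return List with `dataset` (a `tracklet_dataset`, image coordinates)
#'   and `truth` (data frame: `track_id`, `identity`, `angle`, `run`,
#'   `mode`, `expected_fail`).
#' @export
make_benchmark <- function(n_ids = 20L, runs_per_id = 4L,
                           angles = c(0, 45),
                           mean_length = 108, sd_length = 20,
                           contamination = c(standing = 0, low_confidence = 0),
                           sigma = 0.01, fps = 24) {
  if (n_ids < 2L) stop("need at least 2 identities")
  total <- n_ids * runs_per_id
  n_standing <- as.integer(round((contamination["standing"] %||% 0) * total))
  n_lowconf <- as.integer(round((contamination["low_confidence"] %||% 0) * total))
  if (is.na(n_standing)) n_standing <- 0L
  if (is.na(n_lowconf)) n_lowconf <- 0L
  if (n_standing + n_lowconf > total)
    stop("contamination fractions exceed the dataset")
  modes <- rep("walking", total)
  if (n_standing) modes[seq_len(n_standing)] <- "standing"
  if (n_lowconf) modes[n_standing + seq_len(n_lowconf)] <- "low-confidence"
  modes <- sample(modes)            # spread contaminants across identities
  ids <- lapply(seq_len(n_ids), function(i) sample_identity())
  tracklets <- vector("list", total)
  truth <- vector("list", total)
  k <- 0L
  for (i in seq_len(n_ids)) {
    for (r in seq_len(runs_per_id)) {
      k <- k + 1L
      ang <- angles[((r - 1L) %% length(angles)) + 1L]
      len <- as.integer(round(min(400, max(60, stats::rnorm(1, mean_length, sd_length)))))
      sc <- scene_params(angle = ang, fps = fps, sigma = sigma,
                         mode = modes[k])
      tid <- sprintf("id%03d_run%d", i, r)
      t <- synthesize_tracklet(ids[[i]], sc, n_frames = len, track_id = tid)
      t$meta$identity <- sprintf("id%03d", i)
      t$meta$run <- as.character(r)
      tracklets[[k]] <- t
      truth[[k]] <- data.frame(
        track_id = tid, identity = sprintf("id%03d", i),
        angle = ang, run = r, mode = modes[k],
        expected_fail = switch(modes[k],
          walking = NA_character_,
          standing = "velocity",
          `low-confidence` = "feet_visibility"),
        stringsAsFactors = FALSE)
    }
  }
  list(dataset = tracklet_dataset(tracklets,
                                  provenance = list(source = "synthetic")),
       truth = do.call(rbind, truth))
}

#' Phase-aligned gait signature of a tracklet
#'
#' Summarizes a normalized walking tracklet as one average gait cycle:
#' the dominant cadence is estimated from the ankle-swing difference
#' signal by FFT, every joint trajectory is folded onto the cycle phase
#' and averaged into `n_phase` bins. Signatures of two tracklets can be
#' compared with [signature_distance()], which removes the arbitrary
#' phase origin by minimizing over circular shifts.
#'
#' @param t A normalized `tracklet`.
#' @param n_phase Number of phase bins per cycle.
#' @return A `(n_phase x 17 x 2)` array of mean x/y positions per phase
#'   bin.
#' @export
gait_signature <- function(t, n_phase = 32L) {
  stopifnot(inherits(t, "tracklet"))
  n <- n_frames(t)
  s <- t$joints[, .coco$left_ankle, 1] - t$joints[, .coco$right_ankle, 1]
  s <- s - mean(s)
  sp <- Mod(stats::fft(s))[2:floor(n / 2)]
  f_idx <- which.max(sp) + 1L          # dominant frequency bin (1-based)
  cycles <- f_idx - 1L                 # cycles over the whole tracklet
  phase <- ((seq_len(n) - 1) * cycles / n) %% 1
  bin <- pmin(floor(phase * n_phase) + 1L, n_phase)
  sig <- array(NA_real_, dim = c(n_phase, 17L, 2L))
  for (b in seq_len(n_phase)) {
    rows <- bin == b
    if (any(rows)) {
      sig[b, , 1] <- colMeans(t$joints[rows, , 1, drop = FALSE])
      sig[b, , 2] <- colMeans(t$joints[rows, , 2, drop = FALSE])
    }
  }
  # fill empty bins by linear interpolation around the cycle
  for (ch in 1:2) for (j in 1:17) {
    v <- sig[, j, ch]
    if (anyNA(v)) {
      ok <- which(!is.na(v))
      sig[, j, ch] <- stats::approx(ok, v[ok], xout = seq_len(n_phase),
                                    rule = 2)$y
    }
  }
  sig
}

#' Distance between two gait signatures
#'
#' Root-mean-square distance over joints and phase bins, minimized over
#' circular phase shifts (the phase origin of a tracklet is arbitrary).
#'
#' @param s1,s2 Signatures from [gait_signature()] with matching shapes.
#' @return Non-negative scalar distance.
#' @export
signature_distance <- function(s1, s2) {
  stopifnot(identical(dim(s1), dim(s2)))
  nb <- dim(s1)[1]
  best <- Inf
  for (sh in 0:(nb - 1)) {
    idx <- ((seq_len(nb) - 1 + sh) %% nb) + 1
    d <- sqrt(mean((s1 - s2[idx, , , drop = FALSE])^2))
    if (d < best) best <- d
  }
  best
}
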