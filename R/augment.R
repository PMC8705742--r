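#' Augmentation configuration for contrastive view generation
#'
#' @param crop_length Output length of every view, in frames (default 54,
#'   about two gait cycles at 24 fps).
#' @param pace_factors Finite set the time-modification factor is sampled
#'   from uniformly; factors > 1 simulate faster walking (fewer frames),
#'   < 1 slower.
#' @param squeeze_range Interval the horizontal squeeze factor is drawn
#'   from uniformly.
#' @param p_mirror,p_timeflip Probabilities of horizontal mirroring and of
#'   temporal reversal.
#' @param p_joint_dropout,p_frame_dropout Per-joint and per-frame dropout
#'   probabilities (dropped entries are zeroed, shapes never change).
#' @param pad_mode How sequences shorter than `crop_length` are extended:
#'   `"tile"` repeats the sequence from its start until the window is
#'   full.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(crop_length = 54L,
                           pace_factors = c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2),
                           squeeze_range = c(0.8, 1.2),
                           p_mirror = 0.5, p_timeflip = 0.5,
                           p_joint_dropout = 0.1, p_frame_dropout = 0.1,
                           pad_mode = "tile") {
  probs <- c(p_mirror, p_timeflip, p_joint_dropout, p_frame_dropout)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(pace_factors <= 0)) stop("pace factors must be positive")
  if (crop_length <= 0) stop("crop_length must be positive")
  structure(list(crop_length = as.integer(crop_length),
                 pace_factors = pace_factors,
                 squeeze_range = squeeze_range,
                 p_mirror = p_mirror, p_timeflip = p_timeflip,
                 p_joint_dropout = p_joint_dropout,
                 p_frame_dropout = p_frame_dropout,
                 pad_mode = match.arg(pad_mode, "tile")),
            class = "augment_config")
}

as_sequence <- function(x) {
  if (inherits(x, "tracklet")) x <- x$joints
  stopifnot(length(dim(x)) == 3L, dim(x)[2] == 17L, dim(x)[3] == 3L)
  dimnames(x) <- NULL
  x
}

#' Random temporal crop with repeat-padding
#'
#' Takes a contiguous window of `crop_length` frames at a uniformly random
#' start. A sequence shorter than the window is tiled from its start until
#' the window is filled, so the output length is always exactly
#' `crop_length`. Randomness comes from R's RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param x A `tracklet` or a `(frames x 17 x 3)` sequence array.
#' @param crop_length Window length in frames (> 0).
#' @return A `(crop_length x 17 x 3)` sequence array.
#' @export
random_crop <- function(x, crop_length = 54L) {
  if (crop_length <= 0) stop("crop_length must be positive")
  s <- as_sequence(x)
  n <- dim(s)[1]
  idx <- if (n >= crop_length) {
    start <- sample.int(n - crop_length + 1L, 1L)
    start:(start + crop_length - 1L)
  } else {
    ((seq_len(crop_length) - 1L) %% n) + 1L   # tile from the start
  }
  s[idx, , , drop = FALSE]
}

#' Change the pace of a sequence
#'
#' Resamples the sequence in time by `factor`: the new length is
#' `max(2, round(frames / factor))` and output frame i (0-based) is the
#' linear interpolation of the input at instant `i * factor` (clamped to
#' the last frame). `factor > 1` contracts the walk (faster), `< 1`
#' dilates it (slower); integer-spaced output instants reproduce input
#' frames exactly.
#'
#' @param x A `tracklet` or sequence array with at least 2 frames.
#' @param factor Positive pace factor.
#' @return A resampled sequence array.
#' @export
change_pace <- function(x, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("pace factor must be a positive scalar")
  s <- as_sequence(x)
  n <- dim(s)[1]
  if (n < 2L) stop("change_pace needs at least 2 frames")
  if (factor == 1) return(s)
  m <- max(2L, as.integer(round(n / factor)))
  u <- pmin((seq_len(m) - 1) * factor, n - 1)
  flat <- matrix(s, nrow = n)
  out <- matrix(apply(flat, 2L, function(v)
    stats::approx(0:(n - 1), v, xout = u, rule = 2)$y), nrow = m)
  res <- array(out, dim = c(m, 17L, 3L))
  res[, , 3] <- pmin(pmax(res[, , 3], 0), 1)
  res
}

#' Mirror a sequence horizontally
#'
#' Reflects x to -x (valid for normalized, pelvis-centered coordinates)
#' and swaps every left/right joint pair so the skeleton stays
#' anatomically consistent. An involution: `mirror(mirror(s)) == s`.
#'
#' @param x A `tracklet` or sequence array.
#' @return The mirrored sequence array.
#' @export
mirror <- function(x) {
  s <- as_sequence(x)
  pairs <- coco17_lr_pairs()
  perm <- seq_len(17L)
  perm[pairs[, "left"]] <- pairs[, "right"]
  perm[pairs[, "right"]] <- pairs[, "left"]
  s <- s[, perm, , drop = FALSE]
  s[, , 1] <- -s[, , 1]
  s
}

#' Reverse a sequence in time
#'
#' @param x A `tracklet` or sequence array.
#' @return The time-reversed sequence array.
#' @export
time_flip <- function(x) {
  s <- as_sequence(x)
  s[rev(seq_len(dim(s)[1])), , , drop = FALSE]
}

#' Squeeze a sequence horizontally
#'
#' Scales all x coordinates by `sx`, leaving y and confidence untouched.
#'
#' @param x A `tracklet` or sequence array.
#' @param sx Positive horizontal scale factor.
#' @return The squeezed sequence array.
#' @export
squeeze <- function(x, sx) {
  if (!is.numeric(sx) || length(sx) != 1L || sx <= 0)
    stop("squeeze factor must be a positive scalar")
  s <- as_sequence(x)
  s[, , 1] <- sx * s[, , 1]
  s
}

#' Random joint dropout
#'
#' Each joint is independently dropped with probability `p`; a dropped
#' joint has its coordinates and confidence zeroed for the whole sequence.
#' The tensor shape never changes.
#'
#' @param x A `tracklet` or sequence array.
#' @param p Dropout probability in \[0, 1\].
#' @return The sequence array with dropped joints zeroed.
#' @export
dropout_joints <- function(x, p) {
  stopifnot(p >= 0, p <= 1)
  s <- as_sequence(x)
  drop <- stats::runif(17L) < p
  if (any(drop)) s[, drop, ] <- 0
  s
}

#' Random frame dropout
#'
#' Each frame is independently zeroed (all joints, all channels) with
#' probability `p`; frames are zeroed, not deleted, so the length is
#' unchanged.
#'
#' @inheritParams dropout_joints
#' @return The sequence array with dropped frames zeroed.
#' @export
dropout_frames <- function(x, p) {
  stopifnot(p >= 0, p <= 1)
  s <- as_sequence(x)
  drop <- stats::runif(dim(s)[1]) < p
  if (any(drop)) s[drop, , ] <- 0
  s
}

#' Convert a sequence to a model input sample
#'
#' @param x A `tracklet` or `(frames x 17 x 3)` sequence array.
#' @param label Identity/tracklet label carried by the sample.
#' @param ... Further tags stored as attributes (e.g. `angle`, `run`).
#' @return A `gait_sample`: a `(3 x 17 x frames)` array (channels x, y,
#'   confidence) with a `label` attribute.
#' @export
as_gait_sample <- function(x, label, ...) {
  s <- as_sequence(x)
  out <- aperm(s, c(3L, 2L, 1L))
  structure(out, label = as.character(label), class = "gait_sample", ...)
}

#' @export
print.gait_sample <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<gait_sample> label '%s', %d channels x %d joints x %d frames\n",
              attr(x, "label"), d[1], d[2], d[3]))
  invisible(x)
}

#' Generate a two-crop positive pair from a tracklet
#'
#' Produces the two augmented views ("two crops") of one tracklet used as
#' the positive pair in contrastive training. Each view is built
#' independently: pace change (factor sampled uniformly from
#' `cfg$pace_factors`), random crop to `cfg$crop_length`, then horizontal
#' squeeze, optional mirror and time-flip, and joint/frame dropout. Both
#' views inherit the tracklet's label (its track id unless overridden).
#'
#' @param t A filtered, normalized `tracklet`.
#' @param cfg An `augment_config`.
#' @param label Label assigned to both views; defaults to `t$track_id`.
#' @return List of two `gait_sample`s of exactly `cfg$crop_length` frames.
#' @export
make_views <- function(t, cfg = augment_config(), label = t$track_id) {
  stopifnot(inherits(t, "tracklet"))
  one_view <- function() {
    factor <- if (length(cfg$pace_factors) == 1L) cfg$pace_factors
              else sample(cfg$pace_factors, 1L)
    s <- if (n_frames(t) >= 2L) change_pace(t, factor) else as_sequence(t)
    s <- random_crop(s, cfg$crop_length)
    sx <- stats::runif(1, cfg$squeeze_range[1], cfg$squeeze_range[2])
    s <- squeeze(s, sx)
    if (stats::runif(1) < cfg$p_mirror) s <- mirror(s)
    if (stats::runif(1) < cfg$p_timeflip) s <- time_flip(s)
    s <- dropout_joints(s, cfg$p_joint_dropout)
    s <- dropout_frames(s, cfg$p_frame_dropout)
    as_gait_sample(s, label = label)
  }
  list(one_view(), one_view())
}
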