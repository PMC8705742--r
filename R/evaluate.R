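#' Rank-1 gallery/probe retrieval accuracy
#'
#' For each probe embedding, finds its nearest gallery embedding under
#' cosine similarity (the dot product, since embeddings live on the unit
#' sphere) and scores a hit when the nearest gallery item shares the
#' probe's identity label. Ties break to the lowest gallery index, so the
#' metric is deterministic.
#'
#' @param gallery,probe `embedding_set`s (the enrolled references and the
#'   queries).
#' @return Fraction of probes retrieved correctly, in \[0, 1\].
#' @export
rank1_accuracy <- function(gallery, probe) {
  stopifnot(inherits(gallery, "embedding_set"), inherits(probe, "embedding_set"))
  if (nrow(gallery$Z) == 0L) stop("gallery must be non-empty")
  sims <- tcrossprod(probe$Z, gallery$Z)
  nn <- max.col(sims, ties.method = "first")
  mean(gallery$info$label[nn] == probe$info$label)
}

#' Cross-view gallery/probe protocol
#'
#' The viewpoint-invariance protocol: for each probe angle, the probe set
#' is every sample at that angle and the gallery contains all samples at
#' every *other* angle (the probe angle is excluded from the gallery).
#' Reports per-angle rank-1 accuracy and their mean. An angle whose
#' gallery would be empty is omitted with a warning.
#'
#' @param es An `embedding_set` whose `info` has `label` and `angle`.
#' @return List with `per_angle` (named numeric) and `mean`.
#' @export
cross_view_protocol <- function(es) {
  stopifnot(inherits(es, "embedding_set"))
  ang <- es$info$angle
  if (all(is.na(ang))) stop("viewpoint tags required for the cross-view protocol")
  angles <- sort(unique(ang))
  acc <- numeric(0)
  for (a in angles) {
    p_idx <- which(ang == a)
    g_idx <- which(ang != a)
    if (!length(p_idx)) { warning("no probes at angle ", a); next }
    if (!length(g_idx)) { warning("no gallery samples for probe angle ", a); next }
    g <- embedding_set(es$Z[g_idx, , drop = FALSE],
                       es$info[g_idx, , drop = FALSE])
    p <- embedding_set(es$Z[p_idx, , drop = FALSE],
                       es$info[p_idx, , drop = FALSE])
    acc[as.character(a)] <- rank1_accuracy(g, p)
  }
  list(per_angle = acc, mean = mean(acc))
}

# deterministic, evenly spaced crop windows (tiling when short)
.eval_crops <- function(t, crop_length, n_crops) {
  s <- as_sequence(t)
  n <- dim(s)[1]
  starts <- if (n <= crop_length) 1L else
    unique(as.integer(round(seq(1, n - crop_length + 1, length.out = n_crops))))
  lapply(starts, function(s0) {
    idx <- if (n >= crop_length) s0:(s0 + crop_length - 1L)
           else ((seq_len(crop_length) - 1L) %% n) + 1L
    s[idx, , , drop = FALSE]
  })
}

#' Embed a dataset's tracklets with a frozen encoder
#'
#' Deterministic test-time embedding: each tracklet is cut into
#' `n_crops` evenly spaced windows of `crop_length` frames (tiled from
#' the start when shorter), each window is encoded, and the embeddings
#' are averaged and re-normalized onto the unit sphere — the usual
#' multi-crop evaluation, which averages out the arbitrary gait phase a
#' single window would pick. Labels default to the tracklets'
#' `meta$identity` tag when present, else the track id; `meta$angle` and
#' `meta$run` tags are carried into the embedding set.
#'
#' @param model A `gait_encoder`.
#' @param ds A filtered, normalized `tracklet_dataset`.
#' @param crop_length Input window length in frames.
#' @param n_crops Number of evenly spaced windows averaged per tracklet.
#' @return An `embedding_set`.
#' @export
embed_tracklets <- function(model, ds, crop_length = 54L, n_crops = 4L) {
  stopifnot(inherits(model, "gait_encoder"), inherits(ds, "tracklet_dataset"))
  tl <- unname(ds$tracklets)
  crops <- lapply(tl, .eval_crops, crop_length = crop_length,
                  n_crops = n_crops)
  samples <- lapply(unlist(crops, recursive = FALSE), as_gait_sample,
                    label = "crop")
  flat <- encode_matrix(model, samples)
  counts <- vapply(crops, length, integer(1))
  ends <- cumsum(counts)
  Z <- t(vapply(seq_along(tl), function(i) {
    rows <- (ends[i] - counts[i] + 1L):ends[i]
    z <- colMeans(flat[rows, , drop = FALSE])
    z / sqrt(sum(z^2))
  }, numeric(ncol(flat))))
  info <- data.frame(
    label = vapply(tl, function(t)
      as.character(t$meta$identity %||% t$track_id), character(1)),
    angle = vapply(tl, function(t)
      as.character(t$meta$angle %||% NA_character_), character(1)),
    run = vapply(tl, function(t)
      as.character(t$meta$run %||% NA_character_), character(1)),
    stringsAsFactors = FALSE)
  embedding_set(Z, info)
}

# raw embedding matrix for a list of samples (no label bookkeeping)
encode_matrix <- function(model, samples, batch_size = 128L) {
  pieces <- split(seq_along(samples),
                  ceiling(seq_along(samples) / batch_size))
  do.call(rbind, lapply(pieces, function(idx) {
    X <- .stack_samples(samples[idx], model$config$in_channels)
    .encoder_forward(model, X)$Z
  }))
}

#' Direct-transfer evaluation of a frozen encoder
#'
#' Embeds all evaluation-identity samples of a benchmark with the frozen
#' encoder (no fine-tuning) and runs the cross-view protocol. With
#' `n_repeats > 1`, per-identity run subsets of size `runs_fraction` are
#' resampled each repeat and the accuracies averaged, matching the
#' repeated-subsample protocol. Training identities are never allowed
#' into the evaluation set.
#'
#' @param model A `gait_encoder`.
#' @param ds A filtered, normalized `tracklet_dataset` whose tracklets
#'   carry `meta$identity`, `meta$angle`, `meta$run` tags.
#' @param eval_identities Identities forming the evaluation split.
#' @param train_identities Identities used for any training; an overlap
#'   with `eval_identities` is an error (leakage).
#' @param crop_length Model input length.
#' @param n_repeats Number of seeded repetitions.
#' @param runs_fraction Fraction of runs sampled per identity per repeat
#'   (1 = all runs, single deterministic evaluation).
#' @param seed Base seed for the repetitions.
#' @return List with `mean`, `sd`, `per_repeat` (mean accuracy each
#'   repeat) and `per_angle` (matrix, repeats x angles).
#' @export
direct_transfer_eval <- function(model, ds, eval_identities,
                                 train_identities = character(0),
                                 crop_length = 54L, n_repeats = 1L,
                                 runs_fraction = 1.0, seed = 1L) {
  stopifnot(inherits(model, "gait_encoder"), inherits(ds, "tracklet_dataset"))
  if (length(intersect(eval_identities, train_identities)))
    stop("evaluation identities overlap the training split (leakage)")
  ids <- vapply(unname(ds$tracklets), function(t)
    as.character(t$meta$identity %||% t$track_id), character(1))
  keep <- ids %in% as.character(eval_identities)
  if (!any(keep)) stop("no tracklets for the evaluation identities")
  eval_tl <- unname(ds$tracklets)[keep]
  eval_ids <- ids[keep]
  per_repeat <- numeric(n_repeats)
  per_angle <- NULL
  for (r in seq_len(n_repeats)) {
    set.seed(derive_seed(seed, paste0("transfer", r)))
    sel <- if (runs_fraction >= 1) seq_along(eval_tl) else
      unlist(lapply(split(seq_along(eval_tl), eval_ids), function(idx) {
        k <- max(1L, as.integer(round(runs_fraction * length(idx))))
        if (k >= length(idx)) idx else sample(idx, k)
      }), use.names = FALSE)
    es <- embed_tracklets(
      model, tracklet_dataset(eval_tl[sel]), crop_length)
    cv <- cross_view_protocol(es)
    per_repeat[r] <- cv$mean
    per_angle <- rbind(per_angle, cv$per_angle)
  }
  list(mean = mean(per_repeat),
       sd = if (n_repeats > 1L) stats::sd(per_repeat) else NA_real_,
       per_repeat = per_repeat, per_angle = per_angle)
}

#' Accuracy versus pretraining-pool size
#'
#' Direct-transfer accuracy as a function of the fraction of the
#' pretraining corpus used: for each fraction and each seed, a random
#' subsample of the pool is drawn, an encoder is pretrained on it, and
#' the frozen encoder is evaluated cross-view on the benchmark's
#' evaluation identities. Accuracies are averaged over seeds.
#'
#' @param pool A filtered, normalized `tracklet_dataset` (the pretraining
#'   corpus).
#' @param bench_ds A filtered, normalized benchmark `tracklet_dataset`
#'   with identity/angle/run tags.
#' @param eval_identities Evaluation-split identities of the benchmark.
#' @param fractions Pool fractions to test (default 0.1, 0.5, 1).
#' @param enc_cfg An `encoder_config` for the pretrained encoders.
#' @param cfg A `train_config` template; its seed is re-derived per
#'   repetition.
#' @param aug An `augment_config`.
#' @param n_repeats Seeded repetitions per fraction.
#' @param seed Base seed.
#' @return Data frame with columns `fraction`, `n_tracklets`, `mean_acc`,
#'   `sd_acc`.
#' @export
pretraining_size_curve <- function(pool, bench_ds, eval_identities,
                                   fractions = c(0.1, 0.5, 1),
                                   enc_cfg = encoder_config(),
                                   cfg = train_config(),
                                   aug = augment_config(),
                                   n_repeats = 5L, seed = 1L) {
  stopifnot(inherits(pool, "tracklet_dataset"))
  out <- lapply(fractions, function(f) {
    accs <- numeric(n_repeats)
    n_used <- NA_integer_
    for (r in seq_len(n_repeats)) {
      s <- derive_seed(seed, paste0("size", f, "rep", r))
      set.seed(s)
      k <- max(2L, as.integer(round(f * length(pool))))
      sub <- tracklet_dataset(sample(unname(pool$tracklets), k))
      n_used <- k
      cfg_r <- cfg
      cfg_r$seed <- derive_seed(s, "pretrain")
      fit <- pretrain(sub, enc_cfg, cfg_r, aug)
      accs[r] <- direct_transfer_eval(
        fit$model, bench_ds, eval_identities,
        crop_length = aug$crop_length, seed = s)$mean
    }
    data.frame(fraction = f, n_tracklets = n_used,
               mean_acc = mean(accs),
               sd_acc = if (n_repeats > 1L) stats::sd(accs) else NA_real_)
  })
  do.call(rbind, out)
}

#' 2D projection plot of an embedding set
#'
#' Projects the embeddings to 2D with classical multidimensional scaling
#' on cosine distances and draws one point per embedding, colored by
#' identity label or by viewpoint angle.
#'
#' @param es An `embedding_set`.
#' @param color_by `"identity"` or `"viewpoint"`.
#' @param path Output figure file (extension selects the device, e.g.
#'   `.png` or `.pdf`).
#' @return `path`, invisibly.
#' @export
embedding_plot <- function(es, color_by = c("identity", "viewpoint"),
                           path = "embeddings.png") {
  stopifnot(inherits(es, "embedding_set"), nrow(es$Z) >= 2L)
  color_by <- match.arg(color_by)
  D <- 1 - tcrossprod(es$Z)
  D[D < 0] <- 0
  xy <- stats::cmdscale(stats::as.dist(D), k = 2)
  df <- data.frame(x = xy[, 1], y = xy[, 2],
                   group = if (color_by == "identity") es$info$label
                           else es$info$angle)
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         color = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(color = color_by, x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, gp, width = 6, height = 5, dpi = 150)
  invisible(path)
}
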