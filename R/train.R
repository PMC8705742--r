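#' Training configuration
#'
#' @param tau Contrastive temperature (default 0.01).
#' @param sources_per_batch Number of source tracklets per batch (`N`);
#'   each contributes two augmented views, so batches hold `2N` samples.
#' @param lr Base Adam learning rate.
#' @param epochs Number of passes over the tracklet pool.
#' @param seed RNG seed controlling batching, augmentation and
#'   initialization.
#' @param layerwise_decay Fine-tuning only: per-depth-level learning-rate
#'   decay — the projection head trains at `lr`, the deepest (last) block
#'   at `lr * decay`, each earlier block one factor lower, and the
#'   edge-importance mask at the lowest rate.
#' @return An object of class `train_config`.
#' @export
train_config <- function(tau = 0.01, sources_per_batch = 8L, lr = 1e-3,
                         epochs = 10L, seed = 1L, layerwise_decay = 0.5) {
  if (tau <= 0) stop("tau must be positive")
  if (sources_per_batch < 2L) stop("need at least 2 sources per batch")
  structure(list(tau = tau, sources_per_batch = as.integer(sources_per_batch),
                 lr = lr, epochs = as.integer(epochs),
                 seed = as.integer(seed), layerwise_decay = layerwise_decay),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, lr_mult = NULL,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  if (is.null(lr_mult)) {
    params <- tree_map2(function(p, u) p - lr * u, params, upd)
  } else {
    params <- tree_map3(function(p, u, s) p - lr * s * u, params, upd, lr_mult)
  }
  list(params = params, state = state)
}

# lr multiplier tree: head at 1, blocks decaying toward the input, mask lowest
.layerwise_multipliers <- function(params, decay) {
  nb <- length(params$blocks)
  blocks <- lapply(seq_len(nb), function(i) {
    s <- decay ^ (nb - i + 1L)          # last block one level below the head
    list(K = s, b = s)
  })
  list(M = decay ^ (nb + 1L), blocks = blocks,
       W1 = 1, b1 = 1, W2 = 1, b2 = 1)
}

# one optimization pass over a pool of tracklets with given labels
.contrastive_epochs <- function(model, pool, labels, cfg, aug, opt,
                                lr_mult = NULL) {
  n <- length(pool)
  trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$sources_per_batch))
    batches <- batches[vapply(batches, length, integer(1)) >= 2L]
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      views <- unlist(lapply(idx, function(i)
        make_views(pool[[i]], aug, label = labels[i])), recursive = FALSE)
      X <- .stack_samples(views, model$config$in_channels)
      fwd <- .encoder_forward(model, X, with_cache = TRUE)
      y <- rep(labels[idx], each = 2L)
      sc <- supcon_loss(fwd$Z, y, tau = cfg$tau, grad = TRUE)
      grads <- .encoder_backward(model, fwd$cache, sc$grad)
      step <- adam_step(model$params, grads, opt, cfg$lr, lr_mult)
      model$params <- step$params
      opt <- step$state
      losses[bi] <- sc$loss
    }
    trace[ep] <- mean(losses)
  }
  list(model = model, trace = trace, opt = opt)
}

#' Contrastive pretraining on tracklet labels
#'
#' Pretrains the encoder with the supervised contrastive objective where
#' the only supervision is the tracking itself: every tracklet is its own
#' class, and the positives of an anchor are the other augmented crops of
#' the same tracklet. Batches draw `N` tracklets and two views each.
#' Fully reproducible from `cfg$seed`.
#'
#' @param ds A filtered, normalized `tracklet_dataset`.
#' @param model A `gait_encoder`, or an `encoder_config` from which a
#'   fresh encoder is initialized under the training seed.
#' @param cfg A `train_config`.
#' @param aug An `augment_config`.
#' @return List with `model` (the trained `gait_encoder`) and
#'   `loss_trace` (mean batch loss per epoch).
#' @export
pretrain <- function(ds, model = encoder_config(), cfg = train_config(),
                     aug = augment_config()) {
  stopifnot(inherits(ds, "tracklet_dataset"), inherits(cfg, "train_config"))
  if (length(ds) < 2L) stop("pretraining needs at least 2 tracklets")
  set.seed(cfg$seed)
  if (inherits(model, "encoder_config")) model <- init_encoder(model)
  stopifnot(inherits(model, "gait_encoder"))
  pool <- unname(ds$tracklets)
  labels <- vapply(pool, function(t) t$track_id, character(1))
  run <- .contrastive_epochs(model, pool, labels, cfg, aug,
                             adam_init(model$params))
  list(model = run$model, loss_trace = run$trace)
}

#' Few-shot fine-tuning with layer-wise learning rates
#'
#' Continues training a (typically pretrained) encoder on an
#' identity-labeled dataset using the same contrastive objective, now
#' with identity labels, on a per-identity random sample of runs:
#' `round(fraction * runs)` runs per identity, at least 1. The learning
#' rate is highest for the projection head and decays by
#' `cfg$layerwise_decay` per level toward the input blocks, protecting
#' the pretrained low-level representations.
#'
#' @param model A `gait_encoder` (pretrained or freshly initialized).
#' @param ds A filtered, normalized `tracklet_dataset`.
#' @param identities Character vector: identity label of each tracklet,
#'   in `ds` order.
#' @param fraction Fraction of each identity's runs to use (e.g. 0.10,
#'   0.20, 0.30, 0.50, 0.70, 1.00).
#' @param cfg A `train_config`; `cfg$seed` controls the run subsample and
#'   the optimization stream.
#' @param aug An `augment_config`.
#' @return List with `model`, `loss_trace`, and `used` (data frame of the
#'   sampled tracklet/identity pairs).
#' @export
finetune <- function(model, ds, identities, fraction = 1.0,
                     cfg = train_config(), aug = augment_config()) {
  stopifnot(inherits(model, "gait_encoder"), inherits(ds, "tracklet_dataset"))
  if (length(identities) != length(ds))
    stop("one identity label per tracklet required")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  set.seed(cfg$seed)
  pool_idx <- unlist(lapply(split(seq_along(identities), identities),
                            function(idx) {
    k <- max(1L, as.integer(round(fraction * length(idx))))
    if (k >= length(idx)) idx else sample(idx, k)
  }), use.names = FALSE)
  pool <- unname(ds$tracklets)[pool_idx]
  labels <- identities[pool_idx]
  if (length(unique(labels)) < 2L)
    stop("fine-tuning needs at least 2 identities")
  mult <- .layerwise_multipliers(model$params, cfg$layerwise_decay)
  run <- .contrastive_epochs(model, pool, labels, cfg, aug,
                             adam_init(model$params), lr_mult = mult)
  list(model = run$model, loss_trace = run$trace,
       used = data.frame(
         track_id = vapply(pool, function(t) t$track_id, character(1)),
         identity = labels, stringsAsFactors = FALSE))
}

#' Save / load an encoder checkpoint
#'
#' A checkpoint is the serialized `gait_encoder` (parameters, architecture
#' and graph) in RDS format.
#'
#' @param model A `gait_encoder`.
#' @param path Checkpoint file path.
#' @return `path` invisibly (save); the `gait_encoder` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "gait_encoder"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gait_encoder")) stop("not an encoder checkpoint")
  model
}
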