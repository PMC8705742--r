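#' Encoder architecture configuration
#'
#' Describes the spatio-temporal graph-convolutional encoder: a stack of
#' graph-convolution blocks (spatial aggregation by the masked normalized
#' adjacency, `1 x gamma` temporal convolution, ReLU), global average
#' pooling over joints and time, and a projection head (one hidden ReLU
#' layer then a linear map) whose output is L2-normalized onto the unit
#' sphere.
#'
#' @param channels Output channels per block. The default follows the
#'   original ST-GCN recipe scaled to seven blocks; desk-scale experiments
#'   typically use two or three narrow blocks.
#' @param temporal_kernel Temporal window `gamma` (odd, default 9).
#' @param strides Temporal stride per block; default 2 wherever the
#'   channel width increases, else 1.
#' @param embedding_dim Dimension of the unit-norm output embedding.
#' @param hidden_dim Width of the projection head's hidden layer.
#' @param in_channels Input channels; 3 for (x, y, confidence), set 2 to
#'   drop the confidence channel.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(channels = c(64, 64, 64, 128, 128, 256, 256),
                           temporal_kernel = 9L,
                           strides = NULL,
                           embedding_dim = 128L,
                           hidden_dim = 256L,
                           in_channels = 3L) {
  if (temporal_kernel %% 2L != 1L) stop("temporal_kernel must be odd")
  if (any(channels <= 0)) stop("channels must be positive")
  if (is.null(strides)) {
    prev <- c(in_channels, channels[-length(channels)])
    strides <- ifelse(channels > prev & seq_along(channels) > 1L, 2L, 1L)
  }
  if (length(strides) != length(channels))
    stop("strides must match channels in length")
  structure(list(channels = as.integer(channels),
                 temporal_kernel = as.integer(temporal_kernel),
                 strides = as.integer(strides),
                 embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim),
                 in_channels = as.integer(in_channels)),
            class = "encoder_config")
}

#' Initialize a gait encoder
#'
#' Creates the trainable parameters: per-block convolution kernels and
#' biases (He-normal initialization), the shared edge-importance mask
#' (all ones), and the projection head. The parameter count is
#' independent of how many identities the training data contains — there
#' is no classification head.
#'
#' @param cfg An `encoder_config`.
#' @param graph A `skeleton_graph`.
#' @return An object of class `gait_encoder` holding `config`, `graph`
#'   and `params`.
#' @export
init_encoder <- function(cfg = encoder_config(), graph = skeleton_graph()) {
  stopifnot(inherits(cfg, "encoder_config"), inherits(graph, "skeleton_graph"))
  gamma <- cfg$temporal_kernel
  cins <- c(cfg$in_channels, cfg$channels[-length(cfg$channels)])
  blocks <- lapply(seq_along(cfg$channels), function(i) {
    fan_in <- cins[i] * gamma
    list(K = array(stats::rnorm(cfg$channels[i] * cins[i] * gamma,
                                sd = sqrt(2 / fan_in)),
                   dim = c(cfg$channels[i], cins[i], gamma)),
         b = rep(0, cfg$channels[i]))
  })
  c_last <- cfg$channels[length(cfg$channels)]
  params <- list(
    M = matrix(1, graph$n, graph$n),
    blocks = blocks,
    W1 = matrix(stats::rnorm(cfg$hidden_dim * c_last, sd = sqrt(2 / c_last)),
                cfg$hidden_dim, c_last),
    b1 = rep(0.01, cfg$hidden_dim),   # keep some head units active at init
    W2 = matrix(stats::rnorm(cfg$embedding_dim * cfg$hidden_dim,
                             sd = sqrt(1 / cfg$hidden_dim)),
                cfg$embedding_dim, cfg$hidden_dim),
    b2 = stats::rnorm(cfg$embedding_dim, sd = 0.01))
  structure(list(config = cfg, graph = graph, params = params),
            class = "gait_encoder")
}

#' @export
print.gait_encoder <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, identity, how = "unlist"), length,
                   integer(1)))
  cat(sprintf(
    "<gait_encoder> %d blocks (channels %s), gamma %d, embedding dim %d, %d parameters\n",
    length(x$config$channels), paste(x$config$channels, collapse = "/"),
    x$config$temporal_kernel, x$config$embedding_dim, np))
  invisible(x)
}

# stack a list of gait_samples into a (C, V, T, B) batch array
.stack_samples <- function(samples, in_channels = 3L) {
  d <- dim(samples[[1]])
  X <- array(0, dim = c(in_channels, d[2], d[3], length(samples)))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (!identical(dim(s), d)) stop("all samples must share one shape")
    X[, , , i] <- s[seq_len(in_channels), , , drop = FALSE]
  }
  X
}

# full forward pass; returns Z (B x D, unit rows) and caches for backward
.encoder_forward <- function(model, X, with_cache = FALSE) {
  p <- model$params
  scale <- .adjacency_scale(model$graph$A)
  adj <- scale * p$M
  caches <- vector("list", length(p$blocks))
  cur <- X
  for (i in seq_along(p$blocks)) {
    fwd <- .block_forward(cur, adj, p$blocks[[i]]$K, p$blocks[[i]]$b,
                          model$config$strides[i], relu = TRUE)
    caches[[i]] <- if (with_cache) fwd else NULL
    cur <- fwd$out
  }
  d <- dim(cur)
  pooled <- apply(array(cur, dim = c(d[1], d[2] * d[3], d[4])), 3L, rowMeans)
  pooled <- matrix(pooled, nrow = d[1])                     # C_last x B
  H_pre <- p$W1 %*% pooled + p$b1
  H <- pmax(H_pre, 0)
  E <- p$W2 %*% H + p$b2
  r <- sqrt(colSums(E^2))
  if (any(!is.finite(r)) || any(r == 0))
    stop("non-finite or zero-norm embedding; check inputs and learning rate")
  Z <- sweep(E, 2L, r, "/")
  list(Z = t(Z),
       cache = if (with_cache)
         list(X = X, caches = caches, out_dims = d, pooled = pooled,
              H_pre = H_pre, H = H, Zcol = Z, r = r, adj = adj,
              scale = scale) else NULL)
}

# backward pass from dZ (B x D) to parameter gradients
.encoder_backward <- function(model, cache, dZ) {
  p <- model$params
  dZc <- t(dZ)                                              # D x B
  Z <- cache$Zcol
  dE <- sweep(dZc - sweep(Z, 2L, colSums(Z * dZc), "*"), 2L, cache$r, "/")
  gW2 <- tcrossprod(dE, cache$H)
  gb2 <- rowSums(dE)
  dH <- crossprod(p$W2, dE) * (cache$H_pre > 0)
  gW1 <- tcrossprod(dH, cache$pooled)
  gb1 <- rowSums(dH)
  dPooled <- crossprod(p$W1, dH)                            # C_last x B
  d <- cache$out_dims
  dOut <- array(rep(dPooled, each = d[2] * d[3]) / (d[2] * d[3]),
                dim = c(d[2] * d[3], d[1], d[4]))
  dOut <- aperm(array(dOut, dim = c(d[2], d[3], d[1], d[4])), c(3L, 1L, 2L, 4L))
  dAhat <- matrix(0, model$graph$n, model$graph$n)
  gblocks <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    bk <- .block_backward(dOut, cache$caches[[i]], cache$adj,
                          p$blocks[[i]]$K, relu = TRUE)
    gblocks[[i]] <- list(K = bk$dK, b = bk$db)
    dAhat <- dAhat + bk$dAhat
    dOut <- bk$dX
  }
  list(M = cache$scale * dAhat, blocks = gblocks,
       W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

#' Embed gait samples
#'
#' Runs the encoder in inference mode on a batch of fixed-shape
#' `gait_sample`s and returns their unit-norm embeddings with the
#' samples' labels and tags. Deterministic given fixed parameters.
#'
#' @param model A `gait_encoder`.
#' @param samples List of `gait_sample`s sharing one shape.
#' @param batch_size Samples per forward pass.
#' @return An `embedding_set`.
#' @export
encode <- function(model, samples, batch_size = 128L) {
  stopifnot(inherits(model, "gait_encoder"), length(samples) >= 1L)
  pieces <- split(seq_along(samples),
                  ceiling(seq_along(samples) / batch_size))
  Z <- do.call(rbind, lapply(pieces, function(idx) {
    X <- .stack_samples(samples[idx], model$config$in_channels)
    .encoder_forward(model, X)$Z
  }))
  grab <- function(a) vapply(samples, function(s)
    as.character(attr(s, a) %||% NA_character_), character(1))
  embedding_set(Z, data.frame(label = grab("label"),
                              angle = grab("angle"),
                              run = grab("run"),
                              stringsAsFactors = FALSE))
}

#' Construct an embedding set
#'
#' Unit-norm embedding vectors with per-sample labels and optional
#' viewpoint/run tags — the unit of retrieval evaluation and of the
#' contrastive loss.
#'
#' @param Z Numeric matrix, one embedding per row, rows unit-norm within
#'   1e-6.
#' @param info Data frame with one row per embedding; must contain a
#'   `label` column, optionally `angle` and `run`.
#' @return An object of class `embedding_set`.
#' @export
embedding_set <- function(Z, info) {
  Z <- as.matrix(Z)
  stopifnot(is.data.frame(info), nrow(info) == nrow(Z), "label" %in% names(info))
  if (any(is.na(info$label))) stop("labels must be non-empty")
  nrm <- sqrt(rowSums(Z^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("embedding rows must be unit-norm (max deviation ",
         format(max(abs(nrm - 1))), ")")
  structure(list(Z = Z, info = info), class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d embeddings of dim %d, %d distinct labels\n",
              nrow(x$Z), ncol(x$Z), length(unique(x$info$label))))
  invisible(x)
}

#' @export
length.embedding_set <- function(x) nrow(x$Z)
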