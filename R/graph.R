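#' Skeleton graph for graph convolution
#'
#' Builds the joint-adjacency structure the spatial aggregation operates
#' on: a symmetric, zero-diagonal adjacency `A` from an edge list,
#' self-connections `I`, the degree matrix `Lambda` with
#' `Lambda_ii = sum_j (A_ij + I_ij)`, and a learnable edge-importance mask
#' `M` (initialized to all ones) that is multiplied elementwise into
#' `A + I` before normalization.
#'
#' @param edges Two-column integer matrix of undirected edges (1-based
#'   joint indices). Defaults to the COCO-17 skeleton.
#' @param n_joints Number of nodes.
#' @return An object of class `skeleton_graph` with elements `A`, `M`,
#'   `n`.
#' @export
skeleton_graph <- function(edges = coco17_edges(), n_joints = 17L) {
  A <- matrix(0, n_joints, n_joints)
  if (nrow(edges)) {
    A[edges] <- 1
    A[edges[, 2:1, drop = FALSE]] <- 1
  }
  diag(A) <- 0
  structure(list(A = A, M = matrix(1, n_joints, n_joints), n = n_joints),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d joints, %d edges, edge-importance mask %s\n",
              x$n, sum(x$A) / 2,
              if (all(x$M == 1)) "at init (all ones)" else "learned"))
  invisible(x)
}

#' Symmetrically normalized masked adjacency operator
#'
#' Returns `Lambda^(-1/2) ((A + I) * M) Lambda^(-1/2)` where `*` is the
#' elementwise product, `I` the self-connections and
#' `Lambda_ii = sum_j (A_ij + I_ij)`. The degree normalization is computed
#' from `A + I` (not from the masked matrix), so it stays fixed while the
#' mask is learned. With `M` all ones this is the standard symmetric
#' graph-convolution normalization, a symmetric operator with spectral
#' radius at most 1.
#'
#' @param graph A `skeleton_graph`, or a square symmetric zero-diagonal
#'   adjacency matrix.
#' @param M Optional mask matrix; defaults to the graph's mask (all ones
#'   for a plain adjacency).
#' @return The normalized operator matrix.
#' @export
build_normalized_adjacency <- function(graph, M = NULL) {
  if (inherits(graph, "skeleton_graph")) {
    A <- graph$A
    if (is.null(M)) M <- graph$M
  } else {
    A <- as.matrix(graph)
    if (nrow(A) != ncol(A)) stop("adjacency must be square")
    if (any(A != t(A))) stop("adjacency must be symmetric")
    if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
    if (is.null(M)) M <- matrix(1, nrow(A), ncol(A))
  }
  Aplus <- A + diag(nrow(A))
  deg <- rowSums(Aplus)
  if (any(deg <= 0)) stop("graph has a zero-degree node")
  dm12 <- 1 / sqrt(deg)
  (dm12 %o% dm12) * (Aplus * M)
}

# fixed scaling Lambda^(-1/2)(A+I)Lambda^(-1/2) entrywise, so that the
# learned operator is scale * M and d(operator)/dM = scale
.adjacency_scale <- function(A) {
  Aplus <- A + diag(nrow(A))
  dm12 <- 1 / sqrt(rowSums(Aplus))
  (dm12 %o% dm12) * Aplus
}

#' One spatio-temporal graph-convolution block (functional form)
#'
#' Applies the two stages of a spatio-temporal graph-convolution layer to
#' a single `(C, V, T)` feature map: spatial aggregation by a normalized
#' (optionally masked) adjacency operator, then a standard `1 x gamma`
#' temporal convolution whose kernel also realizes the channel-mixing
#' weights. With a length-1 temporal kernel equal to the identity, no
#' bias and no nonlinearity, the block reduces to the pure
#' adjacency-matrix product.
#'
#' @param x Feature map array `(C_in, V, T)`.
#' @param adj `V x V` spatial operator (e.g. from
#'   [build_normalized_adjacency()]).
#' @param kernel Convolution weights, array `(C_out, C_in, gamma)` with
#'   `gamma` odd; temporal padding `floor(gamma/2)` preserves `T` at
#'   stride 1.
#' @param bias Optional length-`C_out` bias (default zeros).
#' @param stride Temporal stride; the output has `ceil(T / stride)`
#'   frames.
#' @param activation `"relu"` or `"identity"`.
#' @param residual If `TRUE`, adds the input to the pre-activation
#'   (requires matching shapes: `C_in == C_out`, stride 1).
#' @return Feature map array `(C_out, V, T_out)`.
#' @export
stgcn_block <- function(x, adj, kernel, bias = NULL, stride = 1L,
                        activation = c("relu", "identity"),
                        residual = FALSE) {
  activation <- match.arg(activation)
  stopifnot(length(dim(x)) == 3L, length(dim(kernel)) == 3L)
  X <- array(x, dim = c(dim(x), 1L))
  fwd <- .block_forward(X, adj, kernel,
                        bias %||% rep(0, dim(kernel)[1]),
                        as.integer(stride), relu = FALSE)
  out <- fwd$pre
  if (residual) {
    if (!identical(dim(out), dim(X)))
      stop("residual connection requires matching input/output shapes")
    out <- out + X
  }
  if (activation == "relu") out <- pmax(out, 0)
  array(out, dim = dim(out)[1:3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- batched block forward/backward (internal) -------------------------
# X: (C, V, T, B). Returns pre-activation (and caches for backward).

.block_forward <- function(X, adj, K, b, stride, relu = TRUE) {
  d <- dim(X); C <- d[1]; V <- d[2]; Tn <- d[3]; B <- d[4]
  gamma <- dim(K)[3]
  if (gamma %% 2L == 0L) stop("temporal kernel size must be odd")
  if (dim(K)[2] != C) stop("kernel input channels do not match feature map")
  # spatial aggregation
  Xm <- matrix(aperm(X, c(2L, 1L, 3L, 4L)), nrow = V)      # V x (C*T*B)
  Sm <- adj %*% Xm
  S <- aperm(array(Sm, dim = c(V, C, Tn, B)), c(2L, 1L, 3L, 4L))
  # temporal 1 x gamma convolution via im2col
  p <- (gamma - 1L) %/% 2L
  Tp <- Tn + 2L * p
  T_out <- (Tp - gamma) %/% stride + 1L
  Xp <- array(0, dim = c(C, V, Tp, B))
  Xp[, , p + seq_len(Tn), ] <- S
  cols <- matrix(0, C * gamma, V * T_out * B)
  t_idx <- stride * (seq_len(T_out) - 1L)
  for (dlt in seq_len(gamma)) {
    sl <- Xp[, , dlt + t_idx, , drop = FALSE]
    cols[(dlt - 1L) * C + seq_len(C), ] <- matrix(sl, nrow = C)
  }
  Kmat <- matrix(K, nrow = dim(K)[1])
  Z <- Kmat %*% cols + b
  pre <- array(Z, dim = c(dim(K)[1], V, T_out, B))
  out <- if (relu) pmax(pre, 0) else pre
  list(out = out, pre = pre, cols = cols, Xm = Xm,
       dims = list(C = C, V = V, Tn = Tn, B = B, gamma = gamma, p = p,
                   Tp = Tp, T_out = T_out, stride = stride))
}

.block_backward <- function(dOut, fwd, adj, K, relu = TRUE) {
  dm <- fwd$dims
  C <- dm$C; V <- dm$V; Tn <- dm$Tn; B <- dm$B
  Cout <- dim(K)[1]
  dpre <- if (relu) dOut * (fwd$pre > 0) else dOut
  dpre_m <- matrix(dpre, nrow = Cout)
  dK <- array(dpre_m %*% t(fwd$cols), dim = dim(K))
  db <- rowSums(dpre_m)
  Kmat <- matrix(K, nrow = Cout)
  dcols <- crossprod(Kmat, dpre_m)
  dXp <- array(0, dim = c(C, V, dm$Tp, B))
  t_idx <- dm$stride * (seq_len(dm$T_out) - 1L)
  for (dlt in seq_len(dm$gamma)) {
    sl <- array(dcols[(dlt - 1L) * C + seq_len(C), ],
                dim = c(C, V, dm$T_out, B))
    dXp[, , dlt + t_idx, ] <- dXp[, , dlt + t_idx, , drop = FALSE] + sl
  }
  dS <- dXp[, , dm$p + seq_len(Tn), , drop = FALSE]
  dSm <- matrix(aperm(dS, c(2L, 1L, 3L, 4L)), nrow = V)
  dAhat <- tcrossprod(dSm, fwd$Xm)                # V x V
  dXm <- crossprod(adj, dSm)
  dX <- aperm(array(dXm, dim = c(V, C, Tn, B)), c(2L, 1L, 3L, 4L))
  list(dX = dX, dK = dK, db = db, dAhat = dAhat)
}
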