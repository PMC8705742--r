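# fixtures built in code: small deterministic skeletons and tracklets

# a frame with hips/shoulders at controlled positions; everything else at
# the body center so normalization stays well-conditioned
fixture_frame <- function(hips_y = 300, shoulders_y = 150,
                          left_x = 90, right_x = 110, conf = 1) {
  x <- rep((left_x + right_x) / 2, 17)
  y <- rep((hips_y + shoulders_y) / 2, 17)
  x[c(6, 12)] <- left_x          # left shoulder / hip
  x[c(7, 13)] <- right_x         # right shoulder / hip
  y[c(6, 7)] <- shoulders_y
  y[c(12, 13)] <- hips_y
  skeleton_frame(x, y, rep(conf, 17))
}

# constant (static) tracklet with given confidence
fixture_tracklet <- function(n = 60, id = "t1", conf = 0.9, fps = 24) {
  f <- fixture_frame(conf = conf)
  joints <- array(0, dim = c(n, 17, 3))
  for (k in seq_len(n)) joints[k, , ] <- f
  tracklet(id, joints, fps = fps)
}

# walking-ish tracklet: ankles/knees oscillate sinusoidally (normalized units)
fixture_walking_tracklet <- function(n = 100, id = "w1", amp = 0.3,
                                     cadence = 1, fps = 24, conf = 0.9) {
  tl <- fixture_tracklet(n, id, conf = conf, fps = fps)
  phi <- 2 * pi * cadence * (seq_len(n) - 1) / fps
  for (j in c(14, 16)) tl$joints[, j, 1] <- tl$joints[, j, 1] + amp * sin(phi)
  for (j in c(15, 17)) tl$joints[, j, 1] <- tl$joints[, j, 1] + amp * sin(phi + pi)
  tl
}

# random symmetric zero-diagonal adjacency with no isolated-node worries
# (self-loops are added inside the operator)
fixture_random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(stats::runif(length(up)) < p)
  A + t(A)
}

# random unit-norm embeddings
fixture_unit_embeddings <- function(n, d) {
  Z <- matrix(stats::rnorm(n * d), n, d)
  Z / sqrt(rowSums(Z^2))
}

# brute-force supervised-contrastive loss: direct double loop
oracle_supcon <- function(Z, labels, tau) {
  n <- nrow(Z)
  total <- 0
  for (i in seq_len(n)) {
    A_i <- setdiff(seq_len(n), i)
    P_i <- A_i[labels[A_i] == labels[i]]
    denom <- sum(exp(Z[i, ] %*% t(Z[A_i, , drop = FALSE]) / tau))
    term <- 0
    for (p in P_i)
      term <- term + log(exp(sum(Z[i, ] * Z[p, ]) / tau) / denom)
    total <- total - term / length(P_i)
  }
  total / n
}

# brute-force normalized adjacency: entrywise double loop
oracle_norm_adjacency <- function(A, M = NULL) {
  n <- nrow(A)
  if (is.null(M)) M <- matrix(1, n, n)
  Ap <- A + diag(n)
  deg <- rowSums(Ap)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- Ap[i, j] * M[i, j] / sqrt(deg[i] * deg[j])
  out
}

# tiny encoder configuration used across model/training tests
fixture_encoder_config <- function(emb = 8)
  encoder_config(channels = c(4, 6), temporal_kernel = 3, strides = c(1, 2),
                 embedding_dim = emb, hidden_dim = 8)
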