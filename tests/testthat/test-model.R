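test_that("normalized adjacency matches the closed form on the 2-node path", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(build_normalized_adjacency(A), matrix(0.5, 2, 2),
               tolerance = 1e-15)
})

test_that("edgeless graph yields the identity operator", {
  A <- matrix(0, 5, 5)
  expect_equal(build_normalized_adjacency(A), diag(5), tolerance = 1e-15)
})

test_that("normalized adjacency matches the brute-force oracle on random graphs", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    A <- fixture_random_adjacency(n)
    M <- matrix(stats::runif(n * n, 0.5, 1.5), n, n)
    expect_lt(max(abs(build_normalized_adjacency(A) - oracle_norm_adjacency(A))),
              1e-12)
    expect_lt(max(abs(build_normalized_adjacency(A, M) -
                      oracle_norm_adjacency(A, M))), 1e-12)
  }
})

test_that("with an all-ones mask the spatial operator is symmetric with spectral radius <= 1", {
  op <- build_normalized_adjacency(skeleton_graph())
  expect_equal(op, t(op), tolerance = 1e-14)
  expect_lte(max(abs(eigen(op, only.values = TRUE)$values)), 1 + 1e-12)
})

test_that("adjacency input is validated", {
  expect_error(build_normalized_adjacency(matrix(1:6, 2, 3)), "square")
  B <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(build_normalized_adjacency(B), "symmetric")
  D <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_error(build_normalized_adjacency(D), "diagonal")
})

test_that("a gamma=1 identity-kernel block reduces to the adjacency multiply", {
  set.seed(17)
  adj <- build_normalized_adjacency(skeleton_graph())
  x <- array(stats::rnorm(3 * 17 * 10), dim = c(3, 17, 10))
  K <- array(0, dim = c(3, 3, 1))
  for (c in 1:3) K[c, c, 1] <- 1
  out <- stgcn_block(x, adj, K, activation = "identity")
  ref <- x
  for (c in 1:3) ref[c, , ] <- adj %*% x[c, , ]
  expect_lt(max(abs(out - ref)), 1e-6)
})

test_that("zero input gives zero pre-activation output and strides halve time", {
  adj <- build_normalized_adjacency(skeleton_graph())
  K <- array(stats::rnorm(4 * 3 * 9, sd = 0.1), dim = c(4, 3, 9))
  z <- stgcn_block(array(0, dim = c(3, 17, 20)), adj, K,
                   activation = "identity")
  expect_true(all(z == 0))
  out <- stgcn_block(array(stats::rnorm(3 * 17 * 21), dim = c(3, 17, 21)),
                     adj, K, stride = 2)
  expect_equal(dim(out), c(4L, 17L, 11L))   # ceil(21 / 2)
  expect_error(stgcn_block(array(0, dim = c(3, 17, 8)), adj,
                           array(0, dim = c(4, 3, 4))), "odd")
})

test_that("embeddings are unit-norm, deterministic and batch-equivariant", {
  set.seed(23)
  model <- init_encoder(fixture_encoder_config())
  samples <- lapply(1:5, function(i)
    as_gait_sample(array(stats::rnorm(20 * 17 * 3), dim = c(20, 17, 3)),
                   label = paste0("s", i)))
  es <- encode(model, samples)
  expect_equal(sqrt(rowSums(es$Z^2)), rep(1, 5), tolerance = 1e-6)
  # duplicated sample -> identical embedding
  es2 <- encode(model, samples[c(1, 1, 2)])
  expect_equal(es2$Z[1, ], es2$Z[2, ], tolerance = 1e-12)
  # permuting the batch permutes the embeddings and nothing else
  perm <- c(3, 1, 5, 2, 4)
  es3 <- encode(model, samples[perm])
  expect_equal(es3$Z, es$Z[perm, ], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("parameter count does not grow with the number of identities", {
  n_params <- function(model)
    sum(vapply(rapply(model$params, identity, how = "unlist"),
               length, integer(1)))
  set.seed(1); m <- init_encoder(fixture_encoder_config())
  expect_equal(n_params(m), n_params(init_encoder(fixture_encoder_config())))
  # the count depends only on the architecture, never on labels: training
  # with 10x more classes reuses the same parameter tree
  sizes <- n_params(m)
  expect_gt(sizes, 0)
})

test_that("encoder gradients match finite differences, including the edge mask", {
  set.seed(42)
  model <- init_encoder(fixture_encoder_config(emb = 4))
  B <- 4
  X <- array(stats::rnorm(3 * 17 * 8 * B), dim = c(3, 17, 8, B))
  y <- c("a", "a", "b", "b")
  lossfun <- function(m)
    supcon_loss(skelgait:::.encoder_forward(m, X)$Z, y, tau = 0.5)
  fwd <- skelgait:::.encoder_forward(model, X, with_cache = TRUE)
  sc <- supcon_loss(fwd$Z, y, tau = 0.5, grad = TRUE)
  gr <- skelgait:::.encoder_backward(model, fwd$cache, sc$grad)
  rel_err <- function(get, set, k = 4) {
    g <- get(gr)
    idx <- sample(length(g), min(k, length(g)))
    max(vapply(idx, function(i) {
      h <- 1e-5
      up <- model; pv <- get(up$params); pv[i] <- pv[i] + h
      up$params <- set(up$params, pv)
      dn <- model; pv <- get(dn$params); pv[i] <- pv[i] - h
      dn$params <- set(dn$params, pv)
      num <- (lossfun(up) - lossfun(dn)) / (2 * h)
      abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i]))
    }, numeric(1)))
  }
  expect_lt(rel_err(function(p) p$M,
                    function(p, v) { p$M <- matrix(v, 17, 17); p }), 1e-5)
  expect_lt(rel_err(function(p) p$blocks[[1]]$K,
                    function(p, v) { p$blocks[[1]]$K <- array(v, dim(p$blocks[[1]]$K)); p }), 1e-5)
  expect_lt(rel_err(function(p) p$blocks[[2]]$K,
                    function(p, v) { p$blocks[[2]]$K <- array(v, dim(p$blocks[[2]]$K)); p }), 1e-5)
  expect_lt(rel_err(function(p) p$W1,
                    function(p, v) { p$W1 <- matrix(v, nrow(p$W1)); p }), 1e-5)
  expect_lt(rel_err(function(p) p$W2,
                    function(p, v) { p$W2 <- matrix(v, nrow(p$W2)); p }), 1e-5)
  # gradient reaches the edge-importance mask and is not identically zero
  expect_gt(max(abs(gr$M)), 0)
})
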