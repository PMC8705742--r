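make_es <- function(Z, labels, angles = NULL) {
  embedding_set(Z, data.frame(label = labels,
                              angle = angles %||% rep(NA_character_,
                                                      length(labels)),
                              stringsAsFactors = FALSE))
}

test_that("rank-1 accuracy behaves at the extremes", {
  set.seed(41)
  Z <- fixture_unit_embeddings(6, 8)
  y <- c("a", "b", "c", "a", "b", "c")
  es <- make_es(Z, y)
  expect_equal(rank1_accuracy(es, es), 1.0)
  g <- make_es(fixture_unit_embeddings(3, 8), rep("g", 3))
  p <- make_es(fixture_unit_embeddings(4, 8), rep("p", 4))
  expect_equal(rank1_accuracy(g, p), 0.0)
})

test_that("rank-1 accuracy equals the brute-force nearest-neighbor loop", {
  set.seed(43)
  G <- fixture_unit_embeddings(30, 16)
  P <- fixture_unit_embeddings(50, 16)
  gy <- sample(letters[1:8], 30, replace = TRUE)
  py <- sample(letters[1:8], 50, replace = TRUE)
  fast <- rank1_accuracy(make_es(G, gy), make_es(P, py))
  hits <- 0
  for (i in 1:50) {
    best <- -Inf; best_j <- 0
    for (j in 1:30) {
      s <- sum(P[i, ] * G[j, ])
      if (s > best) { best <- s; best_j <- j }   # strict: ties keep lowest j
    }
    hits <- hits + (gy[best_j] == py[i])
  }
  expect_equal(fast, hits / 50)
})

test_that("rank-1 is invariant under a common rotation of all embeddings", {
  set.seed(47)
  G <- fixture_unit_embeddings(20, 8)
  P <- fixture_unit_embeddings(25, 8)
  gy <- sample(letters[1:5], 20, replace = TRUE)
  py <- sample(letters[1:5], 25, replace = TRUE)
  base <- rank1_accuracy(make_es(G, gy), make_es(P, py))
  Q <- qr.Q(qr(matrix(stats::rnorm(64), 8, 8)))      # random orthogonal map
  expect_equal(rank1_accuracy(make_es(G %*% Q, gy), make_es(P %*% Q, py)),
               base)
})

test_that("cross-view protocol excludes the probe angle from the gallery", {
  # orthogonal identity clusters across angles: every angle retrieves
  # perfectly from the other angle
  Z <- rbind(diag(4), diag(4))
  y <- rep(c("a", "b", "c", "d"), 2)
  ang <- rep(c("0", "45"), each = 4)
  cv <- cross_view_protocol(make_es(Z, y, ang))
  expect_equal(unname(cv$per_angle), c(1, 1))
  expect_equal(cv$mean, 1)
})

test_that("a handcrafted 4-sample two-angle instance matches hand enumeration", {
  # angle 0: a1 = e1, b1 = e2 ; angle 90: a2 = close to e1, b2 = e3
  Z <- rbind(c(1, 0, 0),
             c(0, 1, 0),
             c(0.9, sqrt(1 - 0.81), 0),
             c(0, 0, 1))
  y <- c("a", "b", "a", "b")
  ang <- c("0", "0", "90", "90")
  cv <- cross_view_protocol(make_es(Z, y, ang))
  # probe angle 0: a1 -> nearest of {a2, b2} is a2 (0.9 > 0): hit;
  #                b1 -> a2 (0.436 > 0): miss  => 0.5
  # probe angle 90: a2 -> a1 (0.9): hit; b2 -> nearest sim 0 =>
  #                ties broken to lowest gallery index (a1): miss => 0.5
  expect_equal(unname(cv$per_angle), c(0.5, 0.5))
})

test_that("label-shuffled embeddings score at chance level", {
  set.seed(53)
  k <- 5
  accs <- replicate(40, {
    Z <- fixture_unit_embeddings(60, 8)
    y <- sample(rep(letters[1:k], 12))
    ang <- rep(c("0", "45"), 30)
    cross_view_protocol(make_es(Z, y, ang))$mean
  })
  p <- 1 / k
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - p), 3 * se + 0.005)
})

test_that("protocol and transfer harness never mix gallery and probe or leak splits", {
  set.seed(59)
  m <- init_encoder(fixture_encoder_config())
  ds <- local({
    tl <- list()
    for (i in 1:4) {
      id <- sample_identity()
      for (a in c(0, 45)) {
        t <- synthesize_tracklet(id, scene_params(angle = a), 60,
                                 sprintf("e%d_a%d", i, a))
        t$meta$identity <- sprintf("e%d", i)
        t$meta$run <- "1"
        tl <- c(tl, list(normalize_tracklet(t)))
      }
    }
    tracklet_dataset(tl)
  })
  expect_error(direct_transfer_eval(m, ds, eval_identities = c("e1", "e2"),
                                    train_identities = c("e2", "e3")),
               "leakage")
  out <- direct_transfer_eval(m, ds, paste0("e", 1:4), character(0),
                              n_repeats = 3, seed = 5)
  expect_length(out$per_repeat, 3L)
  expect_true(is.finite(out$sd))
  expect_true(all(out$per_repeat >= 0 & out$per_repeat <= 1))
})

test_that("embedding plot writes one file per call with a fixed layout", {
  set.seed(61)
  es <- make_es(fixture_unit_embeddings(12, 6),
                rep(c("a", "b", "c"), 4), rep(c("0", "45"), 6))
  tmp <- withr::local_tempfile(fileext = ".png")
  embedding_plot(es, "identity", tmp)
  expect_true(file.exists(tmp))
  expect_gt(file.size(tmp), 0)
})
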