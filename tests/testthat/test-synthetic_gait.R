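test_that("identity sampling is seeded and matches its population moments", {
  set.seed(71); a <- sample_identity()
  set.seed(71); b <- sample_identity()
  expect_identical(a, b)
  set.seed(72)
  cad <- replicate(1000, sample_identity()$cadence)
  expect_lt(abs(mean(cad) - 0.9), 3 * 0.1 / sqrt(1000) + 0.01)
  expect_true(all(cad > 0.5))
  # zero-variance population collapses to identical walkers
  set.seed(73)
  c1 <- sample_identity(cadence_sd = 0, amplitude_sd = 0,
                        proportion_jitter = 0)
  set.seed(74)
  c2 <- sample_identity(cadence_sd = 0, amplitude_sd = 0,
                        proportion_jitter = 0)
  expect_equal(c1$cadence, c2$cadence)
  expect_equal(c1$stride_amplitude, c2$stride_amplitude)
  expect_equal(c1$bone_scale, c2$bone_scale)
})

test_that("generated tracklets satisfy the frame/tracklet invariants", {
  set.seed(75)
  for (mode in c("walking", "standing", "low-confidence")) {
    t <- synthesize_tracklet(sample_identity(), scene_params(mode = mode),
                             80, paste0("m_", mode))
    expect_s3_class(t, "tracklet")
    expect_equal(dim(t$joints), c(80L, 17L, 3L))
    expect_true(all(is.finite(t$joints[, , 1:2])))
    expect_true(all(t$joints[, , 3] >= 0 & t$joints[, , 3] <= 1))
  }
  expect_error(synthesize_tracklet(sample_identity(), scene_params(), 1),
               ">= 2")
})

test_that("noiseless standing tracklets have exactly zero leg velocity", {
  set.seed(76)
  t <- synthesize_tracklet(sample_identity(),
                           scene_params(mode = "standing", sigma = 0), 100)
  nt <- normalize_tracklet(t)
  expect_equal(mean_leg_velocity(nt), 0)
  expect_false(velocity_filter(nt))
})

test_that("clean walkers pass every default filter; contaminants fail theirs", {
  set.seed(77)
  walk <- synthesize_tracklet(sample_identity(), scene_params(), 120, "w")
  nw <- normalize_tracklet(walk)
  expect_true(length_filters(nw))
  expect_true(mean_confidence_filter(nw))
  expect_true(feet_visibility_filter(nw))
  expect_gt(mean_leg_velocity(nw), 0.01)
  low <- synthesize_tracklet(sample_identity(),
                             scene_params(mode = "low-confidence"), 120, "l")
  expect_false(feet_visibility_filter(normalize_tracklet(low)))
  stand <- synthesize_tracklet(sample_identity(),
                               scene_params(mode = "standing"), 120, "s")
  expect_false(velocity_filter(normalize_tracklet(stand)))
})

test_that("benchmark layout, contamination counts and seeding are exact", {
  set.seed(78)
  b <- make_benchmark(n_ids = 10, runs_per_id = 4, angles = c(0, 90),
                      contamination = c(standing = 0.25))
  expect_length(b$dataset, 40L)
  expect_equal(sum(b$truth$mode == "standing"), 10L)
  expect_equal(sum(b$truth$expected_fail == "velocity", na.rm = TRUE), 10L)
  expect_setequal(unique(b$truth$angle), c(0, 90))
  set.seed(78)
  b2 <- make_benchmark(n_ids = 10, runs_per_id = 4, angles = c(0, 90),
                       contamination = c(standing = 0.25))
  expect_identical(b$truth, b2$truth)
  expect_identical(b$dataset$tracklets[[5]]$joints,
                   b2$dataset$tracklets[[5]]$joints)
})

test_that("filter verdicts agree exactly with the contamination ground truth", {
  set.seed(79)
  b <- make_benchmark(n_ids = 12, runs_per_id = 4, angles = c(0, 45),
                      contamination = c(standing = 0.2, low_confidence = 0.1))
  res <- apply_filters(normalize_dataset(b$dataset))
  v <- res$report$verdicts
  truth <- b$truth[match(v$track_id, b$truth$track_id), ]
  expect_equal(v$pass, is.na(truth$expected_fail))
  expect_equal(v$failed_filter[!v$pass], truth$expected_fail[!v$pass])
})

test_that("within-identity gait signatures are closer than between-identity ones", {
  set.seed(80)
  n_ids <- 8
  sigs <- list(); who <- character(0)
  for (i in seq_len(n_ids)) {
    id <- sample_identity()
    for (r in 1:2) {
      t <- synthesize_tracklet(id, scene_params(), 120,
                               sprintf("sig%d_%d", i, r))
      sigs <- c(sigs, list(gait_signature(normalize_tracklet(t))))
      who <- c(who, sprintf("sig%d", i))
    }
  }
  n <- length(sigs)
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- signature_distance(sigs[[i]], sigs[[j]])
  same <- outer(who, who, "==")
  within <- tapply(D[same & upper.tri(D)],
                   who[row(D)[same & upper.tri(D)]], mean)
  ok <- 0; tot <- 0
  for (a in 1:(n_ids - 1)) for (b in (a + 1):n_ids) {
    ia <- which(who == sprintf("sig%d", a))
    ib <- which(who == sprintf("sig%d", b))
    between <- mean(D[ia, ib])
    w <- mean(c(within[sprintf("sig%d", a)], within[sprintf("sig%d", b)]))
    ok <- ok + (w < between); tot <- tot + 1
  }
  expect_gte(ok / tot, 0.95)
})
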