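test_that("jsonl keypoint records are grouped into ordered tracklets", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  rec <- function(tid, frame, kp) {
    jsonlite::toJSON(list(track_id = tid, frame = frame, keypoints = kp),
                     auto_unbox = TRUE, digits = NA)
  }
  set.seed(1)
  kp_a <- lapply(1:60, function(i) as.numeric(rbind(runif(17, 0, 100),
                                                    runif(17, 0, 100),
                                                    runif(17))))
  kp_b <- lapply(1:54, function(i) as.numeric(rbind(runif(17, 0, 100),
                                                    runif(17, 0, 100),
                                                    runif(17))))
  lines <- c(vapply(1:60, function(i) rec("a", i - 1L, kp_a[[i]]), character(1)),
             vapply(1:54, function(i) rec("b", i - 1L, kp_b[[i]]), character(1)))
  writeLines(sample(lines), tmp)    # shuffled on disk; reader must sort
  ds <- read_keypoint_tracklets(tmp, "jsonl")
  expect_length(ds, 2L)
  expect_equal(n_frames(ds$tracklets[["a"]]), 60L)
  expect_equal(n_frames(ds$tracklets[["b"]]), 54L)
  expect_equal(as.numeric(t(matrix(kp_a[[3]], 3, 17))),
               as.numeric(ds$tracklets[["a"]]$joints[3, , ]))
})

test_that("reader rejects malformed, short-joint and gapped records", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines("not json at all {", tmp)
  expect_error(read_keypoint_tracklets(tmp), "parse error")

  kp16 <- as.numeric(rbind(runif(16), runif(16), runif(16)))
  writeLines(as.character(jsonlite::toJSON(
    list(track_id = "a", frame = 0, keypoints = kp16), auto_unbox = TRUE)), tmp)
  expect_error(read_keypoint_tracklets(tmp), "schema error")

  kp <- as.numeric(rbind(runif(17), runif(17), runif(17)))
  writeLines(vapply(c(0, 1, 3), function(f) as.character(jsonlite::toJSON(
    list(track_id = "a", frame = f, keypoints = kp), auto_unbox = TRUE,
    digits = NA)), character(1)), tmp)
  expect_error(read_keypoint_tracklets(tmp), "integrity error")
})

test_that("empty input yields an empty dataset with a warning", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), tmp)
  expect_warning(ds <- read_keypoint_tracklets(tmp), "no records")
  expect_length(ds, 0L)
})

test_that("coco-json dialect parses the annotations array", {
  tmp <- withr::local_tempfile(fileext = ".json")
  kp <- as.numeric(rbind(1:17, 101:117, rep(0.5, 17)))
  doc <- list(annotations = lapply(0:2, function(f)
    list(track_id = "tr", image_id = f, keypoints = kp)))
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           digits = NA)), tmp)
  ds <- read_keypoint_tracklets(tmp, "coco-json")
  expect_length(ds, 1L)
  expect_equal(n_frames(ds$tracklets[[1]]), 3L)
  expect_equal(unname(ds$tracklets[[1]]$joints[1, , 1]), as.numeric(1:17))
})

test_that("archive round-trip is bit-exact for coordinates and metadata", {
  set.seed(42)
  mk <- function(id, n) {
    joints <- array(stats::rnorm(n * 17 * 3), dim = c(n, 17, 3))
    joints[, , 3] <- stats::runif(n * 17)
    tracklet(id, joints, fps = 24,
             meta = list(camera = "café-02", continent = "Europe"))
  }
  ds <- tracklet_dataset(list(mk("u1", 7), mk("u2", 11)),
                         provenance = list(note = "résumé"))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_tracklets(ds, tmp)
  back <- read_tracklet_archive(tmp)
  expect_identical(back$tracklets[["u1"]]$joints, ds$tracklets[["u1"]]$joints)
  expect_identical(back$tracklets[["u2"]]$joints, ds$tracklets[["u2"]]$joints)
  expect_identical(back$tracklets[["u1"]]$meta, ds$tracklets[["u1"]]$meta)
  expect_identical(back$provenance$note, "résumé")
  expect_true(file.exists(sub("\\.json$", "_meta.csv", tmp)))
  # empty dataset round-trips too
  tmp2 <- withr::local_tempfile(fileext = ".json")
  write_tracklets(tracklet_dataset(), tmp2)
  expect_length(read_tracklet_archive(tmp2), 0L)
})

test_that("duplicate track ids are rejected at construction", {
  expect_error(tracklet_dataset(list(fixture_tracklet(10, "x"),
                                     fixture_tracklet(12, "x"))),
               "distinct")
})

test_that("resampling doubles length at doubled fps and matches the interpolation oracle", {
  set.seed(3)
  n <- 50
  joints <- array(stats::rnorm(n * 17 * 3), dim = c(n, 17, 3))
  joints[, , 3] <- stats::runif(n * 17)
  t12 <- tracklet("r", joints, fps = 12)
  t24 <- resample_tracklet(t12, 24)
  expect_equal(n_frames(t24), round(50 * 24 / 12))
  expect_equal(t24$fps, 24)
  # even output frames sit exactly on the original sample instants
  expect_equal(t24$joints[seq(1, 99, by = 2), , 1:2], t12$joints[, , 1:2])
  # odd frames are midpoints of neighbors (pure linear interpolation)
  mid <- (t12$joints[-n, 5, 1] + t12$joints[-1, 5, 1]) / 2
  expect_equal(unname(t24$joints[seq(2, 98, by = 2), 5, 1]), unname(mid))
  # confidences stay clamped to [0, 1]
  expect_true(all(t24$joints[, , 3] >= 0 & t24$joints[, , 3] <= 1))
})

test_that("resampling is identity at the same fps and exact at original knots after up-down", {
  t <- fixture_walking_tracklet(54)
  expect_identical(resample_tracklet(t, t$fps), t)
  up <- resample_tracklet(t, 2 * t$fps)
  down <- resample_tracklet(up, t$fps)
  expect_equal(n_frames(down), n_frames(t))
  expect_lt(max(abs(down$joints[, , 1:2] - t$joints[, , 1:2])), 1e-9)
})
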