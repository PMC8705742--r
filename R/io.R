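#' Read tracked keypoint detections into a tracklet dataset
#'
#' Parses per-detection COCO-17 keypoint records, groups them by track id
#' and orders them by frame index. Two dialects are supported:
#' \describe{
#'   \item{`jsonl`}{one JSON object per line with fields `track_id`,
#'     `frame` (or `frame_id` / `image_id`), `keypoints` (51 numbers,
#'     x/y/confidence interleaved) and optionally `fps` and `meta`.}
#'   \item{`coco-json`}{a single JSON document whose `annotations` array
#'     holds the same records (the usual COCO keypoint layout with a
#'     track-id field added per detection).}
#' }
#' Tracking is contiguous by construction, so a gap in the frame indices
#' within one track is treated as a corrupt file.
#'
#' @param path Path to the file.
#' @param dialect `"jsonl"` or `"coco-json"`.
#' @param default_fps Sampling rate assumed when a record carries none.
#' @return A `tracklet_dataset`.
#' @export
read_keypoint_tracklets <- function(path, dialect = c("jsonl", "coco-json"),
                                    default_fps = 24) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  records <- if (dialect == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e)
                        stop(sprintf("parse error in record %d: %s",
                                     i, conditionMessage(e)), call. = FALSE))
      rec$.record <- i
      rec
    })
  } else {
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e)
                      stop("parse error: ", conditionMessage(e), call. = FALSE))
    anns <- doc$annotations
    if (is.null(anns)) stop("parse error: no 'annotations' array in ", path)
    lapply(seq_along(anns), function(i) { r <- anns[[i]]; r$.record <- i; r })
  }
  if (!length(records)) {
    warning("no records in ", path, "; returning an empty dataset")
    return(tracklet_dataset())
  }
  parsed <- lapply(records, .parse_detection)
  ids <- vapply(parsed, function(r) r$track_id, character(1))
  tracklets <- lapply(split(parsed, ids), .assemble_track, default_fps)
  tracklet_dataset(unname(tracklets), provenance = list(source = path))
}

.parse_detection <- function(rec) {
  i <- rec$.record
  tid <- rec$track_id
  frame <- rec$frame
  if (is.null(frame)) frame <- rec$frame_id
  if (is.null(frame)) frame <- rec$image_id
  if (is.null(tid) || is.null(frame) || is.null(rec$keypoints))
    stop(sprintf(
      "parse error in record %d: needs track_id, frame index and keypoints", i),
      call. = FALSE)
  kp <- as.numeric(unlist(rec$keypoints))
  if (length(kp) != 51L)
    stop(sprintf(
      "schema error in record %d: expected 17 keypoint triples (51 values), got %d values",
      i, length(kp)), call. = FALSE)
  m <- matrix(kp, ncol = 3L, byrow = TRUE)
  list(track_id = as.character(tid), frame = as.integer(frame),
       xyc = m, fps = rec$fps, meta = rec$meta)
}

.assemble_track <- function(dets, default_fps) {
  ord <- order(vapply(dets, function(d) d$frame, integer(1)))
  dets <- dets[ord]
  frames <- vapply(dets, function(d) d$frame, integer(1))
  if (anyDuplicated(frames) || !all(diff(frames) == 1L))
    stop(sprintf(
      "integrity error: non-contiguous frame indices for track '%s' (frames %d..%d, %d detections)",
      dets[[1]]$track_id, min(frames), max(frames), length(frames)),
      call. = FALSE)
  joints <- aperm(simplify2array(lapply(dets, function(d) d$xyc)), c(3L, 1L, 2L))
  fps <- dets[[1]]$fps
  meta <- dets[[1]]$meta
  tracklet(dets[[1]]$track_id, joints,
           fps = if (is.null(fps)) default_fps else fps,
           meta = if (is.null(meta)) list() else as.list(meta))
}

#' Write a tracklet dataset to a single-file archive
#'
#' Serializes the dataset to one JSON archive holding every tracklet's
#' coordinates at full double precision, plus a sidecar CSV metadata table
#' (`<path basename>_meta.csv`) with one row per tracklet. The archive
#' round-trips bit-exactly through [read_tracklet_archive()].
#'
#' @param ds A `tracklet_dataset`.
#' @param path Output path for the JSON archive.
#' @return `path`, invisibly.
#' @export
write_tracklets <- function(ds, path) {
  stopifnot(inherits(ds, "tracklet_dataset"))
  payload <- list(
    format = "skelgait-tracklets-v1",
    provenance = ds$provenance,
    tracklets = lapply(unname(ds$tracklets), function(t) list(
      track_id = t$track_id,
      fps = t$fps,
      meta = t$meta,
      frames = matrix(aperm(t$joints, c(3L, 2L, 1L)), ncol = 51L,
                      byrow = TRUE)   # one row per frame: j1x j1y j1c j2x ...
    ))
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null")   # 17 sig. digits: exact doubles
  ok <- tryCatch({ writeLines(json, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write archive to ", path)
  meta_path <- paste0(tools::file_path_sans_ext(path), "_meta.csv")
  info <- data.frame(
    track_id = vapply(ds$tracklets, function(t) t$track_id, character(1)),
    n_frames = vapply(ds$tracklets, n_frames, integer(1)),
    fps = vapply(ds$tracklets, function(t) t$fps, numeric(1)),
    meta = vapply(ds$tracklets, function(t)
      as.character(jsonlite::toJSON(t$meta, auto_unbox = TRUE)), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  utils::write.csv(info, meta_path, row.names = FALSE)
  invisible(path)
}

#' Read a tracklet archive written by [write_tracklets()]
#'
#' @param path Path to the JSON archive.
#' @return A `tracklet_dataset` identical to the one written.
#' @export
read_tracklet_archive <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (!identical(doc$format, "skelgait-tracklets-v1"))
    stop("not a skelgait tracklet archive: ", path)
  tracklets <- lapply(doc$tracklets, function(rec) {
    fr <- rec$frames
    if (is.null(dim(fr))) fr <- matrix(fr, nrow = 1L)
    n <- nrow(fr)
    joints <- aperm(array(t(fr), dim = c(3L, 17L, n)), c(3L, 2L, 1L))
    tracklet(rec$track_id, joints, fps = rec$fps,
             meta = if (is.null(rec$meta)) list() else as.list(rec$meta))
  })
  prov <- doc$provenance
  tracklet_dataset(tracklets,
                   provenance = if (is.null(prov)) list() else as.list(prov))
}
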