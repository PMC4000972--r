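#' Convert an RGB frame to grayscale intensity
#'
#' Standard luma weighting: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param frame numeric array of dimension height x width x 3.
#' @return a height x width matrix of intensities.
#' @export
rgb_to_intensity <- function(frame) {
  if (!is.array(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("`frame` must be a height x width x 3 RGB array", call. = FALSE)
  if (!all(is.finite(frame)))
    stop("frame values must be finite", call. = FALSE)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# Bilinear resize of one frame to (out_h, out_w). EBImage stores the first
# array dimension as its x axis, so our rows map to its `w` argument.
resize_frame <- function(frame, out_h, out_w) {
  if (nrow(frame) == out_h && ncol(frame) == out_w) return(frame)
  out <- EBImage::imageData(
    EBImage::resize(EBImage::Image(frame), w = out_h, h = out_w,
                    filter = "bilinear")
  )
  matrix(out, out_h, out_w)
}

# Resize every frame of a 3D array; values re-clamped to [0,1] because
# bilinear interpolation at borders can minutely overshoot.
resize_volume_array <- function(arr, target_size) {
  d <- dim(arr)
  if (d[1] == target_size[1] && d[2] == target_size[2]) return(arr)
  out <- array(0, c(target_size[1], target_size[2], d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- resize_frame(arr[, , k], target_size[1], target_size[2])
  pmin(pmax(out, 0), 1)
}

#' Load a video clip as a grayscale intensity volume
#'
#' Ingests a clip stored as a directory of numbered frame images (PNG or
#' TIFF, read in lexicographic filename order). Color frames are converted
#' to grayscale with [rgb_to_intensity()], every frame is resized to
#' `target_size` with bilinear interpolation, and intensities are scaled to
#' `[0, 1]` (8-bit codes divide by 255, which the image reader performs).
#' Container formats such as AVI must be exploded to frames beforehand
#' (e.g. `ffmpeg -i clip.avi frames/%04d.png`); the working resolution of
#' the reference setup is 160 x 128 (width x height), i.e.
#' `target_size = c(128, 160)`.
#'
#' @param path directory containing the frame images of one clip.
#' @param target_size `c(height, width)` of the working resolution.
#'   Default `c(128, 160)`.
#' @param frame_rate frames per second to record on the volume.
#' @param patient_id,clip_id provenance identifiers; `clip_id` defaults to
#'   the directory name.
#' @return a [video_volume()].
#' @export
load_video <- function(path, target_size = c(128, 160), frame_rate = 25,
                       patient_id = "", clip_id = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("video input not found: '%s'", path), call. = FALSE)
  if (!dir.exists(path))
    stop(sprintf("'%s' is not a frame directory; decode containers to numbered PNG/TIFF frames first", path),
         call. = FALSE)
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- sort(files)
  if (length(files) == 0L)
    stop(sprintf("no frames found in '%s'", path), call. = FALSE)
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- EBImage::imageData(EBImage::readImage(files[i]))
    nd <- length(dim(img))
    if (nd == 3L) {
      if (dim(img)[3] >= 3L) img <- rgb_to_intensity(img[, , 1:3, drop = FALSE])
      else img <- img[, , 1]
    } else if (nd != 2L) {
      stop(sprintf("unsupported frame layout in '%s'", files[i]), call. = FALSE)
    }
    frames[[i]] <- resize_frame(img, target_size[1], target_size[2])
  }
  arr <- array(unlist(frames), c(target_size[1], target_size[2], length(frames)))
  arr <- pmin(pmax(arr, 0), 1)
  video_volume(arr, frame_rate = frame_rate, patient_id = patient_id,
               clip_id = clip_id)
}

#' Segment a recording into clips of bounded duration
#'
#' Splits a volume into consecutive, non-overlapping temporal chunks of at
#' most `max_duration_s` seconds each ("no longer than" is inclusive: an
#' exactly 60 s recording stays one clip). The final, possibly shorter,
#' remainder is kept. Concatenating the chunks in order reproduces the
#' input. Chunk clip ids are the parent id with a zero-padded index suffix.
#'
#' @param volume a [video_volume()].
#' @param max_duration_s maximum clip duration in seconds (default 60).
#' @return a list of `video_volume` objects.
#' @export
segment_clips <- function(volume, max_duration_s = 60) {
  stopifnot(inherits(volume, "video_volume"))
  if (!is.numeric(max_duration_s) || max_duration_s <= 0)
    stop("`max_duration_s` must be > 0", call. = FALSE)
  n_frames <- dim(volume$data)[3]
  chunk <- max(1L, floor(max_duration_s * volume$frame_rate))
  starts <- seq.int(1L, n_frames, by = chunk)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:min(starts[i] + chunk - 1L, n_frames)
    id <- if (length(starts) == 1L) volume$clip_id else
      sprintf("%s_%03d", volume$clip_id, i)
    out[[i]] <- video_volume(volume$data[, , idx, drop = FALSE],
                             frame_rate = volume$frame_rate,
                             patient_id = volume$patient_id, clip_id = id)
  }
  out
}

#' Crop a volume to a bounding box
#'
#' Applies one static box to every frame (annotations are per recording, not
#' per frame). The frame count is unchanged.
#'
#' @param volume a [video_volume()].
#' @param box a [bounding_box()].
#' @return the cropped `video_volume`.
#' @export
crop_bbox <- function(volume, box) {
  stopifnot(inherits(volume, "video_volume"), inherits(box, "bounding_box"))
  d <- dim(volume$data)
  if (box$top + box$height > d[1])
    stop(sprintf("bounding box bottom edge (%d) exceeds frame height (%d)",
                 box$top + box$height, d[1]), call. = FALSE)
  if (box$left + box$width > d[2])
    stop(sprintf("bounding box right edge (%d) exceeds frame width (%d)",
                 box$left + box$width, d[2]), call. = FALSE)
  rows <- (box$top + 1L):(box$top + box$height)
  cols <- (box$left + 1L):(box$left + box$width)
  video_volume(volume$data[rows, cols, , drop = FALSE],
               frame_rate = volume$frame_rate,
               patient_id = volume$patient_id, clip_id = volume$clip_id)
}

#' Read a clip annotation table
#'
#' CSV with header `clip,patient_id,label,top,left,height,width`; the four
#' box columns may be empty when no box was annotated. Labels must be
#' exactly `"normal"` or `"abnormal"` (mapped to +1 / -1 downstream).
#'
#' @param path path to the CSV file.
#' @return a data.frame with one row per clip.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clip", "patient_id", "label")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns clip, patient_id, label",
         call. = FALSE)
  bad <- setdiff(unique(ann$label), c("normal", "abnormal"))
  if (length(bad))
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  ann
}

#' Map categorical clip labels to numeric classes
#'
#' `"normal"` maps to +1 and `"abnormal"` to -1, the signs used by the
#' binary SVM throughout the package.
#'
#' @param labels character vector of `"normal"` / `"abnormal"`.
#' @return integer vector of +1 / -1.
#' @export
label_to_class <- function(labels) {
  bad <- setdiff(unique(labels), c("normal", "abnormal"))
  if (length(bad))
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  ifelse(labels == "normal", 1L, -1L)
}
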