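#' Grayscale video volume
#'
#' The basic data container of the pipeline: a 3D array of grayscale
#' intensities in `[0, 1]` with dimensions height x width x frames, together
#' with the frame rate and provenance identifiers. All downstream stages
#' (Gabor filtering, gist pooling) operate on this container or on the bare
#' array it wraps.
#'
#' @param data numeric 3D array, height x width x n_frames, values in
#'   `[0, 1]`. A matrix is promoted to a single-frame volume.
#' @param frame_rate frames per second; must be positive. Default 25, the
#'   rate of standard PAL clinical ward recordings.
#' @param patient_id,clip_id opaque identifier strings used by the
#'   per-patient evaluation protocol.
#' @return an object of class `video_volume`.
#' @examples
#' v <- video_volume(array(0.5, c(8, 10, 4)), frame_rate = 25,
#'                   patient_id = "p1", clip_id = "c1")
#' dim(v$data)
#' @export
video_volume <- function(data, frame_rate = 25, patient_id = "", clip_id = "") {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (height x width x frames)", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("all three dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(data)))
    stop("intensities must be finite", call. = FALSE)
  if (min(data) < 0 || max(data) > 1)
    stop("intensities must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("`frame_rate` must be a positive scalar", call. = FALSE)
  structure(
    list(data = data, frame_rate = frame_rate,
         patient_id = as.character(patient_id),
         clip_id = as.character(clip_id)),
    class = "video_volume"
  )
}

#' @export
print.video_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<video_volume> %d x %d px, %d frames @ %g fps (%.1f s)\n",
              d[1], d[2], d[3], x$frame_rate, d[3] / x$frame_rate))
  if (nzchar(x$patient_id) || nzchar(x$clip_id))
    cat(sprintf("  patient: %s  clip: %s\n", x$patient_id, x$clip_id))
  invisible(x)
}

#' @export
dim.video_volume <- function(x) dim(x$data)

# Accept either a video_volume or a bare 3D array; return the array.
as_volume_array <- function(volume) {
  if (inherits(volume, "video_volume")) return(volume$data)
  if (is.array(volume) && length(dim(volume)) == 3L) return(volume)
  stop("expected a `video_volume` or a 3D array", call. = FALSE)
}

#' Static bounding box annotation
#'
#' A rectangular region locating the patient in the frame, 0-based with
#' top-left origin and half-open extents: the box covers rows
#' `top .. top + height - 1` and columns `left .. left + width - 1`.
#'
#' @param top,left 0-based offsets of the box corner, in pixels.
#' @param height,width box extents in pixels, both >= 1.
#' @return an object of class `bounding_box`.
#' @export
bounding_box <- function(top, left, height, width) {
  vals <- c(top = top, left = left, height = height, width = width)
  if (any(!is.finite(vals)) || any(vals != round(vals)))
    stop("bounding box fields must be finite integers", call. = FALSE)
  if (top < 0 || left < 0)
    stop("`top` and `left` must be >= 0", call. = FALSE)
  if (height < 1 || width < 1)
    stop("`height` and `width` must be >= 1", call. = FALSE)
  structure(as.list(vals), class = "bounding_box")
}
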