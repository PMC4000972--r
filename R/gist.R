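#' Average-pool a response volume over a coarse grid
#'
#' Divides the response grid into `grid[1] x grid[2] x grid[3]` spatiotemporal
#' subregions (default 4 x 4 x 4) and replaces each by the arithmetic mean of
#' its voxels. When a dimension `d` is not divisible by the grid size `g`,
#' bin edges fall at `floor(i * d / g)`, `i = 0..g`: the blocks are
#' near-equal, non-overlapping, and cover every voxel exactly once.
#'
#' The output is ordered with the row-block index slowest, then the
#' column-block, then the time-block fastest.
#'
#' @param response a numeric 3D array of filter responses.
#' @param grid integer block counts per axis, default `c(4, 4, 4)`.
#' @return a numeric vector of length `prod(grid)` (64 by default).
#' @export
pool_grid <- function(response, grid = c(4L, 4L, 4L)) {
  if (!is.array(response) || length(dim(response)) != 3L)
    stop("`response` must be a 3D array", call. = FALSE)
  grid <- as.integer(grid)
  d <- dim(response)
  if (any(d < grid))
    stop(sprintf("response dimensions (%s) must each be >= the grid (%s)",
                 paste(d, collapse = "x"), paste(grid, collapse = "x")),
         call. = FALSE)
  edges <- lapply(1:3, function(k) floor(seq.int(0L, grid[k]) * d[k] / grid[k]))
  out <- numeric(prod(grid))
  pos <- 1L
  for (ri in seq_len(grid[1])) {
    rows <- (edges[[1]][ri] + 1L):edges[[1]][ri + 1L]
    for (ci in seq_len(grid[2])) {
      cols <- (edges[[2]][ci] + 1L):edges[[2]][ci + 1L]
      for (ti in seq_len(grid[3])) {
        times <- (edges[[3]][ti] + 1L):edges[[3]][ti + 1L]
        out[pos] <- mean(response[rows, cols, times])
        pos <- pos + 1L
      }
    }
  }
  out
}

#' Extract the spatiotemporal gist descriptor of a clip
#'
#' Filters the volume with every kernel of the bank ([filter_bank()]) and
#' average-pools each response over the coarse grid ([pool_grid()]),
#' concatenating in bank order (kernel-major layout). With the default
#' four-kernel bank and 4 x 4 x 4 grid the descriptor has
#' `4 * 64 = 256` entries. Because the kernels are zero-mean, the
#' descriptor is invariant to constant illumination offsets, and the coarse
#' pooling makes it tolerant to small spatial and temporal shifts.
#'
#' @param volume a [video_volume()] or bare 3D array.
#' @param bank a `gabor_bank`; default [build_default_bank()].
#' @param grid pooling block counts per axis, default `c(4, 4, 4)`.
#' @return a named numeric vector of length `length(bank) * prod(grid)`;
#'   names are `f000, f001, ...` in layout order.
#' @examples
#' \donttest{
#' clip <- generate_normal_clip(synth_config(frame_size = c(32, 40),
#'                                           n_frames = 24), seed = 1)
#' length(extract_gist(clip))  # 256
#' }
#' @export
extract_gist <- function(volume, bank = build_default_bank(),
                         grid = c(4L, 4L, 4L)) {
  responses <- filter_bank(volume, bank)
  feat <- unlist(lapply(responses, pool_grid, grid = grid), use.names = FALSE)
  names(feat) <- sprintf("f%03d", seq_along(feat) - 1L)
  feat
}

#' Compute the gist feature table of a clip collection
#'
#' @param clips a list of [video_volume()] objects.
#' @param labels character vector of `"normal"` / `"abnormal"` labels, one
#'   per clip (optional; `NA` if omitted).
#' @param bank,grid passed to [extract_gist()].
#' @return a data.frame with columns `clip_id`, `patient_id`, `label`, and
#'   one `fNNN` column per descriptor entry.
#' @export
compute_features <- function(clips, labels = NULL,
                             bank = build_default_bank(),
                             grid = c(4L, 4L, 4L)) {
  stopifnot(is.list(clips), length(clips) >= 1L)
  if (is.null(labels)) labels <- rep(NA_character_, length(clips))
  stopifnot(length(labels) == length(clips))
  feats <- lapply(clips, extract_gist, bank = bank, grid = grid)
  mat <- do.call(rbind, feats)
  out <- data.frame(
    clip_id = vapply(clips, function(v) v$clip_id, character(1)),
    patient_id = vapply(clips, function(v) v$patient_id, character(1)),
    label = labels,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(mat))
}

#' Write / read a gist feature table
#'
#' Plain CSV with the layout produced by [compute_features()]:
#' `clip_id,patient_id,label,f000..fNNN`. The kernel-major feature layout is
#' fixed by the bank order and travels with the file.
#'
#' @param features a [compute_features()] data.frame.
#' @param path CSV file path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the data.frame.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  feats <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("clip_id", "patient_id", "label") %in% names(feats)))
    stop("feature table must have clip_id, patient_id, label columns",
         call. = FALSE)
  feats
}

# Split a feature data.frame into the numeric matrix and metadata columns.
feature_matrix <- function(features) {
  fcols <- grep("^f[0-9]+$", names(features), value = TRUE)
  if (length(fcols) == 0L)
    stop("no feature columns (fNNN) found", call. = FALSE)
  as.matrix(features[, fcols, drop = FALSE])
}
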