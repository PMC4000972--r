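#' Parameters of a 3D spatiotemporal Gabor filter
#'
#' A 3D Gabor filter is a Gaussian envelope multiplied by two cosine
#' carriers, defined over two spatial axes and one temporal axis:
#' \deqn{G(x,y,t) = \exp\!\big(-(X^2/2\sigma_x^2 + Y^2/2\sigma_y^2 +
#'   T^2/2\sigma_t^2)\big)\cos(2\pi X/\lambda_x)\cos(2\pi Y/\lambda_y),}
#' where \eqn{(X,Y,T)} are the input coordinates rotated by the spatial
#' orientation \eqn{\theta} and the temporal orientation \eqn{\omega}
#' (see [rotate_coords()]). Axis convention: `x` runs along frame rows
#' (vertical), `y` along frame columns (horizontal), `t` along frames.
#'
#' The Gaussian denominators are `2*sigma^2` by default (the standard
#' parameterisation, sigma in pixels/frames). Set `sigma_is_variance = TRUE`
#' to use literal `2*sigma` denominators, i.e. to treat the sigma values as
#' variances.
#'
#' @param sigma_x,sigma_y envelope scales along the spatial axes, pixels.
#' @param sigma_t envelope scale along time, frames.
#' @param lambda_x,lambda_y carrier wavelengths, pixels.
#' @param theta spatial orientation, radians.
#' @param omega temporal orientation, radians.
#' @param support integer half-extents `c(hx, hy, ht)` of the sampled tap
#'   grid; the kernel has `2h + 1` taps per axis. Defaults cover roughly
#'   two envelope standard deviations.
#' @param sigma_is_variance if `TRUE`, the sigma parameters are treated as
#'   variances (denominator `2*sigma` instead of `2*sigma^2`).
#' @return an object of class `gabor_params`.
#' @export
gabor_params <- function(sigma_x = 4, sigma_y = 4, sigma_t = 2,
                         lambda_x = 8, lambda_y = 8,
                         theta = 0, omega = 0,
                         support = c(9L, 9L, 5L),
                         sigma_is_variance = FALSE) {
  if (any(c(sigma_x, sigma_y, sigma_t) <= 0))
    stop("all sigma values must be > 0", call. = FALSE)
  if (any(c(lambda_x, lambda_y) <= 0))
    stop("all lambda values must be > 0", call. = FALSE)
  support <- as.integer(round(support))
  if (length(support) != 3L || any(support < 1L))
    stop("`support` must be three half-extents >= 1", call. = FALSE)
  structure(
    list(sigma_x = sigma_x, sigma_y = sigma_y, sigma_t = sigma_t,
         lambda_x = lambda_x, lambda_y = lambda_y,
         theta = theta, omega = omega, support = support,
         sigma_is_variance = isTRUE(sigma_is_variance)),
    class = "gabor_params"
  )
}

#' Rotate spatiotemporal coordinates
#'
#' Applies the spatial rotation (by `theta`, in the y–t plane block of the
#' first matrix) followed by the temporal rotation (by `omega`, in the x–t
#' plane), i.e. \eqn{(X,Y,T)^T = R_\theta R_\omega (x,y,t)^T} with
#' \deqn{R_\theta = \begin{pmatrix}1&0&0\\0&\cos\theta&-\sin\theta\\
#'   0&\sin\theta&\cos\theta\end{pmatrix},\quad
#'   R_\omega = \begin{pmatrix}\cos\omega&0&\sin\omega\\0&1&0\\
#'   -\sin\omega&0&\cos\omega\end{pmatrix}.}
#' Inputs may be vectors (recycled elementwise).
#'
#' @param x,y,t coordinates.
#' @param theta,omega orientations in radians.
#' @return a list with components `X`, `Y`, `T`.
#' @export
rotate_coords <- function(x, y, t, theta, omega) {
  R <- rotation_matrix(theta, omega)
  list(X = R[1, 1] * x + R[1, 2] * y + R[1, 3] * t,
       Y = R[2, 1] * x + R[2, 2] * y + R[2, 3] * t,
       T = R[3, 1] * x + R[3, 2] * y + R[3, 3] * t)
}

rotation_matrix <- function(theta, omega) {
  Rt <- rbind(c(1, 0, 0),
              c(0, cos(theta), -sin(theta)),
              c(0, sin(theta),  cos(theta)))
  Rw <- rbind(c(cos(omega), 0, sin(omega)),
              c(0, 1, 0),
              c(-sin(omega), 0, cos(omega)))
  Rt %*% Rw
}

#' Evaluate the 3D Gabor function at a point
#'
#' @param params a [gabor_params()].
#' @param x,y,t coordinates (vectors allowed, recycled elementwise).
#' @return the filter value(s).
#' @export
gabor_value <- function(params, x, y, t) {
  stopifnot(inherits(params, "gabor_params"))
  rc <- rotate_coords(x, y, t, params$theta, params$omega)
  if (params$sigma_is_variance) {
    dx <- 2 * params$sigma_x; dy <- 2 * params$sigma_y; dt <- 2 * params$sigma_t
  } else {
    dx <- 2 * params$sigma_x^2; dy <- 2 * params$sigma_y^2
    dt <- 2 * params$sigma_t^2
  }
  exp(-(rc$X^2 / dx + rc$Y^2 / dy + rc$T^2 / dt)) *
    cos(2 * pi * rc$X / params$lambda_x) *
    cos(2 * pi * rc$Y / params$lambda_y)
}

#' Sample a Gabor kernel on its tap grid
#'
#' Evaluates [gabor_value()] on the integer grid
#' `[-hx..hx] x [-hy..hy] x [-ht..ht]` and, when `normalize = TRUE`
#' (default), subtracts the tap mean and scales to unit L2 norm. Zero-mean
#' taps give exactly zero response to constant volumes, which is what makes
#' the features robust to global illumination changes; unit norm makes
#' response magnitudes comparable across orientations.
#'
#' @param params a [gabor_params()].
#' @param normalize subtract the mean and L2-normalize the taps.
#' @return an object of class `gabor_kernel` with fields `taps` (3D array
#'   of odd extents), `params`, `normalized`.
#' @export
build_kernel <- function(params, normalize = TRUE) {
  stopifnot(inherits(params, "gabor_params"))
  h <- params$support
  gx <- seq.int(-h[1], h[1]); gy <- seq.int(-h[2], h[2])
  gt <- seq.int(-h[3], h[3])
  grid <- expand.grid(x = gx, y = gy, t = gt)
  taps <- array(gabor_value(params, grid$x, grid$y, grid$t),
                c(length(gx), length(gy), length(gt)))
  if (normalize) {
    taps <- taps - mean(taps)
    nrm <- sqrt(sum(taps^2))
    if (nrm < 1e-12)
      stop("degenerate kernel: taps vanish after mean subtraction; enlarge the support or change the carrier wavelength",
           call. = FALSE)
    taps <- taps / nrm
  }
  structure(list(taps = taps, params = params, normalized = normalize),
            class = "gabor_kernel")
}

#' @export
print.gabor_kernel <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<gabor_kernel> %s taps, theta=%.3f omega=%.3f sigma=(%g,%g,%g) lambda=(%g,%g)%s\n",
    paste(dim(x$taps), collapse = "x"), p$theta, p$omega,
    p$sigma_x, p$sigma_y, p$sigma_t, p$lambda_x, p$lambda_y,
    if (x$normalized) " [zero-mean, unit-L2]" else ""))
  invisible(x)
}

#' Build the default filter bank: one scale, four orientations
#'
#' The default bank holds four kernels sharing a single scale
#' (`sigma`, `lambda`, `support`) at the orientation pairs
#' `(theta, omega) = (0,0), (pi/2,0), (0,pi/2), (pi/2,pi/2)` — the two
#' axis-aligned spatial orientations and their temporally tilted variants.
#' The kernel order is fixed; the gist feature layout depends on it.
#'
#' The default scale is matched to the 4 x 4 x 4 pooling grid at the
#' 160 x 128 working resolution: carrier wavelengths well above the kernel
#' support make each kernel an anisotropic low-frequency band-pass whose
#' response varies on the pooling-cell scale, so the cell means retain the
#' response structure instead of averaging a fine carrier to zero. See the
#' methods vignette for the design discussion.
#'
#' @param orientations list of `c(theta, omega)` pairs in radians.
#' @param sigma `c(sigma_x, sigma_y, sigma_t)` shared envelope scales.
#' @param lambda `c(lambda_x, lambda_y)` shared carrier wavelengths.
#' @param support shared integer half-extents `c(hx, hy, ht)`.
#' @param sigma_is_variance see [gabor_params()].
#' @return an object of class `gabor_bank`: a list of [build_kernel()]
#'   results in the given orientation order.
#' @examples
#' bank <- build_default_bank()
#' length(bank)  # 4
#' @export
build_default_bank <- function(orientations = list(c(0, 0), c(pi / 2, 0),
                                                   c(0, pi / 2),
                                                   c(pi / 2, pi / 2)),
                               sigma = c(12, 8, 6), lambda = c(96, 96),
                               support = c(18L, 18L, 10L),
                               sigma_is_variance = FALSE) {
  if (length(orientations) < 1L)
    stop("at least one (theta, omega) orientation pair is required",
         call. = FALSE)
  kernels <- lapply(orientations, function(ori) {
    build_kernel(gabor_params(
      sigma_x = sigma[1], sigma_y = sigma[2], sigma_t = sigma[3],
      lambda_x = lambda[1], lambda_y = lambda[2],
      theta = ori[1], omega = ori[2], support = support,
      sigma_is_variance = sigma_is_variance))
  })
  structure(kernels, class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("<gabor_bank> %d kernels\n", length(x)))
  for (k in x) {
    p <- k$params
    cat(sprintf("  theta=%6.3f omega=%6.3f  taps %s\n", p$theta, p$omega,
                paste(dim(k$taps), collapse = "x")))
  }
  invisible(x)
}

# --- FFT correlation machinery ---------------------------------------------
#
# Same-size cross-correlation
#   out[i] = sum_s V[i + s] * K[s + h + 1],  s in [-h, h] per axis,
# with edge-replicated borders: the volume is extended by clamping indices,
# so a constant volume yields an exactly constant window everywhere and the
# zero-mean kernels respond with exactly zero — the property behind the
# illumination robustness of the features. The correlation itself is a
# circular convolution of the extended, zero-padded volume with the
# axis-reversed kernel on a grid large enough to avoid wraparound in the
# retained region. Padded extents are rounded to 2-3-5-smooth sizes for
# fast mixed-radix FFTs. Kernel spectra are cached per (kernel, pad shape)
# so filtering a cohort of same-sized clips computes each spectrum once.

.spectrum_cache <- new.env(parent = emptyenv())

pad_dims <- function(d_ext, h) {
  vapply(seq_len(3L), function(k) stats::nextn(d_ext[k] + 2L * h[k], c(2, 3, 5)),
         numeric(1))
}

# Extend a volume by H[k] voxels of edge replication on each side of axis k.
replicate_extend <- function(arr, H) {
  d <- dim(arr)
  arr[pmin(pmax(seq_len(d[1] + 2L * H[1]) - H[1], 1L), d[1]),
      pmin(pmax(seq_len(d[2] + 2L * H[2]) - H[2], 1L), d[2]),
      pmin(pmax(seq_len(d[3] + 2L * H[3]) - H[3], 1L), d[3]), drop = FALSE]
}

kernel_spectrum <- function(kernel, P) {
  taps <- kernel$taps
  key <- paste(c(P, dim(taps),
                 sprintf("%.17g", c(taps[1], taps[length(taps)], sum(taps),
                                    sum(taps^2), sum(taps * seq_along(taps))))),
               collapse = "|")
  hit <- .spectrum_cache[[key]]
  if (!is.null(hit)) return(hit)
  rev_taps <- taps[rev(seq_len(dim(taps)[1])),
                   rev(seq_len(dim(taps)[2])),
                   rev(seq_len(dim(taps)[3])), drop = FALSE]
  kp <- array(0, P)
  kp[seq_len(dim(taps)[1]), seq_len(dim(taps)[2]), seq_len(dim(taps)[3])] <-
    rev_taps
  sp <- stats::fft(kp)
  if (length(ls(.spectrum_cache)) > 32L)
    rm(list = ls(.spectrum_cache), envir = .spectrum_cache)
  assign(key, sp, envir = .spectrum_cache)
  sp
}

check_kernel_fits <- function(d, kernel) {
  kd <- dim(kernel$taps)
  if (any(kd >= d))
    stop(sprintf("kernel taps (%s) must be smaller than the volume (%s) in every dimension",
                 paste(kd, collapse = "x"), paste(d, collapse = "x")),
         call. = FALSE)
}

# Correlate one extended-volume spectrum with up to two kernels at once: for
# real volumes both responses are real, so ifft(Z * (F1 + i F2)) carries the
# first response in its real part and the second in its imaginary part.
# `H` is the replication width of the extended volume behind Z; each
# response is cropped at offset H + h_kernel per axis.
corr_from_spectrum <- function(Z, P, d, H, kernels) {
  stopifnot(length(kernels) %in% c(1L, 2L))
  F1 <- kernel_spectrum(kernels[[1]], P)
  W <- if (length(kernels) == 2L)
    Z * (F1 + 1i * kernel_spectrum(kernels[[2]], P)) else Z * F1
  C <- stats::fft(W, inverse = TRUE) / prod(P)
  crop <- function(part, kernel) {
    o <- H + (dim(kernel$taps) - 1L) %/% 2L
    part[(o[1] + 1L):(o[1] + d[1]),
         (o[2] + 1L):(o[2] + d[2]),
         (o[3] + 1L):(o[3] + d[3]), drop = FALSE]
  }
  out <- list(crop(Re(C), kernels[[1]]))
  if (length(kernels) == 2L) out <- c(out, list(crop(Im(C), kernels[[2]])))
  out
}

filter_volume_once <- function(arr, kernel) {
  d <- dim(arr)
  h <- (dim(kernel$taps) - 1L) %/% 2L
  ext <- replicate_extend(arr, h)
  P <- pad_dims(dim(ext), h)
  vp <- array(0, P)
  vp[seq_len(dim(ext)[1]), seq_len(dim(ext)[2]), seq_len(dim(ext)[3])] <- ext
  Z <- stats::fft(vp)
  corr_from_spectrum(Z, P, d, h, list(kernel))[[1]]
}

#' Filter a volume with one Gabor kernel
#'
#' Same-size cross-correlation of the intensity grid with the kernel taps,
#' computed by FFT. Borders are handled by edge replication, so the
#' zero-mean kernels give exactly zero response to constant volumes at
#' every position, borders included — the property behind the features'
#' robustness to illumination changes. Long clips can be processed in
#' bounded-memory temporal chunks: chunks overlap by the kernel's temporal
#' half-extent on each side before stitching, so the chunked output equals
#' the unchunked output exactly.
#'
#' @param volume a [video_volume()] or a bare 3D array.
#' @param kernel a [build_kernel()] result.
#' @param chunk_frames optional maximum number of frames to filter per
#'   temporal chunk (must exceed twice the kernel's temporal half-extent);
#'   `NULL` (default) filters the whole clip at once.
#' @return a numeric 3D array of responses, same shape as the input.
#' @export
filter_volume <- function(volume, kernel, chunk_frames = NULL) {
  stopifnot(inherits(kernel, "gabor_kernel"))
  arr <- as_volume_array(volume)
  check_kernel_fits(dim(arr), kernel)
  if (is.null(chunk_frames)) return(filter_volume_once(arr, kernel))
  d <- dim(arr)
  ht <- (dim(kernel$taps)[3] - 1L) %/% 2L
  chunk_frames <- as.integer(chunk_frames)
  if (chunk_frames <= 2L * ht)
    stop("`chunk_frames` must exceed twice the kernel's temporal half-extent",
         call. = FALSE)
  out <- array(0, d)
  starts <- seq.int(1L, d[3], by = chunk_frames)
  for (a in starts) {
    b <- min(a + chunk_frames - 1L, d[3])
    lo <- max(1L, a - ht); hi <- min(d[3], b + ht)
    if (hi - lo + 1L <= dim(kernel$taps)[3]) { lo <- 1L; hi <- d[3] }
    sub <- filter_volume_once(arr[, , lo:hi, drop = FALSE], kernel)
    out[, , a:b] <- sub[, , (a - lo + 1L):(b - lo + 1L)]
  }
  out
}

#' Filter a volume with a whole bank
#'
#' Computes the volume's FFT once and reuses it for every kernel, pairing
#' kernels two-per-inverse-transform, so a four-kernel bank costs three
#' large FFTs instead of eight.
#'
#' @param volume a [video_volume()] or a bare 3D array.
#' @param bank a [build_default_bank()] result (class `gabor_bank`).
#' @return a list of response arrays, one per kernel, in bank order.
#' @export
filter_bank <- function(volume, bank) {
  stopifnot(inherits(bank, "gabor_bank"), length(bank) >= 1L)
  arr <- as_volume_array(volume)
  d <- dim(arr)
  for (k in bank) check_kernel_fits(d, k)
  hs <- vapply(bank, function(k) (dim(k$taps) - 1L) %/% 2L, integer(3))
  H <- apply(hs, 1L, max)  # shared extension covers the largest support
  ext <- replicate_extend(arr, H)
  P <- pad_dims(dim(ext), apply(hs, 1L, max))
  vp <- array(0, P)
  vp[seq_len(dim(ext)[1]), seq_len(dim(ext)[2]), seq_len(dim(ext)[3])] <- ext
  Z <- stats::fft(vp)
  out <- vector("list", length(bank))
  i <- 1L
  while (i <= length(bank)) {
    pair <- bank[i:min(i + 1L, length(bank))]
    res <- corr_from_spectrum(Z, P, d, H, pair)
    out[i:(i + length(res) - 1L)] <- res
    i <- i + length(res)
  }
  out
}
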