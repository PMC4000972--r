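test_that("rotate_coords applies the two printed rotation matrices in order", {
  # identity at zero angles
  rc <- rotate_coords(1.2, -0.7, 3.1, 0, 0)
  expect_equal(unlist(rc), c(X = 1.2, Y = -0.7, T = 3.1))

  # theta = pi/2, omega = 0 permutes (x, y, t) -> (x, -t, y)
  rc <- rotate_coords(2, 3, 4, pi / 2, 0)
  expect_equal(unlist(rc), c(X = 2, Y = -4, T = 3))

  # rotations preserve the Euclidean norm
  set.seed(11)
  for (i in 1:20) {
    p <- rnorm(3); ang <- runif(2, -pi, pi)
    rc <- rotate_coords(p[1], p[2], p[3], ang[1], ang[2])
    expect_equal(rc$X^2 + rc$Y^2 + rc$T^2, sum(p^2), tolerance = 1e-12)
  }
})

test_that("gabor_value matches direct evaluation of the filter formula", {
  p <- gabor_params(sigma_x = 4, sigma_y = 3, sigma_t = 2,
                    lambda_x = 8, lambda_y = 6)
  # origin: envelope and carriers are all 1
  expect_equal(gabor_value(p, 0, 0, 0), 1)

  # even symmetry under joint negation
  set.seed(3)
  for (i in 1:10) {
    q <- gabor_params(theta = runif(1, -pi, pi), omega = runif(1, -pi, pi))
    v <- rnorm(3)
    expect_equal(gabor_value(q, v[1], v[2], v[3]),
                 gabor_value(q, -v[1], -v[2], -v[3]), tolerance = 1e-12)
  }

  # half a carrier wavelength along x: cos(pi) times the envelope
  expect_equal(gabor_value(p, 4, 0, 0), -exp(-16 / (2 * 16)))
  expect_equal(gabor_value(p, p$lambda_x / 2, 0, 0),
               -exp(-p$lambda_x^2 / (8 * p$sigma_x^2)))

  # literal printed denominators when sigma is treated as a variance
  pv <- gabor_params(sigma_x = 4, sigma_y = 3, sigma_t = 2,
                     lambda_x = 8, lambda_y = 6, sigma_is_variance = TRUE)
  expect_equal(gabor_value(pv, 4, 0, 0), -exp(-16 / (2 * 4)))
})

test_that("build_kernel samples, zero-means and unit-normalizes the taps", {
  p <- gabor_params(support = c(4, 3, 2))
  k <- build_kernel(p)
  expect_identical(dim(k$taps), c(9L, 7L, 5L))
  expect_lt(abs(sum(k$taps)), 1e-10 * length(k$taps))
  expect_equal(sum(k$taps^2), 1, tolerance = 1e-10)

  # unnormalized taps equal pointwise filter evaluation
  raw <- build_kernel(p, normalize = FALSE)
  expect_equal(raw$taps[4 + 1 + 1, 3 + 1, 2 + 1], gabor_value(p, 1, 0, 0))
  expect_equal(raw$taps[4 + 1 - 2, 3 + 1 + 3, 2 + 1 - 1],
               gabor_value(p, -2, 3, -1))

  # axis-aligned kernels are even under negation of each axis
  expect_equal(k$taps, k$taps[9:1, , ])
  expect_equal(k$taps, k$taps[, 7:1, ])
  expect_equal(k$taps, k$taps[, , 5:1])

  # a kernel whose taps vanish after mean subtraction is rejected
  flat <- gabor_params(sigma_x = 1e8, sigma_y = 1e8, sigma_t = 1e8,
                       lambda_x = 1e12, lambda_y = 1e12, support = c(1, 1, 1))
  expect_error(build_kernel(flat), "degenerate")
})

test_that("the quarter-turn kernel is the base kernel on permuted axes", {
  p0 <- gabor_params(sigma_x = 3, sigma_y = 2, sigma_t = 1.5,
                     lambda_x = 7, lambda_y = 5, theta = 0,
                     support = c(3, 2, 4))
  p90 <- gabor_params(sigma_x = 3, sigma_y = 2, sigma_t = 1.5,
                      lambda_x = 7, lambda_y = 5, theta = pi / 2,
                      support = c(3, 4, 2))
  t0 <- build_kernel(p0, normalize = FALSE)$taps
  t90 <- build_kernel(p90, normalize = FALSE)$taps
  # G_{theta=pi/2}(x, y, t) = G_{theta=0}(x, -t, y)
  expected <- aperm(t0, c(1, 3, 2))[, , dim(t0)[2]:1]
  expect_equal(t90, expected, tolerance = 1e-12)
})

test_that("the default bank has four kernels at one shared scale", {
  bank <- build_default_bank()
  expect_s3_class(bank, "gabor_bank")
  expect_length(bank, 4)
  sig <- vapply(bank, function(k)
    c(k$params$sigma_x, k$params$sigma_y, k$params$sigma_t,
      k$params$lambda_x, k$params$lambda_y), numeric(5))
  expect_true(all(sig == sig[, 1]))
  oris <- vapply(bank, function(k) c(k$params$theta, k$params$omega),
                 numeric(2))
  expect_equal(ncol(unique(t(oris))), 2)
  expect_identical(nrow(unique(t(oris))), 4L)

  # determinism: same configuration, identical taps
  bank2 <- build_default_bank()
  for (i in 1:4) expect_identical(bank[[i]]$taps, bank2[[i]]$taps)

  expect_error(build_default_bank(orientations = list()), "orientation")
})

test_that("filter_volume matches the brute-force correlation oracle", {
  set.seed(21)
  kernels <- list(
    build_kernel(gabor_params(sigma_x = 2, sigma_y = 2, sigma_t = 1.5,
                              lambda_x = 5, lambda_y = 5,
                              support = c(2, 2, 2))),
    build_kernel(gabor_params(theta = pi / 2, omega = pi / 2,
                              sigma_x = 2, sigma_y = 2, sigma_t = 1.5,
                              lambda_x = 5, lambda_y = 5,
                              support = c(2, 3, 1)))
  )
  for (i in 1:3) {
    V <- array(rnorm(9 * 9 * 9), c(9, 9, 9))
    for (k in kernels)
      expect_lt(max(abs(filter_volume(V, k) - brute_correlate(V, k$taps))),
                1e-10)
  }
})

test_that("filtering is linear and blind to constant offsets", {
  set.seed(5)
  k <- build_kernel(gabor_params(support = c(3, 3, 2)))
  V1 <- array(rnorm(12 * 14 * 10), c(12, 14, 10))
  V2 <- array(rnorm(12 * 14 * 10), c(12, 14, 10))

  lhs <- filter_volume(2.5 * V1 - 1.2 * V2, k)
  rhs <- 2.5 * filter_volume(V1, k) - 1.2 * filter_volume(V2, k)
  expect_lt(max(abs(lhs - rhs)), 1e-12)

  # constant volumes give zero response everywhere, borders included
  expect_lt(max(abs(filter_volume(array(0.73, c(12, 14, 10)), k))), 1e-8)
  # additive offsets leave the response untouched
  expect_lt(max(abs(filter_volume(V1 + 0.4, k) - filter_volume(V1, k))), 1e-8)
})

test_that("an interior impulse reproduces the kernel taps", {
  k <- build_kernel(gabor_params(sigma_x = 2, sigma_y = 2, sigma_t = 1,
                                 lambda_x = 5, lambda_y = 5,
                                 support = c(2, 2, 1)))
  V <- array(0, c(11, 11, 7)); V[6, 6, 4] <- 1
  r <- filter_volume(V, k)
  # under cross-correlation, response around the impulse equals the taps
  # with each axis reversed
  got <- r[4:8, 4:8, 3:5]
  expect_equal(got, k$taps[5:1, 5:1, 3:1], tolerance = 1e-12)
})

test_that("temporally chunked filtering equals the single-pass result", {
  set.seed(9)
  k <- build_kernel(gabor_params(support = c(3, 3, 2)))
  V <- array(rnorm(10 * 12 * 37), c(10, 12, 37))
  whole <- filter_volume(V, k)
  for (chunk in c(7, 12, 37))
    expect_lt(max(abs(filter_volume(V, k, chunk_frames = chunk) - whole)),
              1e-12)
  expect_error(filter_volume(V, k, chunk_frames = 4), "temporal half-extent")
})

test_that("kernels larger than the volume are rejected", {
  k <- build_kernel(gabor_params(support = c(5, 5, 3)))
  expect_error(filter_volume(array(0.1, c(8, 20, 20)), k), "smaller than")
})
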