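# Independent brute-force oracles used across the suite. They share no code
# with the package implementation: plain triple loops and direct formula
# evaluation only.

# Same-size cross-correlation with edge-replicated (clamped-index) borders.
brute_correlate <- function(V, K) {
  d <- dim(V)
  h <- (dim(K) - 1L) %/% 2L
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (t in seq_len(d[3])) {
    s <- 0
    for (a in -h[1]:h[1]) for (b in -h[2]:h[2]) for (cc in -h[3]:h[3]) {
      ii <- min(max(i + a, 1L), d[1])
      jj <- min(max(j + b, 1L), d[2])
      tt <- min(max(t + cc, 1L), d[3])
      s <- s + V[ii, jj, tt] * K[a + h[1] + 1L, b + h[2] + 1L, cc + h[3] + 1L]
    }
    out[i, j, t] <- s
  }
  out
}

# Per-block means with floor(i*d/g) bin edges, straight loops.
brute_pool <- function(R, g = c(4L, 4L, 4L)) {
  d <- dim(R)
  out <- numeric(prod(g))
  pos <- 1L
  for (ri in seq_len(g[1])) for (ci in seq_len(g[2])) for (ti in seq_len(g[3])) {
    rows <- (floor((ri - 1) * d[1] / g[1]) + 1L):floor(ri * d[1] / g[1])
    cols <- (floor((ci - 1) * d[2] / g[2]) + 1L):floor(ci * d[2] / g[2])
    tims <- (floor((ti - 1) * d[3] / g[3]) + 1L):floor(ti * d[3] / g[3])
    acc <- 0; nvx <- 0
    for (i in rows) for (j in cols) for (t in tims) {
      acc <- acc + R[i, j, t]; nvx <- nvx + 1
    }
    out[pos] <- acc / nvx
    pos <- pos + 1L
  }
  out
}

# Dense QP solve of the SVM dual via kernlab::ipop (interior point), as an
# implementation-independent oracle. Returns alpha and the dual objective.
oracle_svm_dual <- function(K, y, C) {
  n <- length(y)
  H <- (y %o% y) * K + diag(1e-8, n)
  sol <- kernlab::ipop(c = matrix(-1, n, 1), H = H,
                       A = matrix(y, 1, n), b = 0, r = 0,
                       l = matrix(0, n, 1), u = matrix(C, n, 1),
                       sigf = 8, maxiter = 400, margin = 0.02)
  alpha <- as.numeric(kernlab::primal(sol))
  # evaluate the objective with the exact (unridged) Hessian
  H0 <- (y %o% y) * K
  obj <- sum(alpha) - 0.5 * drop(t(alpha) %*% H0 %*% alpha)
  list(alpha = alpha, objective = obj)
}

# Direct kernel formula evaluation (no shared code with kernel_eval).
oracle_kernel <- function(family, xi, xj, c = 0, d = 2, sigma = 1) {
  switch(family,
         linear = drop(crossprod(xi, xj)),
         polynomial = (drop(crossprod(xi, xj)) + c)^d,
         rbf = exp(-drop(crossprod(xi - xj)) / (2 * sigma^2)))
}

# Small random labeled 2-D dataset with both classes present.
random_2d_set <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n), n, 2)
  y <- sign(x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.3))
  y[y == 0] <- 1
  if (length(unique(y)) < 2) y[1] <- -y[1]
  list(x = x, y = y)
}

# A small, fast synthetic clip configuration for unit tests.
tiny_config <- function(...) {
  synth_config(frame_size = c(32, 40), n_frames = 24, blob_radius = 2.5,
               speed = 2, start_jitter = 3, noise_sd = 0.005, ...)
}

# A small bank so unit tests stay fast.
tiny_bank <- function(n = 4) {
  oris <- list(c(0, 0), c(pi / 2, 0), c(0, pi / 2), c(pi / 2, pi / 2),
               c(pi / 4, 0), c(0, pi / 4), c(pi / 4, pi / 4), c(pi / 3, pi / 6))
  build_default_bank(orientations = oris[seq_len(n)], sigma = c(2, 2, 1.5),
                     lambda = c(6, 6), support = c(3, 3, 2))
}
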