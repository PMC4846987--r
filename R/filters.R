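# Separable 3D filtering primitives used by the feature bank.
#
# All filters are separable Gaussian (derivative) filters applied axis by
# axis as dense matrix products, which keeps the inner loops in BLAS.
# Boundaries are handled by symmetric reflection with edge duplication
# (… c b a | a b c …); with a symmetric kernel the resulting operator matrix
# is symmetric and doubly stochastic, so smoothing preserves the global mean
# exactly.

# Sampled Gaussian kernel, truncated at 3 sigma and normalized to sum 1.
gauss_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Sampled first derivative of a Gaussian (antisymmetric, sums to 0 exactly).
gauss_deriv1 <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  -x / sigma^2 * g
}

# Sampled second derivative of a Gaussian; mean-corrected so that the
# response to a constant signal is exactly zero.
gauss_deriv2 <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- (x^2 / sigma^4 - 1 / sigma^2) * g
  k - mean(k)
}

# Dense n x n operator matrix applying 1D correlation with `kernel` under
# symmetric (edge-duplicating) boundary reflection.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    w <- kernel[o + r + 1L]
    j <- seq_len(n) + o
    # reflect indices into [1, n]; one pass suffices for kernels shorter
    # than the axis, a second covers tiny axes
    for (dummy in 1:2) {
      j <- ifelse(j < 1L, 1L - j, j)
      j <- ifelse(j > n, 2L * n + 1L - j, j)
    }
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + w
  }
  K
}

# Apply per-axis 1D kernels to a 3D array (NULL kernel = identity pass).
apply_separable <- function(vol, kx = NULL, ky = NULL, kz = NULL) {
  d <- dim(vol)
  if (!is.null(kx)) {
    vol <- array(conv_matrix(d[1], kx) %*% matrix(vol, d[1], d[2] * d[3]), d)
  }
  if (!is.null(ky)) {
    v <- aperm(vol, c(2, 1, 3))
    v <- array(conv_matrix(d[2], ky) %*% matrix(v, d[2], d[1] * d[3]),
               c(d[2], d[1], d[3]))
    vol <- aperm(v, c(2, 1, 3))
  }
  if (!is.null(kz)) {
    vol <- array(matrix(vol, d[1] * d[2], d[3]) %*% t(conv_matrix(d[3], kz)), d)
  }
  vol
}

gaussian_smooth3 <- function(vol, sigma) {
  if (sigma == 0) return(vol)
  g <- gauss_kernel(sigma)
  apply_separable(vol, g, g, g)
}

# Gaussian gradient along one axis (derivative on `axis`, smoothing on the rest).
gaussian_gradient_axis <- function(vol, sigma, axis) {
  g <- gauss_kernel(sigma)
  d1 <- gauss_deriv1(sigma)
  ks <- list(g, g, g)
  ks[[axis]] <- d1
  apply_separable(vol, ks[[1]], ks[[2]], ks[[3]])
}

# Second-order Gaussian derivative d^2 / (d axis_i d axis_j).
gaussian_hessian_comp <- function(vol, sigma, i, j) {
  g <- gauss_kernel(sigma)
  ks <- list(g, g, g)
  if (i == j) {
    ks[[i]] <- gauss_deriv2(sigma)
  } else {
    d1 <- gauss_deriv1(sigma)
    ks[[i]] <- d1
    ks[[j]] <- d1
  }
  apply_separable(vol, ks[[1]], ks[[2]], ks[[3]])
}

# Largest eigenvalue of a field of symmetric 3x3 matrices, vectorized
# (trigonometric closed form for symmetric 3x3 eigenvalues).
sym3_largest_eig <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  out <- q # degenerate (near-scalar) matrices: all eigenvalues equal q
  nz <- p > 1e-30
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    out[nz] <- q[nz] + 2 * p[nz] * cos(acos(r) / 3)
  }
  out
}
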