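# Shared fixtures, all built in code.

channel_names <- virtrater:::channel_names
class_ids <- virtrater:::class_ids
class_names <- virtrater:::class_names

# Two-class scheme for mask-level tests.
scheme_fg <- function() {
  label_scheme(c("bg", "fg"), tumor_classes = "fg", background = "bg")
}

# Small phantom spec that fits its grid at every timepoint.
small_spec <- function(grid = 20L, n_timepoints = 1L, seed = 1L, ...) {
  phantom_spec(grid_shape = rep(grid, 3),
               tumor_radii = c(NonEnhancing = 2, Enhancing = 3.5, Edema = 5),
               n_timepoints = n_timepoints, seed = seed, ...)
}

# Tiny 4-modality study with constant-ish channels for wiring tests.
tiny_study <- function(d = c(12L, 12L, 12L), seed = 7L) {
  set.seed(seed)
  mc_volume(list(nT1w = array(rnorm(prod(d), 50, 5), d),
                 ceT1w = array(rnorm(prod(d), 55, 5), d),
                 T2w = array(rnorm(prod(d), 60, 5), d),
                 FLAIR = array(rnorm(prod(d), 45, 5), d)))
}

# Random normalized probability map.
random_prob_map <- function(d = c(8L, 8L, 8L), k = 3L, seed = 1L) {
  set.seed(seed)
  p <- array(stats::runif(prod(d) * k), c(d, k))
  s <- array(rep(apply(p, 1:3, sum), k), c(d, k))
  nm <- paste0("c", seq_len(k) - 1L)
  prob_map(p / s, label_scheme(nm, tumor_classes = nm[-1], background = nm[1]))
}

# Direct (non-separable) 3D correlation with a separable kernel under
# symmetric reflection; independent oracle for the filtering core.
brute_conv3 <- function(vol, k1, k2, k3) {
  d <- dim(vol)
  r1 <- (length(k1) - 1) %/% 2
  r2 <- (length(k2) - 1) %/% 2
  r3 <- (length(k3) - 1) %/% 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (a in -r1:r1) for (b in -r2:r2) for (cc in -r3:r3) {
      acc <- acc + k1[a + r1 + 1] * k2[b + r2 + 1] * k3[cc + r3 + 1] *
        vol[refl(x + a, d[1]), refl(y + b, d[2]), refl(z + cc, d[3])]
    }
    out[x, y, z] <- acc
  }
  out
}

# Independent brute-force multi-category STAPLE EM with explicit per-voxel
# loops, mirroring the documented E/M equations; runs exactly n_iter
# iterations and returns the final posterior matrix.
brute_staple <- function(obs, K, n_iter, init_diag = 0.99999) {
  v <- nrow(obs)
  R <- ncol(obs)
  prior <- numeric(K)
  for (r in seq_len(R)) for (i in seq_len(v))
    prior[obs[i, r]] <- prior[obs[i, r]] + 1
  prior <- prior / (v * R)
  theta <- lapply(seq_len(R), function(r) {
    m <- matrix((1 - init_diag) / (K - 1), K, K)
    diag(m) <- init_diag
    m
  })
  post <- matrix(0, v, K)
  for (it in seq_len(n_iter)) {
    for (i in seq_len(v)) {
      w <- numeric(K)
      for (k in seq_len(K)) {
        w[k] <- prior[k]
        for (r in seq_len(R)) w[k] <- w[k] * theta[[r]][k, obs[i, r]]
      }
      post[i, ] <- w / sum(w)
    }
    for (r in seq_len(R)) {
      th <- matrix(0, K, K)
      for (k in seq_len(K)) {
        denom <- 0
        for (i in seq_len(v)) {
          th[k, obs[i, r]] <- th[k, obs[i, r]] + post[i, k]
          denom <- denom + post[i, k]
        }
        if (denom > 0) th[k, ] <- th[k, ] / denom else th[k, k] <- 1
      }
      theta[[r]] <- th
    }
  }
  post
}

# Label volume on a tiny grid from an integer vector (2-class scheme).
tiny_labels <- function(v, d = NULL, scheme = scheme_fg()) {
  if (is.null(d)) d <- c(length(v), 1L, 1L)
  label_volume(array(as.integer(v), d), scheme)
}
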