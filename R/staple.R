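#' STAPLE parameters
#'
#' Settings for multi-category STAPLE (Simultaneous Truth and Performance
#' Level Estimation): EM estimation of a probabilistic consensus segmentation
#' together with one K x K confusion matrix per rater (rows = true class,
#' columns = observed class).
#'
#' @param max_iterations EM iteration cap (default 100).
#' @param convergence_tol threshold on the mean absolute change of the
#'   consensus posteriors between iterations (default 1e-6).
#' @param init_diag initial confusion-matrix diagonal, in (0.5, 1)
#'   (default 0.99999); off-diagonal mass is spread uniformly.
#' @return an object of class `staple_params`.
#' @export
staple_params <- function(max_iterations = 100L, convergence_tol = 1e-6,
                          init_diag = 0.99999) {
  stopifnot(max_iterations >= 1L, convergence_tol > 0,
            init_diag > 0.5, init_diag < 1)
  structure(
    list(max_iterations = as.integer(max_iterations),
         convergence_tol = convergence_tol, init_diag = init_diag),
    class = "staple_params"
  )
}

#' Fuse segmentations with multi-category STAPLE
#'
#' Expectation-maximization with a stationary class prior (mean observed
#' class frequency across raters): the E step computes per-voxel true-class
#' posteriors proportional to `prior_k * prod_r theta_r[k, obs_r]`, the M
#' step re-estimates each rater's confusion matrix from the posteriors.
#' Deterministic; the data log-likelihood is non-decreasing over iterations.
#'
#' @param segmentations list of >= 2 [label_volume()]s on identical grids
#'   with a common scheme.
#' @param params a [staple_params()].
#' @return an object of class `staple_result`: `consensus_probs`
#'   ([prob_map()]), `consensus` (argmax [label_volume()], ties to the lowest
#'   class id), `theta` (list of confusion matrices), `prior`, `iterations`,
#'   `converged`, `loglik` (trace).
#' @export
staple_fuse <- function(segmentations, params = staple_params()) {
  if (length(segmentations) < 2L)
    stop("need at least two segmentations to fuse")
  stopifnot(all(vapply(segmentations, inherits, TRUE, "label_volume")))
  d <- dim(segmentations[[1]])
  sch <- segmentations[[1]]$scheme
  for (s in segmentations) {
    if (!identical(dim(s), d)) stop("segmentation grids differ")
    if (n_classes(s$scheme) != n_classes(sch)) stop("schemes differ")
  }
  K <- n_classes(sch)
  R <- length(segmentations)
  v <- prod(d)
  obs <- matrix(vapply(segmentations, function(s) as.vector(s$labels) + 1L,
                       integer(v)), nrow = v)
  prior <- rowMeans(vapply(seq_len(R), function(r)
    tabulate(obs[, r], nbins = K) / v, numeric(K)))
  theta <- replicate(R, {
    m <- matrix((1 - params$init_diag) / (K - 1), K, K)
    diag(m) <- params$init_diag
    m
  }, simplify = FALSE)
  post <- matrix(0, v, K)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- matrix(rep(prior, each = v), v, K)
    for (r in seq_len(R)) {
      for (k in seq_len(K)) w[, k] <- w[, k] * theta[[r]][k, obs[, r]]
    }
    norm <- rowSums(w)
    loglik <- c(loglik, sum(log(norm)))
    new_post <- w / norm
    delta <- mean(abs(new_post - post))
    post <- new_post
    for (r in seq_len(R)) {
      th <- vapply(seq_len(K), function(c)
        colSums(post * (obs[, r] == c)), numeric(K))
      denom <- colSums(post)
      ok <- denom > 0
      th[ok, ] <- th[ok, ] / denom[ok]
      th[!ok, ] <- diag(K)[!ok, , drop = FALSE] # unsupported class: keep identity
      theta[[r]] <- th
    }
    if (iter > 1L && delta < params$convergence_tol) { converged <- TRUE; break }
    if (iter >= params$max_iterations) break
  }
  probs <- prob_map(array(post, c(d, K)), sch,
                    segmentations[[1]]$voxel_size_mm)
  structure(
    list(consensus_probs = probs,
         consensus = argmax_labels(probs),
         theta = theta, prior = prior,
         iterations = iter, converged = converged, loglik = loglik),
    class = "staple_result"
  )
}

#' @export
print.staple_result <- function(x, ...) {
  cat("<staple_result> ", length(x$theta), " raters, ",
      x$iterations, " EM iteration(s), ",
      if (x$converged) "converged" else "not converged",
      "; loglik ", signif(utils::tail(x$loglik, 1), 8), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.staple_result <- function(x, ...) {
  sch <- x$consensus$scheme
  nm <- class_names(sch)
  purrr::imap_dfr(x$theta, function(th, r) {
    tibble::tibble(
      rater = r,
      true_class = rep(nm, times = length(nm)),
      observed_class = rep(nm, each = length(nm)),
      probability = as.vector(t(th))
    )
  })
}

#' @export
glance.staple_result <- function(x, ...) {
  tibble::tibble(
    n_raters = length(x$theta),
    iterations = x$iterations,
    converged = x$converged,
    loglik = utils::tail(x$loglik, 1),
    mean_diag = mean(vapply(x$theta, function(th) mean(diag(th)), 1))
  )
}

#' Consensus reference from the available rater segmentations
#'
#' Builds the reference segmentation of a dataset from whatever rater
#' segmentations remain (e.g. after instance dropout): two or more are fused
#' with STAPLE and the argmax consensus is returned; exactly one is passed
#' through verbatim; none returns `NULL` (the dataset is excluded).
#'
#' @param records list of [label_volume()]s (possibly empty).
#' @param params a [staple_params()].
#' @return a [label_volume()] or `NULL`.
#' @export
reference_from_raters <- function(records, params = staple_params()) {
  n <- length(records)
  if (n == 0L) return(NULL)
  if (n == 1L) return(records[[1]])
  staple_fuse(records, params)$consensus
}
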