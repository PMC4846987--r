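#' Configure the random-forest ensemble
#'
#' The classifier trains `n_forests` independent random forests of
#' `trees_per_forest` trees each (each sub-forest on the full training set
#' with its own derived seed) and merges them into a single forest by
#' concatenating trees; the default 10 x 10 gives a 100-tree merged forest.
#'
#' @param n_forests number of sub-forests (default 10).
#' @param trees_per_forest trees per sub-forest (default 10).
#' @param seed RNG seed; sub-forest i trains under `derive_seed(seed, i)`.
#' @param scheme optional [label_scheme()]; when supplied, predictions carry
#'   explicit zero-probability channels for classes absent from training.
#' @return an object of class `forest_config`.
#' @export
forest_config <- function(n_forests = 10L, trees_per_forest = 10L,
                          seed = 1L, scheme = NULL) {
  stopifnot(n_forests >= 1L, trees_per_forest >= 1L)
  structure(
    list(n_forests = as.integer(n_forests),
         trees_per_forest = as.integer(trees_per_forest),
         seed = as.integer(seed), scheme = scheme),
    class = "forest_config"
  )
}

#' Train the forest ensemble on a labeled feature matrix
#'
#' Low-level training entry point used both for single-study scribble
#' training and for multi-study pooled training (rows may come from
#' different studies' feature stacks, as long as the channel order matches).
#'
#' @param x numeric feature matrix (rows = labeled voxels).
#' @param y integer class ids, one per row.
#' @param config a [forest_config()].
#' @return an object of class `forest_ensemble`: the merged
#'   `n_forests * trees_per_forest`-tree forest plus training metadata.
#' @export
train_forest_matrix <- function(x, y, config = forest_config()) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  classes <- sort(unique(as.integer(y)))
  if (length(classes) < 2L) stop("need at least two labeled classes")
  yf <- factor(as.integer(y), levels = classes)
  subs <- lapply(seq_len(config$n_forests), function(i) {
    with_seed(derive_seed(config$seed, "forest", i),
              randomForest::randomForest(x, yf,
                                         ntree = config$trees_per_forest))
  })
  merged <- if (length(subs) > 1L) do.call(randomForest::combine, subs)
            else subs[[1]]
  structure(
    list(forest = merged, subforests = subs, config = config,
         classes_present = classes,
         feature_names = colnames(x), n_features = ncol(x),
         n_samples_per_class = table(yf)),
    class = "forest_ensemble"
  )
}

#' Train the forest ensemble from scribbles on one study
#'
#' Extracts the feature vector of every scribble voxel from the study's
#' feature stack and fits the merged random forest.  Deterministic given the
#' config seed.
#'
#' @param stack feature stack [mc_volume()] (see [assemble_feature_stack()]).
#' @param scribbles scribble tibble (`x`, `y`, `z` 0-based, `class_id`).
#' @param config a [forest_config()].
#' @return a `forest_ensemble`.
#' @export
train_forest_ensemble <- function(stack, scribbles, config = forest_config()) {
  stopifnot(inherits(stack, "mc_volume"))
  x <- features_at(stack, as.matrix(scribbles[, c("x", "y", "z")]))
  train_forest_matrix(x, scribbles$class_id, config)
}

#' @export
print.forest_ensemble <- function(x, ...) {
  cat("<forest_ensemble> ", x$forest$ntree, " trees (",
      x$config$n_forests, " x ", x$config$trees_per_forest, "), ",
      x$n_features, " features, classes {",
      paste(x$classes_present, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
glance.forest_ensemble <- function(x, ...) {
  tibble::tibble(
    n_trees = x$forest$ntree,
    n_forests = x$config$n_forests,
    trees_per_forest = x$config$trees_per_forest,
    n_features = x$n_features,
    n_classes = length(x$classes_present),
    n_samples = sum(x$n_samples_per_class),
    oob_error = tryCatch(x$forest$err.rate[nrow(x$forest$err.rate), "OOB"],
                         error = function(e) NA_real_),
    seed = x$config$seed
  )
}

#' @export
tidy.forest_ensemble <- function(x, ...) {
  tibble::tibble(class_id = x$classes_present,
                 n_samples = as.integer(x$n_samples_per_class))
}

# Raw per-class vote fractions (classes present in training only).
forest_votes <- function(forest, x) {
  # deserialized models need the namespace for predict() dispatch
  loadNamespace("randomForest")
  p <- stats::predict(forest, x, type = "prob")
  unclass(p)
}

#' Predict per-voxel class pseudo-probabilities for a whole study
#'
#' Runs every voxel of the feature stack through the merged forest; the
#' pseudo-probability of a class is the fraction of trees voting for it
#' (trees are fully grown, so this equals the mean leaf class distribution).
#' Classes of the scheme that were absent from training receive an explicit
#' zero channel.
#'
#' @param ensemble a `forest_ensemble`.
#' @param stack feature stack [mc_volume()] with the training channel count.
#' @param scheme [label_scheme()] for the output map; defaults to the
#'   config's scheme, falling back to a scheme of the training classes.
#' @return a [prob_map()].
#' @export
predict_probabilities <- function(ensemble, stack, scheme = NULL) {
  stopifnot(inherits(ensemble, "forest_ensemble"), inherits(stack, "mc_volume"))
  if (length(stack$channels) != ensemble$n_features)
    stop("feature-count mismatch: expected ", ensemble$n_features,
         " channels, got ", length(stack$channels))
  if (is.null(scheme)) scheme <- ensemble$config$scheme
  if (is.null(scheme)) {
    nm <- paste0("class", 0:max(ensemble$classes_present))
    scheme <- label_scheme(nm, tumor_classes = nm[-1], background = nm[1])
  }
  if (!all(ensemble$classes_present %in% class_ids(scheme)))
    stop("scheme does not cover the trained classes")
  d <- dim(stack)
  x <- vapply(stack$channels, as.vector, numeric(prod(d)))
  colnames(x) <- ensemble$feature_names
  votes <- forest_votes(ensemble$forest, x)
  k <- n_classes(scheme)
  probs <- array(0, c(d, k))
  for (j in seq_len(ncol(votes))) {
    cid <- as.integer(colnames(votes)[j])
    probs[, , , cid + 1L] <- votes[, j]
  }
  prob_map(probs, scheme, stack$voxel_size_mm)
}
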