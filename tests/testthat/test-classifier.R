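# Separable two-class training matrix: class means 10 sd apart.
separable_xy <- function(n = 100L, p = 5L, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p, 0, 1), n, p),
             matrix(rnorm(n * p, 10, 1), n, p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(c(0L, 1L), each = n))
}

test_that("the default ensemble merges to exactly 100 trees", {
  d <- separable_xy()
  ens <- train_forest_matrix(d$x, d$y, forest_config())
  expect_equal(ens$forest$ntree, 100)
  expect_length(ens$subforests, 10L)
})

test_that("well-separated classes are learned perfectly", {
  d <- separable_xy()
  ens <- train_forest_matrix(d$x, d$y, forest_config())
  pred <- predict(ens$forest, d$x)
  expect_identical(as.integer(as.character(pred)), d$y)
})

test_that("training with fewer than two classes fails", {
  d <- separable_xy()
  expect_error(train_forest_matrix(d$x, rep(0L, nrow(d$x)), forest_config()),
               "at least two labeled classes")
})

test_that("out-of-bounds scribbles are rejected with their coordinate", {
  study <- tiny_study()
  st <- assemble_feature_stack(study, feature_config(scales_vox = 1.0))
  scr <- tibble::tibble(x = c(1L, 50L), y = c(1L, 1L), z = c(1L, 1L),
                        class_id = c(0L, 1L))
  expect_error(train_forest_ensemble(st, scr), "50")
})

test_that("training and prediction are deterministic given the seed", {
  d <- separable_xy(n = 60L)
  set.seed(99)
  # ambiguous probes between the class means, so votes actually split
  probe <- matrix(rnorm(20 * 5, 5, 4), 20, 5,
                  dimnames = list(NULL, paste0("f", 1:5)))
  p1 <- predict(train_forest_matrix(d$x, d$y, forest_config(seed = 5L))$forest,
                probe, type = "prob")
  p2 <- predict(train_forest_matrix(d$x, d$y, forest_config(seed = 5L))$forest,
                probe, type = "prob")
  expect_identical(unclass(p1), unclass(p2))
  p3 <- predict(train_forest_matrix(d$x, d$y, forest_config(seed = 6L))$forest,
                probe, type = "prob")
  expect_false(identical(unclass(p1), unclass(p3)))
})

test_that("merged-forest prediction equals averaging the sub-forest outputs", {
  d <- separable_xy(n = 50L)
  set.seed(4)
  probe <- matrix(rnorm(40 * 5, 5, 4), 40, 5,
                  dimnames = list(NULL, paste0("f", 1:5)))
  ens <- train_forest_matrix(d$x, d$y, forest_config(n_forests = 4L,
                                                     trees_per_forest = 8L))
  merged <- predict(ens$forest, probe, type = "prob")
  avg <- Reduce(`+`, lapply(ens$subforests, function(f)
    predict(f, probe, type = "prob"))) / length(ens$subforests)
  expect_equal(unclass(merged), unclass(avg), tolerance = 1e-12)
})

test_that("probability maps are normalized and constant stacks give constant fields", {
  sch <- scheme_fg()
  d <- c(10L, 10L, 4L)
  set.seed(8)
  ch <- list(a = array(rnorm(prod(d)), d), b = array(rnorm(prod(d), 3), d))
  stack <- mc_volume(ch)
  scr <- tibble::tibble(x = rep(0:9, 2), y = rep(c(0L, 5L), each = 10L),
                        z = rep(1L, 20L),
                        class_id = rep(c(0L, 1L), each = 10L))
  ens <- train_forest_ensemble(stack, scr, forest_config(scheme = sch))
  probs <- predict_probabilities(ens, stack)
  s <- apply(probs$probs, 1:3, sum)
  expect_lt(max(abs(s - 1)), 1e-9)
  # constant input stack: every voxel gets an identical prediction
  const <- mc_volume(list(a = array(0, d), b = array(0, d)))
  pc <- predict_probabilities(ens, const)
  for (k in 1:2) expect_length(unique(as.vector(pc$probs[, , , k])), 1L)
})

test_that("a feature-count mismatch is reported with both counts", {
  d <- separable_xy()
  ens <- train_forest_matrix(d$x, d$y, forest_config(scheme = scheme_fg()))
  stack <- mc_volume(list(a = array(0, c(4L, 4L, 4L))))
  expect_error(predict_probabilities(ens, stack), "expected 5.*got 1")
})

test_that("more scribbles do not hurt held-out accuracy on the phantom", {
  # statistical property over 5 seeds; allow one violation
  wins <- 0L
  for (s in 1:5) {
    spec <- small_spec(grid = 24L, seed = s)
    ph <- generate_phantom(spec, 0)
    st <- assemble_feature_stack(ph$image, feature_config(scales_vox = 1.0))
    m_small <- rater_model(boundary_jitter_sd = 0, scribble_fraction = 0.05,
                           min_scribbles_per_class = 5L, seed = s)
    m_big <- rater_model(boundary_jitter_sd = 0, scribble_fraction = 0.1,
                         min_scribbles_per_class = 10L, seed = s)
    acc <- vapply(list(m_small, m_big), function(m) {
      scr <- suppressMessages(extract_scribbles(ph$truth, m))
      ens <- train_forest_ensemble(st, scr,
                                   forest_config(scheme = spec$scheme, seed = s))
      seg <- argmax_labels(predict_probabilities(ens, st))
      mean(seg$labels == ph$truth$labels)
    }, numeric(1))
    if (acc[2] >= acc[1] - 0.01) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
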