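test_that("Dice follows its counting definition, is symmetric, and handles empties", {
  a <- array(FALSE, c(4L, 4L, 2L))
  b <- array(FALSE, c(4L, 4L, 2L))
  a[1:4] <- TRUE            # |A| = 4
  b[2:7] <- TRUE            # |B| = 6, |A&B| = 3
  expect_equal(dice(a, b), 2 * 3 / (4 + 6))
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, !a), 0.0)
  empty <- array(FALSE, dim(a))
  expect_equal(dice(empty, empty), 1.0)
  expect_error(dice(a, array(FALSE, c(4L, 4L, 3L))), "differ")
})

test_that("Pearson correlation matches the covariance-formula oracle to 1e-12", {
  set.seed(21)
  x <- rnorm(20)
  y <- 0.6 * x + rnorm(20)
  got <- pearson_cor(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r_oracle * sqrt((20 - 2) / (1 - r_oracle^2))
  p_oracle <- 2 * stats::pt(abs(tt), 18, lower.tail = FALSE)
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  expect_equal(got$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_cor(x, -x)$r, -1.0)
  expect_error(pearson_cor(x, rep(1, 20)), "variance")
  expect_error(pearson_cor(1:2, 2:3), "at least 3")
})

test_that("ICC(1) matches a from-scratch ANOVA decomposition", {
  tab <- matrix(c(9, 2, 5, 8,
                  2, 1, 2, 6,
                  5, 3, 6, 2,
                  8, 4, 2, 6), 4, 4)[, 1:2]
  got <- icc1_oneway(tab)
  # independent oracle: explicit sums of squares
  n <- nrow(tab); k <- ncol(tab)
  grand <- mean(tab)
  ss_total <- sum((tab - grand)^2)
  ss_between <- k * sum((rowMeans(tab) - grand)^2)
  ss_within <- ss_total - ss_between
  msb <- ss_between / (n - 1)
  msw <- ss_within / (n * (k - 1))
  expect_equal(got$icc, (msb - msw) / (msb + (k - 1) * msw), tolerance = 1e-12)
  expect_equal(got$p_value,
               stats::pf(msb / msw, n - 1, n * (k - 1), lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("ICC(1) is 1 for pure subject structure and near 0 for pure noise", {
  subj <- matrix(rep(rnorm(6, 0, 5), 3), 6, 3)
  expect_equal(icc1_oneway(subj)$icc, 1.0)
  set.seed(31)
  noise <- matrix(rnorm(100), 50, 2)
  expect_lt(abs(icc1_oneway(noise)$icc), 0.3)
  expect_error(icc1_oneway(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("ICC(1) approaches Pearson r for balanced equal-variance pairs", {
  set.seed(41)
  s <- rnorm(500, 0, 3)
  a <- s + rnorm(500)
  b <- s + rnorm(500)
  expect_lt(abs(icc1_oneway(cbind(a, b))$icc - pearson_cor(a, b)$r), 0.05)
})

test_that("Fisher's method matches its closed form and identities", {
  got <- fisher_combine(c(0.05, 0.05))
  x2 <- -2 * (log(0.05) + log(0.05))
  expect_equal(got$statistic, x2, tolerance = 1e-12)
  expect_equal(got$statistic, 11.98293, tolerance = 1e-6)
  expect_equal(got$p_value, stats::pchisq(x2, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(got$p_value, 0.01747866, tolerance = 1e-6)
  # k = 1: the chi-square(2) survival function inverts -2 log p exactly
  expect_equal(fisher_combine(0.37)$p_value, 0.37, tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1, 1))$statistic, 0)
  expect_equal(fisher_combine(c(1, 1, 1))$p_value, 1)
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("Fisher statistics add over independent blocks", {
  set.seed(51)
  p1 <- runif(4)
  p2 <- runif(3)
  expect_equal(fisher_combine(c(p1, p2))$statistic,
               fisher_combine(p1)$statistic + fisher_combine(p2)$statistic,
               tolerance = 1e-12)
})

test_that("class volumes and GTV follow the voxel-count definition", {
  truth <- generate_phantom(small_spec(), 0)$truth
  vols <- class_volumes(truth)
  # voxel-loop oracle
  for (i in seq_len(nrow(vols))) {
    n <- 0L
    for (v in as.vector(truth$labels)) if (v == vols$class_id[i]) n <- n + 1L
    expect_identical(vols$n_voxels[i], n)
  }
  expect_equal(attr(vols, "gtv_mm3"),
               sum(vols$volume_mm3[vols$name %in% c("NonEnhancing", "Enhancing")]))
  expect_equal(gtv_volume(truth), attr(vols, "gtv_mm3"))
  # empty tumor classes give zero GTV
  empty <- label_volume(array(1L, c(4L, 4L, 4L)), scheme_gb6())
  expect_equal(gtv_volume(empty), 0)
})

test_that("relative change series is exact arithmetic with a positive baseline", {
  expect_equal(relative_change_series(c(100, 125, 50)), c(0, 25, -50))
  expect_equal(relative_change_series(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(relative_change_series(c(10, 20)), c(0, 100))
  expect_error(relative_change_series(c(0, 10)), "baseline")
})

test_that("response classification uses inclusive cutoffs", {
  th <- response_thresholds()
  expect_identical(rano_classify(25, th), "progression")
  expect_identical(rano_classify(-50, th), "partial_response")
  expect_identical(rano_classify(10, th), "stable")
  expect_identical(rano_classify(24.999, th), "stable")
  expect_identical(rano_classify(c(-100, 0, 100), th),
                   c("partial_response", "stable", "progression"))
})

test_that("primary and alternative cutoffs disagree exactly on the documented bands", {
  th <- response_thresholds()
  grid <- seq(-100, 100, by = 0.5)
  main <- rano_classify(grid, th)
  alt <- rano_classify(grid, th, use_alt = TRUE)
  disagree <- grid[main != alt]
  expected <- grid[(grid >= 25 & grid < 40) | (grid > -65 & grid <= -50)]
  expect_identical(disagree, expected)
})

test_that("bidimensional measurement matches geometry on spheres and single voxels", {
  d <- c(28L, 28L, 28L)
  r <- 10
  cen <- c(14.5, 14.5, 14.5)
  sphere <- virtrater:::ellipsoid_field(d, cen, rep(r, 3)) <= 1
  got <- rano_product_2d(sphere)
  expect_lt(abs(got$product_mm2 - (2 * r)^2) / (2 * r)^2, 0.1)
  single <- array(FALSE, c(8L, 8L, 3L))
  single[4, 4, 2] <- TRUE
  got1 <- rano_product_2d(single)
  expect_equal(got1$d1_mm, 1)
  expect_equal(got1$d2_mm, 1)
  expect_equal(got1$product_mm2, 1)
  empty <- rano_product_2d(array(FALSE, c(4L, 4L, 4L)))
  expect_true(empty$empty)
  expect_equal(empty$product_mm2, 0)
})

test_that("bidimensional diameters agree with a brute-force all-pairs search", {
  set.seed(61)
  mask <- array(FALSE, c(20L, 20L, 3L))
  blob <- virtrater:::ellipsoid_field(c(20L, 20L, 1L), c(10, 9, 1), c(7, 4, 1)) <= 1
  mask[, , 2] <- blob[, , 1]
  got <- rano_product_2d(mask)
  pts <- which(mask[, , 2], arr.ind = TRUE)
  best_d1 <- 0; pair <- NULL
  for (i in seq_len(nrow(pts) - 1)) for (j in (i + 1):nrow(pts)) {
    len <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (len > best_d1) { best_d1 <- len; pair <- c(i, j) }
  }
  u <- (pts[pair[2], ] - pts[pair[1], ]) / best_d1
  best_d2 <- 0
  for (i in seq_len(nrow(pts) - 1)) for (j in (i + 1):nrow(pts)) {
    dv <- pts[j, ] - pts[i, ]
    len <- sqrt(sum(dv^2))
    if (len > 0 && abs(sum(dv * u)) / len <= sin(5 * pi / 180))
      best_d2 <- max(best_d2, len)
  }
  expect_equal(got$d1_mm, best_d1 + 1, tolerance = 1e-9)
  expect_equal(got$d2_mm, max(best_d2 + 1, 1), tolerance = 1e-9)
})
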