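test_that("noise-free phantom reproduces class means exactly and enhancement is rim-only", {
  spec <- small_spec(noise_sd = 0, bias_amplitude = 0)
  spec$intensity_model$sd <- 0
  ph <- generate_phantom(spec, 0)
  im <- spec$intensity_model
  for (r in seq_len(nrow(im))) {
    cid <- class_ids(spec$scheme)[class_names(spec$scheme) == im$name[r]]
    m <- ph$truth$labels == cid
    if (!any(m)) next
    expect_equal(unique(as.vector(ph$image$channels[[im$channel[r]]][m])),
                 im$mean[r], info = paste(im$name[r], im$channel[r]))
  }
  # ceT1w exceeds nT1w only inside the enhancing rim
  diffc <- ph$image$channels$ceT1w - ph$image$channels$nT1w
  enh <- ph$truth$labels == 5L
  expect_true(all(diffc[enh] > 0))
  expect_true(all(diffc[!enh] == 0))
})

test_that("growth scales the GTV like the cube of the radial factor", {
  spec <- phantom_spec(grid_shape = c(40L, 40L, 40L),
                       tumor_radii = c(NonEnhancing = 3, Enhancing = 6, Edema = 8),
                       growth_factor = 1.2, n_timepoints = 2L)
  g0 <- sum(gtv_mask(generate_phantom(spec, 0)$truth))
  g1 <- sum(gtv_mask(generate_phantom(spec, 1)$truth))
  expect_lt(abs(g1 / g0 - 1.2^3), 0.05 * 1.2^3)
})

test_that("growth factor 1 keeps labels identical across timepoints", {
  spec <- small_spec(n_timepoints = 3L)
  spec$growth_factor <- 1.0
  labs <- lapply(0:2, function(t) generate_phantom(spec, t)$truth$labels)
  expect_identical(labs[[1]], labs[[2]])
  expect_identical(labs[[1]], labs[[3]])
})

test_that("phantom generation is deterministic and errors on out-of-grid geometry", {
  spec <- small_spec()
  a <- generate_phantom(spec, 0)
  b <- generate_phantom(spec, 0)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$labels, b$truth$labels)
  bad <- phantom_spec(grid_shape = c(16L, 16L, 16L),
                      tumor_radii = c(NonEnhancing = 4, Enhancing = 8,
                                      Edema = 14))
  expect_error(generate_phantom(bad, 0), "exceeds the grid bounds")
})

test_that("ground-truth class volumes match analytic ellipsoid volumes", {
  spec <- phantom_spec(grid_shape = c(40L, 40L, 40L),
                       tumor_radii = c(NonEnhancing = 5, Enhancing = 8,
                                       Edema = 11))
  truth <- generate_phantom(spec, 0)$truth
  ball <- function(r) 4 / 3 * pi * r^3
  gtv <- sum(gtv_mask(truth))
  expect_lt(abs(gtv - ball(8)) / ball(8), 0.05)
  edema <- sum(truth$labels == 3L)
  expect_lt(abs(edema - (ball(11) - ball(8))) / (ball(11) - ball(8)), 0.05)
})

test_that("enhancement stays detectable above the noise floor", {
  spec <- small_spec(bias_amplitude = 0)
  ph <- generate_phantom(spec, 0)
  enh <- ph$truth$labels == 5L
  diffc <- ph$image$channels$ceT1w - ph$image$channels$nT1w
  expect_gt(mean(diffc[enh]), 3 * spec$noise_sd[1])
})

test_that("a perfect rater reproduces the truth voxel for voxel", {
  truth <- generate_phantom(small_spec(), 0)$truth
  perfect <- rater_model(boundary_bias_vox = 0, boundary_jitter_sd = 0,
                         confusion = NULL)
  expect_identical(simulate_rater(truth, perfect)$labels, truth$labels)
})

test_that("a positive boundary bias dilates the edema region", {
  truth <- generate_phantom(small_spec(), 0)$truth
  biased <- rater_model(boundary_bias_vox = 1, boundary_jitter_sd = 0,
                        perturb_classes = "Edema")
  out <- simulate_rater(truth, biased)
  expect_gt(sum(out$labels == 3L), sum(truth$labels == 3L))
})

test_that("raters with different seeds disagree", {
  truth <- generate_phantom(small_spec(), 0)$truth
  m <- rater_model(boundary_jitter_sd = 0.5)
  a <- simulate_rater(truth, m)
  m$seed <- 2L
  b <- simulate_rater(truth, m)
  expect_lt(dice(gtv_mask(a), gtv_mask(b)), 1.0)
})

test_that("rater simulation is deterministic given its seed", {
  truth <- generate_phantom(small_spec(), 0)$truth
  m <- rater_model(boundary_jitter_sd = 0.5, confusion = list(Edema = c(Rest = 0.3)))
  expect_identical(simulate_rater(truth, m)$labels,
                   simulate_rater(truth, m)$labels)
})

test_that("scribbles are interior, consistent with the dense labels, and exactly counted", {
  dense <- generate_phantom(small_spec(grid = 24L), 0)$truth
  m <- rater_model(scribble_fraction = 0.3, min_scribbles_per_class = 1L)
  scr <- suppressMessages(extract_scribbles(dense, m))
  # subset property: every scribble matches the dense label at its voxel
  lin <- 1L + scr$x + 24L * (scr$y + 24L * scr$z)
  expect_identical(dense$labels[lin], scr$class_id)
  # interior property: scribbles never touch class boundaries
  for (cid in unique(scr$class_id)) {
    er <- virtrater:::binary_erode1(dense$labels == cid)
    expect_true(all(er[lin[scr$class_id == cid]]))
  }
  # exact per-class counts: floor(fraction * eroded size), floored at minimum
  for (cid in unique(scr$class_id)) {
    n_er <- sum(virtrater:::binary_erode1(dense$labels == cid))
    expect_identical(sum(scr$class_id == cid),
                     as.integer(min(n_er, max(floor(0.3 * n_er), 1L))))
  }
})

test_that("full-fraction scribbles equal the whole eroded region", {
  dense <- generate_phantom(small_spec(), 0)$truth
  m <- rater_model(scribble_fraction = 1.0, min_scribbles_per_class = 1L)
  scr <- suppressMessages(extract_scribbles(dense, m))
  for (cid in class_ids(dense$scheme)) {
    n_er <- sum(virtrater:::binary_erode1(dense$labels == cid))
    expect_identical(sum(scr$class_id == cid), n_er)
  }
})

test_that("cohort manifest counts follow patients x timepoints x raters x runs", {
  spec <- small_spec(n_timepoints = 3L)
  d <- withr::local_tempdir()
  man <- generate_cohort(spec, 2L, default_rater_pair(), 2L,
                         out_dir = file.path(d, "cohort"))
  expect_identical(sum(man$kind == "image"), 2L * 3L)
  expect_identical(sum(man$kind == "dense"), 2L * 3L * 2L * 2L)
  expect_identical(sum(man$kind == "scribbles"), 2L * 3L * 2L * 2L)
})

test_that("an empty rater list yields an image-only cohort", {
  spec <- small_spec()
  d <- withr::local_tempdir()
  man <- generate_cohort(spec, 2L, list(), 2L, out_dir = file.path(d, "c"))
  expect_true(all(man$kind %in% c("image", "truth")))
})

test_that("regenerating a cohort is byte-identical and overwrite needs force", {
  spec <- small_spec()
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a"); p2 <- file.path(d, "b")
  generate_cohort(spec, 2L, default_rater_pair(), 1L, out_dir = p1)
  generate_cohort(spec, 2L, default_rater_pair(), 1L, out_dir = p2)
  h1 <- tools::md5sum(file.path(p1, sort(dir(p1))))
  h2 <- tools::md5sum(file.path(p2, sort(dir(p2))))
  expect_identical(unname(h1), unname(h2))
  expect_error(generate_cohort(spec, 2L, list(), 1L, out_dir = p1),
               "force")
})
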