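# Minimal hand-built cohort: scribble counts are what matters, not images.
toy_cohort <- function(n_patients = 2L, n_timepoints = 1L,
                       raters = c("R1", "R2"), runs = 2L,
                       scribbles_per_record = 10L) {
  sch <- scheme_fg()
  studies <- list()
  anns <- list()
  for (p in seq_len(n_patients)) {
    for (t in 0:(n_timepoints - 1L)) {
      studies[[length(studies) + 1L]] <-
        tibble::tibble(patient = p, timepoint = t, image = list(NULL),
                       truth = list(NULL))
      for (r in raters) for (k in seq_len(runs)) {
        scr <- tibble::tibble(x = seq_len(scribbles_per_record) - 1L,
                              y = 0L, z = 0L,
                              class_id = rep_len(c(0L, 1L),
                                                 scribbles_per_record))
        anns[[length(anns) + 1L]] <-
          tibble::tibble(patient = p, timepoint = t, rater = r, run = k,
                         dense = list(NULL), scribbles = list(scr))
      }
    }
  }
  structure(list(spec = NULL, seed = 1L, scheme = sch,
                 studies = dplyr::bind_rows(studies),
                 annotations = dplyr::bind_rows(anns)),
            class = "vr_cohort")
}

test_that("the training pool is the union of history plus the current rater's runs", {
  co <- toy_cohort(n_patients = 2L, raters = c("R1", "R2"), runs = 2L,
                   scribbles_per_record = 10L)
  pool <- assemble_training_pool(co, held_out_patient = 1L,
                                 current_rater = "R1")
  # other patient: 2 raters x 2 runs x 10 = 40; held-out: R1's 2 runs = 20
  expect_identical(nrow(pool), 60L)
  expect_identical(sum(pool$patient == 2L), 40L)
  expect_true(all(pool$rater[pool$patient == 1L] == "R1"))
})

test_that("pools for different current raters differ only on the held-out patient", {
  co <- toy_cohort()
  p1 <- assemble_training_pool(co, 1L, "R1")
  p2 <- assemble_training_pool(co, 1L, "R2")
  expect_identical(p1[p1$patient == 2L, ], p2[p2$patient == 2L, ])
  expect_true(all(p1$rater[p1$patient == 1L] == "R1"))
  expect_true(all(p2$rater[p2$patient == 1L] == "R2"))
})

test_that("pool assembly enforces its preconditions", {
  co <- toy_cohort()
  expect_error(assemble_training_pool(co, 1L, "R9"), "R9")
  solo <- toy_cohort()
  solo$studies <- solo$studies[solo$studies$patient == 1L, ]
  solo$annotations <- solo$annotations[solo$annotations$patient == 1L, ]
  expect_error(assemble_training_pool(solo, 1L, "R1"), "single-patient")
})

test_that("dense subsampling honors the 200/1000 caps", {
  sch <- scheme_fg()
  labs <- array(0L, c(20L, 20L, 20L)) # 8000 - 5000 = 3000 background
  labs[seq_len(5000)] <- 1L           # 5000 tumor voxels
  lv <- label_volume(labs, sch)
  scr <- subsample_dense_labels(lv, pooling_config())
  expect_identical(sum(scr$class_id == 1L), 200L)
  expect_identical(sum(scr$class_id == 0L), 1000L)
  # caps above supply: everything is taken
  small <- array(0L, c(8L, 8L, 8L))
  small[seq_len(150)] <- 1L
  scr2 <- subsample_dense_labels(label_volume(small, sch), pooling_config())
  expect_identical(sum(scr2$class_id == 1L), 150L)
  expect_identical(sum(scr2$class_id == 0L), 362L)
  # subset property: sampled voxels carry their dense label
  lin <- 1L + scr$x + 20L * (scr$y + 20L * scr$z)
  expect_identical(lv$labels[lin], scr$class_id)
})

test_that("pooled-set caps downsample per class deterministically", {
  pool <- tibble::tibble(patient = 1L, timepoint = 0L, rater = "R1", run = 1L,
                         x = seq_len(3000) - 1L, y = 0L, z = 0L,
                         class_id = rep_len(c(0L, 1L), 3000))
  cfg <- pooling_config(seed = 3L)
  out <- subsample_training_pool(pool, scheme_fg(), cfg)
  expect_identical(sum(out$class_id == 0L), 1000L)
  expect_identical(sum(out$class_id == 1L), 200L)
  expect_identical(out, subsample_training_pool(pool, scheme_fg(), cfg))
})

test_that("instance dropout keeps each record independently with probability P", {
  recs <- tibble::tibble(id = 1:4)
  expect_identical(dropout_segmentations(recs, dropout_config(1)), recs)
  kept <- vapply(1:2000, function(i)
    nrow(dropout_segmentations(recs, dropout_config(0.75, seed = i))),
    numeric(1))
  expect_lt(abs(mean(kept) - 3), 0.1)
  kept25 <- vapply(1:2000, function(i)
    nrow(dropout_segmentations(recs, dropout_config(0.25, seed = i))),
    numeric(1))
  expect_lt(abs(mean(kept25) - 1), 0.1)
  # deterministic given the seed
  expect_identical(dropout_segmentations(recs, dropout_config(0.5, seed = 7L)),
                   dropout_segmentations(recs, dropout_config(0.5, seed = 7L)))
})

test_that("leave-one-patient-out yields one report row per patient and timepoint", {
  spec <- small_spec(n_timepoints = 2L, grid = 24L)
  spec$tumor_radii <- c(NonEnhancing = 2, Enhancing = 4, Edema = 5.5)
  co <- simulate_cohort(spec, 3L, default_rater_pair(), 2L)
  vr <- run_virtual_rater_lopo(co, "R1",
                               feat_config = feature_config(scales_vox = 1.0),
                               post_params = postprocess_params(min_component_vox = 20L))
  expect_identical(nrow(vr$report), 3L * 2L)
  expect_identical(nrow(vr$segmentations), 3L * 2L)
  expect_true(all(vr$report$rater == "VR_R1"))
  expect_true(all(vr$report$gtv_mm3 > 0))
  vr2 <- run_virtual_rater_lopo(co, "R2",
                                feat_config = feature_config(scales_vox = 1.0),
                                post_params = postprocess_params(min_component_vox = 20L))
  # two VRs trained on different pools do not produce identical predictions
  same <- mapply(function(a, b) identical(a$labels, b$labels),
                 vr$segmentations$seg, vr2$segmentations$seg)
  expect_false(all(same))
})

test_that("a perfect-rater noise-free cohort yields a near-truth virtual rater", {
  # Easy regime: noise-free channels, unbiased raters.  Scribbles are
  # interior-only by design, so the classifier never sees boundary voxels;
  # at 32-voxel resolution that caps GTV Dice around one voxel of boundary
  # uncertainty (~0.05), hence the 0.9 floor rather than 1.0.
  spec <- phantom_spec(noise_sd = 0, bias_amplitude = 0)
  perfect <- rater_model(boundary_bias_vox = 0, boundary_jitter_sd = 0,
                         scribble_fraction = 0.2)
  co <- simulate_cohort(spec, 2L, list(R1 = perfect, R2 = perfect), 1L)
  vr <- run_virtual_rater_lopo(co, "R1",
                               post_params = postprocess_params(min_component_vox = 50L))
  dd <- vapply(seq_len(nrow(vr$segmentations)), function(i) {
    p <- vr$segmentations$patient[i]
    t <- vr$segmentations$timepoint[i]
    truth <- co$studies$truth[[which(co$studies$patient == p &
                                       co$studies$timepoint == t)]]
    dice(gtv_mask(vr$segmentations$seg[[i]]), gtv_mask(truth))
  }, numeric(1))
  expect_true(all(dd > 0.9))
  expect_gt(mean(dd), 0.93)
})
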