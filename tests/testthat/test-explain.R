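small_config <- function() {
  model_config(filters = c(8L, 12L, 16L), emb_dim = 4L, head_width = 32L,
               conv_dropout = 0.1, head_dropout = 0.2)
}

trained_small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- small_mixed_dataset(n_subjects = 10, target = 8)
      split <- make_inner_split(ds, seed = 2)
      cache <<- list(
        model = train_cnn(subset_dataset(ds, split$train_indices),
                          subset_dataset(ds, split$val_indices),
                          small_config(),
                          train_config(max_epochs = 6, patience = 3,
                                       batch_size = 16, seed = 4)),
        data = ds,
        train_idx = split$train_indices
      )
    }
    cache
  }
})

test_that("attributions satisfy the additivity identity", {
  tr <- trained_small_model()
  bg <- subset_dataset(tr$data, tr$train_idx[1:20])
  for (i in c(3, 17, 40)) {
    s <- get_sample(tr$data, i)
    att <- compute_attribution(tr$model, s, bg)
    total <- sum(att$attr) + att$side_attr
    delta <- att$fx - att$baseline
    expect_equal(total, delta, tolerance = 0.01 * max(abs(delta), 1e-3))
  }
})

test_that("attribution mass follows the features that differ", {
  tr <- trained_small_model()
  s <- get_sample(tr$data, 5)
  # references identical to the sample except one pixel: all attribution
  # mass must sit on that pixel (plus the side embedding term)
  g2 <- s$grid
  g2[10, 12] <- min(1, g2[10, 12] + 0.5)
  refs <- as_pressure_dataset(list(
    pressure_sample(g2, "ref1", s$subject_id, s$side, s$condition)
  ))
  att <- compute_attribution(tr$model, s, refs, target_class = 0L)
  off <- att$attr
  off[10, 12] <- 0
  expect_equal(max(abs(off)), 0, tolerance = 1e-10)
  expect_equal(att$side_attr, 0, tolerance = 1e-10)

  # identical reference: a zero explanation
  same <- as_pressure_dataset(list(
    pressure_sample(s$grid, "ref2", s$subject_id, s$side, s$condition)
  ))
  att0 <- compute_attribution(tr$model, s, same, target_class = 0L)
  expect_equal(max(abs(att0$attr)), 0, tolerance = 1e-10)
  expect_error(
    compute_attribution(tr$model, s, as_pressure_dataset(list())),
    "empty"
  )
})

test_that("thresholding zeroes sub-threshold values and is idempotent", {
  a <- matrix(0, 64, 64)
  a[1, 1] <- 1; a[2, 2] <- 0.19; a[3, 3] <- -0.5
  cfg <- render_config(bilateral_sigma_s = 0.3, bilateral_d = 1)
  out <- threshold_and_smooth(a, cfg)
  expect_equal(out[2, 2], 0)
  expect_true(out[1, 1] > 0)
  expect_true(out[3, 3] < 0)
  # identity settings leave the input unchanged
  id_cfg <- render_config(threshold_fraction = 0, bilateral_d = 1,
                          bilateral_sigma_r = 1e6, bilateral_sigma_s = 1e6)
  expect_equal(threshold_and_smooth(a, id_cfg), a, tolerance = 1e-6)
  # all-zero map returned unchanged
  z <- matrix(0, 64, 64)
  expect_identical(threshold_and_smooth(z, cfg), z)
  # uniform map survives thresholding entirely
  u <- matrix(0.4, 64, 64)
  expect_equal(threshold_and_smooth(u, id_cfg), u, tolerance = 1e-6)
  # smoothing stays local: no new values beyond the filter radius
  spread <- threshold_and_smooth(a, render_config(bilateral_d = 5))
  far <- spread
  far[1:6, 1:6] <- 0; far[1:6, 64] <- 0
  expect_equal(sum(abs(far[10:60, 10:60])), 0)
})

test_that("the triptych renders three panels to a file", {
  skip_if_not(capabilities("png"), "no png device available")
  tr <- trained_small_model()
  s <- get_sample(tr$data, 3)
  bg <- subset_dataset(tr$data, tr$train_idx[1:10])
  att <- compute_attribution(tr$model, s, bg)
  # a minimal spm decision fixture with one significant cluster
  mask_px <- cbind(30:34, 30:34)
  dec <- structure(
    list(pmap = matrix(1, 64, 64),
         clusters = list(list(pixels = mask_px, size = 5L)),
         fwe_threshold = 0L,
         significant = list(list(pixels = mask_px, size = 5L)),
         is_outlier = TRUE),
    class = "spm_decision"
  )
  path <- file.path(tempdir(), "triptych.png")
  on.exit(unlink(path))
  render_triptych(s, dec, att, path, cnn_label = 0L)
  expect_true(file.exists(path))
  expect_gt(file.info(path)$size, 1000)
  # no-cluster decision renders without a contour (and without error)
  dec0 <- dec
  dec0$significant <- list()
  dec0$is_outlier <- FALSE
  path2 <- file.path(tempdir(), "triptych0.png")
  on.exit(unlink(path2), add = TRUE)
  render_triptych(s, dec0, att, path2, survey_parity = TRUE, cnn_label = 3L)
  expect_true(file.exists(path2))
})
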