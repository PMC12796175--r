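test_that("valid-foot simulation is deterministic, mirrored and foot-like", {
  p <- foot_shape_params(seed = 7)
  a <- simulate_valid_foot(p, "L", "S1", seed = 11)
  b <- simulate_valid_foot(p, "L", "S1", seed = 11)
  expect_identical(a$grid, b$grid)

  p0 <- foot_shape_params(seed = 7, noise_sd = 0)
  l <- simulate_valid_foot(p0, "L", "S1", seed = 3)
  r <- simulate_valid_foot(p0, "R", "S1", seed = 3)
  expect_equal(l$grid, r$grid[, 64:1], tolerance = 1e-12)

  # support fraction and connectedness across subjects
  fr <- vapply(1:15, function(i) {
    s <- make_valid(i)
    mask <- s$grid > 0.05
    ncomp <- max(oracle_components(mask, 8))
    expect_equal(ncomp, 1)
    mean(mask)
  }, numeric(1))
  expect_true(all(fr >= 0.10 & fr <= 0.50))
})

test_that("general-error crops zero the stated row bands exactly", {
  s <- make_valid(21)
  ff <- make_general_error(s, "forefoot", fraction = 0.50)
  expect_true(all(ff$grid[1:32, ] == 0))
  expect_identical(ff$grid[33:64, ], s$grid[33:64, ])
  expect_equal(ff$label, 1L)
  expect_equal(ff$side, s$side)
  expect_equal(ff$source_ids, s$sample_id)

  # heel crop at 0.65 keeps the top 22 rows (64 - ceiling(0.65 * 64))
  hl <- make_general_error(s, "heel", fraction = 0.65)
  keep <- 64 - ceiling(0.65 * 64)
  expect_equal(keep, 22)
  expect_identical(hl$grid[seq_len(keep), ], s$grid[seq_len(keep), ])
  expect_true(all(hl$grid[(keep + 1):64, ] == 0))

  # sampled fractions stay inside the stated bands
  fr_ff <- vapply(1:300, function(i) {
    g <- make_general_error(s, "forefoot", seed = i)$grid
    max(which(rowSums(g) == 0 & seq_len(64) <= 40)) / 64
  }, numeric(1))
  expect_true(all(fr_ff >= ceiling(0.45 * 64) / 64 - 1e-9))
  expect_true(all(fr_ff <= ceiling(0.55 * 64) / 64 + 1e-9))

  # fewer non-zero pixels than the source, other classes preserve counts
  expect_lt(sum(ff$grid > 0), sum(s$grid > 0))
  expect_error(make_general_error(ff, "forefoot"), "valid")
})

test_that("double-foot composites sit in opposite quadrants", {
  l <- make_valid(31, side = "L", subject = "SD")
  r <- make_valid(32, side = "R", subject = "SD")
  df <- make_double_foot(l, r, config = "LR",
                         jitter = matrix(0, 2, 2), id = "df0")
  expect_equal(df$label, 2L)
  expect_equal(df$subject_id, "SD")
  expect_setequal(df$source_ids, c(l$sample_id, r$sample_id))
  nz <- which(df$grid > 0, arr.ind = TRUE)
  in_ul <- nz[, 1] <= 32 & nz[, 2] <= 32
  in_lr <- nz[, 1] >= 33 & nz[, 2] >= 33
  expect_true(all(in_ul | in_lr))

  # jittered tiles stay within the quadrants dilated by 2 px and the
  # support centroid moves at most 2 px per tile
  base_ul <- colMeans(which(df$grid > 0 & row(df$grid) <= 32 &
                              col(df$grid) <= 32, arr.ind = TRUE))
  for (seed in 1:25) {
    dj <- make_double_foot(l, r, seed = seed, config = "LR", id = "dfj")
    nzj <- which(dj$grid > 0, arr.ind = TRUE)
    expect_true(all((nzj[, 1] <= 34 & nzj[, 2] <= 34) |
                      (nzj[, 1] >= 31 & nzj[, 2] >= 31)))
    ul <- which(dj$grid > 0 & row(dj$grid) <= 34 & col(dj$grid) <= 34,
                arr.ind = TRUE)
    expect_lte(max(abs(colMeans(ul) - base_ul)), 2 + 0.3)
  }

  # random side assignment is roughly balanced
  sides <- vapply(1:400, function(i) {
    make_double_foot(l, r, seed = 1000 + i, id = "x")$side
  }, character(1))
  bt <- binom.test(sum(sides == "L"), length(sides), 0.5)
  expect_gt(bt$p.value, 0.01)

  expect_error(make_double_foot(l, make_valid(33, side = "R", subject = "SX")),
               "same subject")
  expect_error(make_double_foot(r, r), "left and a right")
})

test_that("inversion is an involution that preserves column sums", {
  s <- make_valid(41)
  inv <- make_inverted(s)
  expect_equal(inv$label, 3L)
  expect_equal(inv$side, s$side)
  expect_identical(make_inverted(plantarqc:::new_derived(
    inv$grid, s, 0L, "tmp", provenance = "synthetic"
  ))$grid, s$grid)
  expect_equal(colSums(inv$grid), colSums(s$grid))
  expect_equal(sum(inv$grid > 0), sum(s$grid > 0))

  one <- matrix(0, 64, 64); one[1, 11] <- 1
  os <- pressure_sample(one, "pix", "s", "L")
  expect_equal(which(make_inverted(os)$grid > 0, arr.ind = TRUE)[1, ],
               c(row = 64, col = 11))

  # rot180 mode additionally mirrors columns
  rot <- make_inverted(s, inversion_mode = "rot180")
  expect_identical(rot$grid, s$grid[64:1, 64:1])
})

test_that("side swap toggles laterality only", {
  s <- make_valid(51, side = "L")
  sw <- make_side_swap(s)
  expect_identical(sw$grid, s$grid)
  expect_equal(sw$side, "R")
  expect_equal(sw$label, 4L)
  back <- make_side_swap(plantarqc:::new_derived(
    sw$grid, s, 0L, "tmp2", side = sw$side, provenance = "synthetic"
  ))
  expect_equal(back$side, s$side)
})

test_that("priority rule demotes the side-annotation label", {
  expect_equal(apply_priority_rule(c(4, 1)), 1L)
  expect_equal(apply_priority_rule(c(0, 4, 3)), 3L)
  expect_equal(apply_priority_rule(4), 4L)
  expect_equal(apply_priority_rule(c(0, 4)), 4L)
  expect_equal(apply_priority_rule(0), 0L)
  expect_error(apply_priority_rule(c(1, 2)), "ambiguous")
  expect_error(apply_priority_rule(integer(0)), "non-empty")
})

test_that("augmentation reaches the per-category target exactly", {
  ds <- simulate_dataset(n_subjects = 10, seed = 5, target = NULL)
  expect_equal(unname(counts_by_label(ds)), c(40L, 0L, 0L, 0L, 0L))
  aug <- augment_to_target(ds, target = 12, seed = 2)
  expect_equal(unname(counts_by_label(aug)), c(40L, 12L, 12L, 12L, 12L))
  # valid samples untouched
  expect_identical(aug$grids[1:40, , ], ds$grids)
  # synthetic samples inherit a source subject present in the dataset
  syn <- aug$manifest[aug$manifest$provenance == "synthetic", ]
  expect_true(all(syn$subject_id %in% ds$manifest$subject_id))
  expect_true(all(nzchar(syn$source_ids)))
  # target equal to existing count adds nothing
  again <- augment_to_target(aug, target = 12, seed = 3)
  expect_identical(again$manifest, aug$manifest)
  expect_error(augment_to_target(aug, target = 5), "below")
})

test_that("generators leave their inputs untouched and are seed-stable", {
  s1 <- make_valid(61)
  before <- s1$grid
  invisible(make_general_error(s1, "forefoot", seed = 1))
  invisible(make_inverted(s1))
  invisible(make_side_swap(s1))
  expect_identical(s1$grid, before)
  a <- make_general_error(s1, "heel", seed = 42)
  b <- make_general_error(s1, "heel", seed = 42)
  expect_identical(a$grid, b$grid)
})
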