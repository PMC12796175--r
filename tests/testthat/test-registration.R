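test_that("apply_affine implements the documented transform", {
  g <- make_valid(1)$grid
  expect_equal(apply_affine(g, affine_params()), g)
  expect_equal(apply_affine(matrix(0, 64, 64), affine_params(17, 3, -2, 1.1)),
               matrix(0, 64, 64))
  # pure integer shift moves a single pixel exactly
  one <- matrix(0, 64, 64); one[20, 30] <- 1
  sh <- apply_affine(one, affine_params(0, 3, 0, 1))
  expect_equal(which(sh == max(sh), arr.ind = TRUE)[1, ],
               c(row = 23, col = 30))
  expect_equal(max(sh), 1)
})

test_that("compute_iou counts binarized overlap", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  b <- matrix(0, 4, 4); b[2:3, 1:2] <- 0.5
  expect_equal(compute_iou(a, a), 1)
  expect_equal(compute_iou(a, matrix(0, 4, 4)), 0)
  expect_equal(compute_iou(a, b), 2 / 6)
  expect_equal(compute_iou(matrix(0, 2, 2), matrix(0, 2, 2)), 0)
  expect_error(compute_iou(a, matrix(0, 3, 3)), "shape")
})

test_that("build_reference centroid-aligns and averages valid maps", {
  s <- make_valid(5)
  ds1 <- as_pressure_dataset(list(s))
  tpl <- build_reference(ds1, "L")
  expect_equal(tpl$n_contributors, 1)
  expect_equal(max(tpl$grid), 1)

  # two identical samples give the same template as one
  s2 <- s; s2$sample_id <- "dup"
  tpl2 <- build_reference(as_pressure_dataset(list(s, s2)), "L")
  expect_equal(tpl2$grid, tpl$grid)

  # two single-pixel grids collapse onto the canvas centre
  g1 <- matrix(0, 64, 64); g1[11, 11] <- 1
  g2 <- matrix(0, 64, 64); g2[21, 21] <- 1
  px <- as_pressure_dataset(list(
    pressure_sample(g1, "p1", "sa", "L"),
    pressure_sample(g2, "p2", "sb", "L")
  ))
  tp <- build_reference(px, "L")
  nz <- which(tp$grid > 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 1)
  # canvas centre 31.5 (0-based); half-integer shifts round to pixel 33
  expect_equal(unname(nz[1, ]), c(33, 33))
  expect_equal(max(tp$grid), 1)

  expect_error(build_reference(ds1, "R"), "no valid samples")
})

test_that("registration recovers known transforms and never worsens MSE", {
  ds <- as_pressure_dataset(lapply(1:8, make_valid, side = "L"))
  tpl <- build_reference(ds, "L")

  # fixed-point: registering the template to itself is near-identity
  fix <- register_map(tpl$grid, tpl)
  expect_lt(abs(fix$params[["angle"]]), 0.5)
  expect_lt(abs(fix$params[["shift_rows"]]), 0.5)
  expect_lt(abs(fix$params[["shift_cols"]]), 0.5)
  expect_lt(abs(fix$params[["zoom"]] - 1), 0.01)
  expect_lt(fix$final_mse, 1e-6)
  expect_gt(fix$iou, 0.99)

  # inverse recovery of a pure shift
  sh <- apply_affine(tpl$grid, affine_params(0, 4, -3, 1))
  rec <- register_map(sh, tpl)
  expect_lt(abs(rec$params[["shift_rows"]] + 4), 0.5)
  expect_lt(abs(rec$params[["shift_cols"]] - 3), 0.5)

  # inverse recovery of rotation + zoom
  rz <- apply_affine(tpl$grid, affine_params(10, 0, 0, 1.1))
  rec2 <- register_map(rz, tpl)
  expect_lt(abs(rec2$params[["angle"]] + 10), 1)
  expect_lt(abs(rec2$params[["zoom"]] - 1 / 1.1), 0.02)

  # returned MSE never exceeds the identity objective
  for (i in 1:5) {
    pert <- apply_affine(ds$grids[i, , ],
                         affine_params(runif(1, -15, 15), runif(1, -5, 5),
                                       runif(1, -5, 5), runif(1, 0.9, 1.15)))
    res <- register_map(pert, tpl)
    id_mse <- mean((pert - tpl$grid)^2)
    expect_lte(res$final_mse, id_mse + 1e-12)
  }
})

test_that("parameter recovery succeeds on nearly all random transforms", {
  set.seed(404)
  ds <- as_pressure_dataset(lapply(1:10, make_valid, side = "L"))
  tpl <- build_reference(ds, "L")
  n_trials <- 40
  ok <- 0
  for (i in seq_len(n_trials)) {
    th <- affine_params(runif(1, -15, 15), runif(1, -6, 6),
                        runif(1, -6, 6), runif(1, 0.88, 1.14))
    pert <- apply_affine(tpl$grid, th)
    rec <- register_map(pert, tpl)
    # the recovered transform composed with the known forward transform
    # must cancel: angle within 1 degree, zoom within 0.02, and the
    # composed displacement of the canvas centre within 0.5 px
    ang_ok <- abs(rec$params[["angle"]] + th[["angle"]]) <= 1
    zoom_ok <- abs(rec$params[["zoom"]] * th[["zoom"]] - 1) <= 0.02
    a2 <- rec$params[["angle"]] * pi / 180
    rot2 <- matrix(c(cos(a2), sin(a2), -sin(a2), cos(a2)), 2, 2)
    d <- rec$params[["zoom"]] * rot2 %*%
      c(th[["shift_rows"]], th[["shift_cols"]]) +
      c(rec$params[["shift_rows"]], rec$params[["shift_cols"]])
    shift_ok <- sqrt(sum(d^2)) <= 0.5
    if (ang_ok && zoom_ok && shift_ok) ok <- ok + 1
  }
  expect_gte(ok / n_trials, 0.95)
})
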