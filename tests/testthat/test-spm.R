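test_that("pixel p-values match brute-force counting", {
  # worked cases
  expect_equal(pixel_pvalue(2, 1:99 / 100), 0.02)       # above all 99 values
  expect_equal(pixel_pvalue(3, c(1, 2, 3, 4, 5)), 1)    # central value capped
  expect_equal(pixel_pvalue(0, rep(0, 50)), 1)          # background ties
  # random instances against the enumeration oracle
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    x <- round(runif(n), 2)
    t <- round(runif(1), 2)
    expect_equal(pixel_pvalue(t, x), oracle_pvalue(t, x))
  }
  expect_error(pixel_pvalue(1, numeric(0)), "empty")
})

make_model <- function(n = 30, side = "L") {
  ds <- as_pressure_dataset(lapply(seq_len(n), make_valid, side = side))
  normative_model(ds, side, min_n = 2)
}

test_that("compute_pmap scores every pixel including background", {
  model <- make_model(25)
  n <- model$n
  # a cohort member is heavily tied: p bounded below by 2/(n+1) and the
  # pmap agrees with the per-pixel oracle
  g <- matrix(model$cohort[3, ], 64, 64)
  pm <- compute_pmap(g, model)
  expect_true(all(pm >= 2 / (n + 1) - 1e-12))
  idx <- sample(4096, 50)
  for (j in idx) {
    expect_equal(as.numeric(pm)[j], oracle_pvalue(model$cohort[3, j],
                                                  model$cohort[, j]))
  }
  # pressure where the cohort is always zero hits the minimum p exactly
  bg <- which(apply(model$cohort, 2, max) == 0)[1]
  g2 <- matrix(0.001, 64, 64)
  pm2 <- compute_pmap(g2, model)
  expect_equal(as.numeric(pm2)[bg], 2 / (n + 1))
  expect_error(compute_pmap(g, model, side = "R"), "side")
})

test_that("find_clusters matches a connected-components oracle", {
  pm <- matrix(1, 4, 4)
  pm[1, 1] <- pm[1, 2] <- pm[2, 2] <- 0.001
  pm[4, 4] <- 0.001
  pad <- matrix(1, 64, 64); pad[1:4, 1:4] <- pm
  cl <- find_clusters(pad, 0.05, min_cluster = 0, connectivity = 8)
  expect_setequal(vapply(cl, `[[`, 0L, "size"), c(3L, 1L))
  cl2 <- find_clusters(pad, 0.05, min_cluster = 2, connectivity = 8)
  expect_equal(vapply(cl2, `[[`, 0L, "size"), 3L)

  # diagonal pair: connectivity decides
  dg <- matrix(1, 64, 64); dg[10, 10] <- dg[11, 11] <- 1e-4
  expect_length(find_clusters(dg, 0.05, 0, 4), 2)
  expect_length(find_clusters(dg, 0.05, 0, 8), 1)

  # random masks against the flood-fill oracle
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(runif(64 * 64), 64, 64)
    for (conn in c(4L, 8L)) {
      cl <- find_clusters(m, 0.2, 0, conn)
      lab <- oracle_components(m < 0.2, conn)
      expect_equal(sort(vapply(cl, `[[`, 0L, "size")),
                   sort(as.integer(tabulate(lab[lab > 0]))))
    }
  }
})

test_that("the permutation null is deterministic and degenerate on ties", {
  model <- make_model(10)
  cfg <- spm_config(alpha_forming = 0.05, min_cluster = 0,
                    n_permutations = 200)
  a <- null_max_cluster_distribution(model, cfg, seed = 5)
  b <- null_max_cluster_distribution(model, cfg, seed = 5)
  expect_identical(a, b)
  expect_length(a, 200)

  # identical cohort grids: every p-value is 1, all null sizes 0
  g <- make_valid(1)$grid
  same <- as_pressure_dataset(lapply(1:5, function(i) {
    pressure_sample(g, paste0("d", i), paste0("s", i), "L")
  }))
  m2 <- normative_model(same, "L", min_n = 2)
  expect_true(all(null_max_cluster_distribution(m2, cfg, 1) == 0))
  expect_error(
    null_max_cluster_distribution(list(side = "L", cohort = m2$cohort[1, ,
      drop = FALSE], n = 1), cfg, 1),
    "two"
  )
})

test_that("the FWE threshold is the nearest-rank percentile, exceeded strictly", {
  sizes <- c(rep(0L, 90), rep(5L, 6), rep(9L, 4))
  expect_equal(nearest_rank_quantile(sizes, 0.95), 5L)
  expect_equal(nearest_rank_quantile(sizes, 0.5), 0L)
  # brute-force nearest rank on random draws
  set.seed(3)
  for (i in 1:20) {
    x <- sample(0:50, 137, replace = TRUE)
    q <- runif(1, 0.5, 0.99)
    expect_equal(nearest_rank_quantile(x, q), sort(x)[ceiling(q * 137)])
  }

  # n = 45 cohort members: the smallest attainable p, 2/46, clears the
  # 0.05 forming threshold (a smaller cohort cannot form clusters at all)
  model <- make_model(45)
  cfg <- spm_config(alpha_forming = 0.05, min_cluster = 0,
                    n_permutations = 100)
  # a heavily tied cohort member: inlier
  flat <- matrix(model$cohort[1, ], 64, 64)
  dec <- classify_spm(flat, model, cfg, rep(0L, 100))
  # candidate exactly at the threshold is not significant
  thr <- dec$fwe_threshold
  expect_equal(thr, 0L)
  if (length(dec$clusters)) {
    at <- Filter(function(cl) cl$size == thr, dec$clusters)
    expect_true(all(!vapply(at, function(cl) cl$size > thr, logical(1))))
  }
  # a cluster of size 1 beats an all-zero null
  spot <- flat
  bg <- which(apply(model$cohort, 2, max) == 0)[1:80]
  spot[bg] <- 0.9
  cfg1 <- spm_config(alpha_forming = 0.05, min_cluster = 0,
                     n_permutations = 100)
  dec2 <- classify_spm(spot, model, cfg1, rep(0L, 100))
  expect_true(dec2$is_outlier)
})

test_that("decisions are invariant to cohort order and monotone in extent", {
  model <- make_model(20)
  cfg <- spm_config(alpha_forming = 0.05, min_cluster = 3,
                    n_permutations = 150)
  nulls <- null_max_cluster_distribution(model, cfg, seed = 9)
  test_grid <- make_general_error(make_valid(77), "forefoot",
                                  fraction = 0.5)$grid
  dec <- classify_spm(test_grid, model, cfg, nulls)

  perm <- sample(model$n)
  model_p <- model
  model_p$cohort <- model$cohort[perm, ]
  dec_p <- classify_spm(test_grid, model_p, cfg, nulls)
  expect_equal(dec$pmap, dec_p$pmap)
  expect_equal(dec$is_outlier, dec_p$is_outlier)

  # growing a deviant region never shrinks the max candidate cluster
  base <- matrix(model$cohort[2, ], 64, 64)
  bg_cols <- which(apply(model$cohort, 2, max) == 0)
  msize <- function(d) {
    if (length(d$clusters)) max(vapply(d$clusters, `[[`, 0L, "size")) else 0L
  }
  sizes <- vapply(c(10, 40, 100), function(k) {
    g <- base
    g[bg_cols[seq_len(k)]] <- 0.9
    msize(classify_spm(g, model, cfg, nulls))
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("randomized tuning returns the F1-maximizing candidate", {
  model <- make_model(18)
  val_in <- lapply(19:24, function(i) as.numeric(make_valid(i)$grid))
  val_out <- lapply(25:30, function(i) {
    as.numeric(make_general_error(make_valid(i), "forefoot", seed = i)$grid)
  })
  grids <- c(val_in, val_out)
  truth <- rep(c(FALSE, TRUE), each = 6)
  base <- spm_config(n_permutations = 100)
  tuned <- tune_spm(model, grids, truth, n_candidates = 4L, seed = 2,
                    base_config = base)
  expect_s3_class(tuned$config, "spm_config")
  expect_equal(nrow(tuned$candidates), 4)
  expect_equal(tuned$f1, max(tuned$candidates$f1))
  # determinism
  tuned2 <- tune_spm(model, grids, truth, n_candidates = 4L, seed = 2,
                     base_config = base)
  expect_equal(tuned$candidates, tuned2$candidates)
  # single-candidate space returns that candidate
  tuned3 <- tune_spm(model, grids, truth, n_candidates = 1L, seed = 7,
                     base_config = base)
  expect_equal(nrow(tuned3$candidates), 1)
  expect_equal(tuned3$config$alpha_forming,
               tuned3$candidates$alpha_forming[1])
  expect_error(tune_spm(model, val_in, rep(FALSE, 6)), "both classes")
})
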