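test_that("confusion matrices count actual x predicted", {
  cm <- confusion(c(0, 0, 1, 1), c(0, 1, 1, 1), 0:1)
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2))
  perfect <- confusion(0:4, 0:4)
  expect_equal(unname(perfect), diag(1L, 5))
  expect_equal(rowSums(confusion(c(0, 0, 2, 3), c(1, 0, 2, 2)))[["0"]], 2)
  expect_error(confusion(c(0, 9), c(0, 0), 0:4), "outside")
  expect_error(confusion(0:1, 0L, 0:1), "length")
})

test_that("mcc and f1 match independent formulations on random matrices", {
  # mcc equals the Pearson correlation of the binary indicator vectors
  set.seed(31)
  for (i in 1:300) {
    n <- sample(4:60, 1)
    yt <- rbinom(n, 1, runif(1, 0.2, 0.8))
    yp <- rbinom(n, 1, runif(1, 0.2, 0.8))
    cm <- confusion(yt, yp, 0:1)
    m <- mcc(cm)
    if (sd(yt) > 0 && sd(yp) > 0) {
      expect_equal(m, cor(yt, yp), tolerance = 1e-12)
    } else {
      expect_equal(m, 0)
    }
    # f1 from precision and recall
    tp <- sum(yt == 1 & yp == 1)
    if (tp > 0) {
      prec <- tp / sum(yp == 1)
      rec <- tp / sum(yt == 1)
      expect_equal(f1_score(cm), 2 * prec * rec / (prec + rec),
                   tolerance = 1e-12)
    } else {
      expect_equal(f1_score(cm), 0)
    }
  }
  expect_equal(mcc(matrix(c(5, 0, 0, 7), 2, 2)), 1)
  expect_equal(f1_score(matrix(c(5, 3, 4, 0), 2, 2)), 0)
})

test_that("outer folds respect subject grouping and stratification", {
  ds <- small_mixed_dataset(n_subjects = 20, target = 15)
  plan <- make_outer_folds(ds, k = 5, seed = 4)
  man <- ds$manifest
  # each subject in exactly one fold; folds partition the dataset
  all_idx <- sort(unlist(plan$test_indices))
  expect_equal(all_idx, seq_len(nrow(man)))
  for (f in 1:5) {
    subj <- unique(man$subject_id[plan$test_indices[[f]]])
    for (g in setdiff(1:5, f)) {
      expect_length(
        intersect(subj, unique(man$subject_id[plan$test_indices[[g]]])), 0
      )
    }
  }
  # synthetic samples stay with their source subject's fold
  syn <- which(man$provenance == "synthetic")
  fold_of <- plan$fold_of_subject
  for (i in syn[1:20]) {
    src_subj <- man$subject_id[i]
    expect_equal(unname(fold_of[src_subj]),
                 unname(fold_of[man$subject_id[i]]))
  }
  # label proportions per fold close to global
  global <- prop.table(table(factor(man$label, levels = 0:4)))
  for (f in 1:5) {
    local <- prop.table(table(factor(man$label[plan$test_indices[[f]]],
                                     levels = 0:4)))
    expect_true(all(abs(local - global) <= 0.10))
  }
  expect_error(make_outer_folds(ds, k = 50), "fewer subjects")
  # k = 1 puts everything in one fold
  p1 <- make_outer_folds(ds, k = 1, seed = 1)
  expect_equal(sort(p1$test_indices[[1]]), seq_len(nrow(man)))
})

test_that("the inner split is grouped, sized and deterministic", {
  ds <- small_mixed_dataset(n_subjects = 10, target = 6)
  s <- make_inner_split(ds, ratio = 0.8, seed = 6)
  expect_length(intersect(s$train_subjects, s$val_subjects), 0)
  expect_setequal(c(s$train_indices, s$val_indices),
                  seq_len(nrow(ds$manifest)))
  frac <- length(s$train_indices) / nrow(ds$manifest)
  expect_gt(frac, 0.65)
  expect_lt(frac, 0.95)
  s2 <- make_inner_split(ds, ratio = 0.8, seed = 6)
  expect_identical(s, s2)
  # ten equal-size subjects split 8/2
  eq <- as_pressure_dataset(lapply(1:10, function(i) {
    make_valid(i, subject = sprintf("E%02d", i))
  }))
  se <- make_inner_split(eq, ratio = 0.8, seed = 1)
  expect_length(se$train_subjects, 8)
  expect_length(se$val_subjects, 2)
})

test_that("the comparison harness evaluates both branches on shared folds", {
  ds <- simulate_dataset(n_subjects = 20, seed = 21, target = 12)
  res <- run_comparison(
    ds, k = 2, folds = 1, seed = 5, spm_candidates = 2,
    cnn_config = model_config(filters = c(8L, 12L, 16L), emb_dim = 4L,
                              head_width = 32L),
    cnn_tc = train_config(max_epochs = 3),
    base_spm = spm_config(n_permutations = 150), min_cohort = 10L
  )
  m <- res$metrics
  expect_setequal(m$branch, c("spm", "cnn"))
  expect_setequal(m$variant, c("full", "real_only"))
  expect_true(all(m$mcc >= -1 & m$mcc <= 1, na.rm = TRUE))
  # both branches scored the identical held-out sample set
  d <- res$details[["1"]]
  expect_identical(d$spm$predictions$sample_id, d$cnn$predictions$sample_id)
  expect_identical(d$manifest$sample_id, d$spm$predictions$sample_id)
  # the five-class confusion covers exactly the evaluated fold
  expect_equal(sum(res$confusion), nrow(d$manifest))
})

test_that("metric reports separate real-only counts as a sub-count", {
  ds <- simulate_dataset(n_subjects = 8, seed = 12,
                         real_outliers = c(2L, 1L, 1L, 1L), target = 6)
  man <- ds$manifest
  pred <- man$label != 0L  # a perfect detector
  rows <- plantarqc:::metric_rows(1L, "x", man, pred)
  expect_equal(rows$variant, c("full", "real_only"))
  expect_lte(rows$n[2], rows$n[1])
  expect_equal(rows$mcc[1], 1)
  expect_equal(rows$mcc[2], 1)
  expect_equal(rows$f1, c(1, 1))
})
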