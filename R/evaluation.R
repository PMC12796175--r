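# Nested grouped stratified cross-validation and the SPM-vs-CNN
# comparison.  All samples of a subject (both feet, every condition, and
# any synthetic sample derived from that subject) stay in one partition.

#' Grouped stratified outer folds
#'
#' Greedy assignment: subjects are ordered by decreasing sample count and
#' each is placed into the fold whose label distribution, after adding the
#' subject, diverges least (summed absolute difference of label
#' proportions) from the global distribution, with fold size as
#' tie-breaker.  Deterministic for a fixed seed (which shuffles equal-count
#' subjects).
#'
#' @param dataset a `pressure_dataset`.
#' @param k number of folds.
#' @param seed integer seed.
#' @return A list of class `fold_plan`: `fold_of_subject` (named integer
#'   vector), `k`, and `test_indices` (list of manifest row indices per
#'   fold).
#' @export
make_outer_folds <- function(dataset, k = 5L, seed = 1L) {
  man <- dataset$manifest
  subjects <- unique(man$subject_id)
  if (length(subjects) < k) {
    stop("fewer subjects than folds", call. = FALSE)
  }
  n_labels <- length(LABELS)
  subj_counts <- matrix(0, length(subjects), n_labels,
                        dimnames = list(subjects, as.character(LABELS)))
  for (i in seq_len(nrow(man))) {
    subj_counts[man$subject_id[i], as.character(man$label[i])] <-
      subj_counts[man$subject_id[i], as.character(man$label[i])] + 1
  }
  desired <- matrix(rep(colSums(subj_counts) / k, each = k), k, n_labels)
  with_seed(seed, {
    ord <- order(-rowSums(subj_counts), stats::runif(length(subjects)))
    fold_counts <- matrix(0, k, n_labels)
    fold_of <- stats::setNames(integer(length(subjects)), subjects)
    for (s in ord) {
      # place the subject where it fills the largest remaining label
      # deficit; ties go to the smallest fold
      gain <- vapply(seq_len(k), function(f) {
        sum(pmin(subj_counts[s, ], pmax(desired[f, ] - fold_counts[f, ], 0)))
      }, numeric(1))
      sizes <- rowSums(fold_counts)
      f <- order(-gain, sizes)[1]
      fold_counts[f, ] <- fold_counts[f, ] + subj_counts[s, ]
      fold_of[subjects[s]] <- f
    }
    structure(
      list(
        fold_of_subject = fold_of, k = k,
        test_indices = lapply(seq_len(k), function(f) {
          which(unname(fold_of[man$subject_id]) == f)
        })
      ),
      class = "fold_plan"
    )
  })
}

#' Grouped stratified inner split
#'
#' Splits a subject set into training and validation subjects at
#' approximately `ratio` of the samples, greedily balancing label
#' proportions; subjects never straddle the two sides.
#'
#' @param dataset a `pressure_dataset` (outer training partition).
#' @param ratio target training share by sample count.
#' @param seed integer seed.
#' @return List with `train_subjects`, `val_subjects`, `train_indices`,
#'   `val_indices`.
#' @export
make_inner_split <- function(dataset, ratio = 0.8, seed = 1L) {
  man <- dataset$manifest
  subjects <- unique(man$subject_id)
  if (length(subjects) < 2) stop("need at least two subjects", call. = FALSE)
  n_total <- nrow(man)
  n_labels <- length(LABELS)
  subj_counts <- matrix(0, length(subjects), n_labels,
                        dimnames = list(subjects, as.character(LABELS)))
  for (i in seq_len(n_total)) {
    subj_counts[man$subject_id[i], as.character(man$label[i])] <-
      subj_counts[man$subject_id[i], as.character(man$label[i])] + 1
  }
  global <- colSums(subj_counts) / n_total
  targets <- c(train = ratio, val = 1 - ratio) * n_total
  with_seed(seed, {
    ord <- order(-rowSums(subj_counts), stats::runif(length(subjects)))
    bin_counts <- matrix(0, 2, n_labels)
    assign_bin <- integer(length(subjects))
    for (s in ord) {
      deficit <- targets - rowSums(bin_counts)
      open <- which(deficit > 0)
      if (length(open) == 0) open <- which.max(deficit)
      div <- vapply(open, function(b) {
        cand <- bin_counts[b, ] + subj_counts[s, ]
        sum(abs(cand / sum(cand) - global))
      }, numeric(1))
      b <- open[order(div, -deficit[open])[1]]
      bin_counts[b, ] <- bin_counts[b, ] + subj_counts[s, ]
      assign_bin[s] <- b
    }
    # both sides must be non-empty
    if (all(assign_bin == 1L)) assign_bin[ord[length(ord)]] <- 2L
    if (all(assign_bin == 2L)) assign_bin[ord[length(ord)]] <- 1L
    take <- subjects[assign_bin == 1L]
    val <- subjects[assign_bin == 2L]
    list(
      train_subjects = take, val_subjects = val,
      train_indices = which(man$subject_id %in% take),
      val_indices = which(man$subject_id %in% val)
    )
  })
}

#' Confusion matrix
#'
#' @param y_true,y_pred equal-length vectors of labels drawn from
#'   `classes`.
#' @param classes ordered class set defining rows (actual) and columns
#'   (predicted).
#' @return A `length(classes)` square integer matrix; rows = actual.
#' @export
confusion <- function(y_true, y_pred, classes = LABELS) {
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch", call. = FALSE)
  }
  if (!all(y_true %in% classes) || !all(y_pred %in% classes)) {
    stop("labels outside the class set", call. = FALSE)
  }
  tab <- table(factor(y_true, levels = classes),
               factor(y_pred, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(actual = as.character(classes),
                              predicted = as.character(classes)))
  m
}

#' Matthews correlation coefficient of a binary confusion matrix
#'
#' The outlier class (second row/column) is the positive class; returns 0
#' when any marginal is zero.
#'
#' @param cm 2x2 confusion matrix, rows = actual `(valid, outlier)`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  stopifnot(all(dim(cm) == 2))
  tn <- as.numeric(cm[1, 1]); fp <- as.numeric(cm[1, 2])
  fn <- as.numeric(cm[2, 1]); tp <- as.numeric(cm[2, 2])
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' F1 score of a binary confusion matrix
#'
#' @inheritParams mcc
#' @return F1 in `[0, 1]`; 0 when there are no true positives.
#' @export
f1_score <- function(cm) {
  stopifnot(all(dim(cm) == 2))
  tp <- as.numeric(cm[2, 2]); fp <- as.numeric(cm[1, 2])
  fn <- as.numeric(cm[2, 1])
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

binary_metrics <- function(y_true_outlier, y_pred_outlier) {
  cm <- confusion(as.integer(y_true_outlier), as.integer(y_pred_outlier), 0:1)
  list(cm = cm, mcc = mcc(cm), f1 = f1_score(cm))
}

#' Run the SPM branch on one outer fold
#'
#' Registers the fold's maps to templates built from the inner-training
#' valid cohort, tunes the forming threshold and minimum cluster size on
#' the inner validation split by binary F1, and classifies the held-out
#' test samples.  Samples are always tested against the normative model of
#' their annotated side, which is the mechanism by which swapped side
#' labels can be caught.
#'
#' @param train,val,test `pressure_dataset` partitions.
#' @param n_candidates randomized-search size for the inner loop.
#' @param seed integer seed.
#' @param base_config fixed test settings ([spm_config()]).
#' @param multistart multi-start registration; off by default since
#'   pipeline maps start near the canonical pose.
#' @param min_cohort minimum admissible per-side normative cohort size.
#' @return List: predictions data frame (`sample_id`, `is_outlier`,
#'   `n_significant_clusters`, `max_cluster_size`, `fwe_threshold`),
#'   selected `config`, registration `iou` summary.
#' @export
run_spm_fold <- function(train, val, test, n_candidates = 10L, seed = 1L,
                         base_config = spm_config(), multistart = FALSE,
                         min_cohort = 20L) {
  templates <- list(L = build_reference(train, "L"),
                    R = build_reference(train, "R"))
  reg_train <- register_dataset(train, templates = templates,
                                multistart = multistart)
  reg_val <- register_dataset(val, templates = templates,
                              multistart = multistart)
  reg_test <- register_dataset(test, templates = templates,
                               multistart = multistart)
  models <- list(L = normative_model(reg_train$dataset, "L", min_cohort),
                 R = normative_model(reg_train$dataset, "R", min_cohort))
  vg <- lapply(seq_len(nrow(val$manifest)),
               function(i) as.numeric(reg_val$dataset$grids[i, , ]))
  tuned <- tune_spm(models, vg, val$manifest$label != 0L,
                    val_sides = val$manifest$side,
                    n_candidates = n_candidates, seed = seed,
                    base_config = base_config)
  nulls <- lapply(models, null_max_cluster_distribution,
                  config = tuned$config, seed = seed)
  n <- nrow(test$manifest)
  pred <- data.frame(
    sample_id = test$manifest$sample_id, is_outlier = logical(n),
    n_significant_clusters = integer(n), max_cluster_size = integer(n),
    fwe_threshold = integer(n), stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    sd_ <- test$manifest$side[i]
    dec <- classify_spm(reg_test$dataset$grids[i, , ], models[[sd_]],
                        tuned$config, nulls[[sd_]])
    pred$is_outlier[i] <- dec$is_outlier
    pred$n_significant_clusters[i] <- length(dec$significant)
    pred$max_cluster_size[i] <-
      if (length(dec$clusters)) max(vapply(dec$clusters, `[[`, 0L, "size"))
      else 0L
    pred$fwe_threshold[i] <- dec$fwe_threshold
  }
  list(predictions = pred, config = tuned$config,
       val_f1 = tuned$f1,
       mean_train_iou = mean(reg_train$report$iou[train$manifest$label == 0L]))
}

#' Run the CNN branch on one outer fold
#'
#' @param train,val,test `pressure_dataset` partitions (unregistered).
#' @param config a [model_config()].
#' @param tc a [train_config()].
#' @return List: `predictions` ([predict_cnn()] output on `test`),
#'   `model`.
#' @export
run_cnn_fold <- function(train, val, test, config = model_config(),
                         tc = train_config()) {
  model <- train_cnn(train, val, config, tc)
  list(predictions = predict_cnn(model, test), model = model)
}

fold_partitions <- function(dataset, plan, fold, inner_ratio = 0.8,
                            seed = 1L) {
  test_idx <- plan$test_indices[[fold]]
  trainval <- subset_dataset(dataset, setdiff(seq_len(nrow(dataset$manifest)),
                                              test_idx))
  split <- make_inner_split(trainval, ratio = inner_ratio, seed = seed)
  list(
    train = subset_dataset(trainval, split$train_indices),
    val = subset_dataset(trainval, split$val_indices),
    test = subset_dataset(dataset, test_idx)
  )
}

metric_rows <- function(fold, branch, manifest, pred_outlier) {
  truth <- manifest$label != 0L
  full <- binary_metrics(truth, pred_outlier)
  real <- manifest$provenance == "real"
  out <- data.frame(
    fold = fold, branch = branch,
    variant = c("full", "real_only"),
    mcc = NA_real_, f1 = NA_real_, n = c(length(truth), sum(real)),
    stringsAsFactors = FALSE
  )
  out$mcc[1] <- full$mcc
  out$f1[1] <- full$f1
  if (sum(real) > 0 && length(unique(truth[real])) == 2) {
    ro <- binary_metrics(truth[real], pred_outlier[real])
    out$mcc[2] <- ro$mcc
    out$f1[2] <- ro$f1
  }
  out
}

#' Full nested comparison of the two branches
#'
#' Executes the nested protocol (grouped stratified outer folds, grouped
#' 80/20 inner split) for both detectors on identical partitions: the SPM
#' branch is tuned in the inner loop and evaluated on the held-out test
#' fold, the CNN is trained with early stopping on the inner validation
#' split and its five-class predictions reduced to binary for the
#' comparison.  Metrics are reported per fold, pooled, and in a variant
#' restricted to real-provenance test samples.
#'
#' @param dataset a `pressure_dataset` with all five labels.
#' @param k outer fold count.
#' @param folds optional subset of outer folds to run (default: all).
#' @param seed master seed.
#' @param spm_candidates inner randomized-search size for the SPM branch.
#' @param cnn_config,cnn_tc CNN configurations.
#' @param base_spm fixed SPM test settings.
#' @param min_cohort minimum admissible per-side normative cohort size.
#' @return A list of class `metric_report`: `metrics` (per fold/branch/
#'   variant data frame), `pooled` (same shape, folds pooled), `confusion`
#'   (five-class CNN confusion on pooled test folds), `fold_plan`,
#'   `details` (per-fold branch outputs).
#' @export
run_comparison <- function(dataset, k = 5L, folds = NULL, seed = 1L,
                           spm_candidates = 10L,
                           cnn_config = model_config(),
                           cnn_tc = train_config(),
                           base_spm = spm_config(), min_cohort = 20L) {
  plan <- make_outer_folds(dataset, k = k, seed = seed)
  if (is.null(folds)) folds <- seq_len(k)
  metrics <- list()
  details <- list()
  pooled_truth <- list()
  pooled_spm <- list()
  pooled_cnn <- list()
  cm5 <- matrix(0L, 5, 5, dimnames = list(actual = as.character(LABELS),
                                          predicted = as.character(LABELS)))
  for (f in folds) {
    parts <- fold_partitions(dataset, plan, f, seed = seed + f)
    fold_detail <- list()
    spm_res <- tryCatch(
      run_spm_fold(parts$train, parts$val, parts$test,
                   n_candidates = spm_candidates, seed = seed + f,
                   base_config = base_spm, min_cohort = min_cohort),
      error = function(e) e
    )
    cnn_res <- tryCatch(
      run_cnn_fold(parts$train, parts$val, parts$test, cnn_config,
                   within_seed(cnn_tc, seed + f)),
      error = function(e) e
    )
    man <- parts$test$manifest
    if (!inherits(spm_res, "error")) {
      metrics[[length(metrics) + 1]] <-
        metric_rows(f, "spm", man, spm_res$predictions$is_outlier)
      pooled_spm[[f]] <- spm_res$predictions$is_outlier
      fold_detail$spm <- spm_res
    } else {
      warning("SPM branch failed on fold ", f, ": ",
              conditionMessage(spm_res))
      fold_detail$spm_error <- conditionMessage(spm_res)
    }
    if (!inherits(cnn_res, "error")) {
      metrics[[length(metrics) + 1]] <-
        metric_rows(f, "cnn", man, cnn_res$predictions$binary_pred)
      pooled_cnn[[f]] <- cnn_res$predictions$binary_pred
      cm5 <- cm5 + confusion(man$label, cnn_res$predictions$label_pred)
      fold_detail$cnn <- cnn_res
    } else {
      warning("CNN branch failed on fold ", f, ": ",
              conditionMessage(cnn_res))
      fold_detail$cnn_error <- conditionMessage(cnn_res)
    }
    pooled_truth[[f]] <- man$label != 0L
    fold_detail$manifest <- man
    details[[as.character(f)]] <- fold_detail
  }
  metrics <- do.call(rbind, metrics)
  pooled <- list()
  for (br in c("spm", "cnn")) {
    preds <- if (br == "spm") pooled_spm else pooled_cnn
    ok <- !vapply(preds[folds], is.null, logical(1))
    if (!any(ok)) next
    truth <- unlist(pooled_truth[folds][ok])
    pred <- unlist(preds[folds][ok])
    man_all <- do.call(rbind, lapply(details[as.character(folds[ok])],
                                     `[[`, "manifest"))
    pooled[[br]] <- metric_rows(NA_integer_, br, man_all, pred)
  }
  structure(
    list(metrics = metrics, pooled = do.call(rbind, pooled),
         confusion = cm5, fold_plan = plan, details = details),
    class = "metric_report"
  )
}

within_seed <- function(tc, seed) {
  tc$seed <- as.integer(seed %% .Machine$integer.max)
  tc
}
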