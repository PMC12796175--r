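# Non-parametric normative statistical mapping with cluster-based
# permutation control of the family-wise error rate.  A test map is scored
# pixel-wise against the empirical distribution of a registered valid
# cohort of the same side; contiguous suprathreshold p-value clusters are
# compared against a permutation null of maximum cluster sizes.

#' Configuration for the normative cluster test
#'
#' @param alpha_forming uncorrected per-pixel cluster-forming threshold,
#'   in `[0.01, 0.05]`.
#' @param min_cluster minimum candidate cluster size in pixels, 0..30.
#' @param n_permutations permutation count for the max-cluster null
#'   (>= 100).
#' @param alpha_fwe family-wise error level for the cluster-size
#'   percentile.
#' @param connectivity pixel adjacency: 4 or 8 (default; diagonal contact
#'   counts).
#' @return A list of class `spm_config`.
#' @export
spm_config <- function(alpha_forming = 0.01, min_cluster = 5L,
                       n_permutations = 1000L, alpha_fwe = 0.05,
                       connectivity = 8L) {
  stopifnot(
    alpha_forming >= 0.01, alpha_forming <= 0.05,
    min_cluster >= 0, min_cluster <= 30,
    n_permutations >= 100,
    alpha_fwe > 0, alpha_fwe < 1,
    connectivity %in% c(4L, 8L)
  )
  structure(
    list(alpha_forming = alpha_forming, min_cluster = as.integer(min_cluster),
         n_permutations = as.integer(n_permutations), alpha_fwe = alpha_fwe,
         connectivity = as.integer(connectivity)),
    class = "spm_config"
  )
}

#' Assemble a normative model from registered valid maps
#'
#' @param dataset a `pressure_dataset` of registered maps.
#' @param side `"L"` or `"R"`.
#' @param min_n minimum admissible cohort size.
#' @return A list of class `normative_model` with the `side` and the
#'   `n x 4096` cohort matrix (one flattened map per row).
#' @export
normative_model <- function(dataset, side, min_n = 20L) {
  idx <- which(dataset$manifest$label == 0L & dataset$manifest$side == side)
  if (length(idx) < min_n) {
    stop(sprintf("normative cohort for side %s has %d < %d samples",
                 side, length(idx), min_n), call. = FALSE)
  }
  cohort <- matrix(0, length(idx), GRID_SIZE^2)
  for (j in seq_along(idx)) cohort[j, ] <- as.numeric(dataset$grids[idx[j], , ])
  structure(list(side = side, cohort = cohort, n = length(idx)),
            class = "normative_model")
}

#' Two-tailed empirical p-value of one intensity against a cohort
#'
#' Rank-based with the add-one correction so p is never zero; ties are
#' counted on both tails:
#' `p = min(1, 2 * min((1 + #\{x >= t\}), (1 + #\{x <= t\})) / (n + 1))`.
#'
#' @param t observed intensity.
#' @param cohort_values numeric vector of cohort intensities at the same
#'   pixel.
#' @return p-value in `(0, 1]`.
#' @export
pixel_pvalue <- function(t, cohort_values) {
  n <- length(cohort_values)
  if (n < 1) stop("empty cohort", call. = FALSE)
  p_high <- (1 + sum(cohort_values >= t)) / (n + 1)
  p_low <- (1 + sum(cohort_values <= t)) / (n + 1)
  min(1, 2 * min(p_high, p_low))
}

#' Pixel-wise p-map of a test sample under a normative model
#'
#' Applies [pixel_pvalue()] at every canvas pixel, including background
#' pixels (where the cohort is all zero), so that pressure appearing
#' outside the normal footprint is testable.
#'
#' @param grid registered 64x64 test map.
#' @param model a [normative_model()].
#' @param side optional side of the test sample; a mismatch with the model
#'   side raises an error.
#' @return 64x64 matrix of p-values in `(0, 1]`.
#' @export
compute_pmap <- function(grid, model, side = NULL) {
  if (!is.null(side) && side != model$side) {
    stop("sample side does not match model side", call. = FALSE)
  }
  p <- .pmap_cpp(as.numeric(grid), model$cohort)
  matrix(p, GRID_SIZE, GRID_SIZE)
}

#' Suprathreshold clusters of a p-map
#'
#' Connected components of `p < alpha_forming` under the configured
#' adjacency; components smaller than `min_cluster` are discarded.
#'
#' @param pmap matrix of p-values.
#' @param alpha_forming cluster-forming threshold.
#' @param min_cluster minimum component size in pixels.
#' @param connectivity 4 or 8.
#' @return List of clusters, each a list with `pixels` (two-column matrix
#'   of 1-based row/col coordinates) and `size`.
#' @export
find_clusters <- function(pmap, alpha_forming, min_cluster = 0L,
                          connectivity = 8L) {
  mask <- pmap < alpha_forming
  if (!any(mask)) return(list())
  lab <- .label_components_cpp(mask, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_cluster)
  lapply(keep, function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    dimnames(px) <- NULL
    list(pixels = px, size = sizes[k])
  })
}

#' Permutation null of maximum surviving cluster sizes
#'
#' Each of `n_permutations` iterations draws one cohort member uniformly
#' (with replacement across iterations), computes its p-map against the
#' remaining members (leave-one-out), finds surviving clusters under the
#' configuration, and records the maximum cluster size (0 when none
#' survive).  Deterministic for a fixed seed.
#'
#' @param model a [normative_model()] with at least two members.
#' @param config an [spm_config()].
#' @param seed integer seed.
#' @return Integer vector of `n_permutations` maximum cluster sizes.
#' @export
null_max_cluster_distribution <- function(model, config, seed = 1L) {
  if (model$n < 2) stop("need at least two cohort members", call. = FALSE)
  .null_max_sizes_cpp(
    model$cohort, GRID_SIZE, GRID_SIZE, config$alpha_forming,
    config$min_cluster, config$connectivity, config$n_permutations,
    as.integer(seed)
  )
}

#' Nearest-rank upper percentile used for the cluster-size threshold
#'
#' @param x numeric vector.
#' @param q percentile in (0, 1).
#' @return The nearest-rank `q`-th percentile of `x`.
#' @export
nearest_rank_quantile <- function(x, q) {
  s <- sort(x)
  s[max(1L, ceiling(q * length(s)))]
}

#' Classify one sample as outlier or inlier
#'
#' Candidate clusters must strictly exceed the nearest-rank
#' `(1 - alpha_fwe)` percentile of the permutation null to be significant;
#' the sample is an outlier when at least one significant cluster remains.
#'
#' @param grid registered 64x64 test map.
#' @param model a [normative_model()].
#' @param config an [spm_config()].
#' @param null_sizes null distribution from
#'   [null_max_cluster_distribution()] for the same model and config.
#' @param side optional declared side of the sample (checked against the
#'   model).
#' @return A list of class `spm_decision`: `pmap`, `clusters`,
#'   `fwe_threshold`, `significant`, `is_outlier`.
#' @export
classify_spm <- function(grid, model, config, null_sizes, side = NULL) {
  pmap <- compute_pmap(grid, model, side)
  clusters <- find_clusters(pmap, config$alpha_forming, config$min_cluster,
                            config$connectivity)
  thr <- nearest_rank_quantile(null_sizes, 1 - config$alpha_fwe)
  significant <- Filter(function(cl) cl$size > thr, clusters)
  structure(
    list(pmap = pmap, clusters = clusters, fwe_threshold = thr,
         significant = significant,
         is_outlier = length(significant) > 0),
    class = "spm_decision"
  )
}

#' Randomized search for the forming threshold and minimum cluster size
#'
#' Samples `n_candidates` configurations (`alpha_forming` uniform in
#' `[0.01, 0.05]`, `min_cluster` uniform integer in 0..30), evaluates each
#' on a labelled validation set by binary F1 (outlier = positive) and
#' returns the best pair.  Ties are broken toward the more conservative
#' setting: larger `min_cluster`, then smaller `alpha_forming`.
#'
#' @param models a [normative_model()] or a list of them keyed by side
#'   (`list(L = , R = )`), built from the training cohort.
#' @param val_grids list (or n x 4096 matrix) of registered validation
#'   maps.
#' @param val_outlier logical vector: TRUE for outliers.
#' @param val_sides character vector of annotated sides; required when
#'   `models` holds one model per side.
#' @param n_candidates number of sampled configurations.
#' @param seed integer seed (candidate sampling and permutation nulls).
#' @param base_config an [spm_config()] carrying the fixed fields
#'   (`n_permutations`, `alpha_fwe`, `connectivity`).
#' @return List: `config` (the selected [spm_config()]), `f1` achieved on
#'   validation, `candidates` (data frame of all evaluated pairs).
#' @export
tune_spm <- function(models, val_grids, val_outlier, val_sides = NULL,
                     n_candidates = 10L, seed = 1L,
                     base_config = spm_config()) {
  if (length(unique(val_outlier)) < 2) {
    stop("validation set must contain both classes", call. = FALSE)
  }
  if (inherits(models, "normative_model")) {
    models <- stats::setNames(list(models), models$side)
  }
  if (is.null(val_sides)) {
    if (length(models) > 1) stop("val_sides required", call. = FALSE)
    val_sides <- rep(names(models), length(val_outlier))
  }
  if (is.matrix(val_grids)) {
    val_grids <- lapply(seq_len(nrow(val_grids)),
                        function(i) val_grids[i, ])
  }
  with_seed(seed, {
    af <- stats::runif(n_candidates, 0.01, 0.05)
    mc <- sample(0:30, n_candidates, replace = TRUE)
    null_seeds <- sample.int(1e6, n_candidates)
    scores <- numeric(n_candidates)
    for (k in seq_len(n_candidates)) {
      cfg <- spm_config(af[k], mc[k], base_config$n_permutations,
                        base_config$alpha_fwe, base_config$connectivity)
      nulls <- lapply(models, null_max_cluster_distribution,
                      config = cfg, seed = null_seeds[k])
      pred <- vapply(seq_along(val_grids), function(i) {
        sd_ <- val_sides[i]
        classify_spm(matrix(val_grids[[i]], GRID_SIZE, GRID_SIZE),
                     models[[sd_]], cfg, nulls[[sd_]])$is_outlier
      }, logical(1))
      cm <- confusion(as.integer(val_outlier), as.integer(pred), 0:1)
      scores[k] <- f1_score(cm)
    }
    ord <- order(-scores, -mc, af)
    best <- ord[1]
    list(
      config = spm_config(af[best], mc[best], base_config$n_permutations,
                          base_config$alpha_fwe, base_config$connectivity),
      f1 = scores[best],
      candidates = data.frame(alpha_forming = af, min_cluster = mc,
                              f1 = scores)
    )
  })
}
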