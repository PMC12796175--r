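# Five-class convolutional classifier on unregistered maps.  The network
# itself (im2col/gemm convolutions, batch normalization, max pooling,
# channel dropout, laterality embedding, Adam, weighted cross-entropy,
# early stopping) lives in compiled code; this file holds the
# configuration objects and the user-facing train/predict interface.

#' Architecture configuration
#'
#' Three convolutional blocks (two 3x3 conv layers each, batch norm, ReLU,
#' 2x2 max pooling, channel dropout) with increasing filter counts, an
#' 8-dimensional embedding of the integer side label concatenated to the
#' flattened features, and a two-layer head with batch norm and dropout.
#' With the defaults the spatial size halves per block (64 to 32 to 16 to
#' 8), the flattened convolutional output has `128 * 8 * 8 = 8192`
#' features and the concatenated vector 8200.
#'
#' @param filters filter counts of the three blocks.
#' @param emb_dim side-embedding dimension.
#' @param head_width hidden width of the classifier head.
#' @param conv_dropout channel dropout rate after each pooling step.
#' @param head_dropout dropout rate in the head.
#' @param n_classes number of output classes.
#' @return A list of class `model_config`.
#' @export
model_config <- function(filters = c(32L, 64L, 128L), emb_dim = 8L,
                         head_width = 256L, conv_dropout = 0.25,
                         head_dropout = 0.5, n_classes = 5L) {
  stopifnot(length(filters) == 3, all(filters >= 1), emb_dim >= 1,
            head_width >= 2, conv_dropout >= 0, conv_dropout < 1,
            head_dropout >= 0, head_dropout < 1, n_classes >= 2)
  structure(
    list(filters = as.integer(filters), emb_dim = as.integer(emb_dim),
         head_width = as.integer(head_width),
         conv_dropout = conv_dropout, head_dropout = head_dropout,
         n_classes = as.integer(n_classes)),
    class = "model_config"
  )
}

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs upper bound on training epochs.
#' @param patience early-stopping patience: training halts once the
#'   validation loss has not improved by at least `min_delta` for this
#'   many consecutive epochs; the checkpoint with the lowest validation
#'   loss is retained regardless.
#' @param min_delta smallest validation-loss decrease that counts as an
#'   improvement for the patience counter.
#' @param balanced_sampling draw each epoch's minibatches class-balanced
#'   (uniform over classes, with replacement).
#' @param weighted_loss weight the cross-entropy inversely to training
#'   class frequencies.
#' @param seed integer seed for initialization, sampling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 0.001, batch_size = 16L, max_epochs = 200L,
                         patience = 10L, min_delta = 1e-4,
                         balanced_sampling = TRUE,
                         weighted_loss = TRUE, seed = 1L) {
  stopifnot(lr > 0, batch_size >= 2, max_epochs >= 1, patience >= 1,
            min_delta >= 0)
  structure(
    list(lr = lr, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         min_delta = min_delta,
         balanced_sampling = isTRUE(balanced_sampling),
         weighted_loss = isTRUE(weighted_loss), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Fold-wise standardization statistics
#'
#' Scalar mean and standard deviation over all training pixels, computed
#' exclusively from the training partition of a fold so that validation
#' and test data never leak into the normalization.
#'
#' @param dataset a `pressure_dataset` (the training partition).
#' @return List with `mean` and `sd`.
#' @export
compute_fold_stats <- function(dataset) {
  if (nrow(dataset$manifest) < 2) {
    stop("need at least two training samples", call. = FALSE)
  }
  m <- mean(dataset$grids)
  s <- stats::sd(as.numeric(dataset$grids))
  if (s <= 0) stop("training pixels have zero variance", call. = FALSE)
  list(mean = m, sd = s)
}

#' Instantiate an untrained model
#'
#' Creates the parameter tensors (randomly initialized, He scheme) for the
#' configured architecture together with the structural shape summary.
#'
#' @param config a [model_config()].
#' @param seed initialization seed.
#' @return A list of class `cnn_model`: `config`, `params`, `shapes`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  # initialize by running zero epochs of training on a dummy pair
  dummy <- matrix(0, GRID_SIZE^2, 2)
  fit <- .cnn_train_cpp(dummy, c(0L, 1L), c(0L, 1L), dummy, c(0L, 1L),
                        c(0L, 1L), unclass(config),
                        rep(1, config$n_classes), 0.001, 2L, 0L, 1L, 0,
                        FALSE, as.integer(seed), FALSE)
  out_spatial <- GRID_SIZE / 2^3
  structure(
    list(
      config = config, params = fit$params,
      fold_stats = NULL, history = NULL,
      shapes = list(
        flat_dim = config$filters[3] * out_spatial^2,
        concat_dim = config$filters[3] * out_spatial^2 + config$emb_dim,
        out_spatial = out_spatial
      )
    ),
    class = "cnn_model"
  )
}

#' Inverse-frequency class weights
#'
#' @param labels integer training labels (0-based classes).
#' @param n_classes total class count.
#' @return Numeric weights proportional to `1 / frequency`, normalized to
#'   mean 1.
#' @export
class_weights <- function(labels, n_classes = 5L) {
  counts <- tabulate(labels + 1L, nbins = n_classes)
  if (any(counts == 0)) {
    stop("every class must be present in the training set", call. = FALSE)
  }
  w <- 1 / counts
  w / mean(w)
}

dataset_to_xy <- function(dataset, stats = NULL) {
  n <- nrow(dataset$manifest)
  x <- matrix(0, GRID_SIZE^2, n)
  for (i in seq_len(n)) x[, i] <- as.numeric(dataset$grids[i, , ])
  if (!is.null(stats)) x <- (x - stats$mean) / stats$sd
  list(
    x = x,
    side = ifelse(dataset$manifest$side == "L", 0L, 1L),
    y = as.integer(dataset$manifest$label)
  )
}

#' Train the classifier
#'
#' Standardizes with statistics from the training partition, weights the
#' cross-entropy inversely to training class frequencies, samples epochs
#' class-balanced, and early-stops on the validation loss, retaining the
#' checkpoint with the lowest validation loss.  Deterministic for a fixed
#' seed.
#'
#' @param train,val `pressure_dataset` partitions; all classes must be
#'   present in `train`.
#' @param config a [model_config()].
#' @param tc a [train_config()].
#' @param verbose print per-epoch losses.
#' @return A `cnn_model` with `params`, `fold_stats` and `history`
#'   (`train_loss`, `val_loss`, `best_epoch`).
#' @export
train_cnn <- function(train, val, config = model_config(),
                      tc = train_config(), verbose = FALSE) {
  stats <- compute_fold_stats(train)
  tr <- dataset_to_xy(train, stats)
  vl <- dataset_to_xy(val, stats)
  w <- if (tc$weighted_loss) class_weights(tr$y, config$n_classes)
       else rep(1, config$n_classes)
  fit <- .cnn_train_cpp(
    tr$x, tr$side, tr$y, vl$x, vl$side, vl$y, unclass(config), w,
    tc$lr, tc$batch_size, tc$max_epochs, tc$patience, tc$min_delta,
    tc$balanced_sampling, tc$seed, verbose
  )
  structure(
    list(
      config = config, params = fit$params, fold_stats = stats,
      history = list(train_loss = fit$train_loss, val_loss = fit$val_loss,
                     best_epoch = fit$best_epoch),
      shapes = list(
        flat_dim = config$filters[3] * (GRID_SIZE / 8)^2,
        concat_dim = config$filters[3] * (GRID_SIZE / 8)^2 + config$emb_dim,
        out_spatial = GRID_SIZE / 8
      )
    ),
    class = "cnn_model"
  )
}

#' Predict class probabilities
#'
#' Applies the model's fold standardization and runs the forward pass in
#' inference mode (running batch-norm statistics, no dropout).
#'
#' @param model a trained `cnn_model`.
#' @param dataset a `pressure_dataset`.
#' @param fold_stats standardization statistics; defaults to the ones
#'   stored with the model.
#' @return A data frame with `sample_id`, probability columns `p0`..`p4`,
#'   `label_pred` (argmax) and `binary_pred` (`label_pred != 0`).
#' @export
predict_cnn <- function(model, dataset, fold_stats = model$fold_stats) {
  if (is.null(fold_stats)) {
    stop("model has no fold statistics; pass fold_stats", call. = FALSE)
  }
  d <- dataset_to_xy(dataset, fold_stats)
  probs <- .cnn_predict_cpp(model$params, unclass(model$config), d$x, d$side)
  k <- nrow(probs)
  out <- data.frame(sample_id = dataset$manifest$sample_id,
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[paste0("p", j - 1L)]] <- probs[j, ]
  out$label_pred <- max.col(t(probs)) - 1L
  out$binary_pred <- out$label_pred != 0L
  out
}
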