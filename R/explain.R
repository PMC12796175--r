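# Shapley-additive per-pixel attributions for the classifier and the
# three-panel comparison figure.  Attributions are computed by multiplier
# back-propagation against a background set (rescale rule through ReLU,
# delta routing through max-pooling), so for every background reference
# the contributions sum exactly to the difference between the sample's
# target-class logit and the reference's.

#' Per-pixel attribution of a classifier decision
#'
#' @param model a trained `cnn_model`.
#' @param sample a [pressure_sample()].
#' @param background a `pressure_dataset` of background samples drawn from
#'   the training partition (100 by default in callers).
#' @param target_class class whose logit is explained; defaults to the
#'   predicted class.
#' @return A list of class `attribution_map`: `attr` (64x64 signed
#'   matrix), `side_attr` (contribution of the laterality embedding),
#'   `target_class`, `fx` (target logit of the sample), `baseline` (mean
#'   background logit), `n_background`.
#' @export
compute_attribution <- function(model, sample, background,
                                target_class = NULL) {
  n_bg <- nrow(background$manifest)
  if (n_bg == 0) stop("background set is empty", call. = FALSE)
  stats <- model$fold_stats
  if (is.null(stats)) stop("model lacks fold statistics", call. = FALSE)
  if (is.null(target_class)) {
    one <- subset_dataset(as_pressure_dataset(list(sample)), 1L)
    target_class <- predict_cnn(model, one)$label_pred[1]
  }
  x <- (as.numeric(sample$grid) - stats$mean) / stats$sd
  bg <- dataset_to_xy(background, stats)
  res <- .cnn_deeplift_cpp(
    model$params, unclass(model$config), x,
    if (sample$side == "L") 0L else 1L, bg$x, bg$side,
    as.integer(target_class)
  )
  structure(
    list(
      attr = matrix(res$attr, GRID_SIZE, GRID_SIZE),
      side_attr = res$emb_attr, target_class = as.integer(target_class),
      fx = res$fx, baseline = res$baseline, n_background = n_bg
    ),
    class = "attribution_map"
  )
}

#' Rendering configuration for attribution maps
#'
#' @param threshold_fraction attributions below this fraction of the
#'   maximum absolute value are omitted before smoothing.
#' @param bilateral_d bilateral filter diameter in pixels.
#' @param bilateral_sigma_r range sigma (attribution units).
#' @param bilateral_sigma_s spatial sigma in pixels.
#' @return A list of class `render_config`.
#' @export
render_config <- function(threshold_fraction = 0.20, bilateral_d = 5L,
                          bilateral_sigma_r = 0.1, bilateral_sigma_s = 2) {
  stopifnot(threshold_fraction >= 0, threshold_fraction < 1,
            bilateral_d >= 1, bilateral_sigma_r > 0, bilateral_sigma_s > 0)
  structure(
    list(threshold_fraction = threshold_fraction,
         bilateral_d = as.integer(bilateral_d),
         bilateral_sigma_r = bilateral_sigma_r,
         bilateral_sigma_s = bilateral_sigma_s),
    class = "render_config"
  )
}

#' Edge-preserving bilateral filter
#'
#' @param img numeric matrix.
#' @param d neighbourhood diameter in pixels (odd).
#' @param sigma_r range sigma (intensity units).
#' @param sigma_s spatial sigma (pixels).
#' @return The filtered matrix.
#' @export
bilateral_filter <- function(img, d = 5L, sigma_r = 0.1, sigma_s = 2) {
  rad <- d %/% 2L
  h <- nrow(img); w <- ncol(img)
  num <- matrix(0, h, w)
  den <- matrix(0, h, w)
  for (dr in -rad:rad) {
    for (dc in -rad:rad) {
      sw <- exp(-(dr^2 + dc^2) / (2 * sigma_s^2))
      src_r <- (1:h) + dr
      src_c <- (1:w) + dc
      ok_r <- src_r >= 1 & src_r <= h
      ok_c <- src_c >= 1 & src_c <= w
      shifted <- matrix(0, h, w)
      shifted[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
      rw <- exp(-(shifted - img)^2 / (2 * sigma_r^2))
      ww <- sw * rw
      ww[!ok_r, ] <- 0
      ww[, !ok_c] <- 0
      num <- num + ww * shifted
      den <- den + ww
    }
  }
  out <- num / den
  out[den == 0] <- 0
  out
}

#' Threshold and smooth an attribution map for display
#'
#' Zeroes attributions whose magnitude falls below
#' `threshold_fraction * max(|attr|)`, then applies the bilateral filter.
#' An all-zero map is returned unchanged.
#'
#' @param attr an `attribution_map` (or bare matrix).
#' @param config a [render_config()].
#' @return The input with its `attr` matrix thresholded and smoothed.
#' @export
threshold_and_smooth <- function(attr, config = render_config()) {
  a <- if (inherits(attr, "attribution_map")) attr$attr else attr
  m <- max(abs(a))
  if (m == 0) return(attr)
  a[abs(a) < config$threshold_fraction * m] <- 0
  a <- bilateral_filter(a, config$bilateral_d, config$bilateral_sigma_r,
                        config$bilateral_sigma_s)
  if (inherits(attr, "attribution_map")) {
    attr$attr <- a
    attr
  } else {
    a
  }
}

# mask of significant-cluster pixels from an spm_decision
significant_mask <- function(decision) {
  mask <- matrix(FALSE, GRID_SIZE, GRID_SIZE)
  for (cl in decision$significant) mask[cl$pixels] <- TRUE
  mask
}

#' Render the three-panel comparison figure
#'
#' Left: the original grayscale pressure map.  Middle: the same map with
#' green contours around statistically significant normative-deviation
#' clusters.  Right: the map overlaid with the thresholded and smoothed
#' attribution heatmap (blue = pixels supporting the predicted class,
#' red = pixels against it).
#'
#' @param sample a [pressure_sample()].
#' @param spm_decision an `spm_decision` for the same sample.
#' @param attr an `attribution_map` for the same sample.
#' @param out_path PNG file path.
#' @param config a [render_config()].
#' @param survey_parity suppress the outlier subtype in the caption,
#'   showing only outlier/valid.
#' @param cnn_label predicted class (for the caption) when known.
#' @return `out_path`, invisibly.
#' @export
render_triptych <- function(sample, spm_decision, attr, out_path,
                            config = render_config(),
                            survey_parity = FALSE, cnn_label = NULL) {
  sm <- threshold_and_smooth(attr, config)
  a <- sm$attr
  grDevices::png(out_path, width = 1200, height = 440)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  img <- t(sample$grid[GRID_SIZE:1, ])  # image() draws column-major upward
  greys <- grDevices::gray.colors(256, start = 1, end = 0)
  draw_base <- function(title) {
    graphics::image(img, col = greys, axes = FALSE, main = title,
                    cex.main = 1.6, useRaster = TRUE)
  }
  draw_base("Pressure map")
  # middle: green significant-cluster contours
  lab <- if (survey_parity) {
    if (spm_decision$is_outlier) "outlier" else "valid"
  } else if (spm_decision$is_outlier) {
    sprintf("outlier (%d cluster%s)", length(spm_decision$significant),
            if (length(spm_decision$significant) == 1) "" else "s")
  } else "valid"
  draw_base(sprintf("Normative map: %s", lab))
  mask <- significant_mask(spm_decision)
  if (any(mask)) {
    mimg <- t(mask[GRID_SIZE:1, ]) * 1
    graphics::contour(mimg, levels = 0.5, add = TRUE, col = "green3",
                      lwd = 2.5, drawlabels = FALSE)
  }
  # right: diverging attribution overlay
  cl <- if (!is.null(cnn_label)) {
    if (survey_parity) {
      if (cnn_label != 0L) "outlier" else "valid"
    } else {
      LABEL_NAMES[cnn_label + 1L]
    }
  } else "prediction"
  draw_base(sprintf("Attributions: %s", cl))
  mx <- max(abs(a))
  if (mx > 0) {
    rel <- a / mx  # grid orientation: row 1 = top of the display
    cols <- grDevices::rgb(
      red = as.numeric(rel < 0), green = 0, blue = as.numeric(rel > 0),
      alpha = pmin(abs(rel) * 0.85, 0.85)
    )
    usr <- graphics::par("usr")
    graphics::rasterImage(
      grDevices::as.raster(matrix(cols, GRID_SIZE, GRID_SIZE)),
      usr[1], usr[3], usr[2], usr[4], interpolate = FALSE
    )
  }
  invisible(out_path)
}
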