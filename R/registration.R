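# Affine registration of pressure maps to a per-side reference template.
# Mean-squared-error objective over bounded (angle, shift, zoom) parameters,
# minimized with L-BFGS-B; alignment quality is quantified by the IoU of
# the binarized footprints.

#' Affine parameter container
#'
#' @param angle rotation in degrees about the canvas centre.
#' @param shift_rows,shift_cols translation in pixels.
#' @param zoom isotropic scale factor (> 0).
#' @return A named numeric vector of class `affine_params`.
#' @export
affine_params <- function(angle = 0, shift_rows = 0, shift_cols = 0,
                          zoom = 1) {
  stopifnot(zoom > 0)
  structure(c(angle = angle, shift_rows = shift_rows,
              shift_cols = shift_cols, zoom = zoom),
            class = "affine_params")
}

#' Default registration bounds
#'
#' Realistic limits for plantar pressure alignment: rotation within +/-30
#' degrees, shifts within +/-10 px, zoom within `[0.8, 1.25]`.
#'
#' @return List with `lower` and `upper` numeric vectors.
#' @export
registration_bounds <- function() {
  list(lower = c(angle = -30, shift_rows = -10, shift_cols = -10, zoom = 0.8),
       upper = c(angle = 30, shift_rows = 10, shift_cols = 10, zoom = 1.25))
}

#' Apply an affine transform to a grid
#'
#' Rotates about the canvas centre, scales, then translates, with bilinear
#' interpolation; samples falling outside the canvas are zero and the
#' output is clipped to `[0, 1]`.
#'
#' @param grid 64x64 numeric matrix.
#' @param params an [affine_params()] vector.
#' @return The transformed matrix.
#' @export
apply_affine <- function(grid, params) {
  .warp_affine_cpp(grid, params[["angle"]], params[["shift_rows"]],
                   params[["shift_cols"]], params[["zoom"]])
}

#' Build the per-side reference template
#'
#' Centroid-aligns (integer pixel shifts) all valid maps of one side onto
#' the canvas centre, averages them pixel-wise and re-normalizes to max 1.
#' With `mode = "exemplar"` the first valid sample (centroid-centred) is
#' used instead of the average.
#'
#' @param dataset a `pressure_dataset`.
#' @param side `"L"` or `"R"`.
#' @param mode `"mean"` (default) or `"exemplar"`.
#' @return A list of class `reference_template` with fields `side`, `grid`,
#'   `n_contributors`.
#' @export
build_reference <- function(dataset, side, mode = c("mean", "exemplar")) {
  mode <- match.arg(mode)
  idx <- which(dataset$manifest$label == 0L & dataset$manifest$side == side)
  if (length(idx) == 0) {
    stop("no valid samples of side ", side, call. = FALSE)
  }
  if (mode == "exemplar") idx <- idx[1]
  centre <- (GRID_SIZE - 1) / 2
  acc <- matrix(0, GRID_SIZE, GRID_SIZE)
  for (i in idx) {
    g <- dataset$grids[i, , ]
    tot <- sum(g)
    cr <- sum((row(g) - 1) * g) / tot
    cc <- sum((col(g) - 1) * g) / tot
    dr <- round(centre - cr)
    dc <- round(centre - cc)
    shifted <- matrix(0, GRID_SIZE, GRID_SIZE)
    src_r <- seq_len(GRID_SIZE) - dr
    src_c <- seq_len(GRID_SIZE) - dc
    ok_r <- src_r >= 1 & src_r <= GRID_SIZE
    ok_c <- src_c >= 1 & src_c <= GRID_SIZE
    shifted[which(ok_r), which(ok_c)] <- g[src_r[ok_r], src_c[ok_c]]
    acc <- acc + shifted
  }
  acc <- acc / length(idx)
  acc <- acc / max(acc)
  structure(list(side = side, grid = acc, n_contributors = length(idx)),
            class = "reference_template")
}

#' Intersection over union of two binarized footprints
#'
#' Masks are `pressure > 0`; the IoU is `|A & B| / |A | B|`, defined as 0
#' when both masks are empty.
#'
#' @param grid_a,grid_b equally sized numeric matrices.
#' @return IoU in `[0, 1]`.
#' @export
compute_iou <- function(grid_a, grid_b) {
  if (!all(dim(grid_a) == dim(grid_b))) {
    stop("grids must have identical shapes", call. = FALSE)
  }
  a <- grid_a > 0
  b <- grid_b > 0
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

#' Register a map to a reference template
#'
#' Minimizes the mean squared intensity error between the affinely
#' transformed map and the template over bounded parameters, using
#' L-BFGS-B with numerical gradients.  An optional multi-start (identity
#' plus rotated/shifted initializations) guards against local minima; the
#' best final MSE wins, ties broken by the smaller parameter norm.  The
#' returned MSE is never worse than the identity initialization.
#'
#' @param grid 64x64 map to align.
#' @param template a `reference_template` (or bare 64x64 matrix).
#' @param bounds list with `lower` / `upper` as in [registration_bounds()].
#' @param init optional [affine_params()] starting point.
#' @param multistart use additional rotated / shifted starting points.
#' @return A list of class `registration_result`: `params`, `final_mse`,
#'   `iou`, `registered` (the transformed grid).
#' @export
register_map <- function(grid, template, bounds = registration_bounds(),
                         init = affine_params(), multistart = TRUE) {
  ref <- if (inherits(template, "reference_template")) template$grid
         else template
  objective <- function(th) {
    mean((.warp_affine_cpp(grid, th[1], th[2], th[3], th[4]) - ref)^2)
  }
  starts <- list(as.numeric(init))
  if (multistart) {
    starts <- c(starts, list(
      c(10, 0, 0, 1), c(-10, 0, 0, 1), c(0, 5, 0, 1), c(0, -5, 0, 1)
    ))
  }
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, bounds$lower), bounds$upper)
    fit <- tryCatch(
      stats::optim(s, objective, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = 200, factr = 1e7,
                                  ndeps = rep(1e-3, 4))),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    cand <- list(par = fit$par, value = fit$value)
    better <- is.null(best) ||
      cand$value < best$value - 1e-12 ||
      (abs(cand$value - best$value) <= 1e-12 &&
         sum(cand$par^2) < sum(best$par^2))
    if (better) best <- cand
  }
  if (is.null(best)) {
    stop("registration optimizer failed from every start", call. = FALSE)
  }
  id_mse <- objective(as.numeric(init))
  if (id_mse < best$value) {
    best <- list(par = as.numeric(init), value = id_mse)
  }
  registered <- .warp_affine_cpp(grid, best$par[1], best$par[2],
                                 best$par[3], best$par[4])
  structure(
    list(
      params = affine_params(best$par[1], best$par[2], best$par[3],
                             best$par[4]),
      final_mse = best$value,
      iou = compute_iou(registered, ref),
      registered = registered
    ),
    class = "registration_result"
  )
}

#' Register every map of a dataset to its side template
#'
#' Builds one template per side from the valid samples of `reference_from`
#' (default: the dataset itself) and registers all maps of `dataset` to the
#' template matching their annotated side.
#'
#' @param dataset a `pressure_dataset`.
#' @param reference_from dataset supplying the valid cohort for the
#'   templates.
#' @param templates optional precomputed `list(L = , R = )` of templates.
#' @param ... passed to [register_map()].
#' @return List with `dataset` (registered grids, same manifest), `report`
#'   (per-sample data frame of parameters, MSE, IoU) and `templates`.
#' @export
register_dataset <- function(dataset, reference_from = dataset,
                             templates = NULL, ...) {
  if (is.null(templates)) {
    templates <- list(L = build_reference(reference_from, "L"),
                      R = build_reference(reference_from, "R"))
  }
  n <- nrow(dataset$manifest)
  out <- dataset
  report <- data.frame(
    sample_id = dataset$manifest$sample_id, angle = numeric(n),
    shift_rows = numeric(n), shift_cols = numeric(n), zoom = numeric(n),
    mse = numeric(n), iou = numeric(n), stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    side <- dataset$manifest$side[i]
    res <- register_map(dataset$grids[i, , ], templates[[side]], ...)
    out$grids[i, , ] <- res$registered
    report[i, 2:5] <- as.numeric(res$params)
    report$mse[i] <- res$final_mse
    report$iou[i] <- res$iou
  }
  list(dataset = out, report = report, templates = templates)
}
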