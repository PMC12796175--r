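#' Construct a single pressure sample
#'
#' A pressure sample is one standardized 64x64 plantar pressure map in
#' `[0, 1]` together with its metadata: subject, laterality, acquisition
#' condition, quality label and provenance.
#'
#' @param grid 64x64 numeric matrix with values in `[0, 1]`.
#' @param sample_id unique sample identifier.
#' @param subject_id opaque subject identifier (grouping key for
#'   cross-validation).
#' @param side `"L"` or `"R"`.
#' @param condition `"static"` or `"dynamic"`.
#' @param label integer quality label: 0 valid, 1 general acquisition error,
#'   2 double-foot capture, 3 inverted orientation, 4 incorrect side
#'   annotation.
#' @param provenance `"real"` or `"synthetic"`.
#' @param source_ids character vector of sample ids this sample was derived
#'   from; empty for non-derived samples.
#' @return An object of class `pressure_sample`.
#' @export
pressure_sample <- function(grid, sample_id, subject_id, side,
                            condition = "static", label = 0L,
                            provenance = "real", source_ids = character()) {
  s <- structure(
    list(
      grid = grid, sample_id = as.character(sample_id),
      subject_id = as.character(subject_id), side = side,
      condition = condition, label = as.integer(label),
      provenance = provenance, source_ids = as.character(source_ids)
    ),
    class = "pressure_sample"
  )
  validate_sample(s)
  s
}

validate_sample <- function(s) {
  stopifnot(is.matrix(s$grid))
  if (!all(dim(s$grid) == GRID_SIZE)) {
    stop("grid must be ", GRID_SIZE, "x", GRID_SIZE, call. = FALSE)
  }
  if (anyNA(s$grid) || min(s$grid) < 0 || max(s$grid) > 1) {
    stop("grid values must lie in [0, 1]", call. = FALSE)
  }
  if (!s$side %in% SIDES) stop("side must be 'L' or 'R'", call. = FALSE)
  if (!s$condition %in% CONDITIONS) {
    stop("condition must be 'static' or 'dynamic'", call. = FALSE)
  }
  if (!s$label %in% LABELS) stop("label must be in 0..4", call. = FALSE)
  if (!s$provenance %in% PROVENANCES) {
    stop("provenance must be 'real' or 'synthetic'", call. = FALSE)
  }
  if (s$provenance == "synthetic" && length(s$source_ids) == 0) {
    stop("synthetic samples must carry non-empty source_ids", call. = FALSE)
  }
  invisible(s)
}

#' @export
print.pressure_sample <- function(x, ...) {
  cat(sprintf(
    "<pressure_sample %s: subject %s, side %s, %s, label %d (%s), %s>\n",
    x$sample_id, x$subject_id, x$side, x$condition, x$label,
    LABEL_NAMES[x$label + 1L], x$provenance
  ))
  invisible(x)
}

#' Assemble samples into a dataset
#'
#' A `pressure_dataset` couples an `n x 64 x 64` grid array with a manifest
#' data frame (one row per sample, same order).  Sample ids must be unique.
#'
#' @param samples list of [pressure_sample()] objects.
#' @return A `pressure_dataset` with elements `grids` (array) and
#'   `manifest` (data frame with columns `sample_id`, `subject_id`, `side`,
#'   `condition`, `label`, `provenance`, `source_ids`).
#' @export
as_pressure_dataset <- function(samples) {
  stopifnot(is.list(samples))
  lapply(samples, validate_sample)
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  n <- length(samples)
  grids <- array(0, dim = c(n, GRID_SIZE, GRID_SIZE))
  for (i in seq_len(n)) grids[i, , ] <- samples[[i]]$grid
  manifest <- data.frame(
    sample_id = ids,
    subject_id = vapply(samples, function(s) s$subject_id, character(1)),
    side = vapply(samples, function(s) s$side, character(1)),
    condition = vapply(samples, function(s) s$condition, character(1)),
    label = vapply(samples, function(s) s$label, integer(1)),
    provenance = vapply(samples, function(s) s$provenance, character(1)),
    source_ids = vapply(
      samples, function(s) paste(s$source_ids, collapse = ";"), character(1)
    ),
    stringsAsFactors = FALSE
  )
  structure(list(grids = grids, manifest = manifest),
            class = "pressure_dataset")
}

#' @export
print.pressure_dataset <- function(x, ...) {
  tab <- counts_by_label(x)
  cat(sprintf(
    "<pressure_dataset: %d samples, %d subjects>\n  counts by label: %s\n",
    nrow(x$manifest), length(unique(x$manifest$subject_id)),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}

#' Per-label sample counts of a dataset
#'
#' @param dataset a `pressure_dataset`.
#' @return Named integer vector over labels `"0"`..`"4"`.
#' @export
counts_by_label <- function(dataset) {
  tab <- table(factor(dataset$manifest$label, levels = LABELS))
  stats::setNames(as.integer(tab), names(tab))
}

#' Extract one sample from a dataset
#'
#' @param dataset a `pressure_dataset`.
#' @param i row index or sample id.
#' @return A [pressure_sample()].
#' @export
get_sample <- function(dataset, i) {
  if (is.character(i)) i <- match(i, dataset$manifest$sample_id)
  m <- dataset$manifest[i, ]
  src <- strsplit(m$source_ids, ";", fixed = TRUE)[[1]]
  pressure_sample(
    grid = dataset$grids[i, , ], sample_id = m$sample_id,
    subject_id = m$subject_id, side = m$side, condition = m$condition,
    label = m$label, provenance = m$provenance,
    source_ids = src[nzchar(src)]
  )
}

#' Subset a dataset by row indices
#'
#' @param dataset a `pressure_dataset`.
#' @param idx integer or logical index into the manifest rows.
#' @return A `pressure_dataset` with the selected samples, in `idx` order.
#' @export
subset_dataset <- function(dataset, idx) {
  if (is.logical(idx)) idx <- which(idx)
  structure(
    list(
      grids = dataset$grids[idx, , , drop = FALSE],
      manifest = dataset$manifest[idx, , drop = FALSE]
    ),
    class = "pressure_dataset"
  )
}

#' Embed a raw pressure grid into the standardized 64x64 canvas
#'
#' The raw grid (arbitrary size, possibly anisotropic sensor spacing) is
#' proportionally resized so that its longer physical side spans 64 pixels,
#' preserving the physical aspect ratio `H * row_spacing : W * col_spacing`,
#' then centred on a zero-padded 64x64 canvas.  Bilinear interpolation is
#' used and intensities are re-normalized to max 1 afterwards.
#'
#' @param raw non-negative numeric matrix (H x W).
#' @param row_spacing,col_spacing physical sensor spacing in mm (> 0).
#' @return A 64x64 matrix in `[0, 1]`.
#' @export
embed_to_grid <- function(raw, row_spacing = 1, col_spacing = 1) {
  if (!is.matrix(raw) || nrow(raw) < 1 || ncol(raw) < 1) {
    stop("raw must be a non-empty matrix", call. = FALSE)
  }
  if (row_spacing <= 0 || col_spacing <= 0) {
    stop("sensor spacings must be positive", call. = FALSE)
  }
  if (anyNA(raw) || min(raw) < 0) {
    stop("raw grid must be non-negative", call. = FALSE)
  }
  ph <- nrow(raw) * row_spacing
  pw <- ncol(raw) * col_spacing
  if (ph >= pw) {
    out_h <- GRID_SIZE
    out_w <- max(1L, round(GRID_SIZE * pw / ph))
  } else {
    out_w <- GRID_SIZE
    out_h <- max(1L, round(GRID_SIZE * ph / pw))
  }
  content <-
    if (out_h == nrow(raw) && out_w == ncol(raw)) raw
    else .resize_bilinear_cpp(raw, out_h, out_w)
  canvas <- matrix(0, GRID_SIZE, GRID_SIZE)
  r0 <- (GRID_SIZE - out_h) %/% 2L
  c0 <- (GRID_SIZE - out_w) %/% 2L
  canvas[r0 + seq_len(out_h), c0 + seq_len(out_w)] <- content
  if (max(canvas) > 0) canvas <- canvas / max(canvas)
  canvas
}

#' Normalize pressure intensities to [0, 1]
#'
#' Divides by the grid maximum so the strongest pixel becomes 1; zeros are
#' preserved.
#'
#' @param grid non-negative numeric matrix with at least one positive value.
#' @return The rescaled matrix.
#' @export
normalize_intensity <- function(grid) {
  if (anyNA(grid) || min(grid) < 0) {
    stop("grid must be non-negative", call. = FALSE)
  }
  m <- max(grid)
  if (m <= 0) stop("cannot normalize an all-zero grid", call. = FALSE)
  grid / m
}

#' Remove exact duplicate samples
#'
#' Two samples are duplicates when their standardized grids are bit-identical
#' and they share subject, side and condition.  The first record in manifest
#' order is retained from each duplicate group.
#'
#' @param dataset a `pressure_dataset`.
#' @return The deduplicated `pressure_dataset`.
#' @export
deduplicate <- function(dataset) {
  n <- nrow(dataset$manifest)
  if (n <= 1) return(dataset)
  keys <- vapply(seq_len(n), function(i) {
    m <- dataset$manifest[i, ]
    paste(
      m$subject_id, m$side, m$condition,
      paste(sprintf("%.17g", dataset$grids[i, , ]), collapse = ","),
      sep = "|"
    )
  }, character(1))
  subset_dataset(dataset, !duplicated(keys))
}

#' Read / write a dataset directory
#'
#' The on-disk container is a plain directory holding `manifest.csv`
#' (columns `sample_id`, `subject_id`, `side`, `condition`, `label`,
#' `provenance`, `source_ids` with `;`-separated ids) and one headerless
#' CSV matrix per sample, named `<sample_id>.csv`.  The round trip
#' write-then-read is lossless: grids are stored with full double precision.
#'
#' @param path directory path.
#' @return `read_dataset` returns a `pressure_dataset`; `write_dataset`
#'   returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv under ", path, call. = FALSE)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE,
                              colClasses = c(
                                sample_id = "character",
                                subject_id = "character",
                                source_ids = "character"
                              ))
  required <- c("sample_id", "subject_id", "side", "condition", "label",
                "provenance", "source_ids")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(manifest)
  if (n == 0) return(as_pressure_dataset(list()))
  for (i in seq_len(n)) {  # validate the whole manifest before any grid IO
    m <- manifest[i, ]
    bad <- !m$label %in% LABELS || !m$side %in% SIDES ||
      !m$condition %in% CONDITIONS || !m$provenance %in% PROVENANCES
    if (bad) {
      stop(sprintf("malformed manifest row %d (sample_id %s)", i, m$sample_id),
           call. = FALSE)
    }
  }
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    m <- manifest[i, ]
    g <- as.matrix(utils::read.csv(
      file.path(path, paste0(m$sample_id, ".csv")),
      header = FALSE
    ))
    dimnames(g) <- NULL
    src <- strsplit(m$source_ids, ";", fixed = TRUE)[[1]]
    samples[[i]] <- pressure_sample(
      grid = g, sample_id = m$sample_id, subject_id = m$subject_id,
      side = m$side, condition = m$condition, label = m$label,
      provenance = m$provenance, source_ids = src[nzchar(src)]
    )
  }
  as_pressure_dataset(samples)
}

#' @rdname read_dataset
#' @param dataset a `pressure_dataset` to serialize.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$manifest, file.path(path, "manifest.csv"),
                   row.names = FALSE)
  for (i in seq_len(nrow(dataset$manifest))) {
    g <- format(dataset$grids[i, , ], digits = 17, scientific = TRUE,
                trim = TRUE)
    utils::write.table(
      matrix(g, GRID_SIZE, GRID_SIZE),
      file.path(path, paste0(dataset$manifest$sample_id[i], ".csv")),
      sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}
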