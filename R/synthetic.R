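# Synthetic plantar-pressure generator and the four outlier transformations.
# Orientation convention: row 0 = distal (toes), row 63 = proximal (heel);
# columns increase left-to-right in the image plane.  A left foot is built
# from the parameter template; the right foot is its column mirror.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Sample subject-level foot shape parameters
#'
#' Draws one subject's anatomical parameters for the synthetic foot model:
#' a heel ellipse, a lateral midfoot band with a medial arch void, five
#' metatarsal blobs and five toe blobs, plus per-sample jitter and noise
#' settings.  Parameters describe the LEFT foot; the right foot is derived
#' by column mirroring.
#'
#' @param seed integer seed for the subject draw; `NULL` uses the current
#'   RNG stream.
#' @param noise_sd multiplicative intensity noise SD applied per sample.
#' @param jitter_angle_sd,jitter_shift_sd,jitter_zoom_sd SDs of the random
#'   per-sample placement jitter (degrees, pixels, zoom fraction).
#' @return A list of class `foot_shape_params`.
#' @export
foot_shape_params <- function(seed = NULL, noise_sd = 0.10,
                              jitter_angle_sd = 2, jitter_shift_sd = 1.5,
                              jitter_zoom_sd = 0.03) {
  with_seed(seed, {
    size <- stats::rnorm(1, 1, 0.06)          # overall foot size factor
    size <- min(max(size, 0.85), 1.15)
    width <- stats::rnorm(1, 1, 0.05)         # mediolateral width factor
    width <- min(max(width, 0.85), 1.15)
    heel_peak <- stats::runif(1, 0.85, 1.0)
    meta_peak <- stats::runif(1, 0.75, 1.0)
    toe_peak <- stats::runif(1, 0.45, 0.7)
    mid_peak <- stats::runif(1, 0.30, 0.45)
    arch_offset <- stats::runif(1, 2, 5)      # medial concavity depth, px
    structure(list(
      size = size, width = width,
      heel = list(center = c(50, 31), radii = c(7.5, 6.5), peak = heel_peak),
      midfoot = list(rows = c(30, 44), center_col = 36, width = 5.5,
                     peak = mid_peak),
      arch_offset = arch_offset,
      meta = list(
        rows = c(23, 21.5, 21, 21.5, 23),
        cols = c(22, 27.5, 32.5, 37.5, 42),
        radii = c(3.4, 3.0, 2.9, 2.8, 2.7),
        peaks = meta_peak * c(1.0, 0.95, 0.88, 0.8, 0.72)
      ),
      toes = list(
        rows = c(13, 12.5, 12.5, 13, 13.5),
        cols = c(21.5, 27, 31.5, 36, 40.5),
        radii = c(3.0, 2.1, 2.0, 1.9, 1.8),
        peaks = toe_peak * c(1.0, 0.8, 0.72, 0.65, 0.6)
      ),
      noise_sd = noise_sd,
      jitter_angle_sd = jitter_angle_sd,
      jitter_shift_sd = jitter_shift_sd,
      jitter_zoom_sd = jitter_zoom_sd
    ), class = "foot_shape_params")
  })
}

# Deterministic left-foot intensity template from subject parameters.
foot_template <- function(params) {
  sz <- GRID_SIZE
  r <- matrix(rep(0:(sz - 1), sz), sz, sz)
  c <- matrix(rep(0:(sz - 1), each = sz), sz, sz)
  cr0 <- 32  # anatomical anchor row
  gauss <- function(cr, cc, sr, sc, peak) {
    peak * exp(-(((r - cr)^2) / (2 * sr^2) + ((c - cc)^2) / (2 * sc^2)))
  }
  p <- params
  scale_r <- function(row) cr0 + (row - cr0) * p$size
  scale_c <- function(col) 31.5 + (col - 31.5) * p$size * p$width
  g <- matrix(0, sz, sz)
  # heel: a primary loading maximum, comparable to the metatarsal heads
  g <- g + 1.5 * gauss(scale_r(p$heel$center[1]), scale_c(p$heel$center[2]),
                       p$heel$radii[1] * p$size,
                       p$heel$radii[2] * p$size * p$width,
                       p$heel$peak)
  # lateral midfoot band (arch void on the medial/left column side)
  mid_rows <- seq(p$midfoot$rows[1], p$midfoot$rows[2], by = 2)
  for (mr in mid_rows) {
    # band drifts medially toward heel; arch offset pushes it lateral distally
    frac <- (mr - p$midfoot$rows[1]) / diff(p$midfoot$rows)
    cc <- p$midfoot$center_col - frac * p$arch_offset * 0.4 +
      (1 - frac) * p$arch_offset * 0.4
    g <- g + gauss(scale_r(mr), scale_c(cc), 2.6 * p$size,
                   p$midfoot$width * p$size * p$width * 0.55, p$midfoot$peak)
  }
  # metatarsal heads
  for (i in seq_along(p$meta$cols)) {
    g <- g + gauss(scale_r(p$meta$rows[i]), scale_c(p$meta$cols[i]),
                   p$meta$radii[i] * 1.25 * p$size,
                   p$meta$radii[i] * p$size * p$width, p$meta$peaks[i])
  }
  # toes (connected to metatarsals by slightly elongated row radii)
  for (i in seq_along(p$toes$cols)) {
    g <- g + gauss(scale_r(p$toes$rows[i]), scale_c(p$toes$cols[i]),
                   p$toes$radii[i] * 1.7 * p$size,
                   p$toes$radii[i] * p$size * p$width, p$toes$peaks[i])
  }
  g[g < 0.02] <- 0  # cut far tails so the background is exactly zero
  g / max(g)
}

#' Simulate one valid plantar pressure sample
#'
#' Renders the subject's foot template for the requested side (right feet
#' are column-mirrored left templates), applies a small random placement
#' jitter (rotation, shift, zoom) and multiplicative intensity noise, and
#' re-normalizes to `[0, 1]`.  Deterministic for a fixed seed.
#'
#' @param params subject parameters from [foot_shape_params()].
#' @param side `"L"` or `"R"`.
#' @param subject_id subject identifier stored in the sample.
#' @param condition `"static"` or `"dynamic"`; dynamic maps receive a
#'   mildly accentuated forefoot load.
#' @param seed per-sample seed; `NULL` uses the current RNG stream.
#' @param sample_id id for the new sample; derived from subject, side and
#'   condition when missing.
#' @return A [pressure_sample()] with label 0.
#' @export
simulate_valid_foot <- function(params, side, subject_id,
                                condition = "static", seed = NULL,
                                sample_id = NULL) {
  stopifnot(inherits(params, "foot_shape_params"), side %in% SIDES)
  g <- foot_template(params)
  if (condition == "dynamic") {
    ramp <- 1 + 0.25 * (1 - (0:(GRID_SIZE - 1)) / (GRID_SIZE - 1))
    g <- g * matrix(ramp, GRID_SIZE, GRID_SIZE)
  }
  if (side == "R") g <- g[, GRID_SIZE:1]
  g <- with_seed(seed, {
    ang <- stats::rnorm(1, 0, params$jitter_angle_sd)
    shr <- stats::rnorm(1, 0, params$jitter_shift_sd)
    shc <- stats::rnorm(1, 0, params$jitter_shift_sd)
    zm <- exp(stats::rnorm(1, 0, params$jitter_zoom_sd))
    if (side == "R") {  # mirror-covariant placement jitter
      ang <- -ang
      shc <- -shc
    }
    out <- .warp_affine_cpp(g / max(g), ang, shr, shc, zm)
    if (params$noise_sd > 0) {
      noise <- 1 + params$noise_sd *
        matrix(stats::rnorm(GRID_SIZE^2), GRID_SIZE, GRID_SIZE)
      noise[noise < 0] <- 0
      out <- out * noise
    }
    out
  })
  g <- g / max(g)
  if (is.null(sample_id)) {
    sample_id <- paste(subject_id, side, condition, sep = "_")
  }
  pressure_sample(g, sample_id, subject_id, side, condition,
                  label = 0L, provenance = "real")
}

new_derived <- function(grid, src, label, id, side = src$side,
                        subject_id = src$subject_id, sources = src$sample_id,
                        provenance = "synthetic") {
  pressure_sample(
    grid, id, subject_id, side, src$condition, label,
    provenance = provenance, source_ids = sources
  )
}

#' Create a general acquisition error (label 1) by regional cropping
#'
#' Zeroes the distal (forefoot) or proximal (heel) part of a valid sample.
#' The forefoot crop removes the distal fraction `f ~ U(0.45, 0.55)` of
#' rows; the heel crop removes the proximal fraction `f ~ U(0.60, 0.70)`.
#' Untouched pixels are preserved exactly and the laterality label is
#' retained.
#'
#' @param sample a valid (label 0) [pressure_sample()].
#' @param mode `"forefoot"` or `"heel"`.
#' @param seed optional seed for the crop fraction draw.
#' @param fraction optional fixed crop fraction overriding the random draw.
#' @param id sample id for the derived sample.
#' @return A [pressure_sample()] with label 1.
#' @export
make_general_error <- function(sample, mode = c("forefoot", "heel"),
                               seed = NULL, fraction = NULL, id = NULL) {
  mode <- match.arg(mode)
  if (sample$label != 0L) {
    stop("general-error source must be a valid (label 0) sample",
         call. = FALSE)
  }
  f <- if (!is.null(fraction)) fraction else with_seed(seed, {
    if (mode == "forefoot") stats::runif(1, 0.45, 0.55)
    else stats::runif(1, 0.60, 0.70)
  })
  k <- ceiling(f * GRID_SIZE)
  g <- sample$grid
  if (mode == "forefoot") {
    g[seq_len(k), ] <- 0            # rows 0..k-1 (distal)
  } else {
    g[(GRID_SIZE - k + 1):GRID_SIZE, ] <- 0  # proximal k rows
  }
  if (is.null(id)) id <- paste0(sample$sample_id, "-ge")
  new_derived(g, sample, 1L, id)
}

#' Create a double-foot capture (label 2) from a left/right pair
#'
#' Downscales each 64x64 input to a 32x32 tile and places the two tiles in
#' diagonally opposite quadrants (upper-left + lower-right); which foot
#' occupies which quadrant is chosen uniformly at random.  Each tile is
#' independently shifted 0-2 px in one uniformly chosen cardinal direction.
#' The laterality label of the composite is assigned at random.
#'
#' @param left,right valid (label 0) samples of the same subject, sides
#'   `"L"` and `"R"`.
#' @param seed optional seed controlling configuration, jitter and the
#'   random side label.
#' @param config optional `"LR"` (left tile upper-left) or `"RL"` override.
#' @param jitter optional 2x2 matrix of fixed (row, col) shifts per tile,
#'   overriding the random draw.
#' @param id sample id for the derived sample.
#' @return A [pressure_sample()] with label 2.
#' @export
make_double_foot <- function(left, right, seed = NULL, config = NULL,
                             jitter = NULL, id = NULL) {
  if (left$label != 0L || right$label != 0L) {
    stop("double-foot sources must be valid (label 0) samples", call. = FALSE)
  }
  if (left$side != "L" || right$side != "R") {
    stop("inputs must be a left and a right sample, in that order",
         call. = FALSE)
  }
  if (left$subject_id != right$subject_id) {
    stop("double-foot sources must come from the same subject", call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(config)) config <- if (stats::runif(1) < 0.5) "LR" else "RL"
    if (is.null(jitter)) {
      jitter <- t(vapply(1:2, function(i) {
        mag <- sample(0:2, 1)
        dir <- sample(1:4, 1)  # up, down, left, right
        switch(dir, c(-mag, 0), c(mag, 0), c(0, -mag), c(0, mag))
      }, numeric(2)))
    }
    side <- if (stats::runif(1) < 0.5) "L" else "R"
    half <- GRID_SIZE / 2L
    tiles <- list(
      .resize_bilinear_cpp(left$grid, half, half),
      .resize_bilinear_cpp(right$grid, half, half)
    )
    # quadrant top-left corners (1-based): UL and LR
    corners <- if (config == "LR") list(c(1, 1), c(half + 1, half + 1))
               else list(c(half + 1, half + 1), c(1, 1))
    g <- matrix(0, GRID_SIZE, GRID_SIZE)
    for (i in 1:2) {
      r0 <- corners[[i]][1] + jitter[i, 1]
      c0 <- corners[[i]][2] + jitter[i, 2]
      rr <- r0:(r0 + half - 1)
      cc <- c0:(c0 + half - 1)
      ok_r <- rr >= 1 & rr <= GRID_SIZE
      ok_c <- cc >= 1 & cc <= GRID_SIZE
      g[rr[ok_r], cc[ok_c]] <- g[rr[ok_r], cc[ok_c]] +
        tiles[[i]][which(ok_r), which(ok_c)]
    }
    g[g > 1] <- 1
    if (is.null(id)) id <- paste0(left$sample_id, "+", right$sample_id, "-df")
    new_derived(g, left, 2L, id, side = side,
                sources = c(left$sample_id, right$sample_id))
  })
}

#' Create an inverted-orientation outlier (label 3)
#'
#' Flips the map vertically (row reversal, heel and toes exchanged).  A
#' `"rot180"` mode additionally mirrors columns, turning the flip into a
#' half-turn rotation.  Laterality is retained.
#'
#' @param sample a valid (label 0) [pressure_sample()].
#' @param inversion_mode `"flip_rows"` (default) or `"rot180"`.
#' @param id sample id for the derived sample.
#' @return A [pressure_sample()] with label 3.
#' @export
make_inverted <- function(sample, inversion_mode = c("flip_rows", "rot180"),
                          id = NULL) {
  inversion_mode <- match.arg(inversion_mode)
  if (sample$label != 0L) {
    stop("inversion source must be a valid (label 0) sample", call. = FALSE)
  }
  g <- sample$grid[GRID_SIZE:1, ]
  if (inversion_mode == "rot180") g <- g[, GRID_SIZE:1]
  if (is.null(id)) id <- paste0(sample$sample_id, "-inv")
  new_derived(g, sample, 3L, id)
}

#' Create an incorrect-side-annotation outlier (label 4)
#'
#' Toggles the laterality label while leaving the pressure map untouched.
#'
#' @param sample a valid (label 0) [pressure_sample()].
#' @param id sample id for the derived sample.
#' @return A [pressure_sample()] with label 4.
#' @export
make_side_swap <- function(sample, id = NULL) {
  if (sample$label != 0L) {
    stop("side-swap source must be a valid (label 0) sample", call. = FALSE)
  }
  if (is.null(id)) id <- paste0(sample$sample_id, "-ss")
  new_derived(sample$grid, sample, 4L, id,
              side = if (sample$side == "L") "R" else "L")
}

#' Resolve multiple quality annotations to a single category
#'
#' The incorrect-side-annotation label (4) has the lowest priority and is
#' superseded by any co-occurring outlier category; the valid label only
#' survives on its own.  Multiple non-side outlier categories are ambiguous
#' and raise an error, since no ranking is defined among them.
#'
#' @param labels integer vector (a set) of observed categories in 0..4.
#' @return The single resolved category.
#' @export
apply_priority_rule <- function(labels) {
  labels <- unique(as.integer(labels))
  if (length(labels) == 0 || !all(labels %in% LABELS)) {
    stop("labels must be a non-empty subset of 0..4", call. = FALSE)
  }
  hard <- setdiff(labels, c(0L, 4L))
  if (length(hard) > 1) {
    stop("ambiguous annotation: multiple outlier categories ",
         paste(sort(hard), collapse = ","), call. = FALSE)
  }
  if (length(hard) == 1) return(hard)
  if (4L %in% labels) return(4L)
  0L
}

#' Augment each outlier category to a fixed per-category size
#'
#' Appends synthetic outliers derived from randomly chosen valid samples
#' until every category 1-4 holds exactly `target` samples.  Double-foot
#' composites are built from same-subject left/right valid pairs; all
#' derived samples inherit their source subject so grouped cross-validation
#' keeps them with their source.
#'
#' @param dataset a `pressure_dataset` containing valid (label 0) samples.
#' @param target per-category target count (default 500).
#' @param seed integer seed for source selection and the generators.
#' @return The augmented `pressure_dataset`.
#' @export
augment_to_target <- function(dataset, target = 500L, seed = 1L) {
  counts <- counts_by_label(dataset)
  existing <- counts[as.character(1:4)]
  if (any(existing > target)) {
    stop("target is below an existing category count", call. = FALSE)
  }
  valid_idx <- which(dataset$manifest$label == 0L)
  if (length(valid_idx) == 0) {
    stop("no valid samples to derive from", call. = FALSE)
  }
  with_seed(seed, {
    new_samples <- list()
    k <- 0L
    add <- function(s) {
      k <<- k + 1L
      new_samples[[k]] <<- s
    }
    n_needed <- target - existing
    # category 1: regional crops, alternating forefoot/heel modes
    if (n_needed[1] > 0) {
      src <- sample(valid_idx, n_needed[1], replace = TRUE)
      for (j in seq_len(n_needed[1])) {
        add(make_general_error(
          get_sample(dataset, src[j]),
          mode = if (j %% 2 == 1) "forefoot" else "heel",
          id = sprintf("syn1_%04d", j)
        ))
      }
    }
    # category 2: same-subject left/right pairs
    if (n_needed[2] > 0) {
      vm <- dataset$manifest[valid_idx, ]
      pairable <- intersect(
        unique(vm$subject_id[vm$side == "L"]),
        unique(vm$subject_id[vm$side == "R"])
      )
      if (length(pairable) == 0) {
        stop("no subject has valid samples of both sides", call. = FALSE)
      }
      subj <- sample(pairable, n_needed[2], replace = TRUE)
      for (j in seq_len(n_needed[2])) {
        li <- valid_idx[vm$subject_id == subj[j] & vm$side == "L"]
        ri <- valid_idx[vm$subject_id == subj[j] & vm$side == "R"]
        add(make_double_foot(
          get_sample(dataset, if (length(li) > 1) sample(li, 1) else li),
          get_sample(dataset, if (length(ri) > 1) sample(ri, 1) else ri),
          id = sprintf("syn2_%04d", j)
        ))
      }
    }
    # categories 3 and 4: flips and side swaps
    for (cat in 3:4) {
      if (n_needed[cat] <= 0) next
      src <- sample(valid_idx, n_needed[cat], replace = TRUE)
      for (j in seq_len(n_needed[cat])) {
        s <- get_sample(dataset, src[j])
        add(
          if (cat == 3) make_inverted(s, id = sprintf("syn3_%04d", j))
          else make_side_swap(s, id = sprintf("syn4_%04d", j))
        )
      }
    }
    if (k == 0) return(dataset)
    extra <- as_pressure_dataset(new_samples)
    bind_datasets(dataset, extra)
  })
}

# row-bind two datasets (grids and manifests)
bind_datasets <- function(a, b) {
  n1 <- nrow(a$manifest)
  n2 <- nrow(b$manifest)
  grids <- array(0, dim = c(n1 + n2, GRID_SIZE, GRID_SIZE))
  if (n1 > 0) grids[seq_len(n1), , ] <- a$grids
  if (n2 > 0) grids[n1 + seq_len(n2), , ] <- b$grids
  manifest <- rbind(a$manifest, b$manifest)
  rownames(manifest) <- NULL
  if (anyDuplicated(manifest$sample_id)) {
    stop("duplicate sample ids when binding datasets", call. = FALSE)
  }
  structure(list(grids = grids, manifest = manifest),
            class = "pressure_dataset")
}

#' Simulate a complete study dataset
#'
#' Generates `n_subjects` subjects, each contributing a left and a right
#' valid sample under the requested conditions, optionally appends
#' generator-derived stand-ins for real outliers (provenance `"real"`),
#' and optionally augments every outlier category to `target` samples with
#' synthetic derivations.
#'
#' @param n_subjects number of subjects.
#' @param seed master seed; all randomness in the simulation derives from
#'   it.
#' @param conditions acquisition conditions generated per subject and side.
#' @param real_outliers integer vector of length 4: how many real-provenance
#'   outlier samples of categories 1-4 to include.
#' @param n_valid optionally trim the valid cohort to exactly this many
#'   samples (drops the final ones).
#' @param target per-category augmentation target; `NULL` skips
#'   augmentation.
#' @return A `pressure_dataset`.
#' @export
simulate_dataset <- function(n_subjects = 200L, seed = 1L,
                             conditions = c("static", "dynamic"),
                             real_outliers = c(0L, 0L, 0L, 0L),
                             n_valid = NULL, target = 500L) {
  with_seed(seed, {
    samples <- list()
    k <- 0L
    for (i in seq_len(n_subjects)) {
      subject <- sprintf("S%04d", i)
      params <- foot_shape_params()
      for (cond in conditions) {
        for (side in SIDES) {
          k <- k + 1L
          samples[[k]] <- simulate_valid_foot(params, side, subject,
                                              condition = cond)
        }
      }
    }
    if (!is.null(n_valid)) {
      stopifnot(n_valid <= k)
      samples <- samples[seq_len(n_valid)]
    }
    ds <- as_pressure_dataset(samples)
    # real-provenance outlier stand-ins, derived from the valid cohort but
    # recorded as real recordings (empty source list)
    if (any(real_outliers > 0)) {
      vi <- which(ds$manifest$label == 0L)
      vm <- ds$manifest[vi, ]
      extra <- list()
      e <- 0L
      strip <- function(s, id) {
        s$sample_id <- id
        s$provenance <- "real"
        s$source_ids <- character()
        validate_sample(s)
        s
      }
      for (cat in 1:4) {
        nr <- real_outliers[cat]
        if (nr == 0) next
        for (j in seq_len(nr)) {
          e <- e + 1L
          id <- sprintf("real%d_%03d", cat, j)
          if (cat == 2) {
            pairable <- intersect(unique(vm$subject_id[vm$side == "L"]),
                                  unique(vm$subject_id[vm$side == "R"]))
            subj <- sample(pairable, 1)
            li <- vi[vm$subject_id == subj & vm$side == "L"]
            ri <- vi[vm$subject_id == subj & vm$side == "R"]
            s <- make_double_foot(
              get_sample(ds, if (length(li) > 1) sample(li, 1) else li),
              get_sample(ds, if (length(ri) > 1) sample(ri, 1) else ri)
            )
          } else {
            src <- get_sample(ds, vi[sample(length(vi), 1)])
            s <- switch(as.character(cat),
              "1" = make_general_error(src,
                mode = if (j %% 2 == 1) "forefoot" else "heel"),
              "3" = make_inverted(src),
              "4" = make_side_swap(src)
            )
          }
          extra[[e]] <- strip(s, id)
        }
      }
      all_samples <- c(
        lapply(seq_len(nrow(ds$manifest)), function(i) get_sample(ds, i)),
        extra
      )
      ds <- as_pressure_dataset(all_samples)
    }
    if (!is.null(target)) {
      ds <- augment_to_target(ds, target = target,
                              seed = sample.int(.Machine$integer.max, 1))
    }
    ds
  })
}
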