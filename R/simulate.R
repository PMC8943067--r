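#' Configuration for the synthetic multiplexed-field simulator
#'
#' The simulator emulates a multiplexed serial-immunostaining field:
#' sparse, round, non-overlapping adherent cells on a dark background,
#' each carrying one of a small library of phenotypes. A phenotype is a
#' per-marker expression probability vector; marker presence is drawn
#' independently per pixel given the cell's phenotype, so each cell yields
#' a distribution of CMPs rather than a single one (which is what makes a
#' per-cell "top 20 CMPs" summary meaningful). Marker 0 is punctate
#' autofluorescence (small bright granules); the last marker is diffuse
#' F-actin. Grayscale images are `base + amplitude * presence + noise`
#' clipped at zero, and each channel has a matched post-bleach background
#' image (`bleach_residual` of the clean signal plus fresh noise), so
#' subtraction and thresholding are non-trivial but controllable.
#'
#' @param field_size Pixels per side (512 by default; 2048 mirrors a full
#'   instrument field).
#' @param n_cells Cells per field.
#' @param cell_radius_range Min/max cell radius in pixels.
#' @param n_markers Panel size (12, or 7 for reduced-panel studies).
#' @param phenotype_library Phenotype x marker probability matrix in
#'   \[0, 1\] (marker 0's column is ignored: autofluorescence comes from
#'   the puncta process). Default: [default_phenotype_library()].
#' @param phenotype_weights Mapping from (group, sex) to a probability
#'   vector over phenotypes: a function, a single numeric vector (used for
#'   all groups), or a data frame with columns `group`, `sex` (`NA` = any)
#'   and list-column `weights`. Default:
#'   [default_phenotype_weights()] — treatment spreads weight over more
#'   phenotypes (higher diversity), sex shifts which phenotypes are
#'   favored.
#' @param af_puncta_rate Expected autofluorescence puncta per cell.
#' @param puncta_radius_range Min/max puncta radius in pixels.
#' @param noise_sd Gaussian noise SD on the grayscale images.
#' @param bleach_residual Fraction of clean signal remaining in the
#'   post-bleach background image.
#' @param shift_max Max absolute per-channel mis-registration in pixels.
#' @param base_level,amplitude Grayscale background level and
#'   presence amplitude.
#' @param margin Border margin excluded downstream; cells are placed
#'   fully inside it.
#' @param seed Master seed; per-sample streams use `seed + sample index`.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(field_size = 512L, n_cells = 12L,
                       cell_radius_range = c(8, 14), n_markers = 12L,
                       phenotype_library = NULL, phenotype_weights = NULL,
                       af_puncta_rate = 4, puncta_radius_range = c(1, 2),
                       noise_sd = 6, bleach_residual = 0.1, shift_max = 0L,
                       base_level = 10, amplitude = 190, margin = 15L,
                       seed = 1L) {
  if (is.null(phenotype_library)) {
    phenotype_library <- default_phenotype_library(n_markers)
  }
  stopifnot(is.matrix(phenotype_library),
            ncol(phenotype_library) == n_markers,
            all(phenotype_library >= 0 & phenotype_library <= 1),
            n_cells >= 0, field_size >= 1, n_markers >= 2,
            length(cell_radius_range) == 2,
            cell_radius_range[1] <= cell_radius_range[2],
            af_puncta_rate >= 0, noise_sd >= 0,
            bleach_residual >= 0, bleach_residual <= 1,
            shift_max >= 0, margin >= 0, amplitude > 0)
  n_ph <- nrow(phenotype_library)
  weights_fn <- as_weights_fn(
    phenotype_weights %||% default_phenotype_weights(n_ph), n_ph)
  structure(
    list(field_size = as.integer(field_size), n_cells = as.integer(n_cells),
         cell_radius_range = cell_radius_range,
         n_markers = as.integer(n_markers),
         phenotype_library = phenotype_library, weights_fn = weights_fn,
         af_puncta_rate = af_puncta_rate,
         puncta_radius_range = puncta_radius_range, noise_sd = noise_sd,
         bleach_residual = bleach_residual, shift_max = as.integer(shift_max),
         base_level = base_level, amplitude = amplitude,
         margin = as.integer(margin), seed = as.integer(seed)),
    class = "sim_config")
}

as_weights_fn <- function(w, n_ph) {
  fn <- if (is.function(w)) {
    w
  } else if (is.numeric(w)) {
    force(w); function(group, sex) w
  } else if (is.data.frame(w)) {
    function(group, sex) {
      hit <- (is.na(w$group) | w$group == group) &
        (is.na(w$sex) | w$sex == sex)
      if (!any(hit)) stop("no phenotype weights for (", group, ", ", sex,
                          ").", call. = FALSE)
      w$weights[[which(hit)[1]]]
    }
  } else {
    stop("unsupported `phenotype_weights` specification.", call. = FALSE)
  }
  function(group, sex) {
    v <- fn(group, sex)
    if (length(v) != n_ph || any(v < 0) ||
        !isTRUE(all.equal(sum(v), 1))) {
      stop("phenotype weights must be a probability vector over the ",
           n_ph, " phenotypes.", call. = FALSE)
    }
    v
  }
}

#' Default phenotype library
#'
#' Each phenotype expresses a distinct overlapping block of the inner
#' markers at high probability (0.8) against a low background (0.06); the
#' last marker (F-actin) is diffuse at 0.9 everywhere; marker 0 is driven
#' by the puncta process, not this matrix.
#'
#' @param n_markers Panel size.
#' @param n_phenotypes Library size (default 5).
#' @return `n_phenotypes` x `n_markers` probability matrix.
#' @export
default_phenotype_library <- function(n_markers, n_phenotypes = 5L) {
  stopifnot(n_markers >= 3, n_phenotypes >= 1)
  inner <- seq(2L, n_markers - 1L)          # 1-based columns of markers 1..M-2
  bs <- max(1L, floor(length(inner) / 2))
  lib <- matrix(0.06, n_phenotypes, n_markers)
  for (p in seq_len(n_phenotypes)) {
    start <- 1L + round((p - 1L) * (length(inner) - bs) /
                          max(n_phenotypes - 1L, 1L))
    lib[p, inner[seq.int(start, start + bs - 1L)]] <- 0.8
  }
  lib[, 1] <- 0                              # marker 0: puncta process
  lib[, n_markers] <- 0.9                    # F-actin, diffuse
  rownames(lib) <- paste0("ph", seq_len(n_phenotypes))
  lib
}

#' Default (group, sex) phenotype weights
#'
#' Vehicle-treated cells concentrate on the first two phenotypes (low
#' diversity); rescue-treated cells are uniform over all phenotypes
#' (higher diversity). Males favor a rotated set of phenotypes, shifting
#' marker prevalence between the sexes.
#'
#' @param n_phenotypes Library size.
#' @return Function `(group, sex) -> probability vector`.
#' @export
default_phenotype_weights <- function(n_phenotypes = 5L) {
  function(group, sex) {
    w <- if (identical(group, "Vehicle") && n_phenotypes >= 3) {
      c(rep(0.45, 2), rep(0.1 / (n_phenotypes - 2), n_phenotypes - 2))
    } else {
      rep(1 / n_phenotypes, n_phenotypes)
    }
    if (identical(sex, "Male") && n_phenotypes > 1) {
      w <- w[c(n_phenotypes, seq_len(n_phenotypes - 1L))]
    }
    w
  }
}

disk_pixels <- function(cr, cc, radius, field) {
  r0 <- max(1L, floor(cr - radius)); r1 <- min(field, ceiling(cr + radius))
  c0 <- max(1L, floor(cc - radius)); c1 <- min(field, ceiling(cc + radius))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  g[(g$row - cr)^2 + (g$col - cc)^2 <= radius^2, , drop = FALSE]
}

#' Simulate one multiplexed field
#'
#' Generates a single sample: grayscale signal and post-bleach background
#' stacks (one image per marker) plus the full ground truth (cell table,
#' label mask, per-pixel true CMP codes). Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param sample_id,group,sex Sample metadata.
#' @param seed Stream seed for this sample (default `config$seed`).
#' @param images Generate the grayscale stacks? Set `FALSE` for
#'   ground-truth-only simulations (much faster at scale).
#' @return Object of class `tis_sample`: metadata, `signal` and
#'   `background` arrays (rows x cols x markers, `NULL` when
#'   `images = FALSE`), `shifts` (true per-channel mis-registration), and
#'   `truth` (list: `cells` tibble, `labels` mask, `code` matrix).
#' @export
simulate_field <- function(config, sample_id = "s1", group = "Vehicle",
                           sex = "Female", seed = config$seed,
                           images = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  fs <- config$field_size
  M <- config$n_markers
  margin <- config$margin

  # -- cell packing: non-overlapping disks fully inside the margin --------
  cells <- list()
  tries <- 0L; max_tries <- 200L * max(config$n_cells, 1L)
  while (length(cells) < config$n_cells && tries < max_tries) {
    tries <- tries + 1L
    radius <- stats::runif(1, config$cell_radius_range[1],
                           config$cell_radius_range[2])
    lo <- margin + radius + 1
    hi <- fs - margin - radius
    if (lo >= hi) stop("infeasible config: cells do not fit inside the ",
                       "field margin.", call. = FALSE)
    cr <- stats::runif(1, lo, hi); cc <- stats::runif(1, lo, hi)
    ok <- all(vapply(cells, function(cl) {
      (cl$row - cr)^2 + (cl$col - cc)^2 > (cl$radius + radius + 2)^2
    }, logical(1)))
    if (ok) cells[[length(cells) + 1L]] <-
        list(row = cr, col = cc, radius = radius)
  }
  if (length(cells) < config$n_cells) {
    stop("infeasible config: could not place ", config$n_cells,
         " non-overlapping cells after ", max_tries, " tries.",
         call. = FALSE)
  }

  labels <- matrix(0L, fs, fs)
  code <- matrix(0L, fs, fs)
  weights <- config$weights_fn(group, sex)
  n_ph <- nrow(config$phenotype_library)
  cell_rows <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    px <- disk_pixels(cl$row, cl$col, cl$radius, fs)
    idx <- cbind(px$row, px$col)
    labels[idx] <- i
    phenotype <- sample.int(n_ph, 1L, prob = weights)
    probs <- config$phenotype_library[phenotype, ]
    cell_code <- integer(nrow(px))
    for (m in seq.int(2L, M)) {   # markers 1..M-1: pixel-level Bernoulli
      on <- stats::runif(nrow(px)) < probs[m]
      cell_code <- cell_code + bitwShiftL(1L, m - 1L) * on
    }
    # marker 0: punctate autofluorescence
    n_puncta <- stats::rpois(1, config$af_puncta_rate)
    if (n_puncta > 0) {
      af <- rep(FALSE, nrow(px))
      for (j in seq_len(n_puncta)) {
        centre <- px[sample.int(nrow(px), 1L), ]
        pr <- stats::runif(1, config$puncta_radius_range[1],
                           config$puncta_radius_range[2])
        af <- af | ((px$row - centre$row)^2 + (px$col - centre$col)^2 <= pr^2)
      }
      cell_code <- cell_code + 1L * af
    }
    code[idx] <- as.integer(cell_code)
    cell_rows[[i]] <- tibble::tibble(
      cell_id = i, row = cl$row, col = cl$col, radius = cl$radius,
      phenotype = phenotype)
  }
  cell_tbl <- if (length(cell_rows)) dplyr::bind_rows(cell_rows) else
    tibble::tibble(cell_id = integer(), row = numeric(), col = numeric(),
                   radius = numeric(), phenotype = integer())

  markers <- c("AF",
               if (M > 2) paste0("marker", seq_len(M - 2)),
               "F-actin")
  shifts <- matrix(0L, M, 2, dimnames = list(markers, c("dr", "dc")))
  signal <- background <- NULL
  if (images) {
    signal <- array(0, c(fs, fs, M))
    background <- array(0, c(fs, fs, M))
    for (m in seq_len(M)) {
      presence <- matrix(bitwAnd(as.vector(code), bitwShiftL(1L, m - 1L)) != 0L,
                         fs, fs)
      clean <- config$base_level + config$amplitude * presence
      sig <- clean + stats::rnorm(fs * fs, 0, config$noise_sd)
      bg <- config$bleach_residual * clean +
        stats::rnorm(fs * fs, 0, config$noise_sd)
      if (config$shift_max > 0L && m > 1L) {
        shifts[m, ] <- sample(seq.int(-config$shift_max, config$shift_max),
                              2L, replace = TRUE)
        sig <- shift_image(sig, shifts[m, 1], shifts[m, 2])
        bg <- shift_image(bg, shifts[m, 1], shifts[m, 2])
      }
      signal[, , m] <- pmax(sig, 0)
      background[, , m] <- pmax(bg, 0)
    }
  }
  structure(
    list(sample_id = sample_id, group = group, sex = sex,
         seed = as.integer(seed), markers = markers, margin = margin,
         signal = signal, background = background, shifts = shifts,
         truth = list(cells = cell_tbl, labels = labels, code = code)),
    class = "tis_sample")
}

#' @export
print.tis_sample <- function(x, ...) {
  cat(sprintf("<tis_sample> %s (%s, %s): %d cells, %d markers, %dx%d px\n",
              x$sample_id, x$group, x$sex, nrow(x$truth$cells),
              length(x$markers), nrow(x$truth$code), ncol(x$truth$code)))
  invisible(x)
}

#' Simulate a cohort of samples
#'
#' One field per design row, with independent per-sample seed streams
#' derived from the master seed by fixed arithmetic (`seed + index - 1`).
#'
#' @param config A [sim_config()].
#' @param design Data frame with columns `sample_id`, `group`, `sex`
#'   (unique sample ids).
#' @param images Generate grayscale stacks? See [simulate_field()].
#' @return Object of class `tis_cohort`: `samples` (named list of
#'   `tis_sample`), `design`, `config`.
#' @export
simulate_cohort <- function(config, design, images = TRUE) {
  design <- tibble::as_tibble(design)
  stopifnot(all(c("sample_id", "group", "sex") %in% names(design)),
            nrow(design) >= 1)
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample ids in `design`.", call. = FALSE)
  }
  samples <- lapply(seq_len(nrow(design)), function(i) {
    simulate_field(config, sample_id = design$sample_id[i],
                   group = design$group[i], sex = design$sex[i],
                   seed = config$seed + i - 1L, images = images)
  })
  names(samples) <- design$sample_id
  structure(list(samples = samples, design = design, config = config),
            class = "tis_cohort")
}

#' Ground-truth CMP image
#'
#' Builds the per-pixel CMP image directly from a sample's true marker
#' matrix, bypassing binarization entirely; the oracle against which the
#' preprocessing chain is validated.
#'
#' @param x A `tis_sample`, or its `truth` list together with `markers`
#'   and `margin`.
#' @param markers,margin Panel and margin when `x` is a bare truth list.
#' @return A [new_cmp_image()] object.
#' @export
ground_truth_cmp_image <- function(x, markers = NULL, margin = 15L) {
  if (inherits(x, "tis_sample")) {
    new_cmp_image(x$truth$code, x$markers, x$margin)
  } else {
    stopifnot(is.list(x), !is.null(x$code), !is.null(markers))
    new_cmp_image(x$code, markers, margin)
  }
}

#' Write / read a simulated sample as TIFF files
#'
#' Writes one 16-bit grayscale TIFF per marker for the signal and
#' post-bleach background, a 16-bit label-mask TIFF of cell ids, and a
#' `metadata.csv` (sample_id, group, sex, seed, markers).
#'
#' @param x A `tis_sample` (with images).
#' @param dir Output directory (created if missing).
#' @return `write_sample_tiffs()`: `dir`, invisibly.
#'   `read_sample_tiffs()`: list with `signal`, `background`, `labels`,
#'   `markers` and `meta`.
#' @export
write_sample_tiffs <- function(x, dir) {
  stopifnot(inherits(x, "tis_sample"), !is.null(x$signal))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  M <- length(x$markers)
  for (m in seq_len(M)) {
    tiff::writeTIFF(pmin(x$signal[, , m], 65535) / 65535,
                    file.path(dir, sprintf("signal_%02d.tif", m - 1L)),
                    bits.per.sample = 16L)
    tiff::writeTIFF(pmin(x$background[, , m], 65535) / 65535,
                    file.path(dir, sprintf("background_%02d.tif", m - 1L)),
                    bits.per.sample = 16L)
  }
  tiff::writeTIFF(x$truth$labels / 65535, file.path(dir, "labels.tif"),
                  bits.per.sample = 16L)
  readr::write_csv(
    tibble::tibble(sample_id = x$sample_id, group = x$group, sex = x$sex,
                   seed = x$seed, markers = paste(x$markers, collapse = ";")),
    file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' @rdname write_sample_tiffs
#' @export
read_sample_tiffs <- function(dir) {
  meta <- readr::read_csv(file.path(dir, "metadata.csv"),
                          show_col_types = FALSE)
  markers <- strsplit(meta$markers[1], ";", fixed = TRUE)[[1]]
  M <- length(markers)
  rd <- function(f) tiff::readTIFF(file.path(dir, f)) * 65535
  first <- rd("signal_00.tif")
  signal <- array(0, c(dim(first), M))
  background <- array(0, c(dim(first), M))
  for (m in seq_len(M)) {
    signal[, , m] <- rd(sprintf("signal_%02d.tif", m - 1L))
    background[, , m] <- rd(sprintf("background_%02d.tif", m - 1L))
  }
  labels <- round(rd("labels.tif"))
  storage.mode(labels) <- "integer"
  list(signal = signal, background = background, labels = labels,
       markers = markers, meta = meta)
}
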