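#' Per-pixel CMP image
#'
#' Container for a merged multiplexed field: an integer matrix of CMP codes
#' (marker m, 0-based, contributes `2^m`; 0 = background), the ordered
#' marker panel, and the excluded border margin. Pixels within `margin` of
#' any edge are always background, mirroring the border exclusion applied
#' to whole-field acquisitions.
#'
#' @param code Integer matrix of CMP codes.
#' @param markers Character vector of marker names, in panel order
#'   (marker 0 first).
#' @param margin Excluded border width in pixels (default 15).
#' @return An object of class `cmp_image`.
#' @export
new_cmp_image <- function(code, markers, margin = 15L) {
  stopifnot(is.matrix(code), length(markers) >= 1)
  margin <- as.integer(margin)
  storage.mode(code) <- "integer"
  code <- apply_margin(code, margin)
  structure(
    list(code = code, markers = as.character(markers), margin = margin),
    class = "cmp_image"
  )
}

apply_margin <- function(code, margin) {
  if (margin > 0L) {
    nr <- nrow(code); nc <- ncol(code)
    if (2L * margin >= min(nr, nc)) {
      code[] <- 0L
      return(code)
    }
    code[c(seq_len(margin), nr - seq_len(margin) + 1L), ] <- 0L
    code[, c(seq_len(margin), nc - seq_len(margin) + 1L)] <- 0L
  }
  code
}

#' @export
print.cmp_image <- function(x, ...) {
  fg <- sum(x$code != 0L)
  cat(sprintf("<cmp_image> %d x %d px, %d markers, margin %d, %d foreground px\n",
              nrow(x$code), ncol(x$code), length(x$markers), x$margin, fg))
  invisible(x)
}

#' Foreground mask of a CMP image
#'
#' @param x A [new_cmp_image()] object.
#' @return Logical matrix: `TRUE` where at least one marker is present
#'   (inside the margin-cropped area).
#' @export
foreground_mask <- function(x) {
  stopifnot(inherits(x, "cmp_image"))
  x$code != 0L
}

# Translate image content by (dr, dc): out[r, c] = x[r - dr, c - dc],
# zero-filled at the exposed border.
shift_image <- function(x, dr, dc) {
  out <- matrix(0, nrow(x), ncol(x))
  nr <- nrow(x); nc <- ncol(x)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(sr) && length(sc) && dr > -nr && dr < nr && dc > -nc && dc < nc) {
    out[sr, sc] <- x[sr - dr, sc - dc]
  }
  out
}

#' Align one channel to a reference by integer translation
#'
#' Serial immunostaining re-images the same fixed specimen over many
#' cycles; the dominant mis-registration is a small rigid drift. The
#' channel is aligned by the integer translation that maximizes zero-mean
#' cross-correlation with the reference (both images are demeaned first,
#' so the flat illumination background carries no weight), searched
#' exhaustively within `±shift_max` pixels. Ties are broken toward the
#' smallest L1 shift, then lexicographically, so a flat channel aligns
#' with shift (0, 0).
#'
#' @param moving,reference Numeric matrices of equal dimensions.
#' @param shift_max Maximum absolute shift searched, per axis.
#' @return List with `image` (shifted `moving`, zero-filled border) and
#'   `shift` (integer `c(dr, dc)` applied).
#' @export
register_pair <- function(moving, reference, shift_max = 5L) {
  stopifnot(is.matrix(moving), is.matrix(reference),
            all(dim(moving) == dim(reference)), shift_max >= 0)
  shift_max <- as.integer(shift_max)
  if (shift_max >= min(dim(moving))) {
    stop("shift_max must be smaller than the image size.", call. = FALSE)
  }
  dm <- moving - mean(moving)
  dr_ref <- reference - mean(reference)
  best <- c(0L, 0L); best_cc <- -Inf
  grid <- seq.int(-shift_max, shift_max)
  for (dr in grid) {
    for (dc in grid) {
      cc <- sum(shift_image(dm, dr, dc) * dr_ref)
      better <- cc > best_cc ||
        (cc == best_cc && (abs(dr) + abs(dc) < sum(abs(best)) ||
                           (abs(dr) + abs(dc) == sum(abs(best)) &&
                            (dr < best[1] || (dr == best[1] && dc < best[2])))))
      if (better) {
        best_cc <- cc
        best <- c(dr, dc)
      }
    }
  }
  list(image = shift_image(moving, best[1], best[2]), shift = best)
}

#' Photobleach background subtraction
#'
#' After each staining cycle the bound fluorophore is photobleached and the
#' specimen re-imaged; that post-bleach image is the per-cycle background.
#' Subtraction is pixel-wise and clipped at zero.
#'
#' @param signal,bleached Numeric matrices of equal dimensions.
#' @return Matrix `pmax(signal - bleached, 0)`.
#' @export
subtract_background <- function(signal, bleached) {
  if (!all(dim(signal) == dim(bleached))) {
    stop("signal and background images must have equal dimensions.",
         call. = FALSE)
  }
  pmax(signal - bleached, 0)
}

#' Binarize a channel image
#'
#' Converts a background-subtracted intensity image to a presence mask.
#' The mask is `TRUE` where intensity strictly exceeds the resolved
#' threshold (so a threshold of 0 excludes exact zeros). Policies:
#' `"otsu"` (default; parameter-free, via [EBImage::otsu()]), `"fixed"`
#' (explicit `threshold`), and `"quantile"` (`quantile(image, q)`).
#' A constant image under Otsu yields an all-`FALSE` mask with a warning,
#' since no separating threshold exists.
#'
#' @param image Non-negative numeric matrix.
#' @param policy One of `"otsu"`, `"fixed"`, `"quantile"`.
#' @param threshold Threshold for `policy = "fixed"`.
#' @param q Probability for `policy = "quantile"`.
#' @return Logical matrix with attribute `threshold` (the resolved value).
#' @export
binarize_channel <- function(image, policy = c("otsu", "fixed", "quantile"),
                             threshold = NULL, q = 0.99) {
  policy <- match.arg(policy)
  if (any(image < 0)) stop("image must be non-negative.", call. = FALSE)
  thr <- switch(policy,
    fixed = {
      if (is.null(threshold)) stop("policy 'fixed' needs `threshold`.",
                                   call. = FALSE)
      threshold
    },
    quantile = stats::quantile(image, q, names = FALSE),
    otsu = {
      rng <- range(image)
      if (rng[1] == rng[2]) {
        warning("constant image: Otsu has no separating threshold; ",
                "returning an all-background mask.", call. = FALSE)
        rng[2]   # strict '>' then yields all-FALSE
      } else {
        scaled <- (image - rng[1]) / (rng[2] - rng[1])
        EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) *
          (rng[2] - rng[1]) + rng[1]
      }
    })
  mask <- image > thr
  attr(mask, "threshold") <- unname(thr)
  mask
}

#' Merge binarized channels into a CMP image
#'
#' Stacks an ordered list of presence masks into a per-pixel CMP image.
#' List order defines marker indices: the first mask is marker 0. Pixels
#' with no marker present, and all pixels within the border margin, are
#' background; the all-zero CMP is never tabulated.
#'
#' @param masks List of logical matrices, equal dimensions, in panel order.
#' @param markers Optional marker names; defaults to `names(masks)` or
#'   `"m0" ... "m<M-1>"`.
#' @param margin Excluded border width in pixels.
#' @return A [new_cmp_image()] object.
#' @export
merge_channels <- function(masks, markers = NULL, margin = 15L) {
  if (!length(masks)) stop("`masks` must be a non-empty list.", call. = FALSE)
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) {
    stop("all masks must have identical dimensions.", call. = FALSE)
  }
  if (is.null(markers)) {
    markers <- names(masks) %||% paste0("m", seq_along(masks) - 1L)
  }
  stopifnot(length(markers) == length(masks))
  code <- matrix(0L, dims[[1]][1], dims[[1]][2])
  for (m in seq_along(masks)) {
    code <- code + bitwShiftL(1L, m - 1L) * (masks[[m]] != 0)
  }
  new_cmp_image(code, markers, margin)
}

#' Preprocess a raw channel stack into a CMP image
#'
#' Runs the full preprocessing chain on one sample: align every channel
#' (signal and its post-bleach background) to the reference channel,
#' subtract the background, binarize, and merge into a per-pixel CMP
#' image.
#'
#' @param signal 3-D array (rows x cols x markers) of intensity images.
#' @param background Matching 3-D array of post-bleach images.
#' @param markers Marker names in panel order.
#' @param shift_max Registration search radius; 0 skips registration.
#' @param policy,threshold,q Binarization policy, see [binarize_channel()].
#' @param margin Excluded border width.
#' @param reference Index (1-based) of the reference channel for
#'   registration.
#' @return A [new_cmp_image()] object; per-channel resolved thresholds and
#'   shifts are attached as attributes `thresholds` and `shifts`.
#' @export
prep_channels <- function(signal, background, markers = NULL,
                          shift_max = 0L, policy = "otsu", threshold = NULL,
                          q = 0.99, margin = 15L, reference = 1L) {
  stopifnot(length(dim(signal)) == 3L, all(dim(signal) == dim(background)))
  M <- dim(signal)[3]
  if (is.null(markers)) markers <- paste0("m", seq_len(M) - 1L)
  masks <- vector("list", M)
  thresholds <- numeric(M)
  shifts <- matrix(0L, M, 2, dimnames = list(markers, c("dr", "dc")))
  ref_img <- signal[, , reference]
  for (m in seq_len(M)) {
    sig <- signal[, , m]
    bg <- background[, , m]
    if (shift_max > 0L && m != reference) {
      reg <- register_pair(sig, ref_img, shift_max)
      shifts[m, ] <- reg$shift
      sig <- reg$image
      bg <- shift_image(bg, reg$shift[1], reg$shift[2])
    }
    corrected <- subtract_background(sig, bg)
    masks[[m]] <- binarize_channel(corrected, policy, threshold = threshold,
                                   q = q)
    thresholds[m] <- attr(masks[[m]], "threshold")
  }
  out <- merge_channels(masks, markers, margin)
  attr(out, "thresholds") <- stats::setNames(thresholds, markers)
  attr(out, "shifts") <- shifts
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
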