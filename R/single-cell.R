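#' Extract the CMP multiset of one cell
#'
#' Pulls the foreground CMPs at a cell's pixel addresses out of a merged
#' CMP image. Background pixels inside the ROI (including any pixels that
#' fall in the excluded border margin) are dropped; their number is
#' reported in the `n_background` attribute.
#'
#' @param x A `cmp_image`.
#' @param roi Either a data frame with 0-based `row`, `col` pixel
#'   coordinates, or an integer label mask (same dimensions as the image)
#'   together with `label`.
#' @param label Cell id to extract when `roi` is a label mask.
#' @return Character vector of CMP bitstrings (the cell's pixel multiset),
#'   with attribute `n_background`. Empty (with a warning) when the ROI
#'   contains no foreground.
#' @export
extract_cell_pixels <- function(x, roi, label = NULL) {
  stopifnot(inherits(x, "cmp_image"))
  if (is.matrix(roi)) {
    if (is.null(label)) stop("`label` is required with a label mask.",
                             call. = FALSE)
    stopifnot(all(dim(roi) == dim(x$code)))
    codes <- x$code[roi == label]
  } else {
    roi <- as.data.frame(roi)
    stopifnot(all(c("row", "col") %in% names(roi)))
    r <- roi$row + 1L; c <- roi$col + 1L
    if (any(r < 1L | r > nrow(x$code) | c < 1L | c > ncol(x$code))) {
      stop("ROI pixels out of image bounds.", call. = FALSE)
    }
    codes <- x$code[cbind(r, c)]
  }
  fg <- codes != 0L
  out <- codes_to_cmp(codes[fg], length(x$markers))
  attr(out, "n_background") <- sum(!fg)
  if (!length(out)) warning("ROI contains no foreground pixels.",
                            call. = FALSE)
  out
}

#' Top-20-CMP marker profile of a cell
#'
#' The per-cell summary used for clustering: rank the cell's CMPs by
#' within-cell pixel count, keep the `top` most abundant (20 by default),
#' and count for each marker how many of those CMPs contain it
#' (`k`, an integer in 0..20). The fraction `f = k / n_used` normalizes by
#' the number of CMPs actually used, so cells with fewer than 20 distinct
#' CMPs remain comparable.
#'
#' @param cmps Character vector (the cell's CMP multiset) or a
#'   `cmp_table` already compiled for the cell.
#' @param top Number of most-abundant CMPs summarized (default 20).
#' @return Tibble with columns `marker` (0-based), `k`, `f`, and attribute
#'   `n_used` (number of CMPs summarized).
#' @export
cell_profile <- function(cmps, top = 20L) {
  tab <- if (inherits(cmps, "cmp_table")) cmps else compile_cmp_table(cmps)
  if (!nrow(tab)) stop("cannot profile a cell with no foreground CMPs.",
                       call. = FALSE)
  M <- attr(tab, "n_markers")
  sel <- cmp_top_n(tab, top)
  k <- vapply(seq_len(M) - 1L,
              function(m) sum(cmp_has_marker(sel$cmp, m)), integer(1))
  out <- tibble::tibble(marker = seq_len(M) - 1L, k = k,
                        f = k / nrow(sel))
  attr(out, "n_used") <- nrow(sel)
  out
}

#' Profiles for every cell in a labeled image
#'
#' Convenience wrapper building [cell_profile()]s for all cells of a
#' sample from a label mask (cell id = positive label), returning one long
#' tibble ready for grouping and clustering.
#'
#' @param x A `cmp_image`.
#' @param labels Integer label mask (0 = no cell).
#' @param top Passed to [cell_profile()].
#' @param meta Optional one-row data frame (e.g. sample_id, group, sex)
#'   replicated onto every row.
#' @return Long tibble: `cell_id`, metadata columns, `marker`, `k`, `f`.
#'   Cells whose ROI has no foreground are skipped with a warning.
#' @export
cell_profiles <- function(x, labels, top = 20L, meta = NULL) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  rows <- lapply(ids, function(id) {
    cmps <- suppressWarnings(extract_cell_pixels(x, labels, label = id))
    if (!length(cmps)) return(NULL)
    prof <- cell_profile(cmps, top)
    dplyr::bind_cols(tibble::tibble(cell_id = id), prof)
  })
  skipped <- vapply(rows, is.null, logical(1))
  if (any(skipped)) {
    warning(sum(skipped), " cell(s) had no foreground pixels and were skipped.",
            call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(meta)) out <- dplyr::bind_cols(tibble::as_tibble(meta), out)
  out
}

#' Mean marker profile of a set of cells
#'
#' Arithmetic mean of the per-marker fractions (and counts) across cells,
#' e.g. the "signature" of all cells in one cluster.
#'
#' @param profiles Long profile tibble ([cell_profiles()] format, possibly
#'   filtered to one cluster).
#' @return Tibble: `marker`, `k` (mean), `f` (mean), `n_cells`.
#' @export
cluster_mean_profile <- function(profiles) {
  stopifnot(nrow(profiles) > 0)
  profiles |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(n_cells = dplyr::n(), k = mean(.data$k),
                     f = mean(.data$f), .groups = "drop") |>
    dplyr::relocate("n_cells", .after = "f")
}

#' Pivot long profiles to a cell-by-marker matrix
#'
#' @param profiles Long profile tibble.
#' @param value Which value to spread: `"f"` (default) or `"k"`.
#' @param id Column identifying cells (default `"cell_id"`; use a
#'   combination key if ids repeat across samples).
#' @return Numeric matrix, rows = cells (named by `id`), columns markers.
#' @export
profiles_matrix <- function(profiles, value = c("f", "k"), id = "cell_id") {
  value <- match.arg(value)
  wide <- profiles |>
    dplyr::select(dplyr::all_of(c(id, "marker", value))) |>
    tidyr::pivot_wider(names_from = "marker", values_from = dplyr::all_of(value),
                       names_prefix = paste0(value, "_"))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide[[id]])
  m
}
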