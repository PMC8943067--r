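#' Compile a frequency-ranked CMP table
#'
#' Tabulates a multiset of CMPs (from a whole image or a single cell's
#' pixels) into a ranked frequency table: one row per distinct CMP, sorted
#' by pixel count descending with ties broken by ascending bitstring, the
#' most abundant CMP getting rank 0. Frequencies are raw pixel counts:
#' whole-image abundance depends strongly on how many cells the field
#' happens to contain, so normalization is deliberately left to downstream
#' consumers.
#'
#' @param x A `cmp_image`, or a character vector of CMP bitstrings (the
#'   pixel multiset). Background (all-zero) pixels are never tabulated.
#' @return A tibble of class `cmp_table` with columns `rank` (0-based),
#'   `cmp` (bitstring) and `count`, and attribute `n_markers`.
#' @examples
#' compile_cmp_table(c("0100", "0100", "0100", "0011"))
#' @export
compile_cmp_table <- function(x) {
  if (inherits(x, "cmp_image")) {
    codes <- x$code[x$code != 0L]
    cmps <- codes_to_cmp(codes, length(x$markers))
    M <- length(x$markers)
  } else {
    cmps <- as.character(x)
    M <- unique(nchar(cmps))
    if (length(M) > 1L) {
      stop("all CMP bitstrings must have the same length.", call. = FALSE)
    }
    cmps <- cmps[grepl("1", cmps, fixed = TRUE)]
    if (!length(M)) M <- NA_integer_
  }
  if (!length(cmps)) {
    out <- tibble::tibble(rank = integer(), cmp = character(),
                          count = integer())
  } else {
    out <- tibble::tibble(cmp = cmps) |>
      dplyr::count(.data$cmp, name = "count") |>
      dplyr::arrange(dplyr::desc(.data$count), .data$cmp) |>
      dplyr::mutate(rank = dplyr::row_number() - 1L, .before = 1L)
  }
  attr(out, "n_markers") <- as.integer(M)
  class(out) <- c("cmp_table", class(out))
  out
}

#' Keep the N most abundant CMPs
#'
#' Whole-image conservation analyses restrict attention to the 54 most
#' abundant CMPs of each sample; the cut is deterministic because the
#' compile ordering already fixes ties.
#'
#' @param table A [compile_cmp_table()] result.
#' @param n Number of rows to keep (default 54).
#' @return The first `min(n, nrow)` rows, same class and attributes.
#' @export
cmp_top_n <- function(table, n = 54L) {
  stopifnot(n >= 1)
  out <- table[seq_len(min(n, nrow(table))), , drop = FALSE]
  attr(out, "n_markers") <- attr(table, "n_markers")
  class(out) <- class(table)
  out
}

#' Marker-specific ("lead protein") CMP table
#'
#' Restricts a ranked CMP table to CMPs that contain a given marker,
#' preserving the relative order of the full ranking (the original ranks
#' are kept in `source_rank`, so the numbering is no longer consecutive),
#' then truncates to the `n` most abundant. The selected marker acts as a
#' lead protein: it is present in every CMP of the result.
#'
#' @param table A [compile_cmp_table()] result built from the full image.
#' @param marker 0-based marker index.
#' @param n Rows to keep after filtering (default 54).
#' @return A `cmp_table` tibble with columns `rank` (re-numbered from 0),
#'   `source_rank` (rank in `table`), `cmp`, `count`.
#' @export
marker_table <- function(table, marker, n = 54L) {
  M <- attr(table, "n_markers")
  if (!is.na(M) && (marker < 0L || marker >= M)) {
    stop("`marker` out of range for this panel.", call. = FALSE)
  }
  out <- table |>
    dplyr::filter(cmp_has_marker(.data$cmp, marker)) |>
    dplyr::rename(source_rank = "rank") |>
    dplyr::mutate(rank = dplyr::row_number() - 1L, .before = 1L)
  out <- out[seq_len(min(n, nrow(out))), , drop = FALSE]
  attr(out, "n_markers") <- M
  class(out) <- unique(c("cmp_table", class(out)))
  out
}

#' Restrict a CMP image to a marker subset
#'
#' Re-merges a CMP image onto an ordered subset of the panel, as done when
#' comparing studies that share only part of their marker panels. The
#' reduction is a true re-merge, not a projection of tabulated results: a
#' pixel whose only present markers are dropped becomes background in the
#' reduced space.
#'
#' @param x A `cmp_image`.
#' @param keep Integer vector of 0-based marker indices to retain; its
#'   order defines the new panel numbering.
#' @return A `cmp_image` over the reduced panel.
#' @export
subset_panel <- function(x, keep) {
  stopifnot(inherits(x, "cmp_image"), length(keep) >= 1)
  keep <- as.integer(keep)
  M <- length(x$markers)
  if (anyDuplicated(keep) || any(keep < 0L) || any(keep >= M)) {
    stop("`keep` must be distinct 0-based indices within the panel.",
         call. = FALSE)
  }
  code <- matrix(0L, nrow(x$code), ncol(x$code))
  for (j in seq_along(keep)) {
    has <- bitwAnd(x$code, bitwShiftL(1L, keep[j])) != 0L
    code <- code + bitwShiftL(1L, j - 1L) * has
  }
  new_cmp_image(code, x$markers[keep + 1L], x$margin)
}

#' Write / read a CMP table as CSV
#'
#' @param table A `cmp_table`.
#' @param path File path.
#' @return `write_cmp_table()` returns `path` invisibly; `read_cmp_table()`
#'   returns a `cmp_table` tibble.
#' @export
write_cmp_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_cmp_table
#' @export
read_cmp_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    cmp = readr::col_character(), .default = readr::col_integer()))
  attr(out, "n_markers") <- nchar(out$cmp[1])
  class(out) <- c("cmp_table", class(out))
  out
}
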