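#' Encode a marker set as a CMP bitstring
#'
#' A combinatorial molecular phenotype (CMP) is the binary present/absent
#' pattern of all markers at one pixel, written as a bitstring whose
#' leftmost character is marker 0 (the panel's first marker, by convention
#' the autofluorescence channel). A pixel where only marker 8 of a
#' 12-marker panel is present has CMP `"000000001000"`.
#'
#' @param markers Integer vector of 0-based marker indices present
#'   (may be empty).
#' @param n_markers Panel size M.
#' @return A single bitstring of length `n_markers`. The all-zero string is
#'   a valid encoding but is never tabulated as foreground downstream.
#' @examples
#' cmp_encode(8, 12)
#' cmp_decode("000000001000")
#' @export
cmp_encode <- function(markers, n_markers) {
  markers <- as.integer(markers)
  stopifnot(n_markers >= 1)
  if (length(markers) && (anyNA(markers) || any(markers < 0L) ||
                          any(markers >= n_markers))) {
    stop("marker indices must lie in [0, n_markers).", call. = FALSE)
  }
  bits <- rep.int("0", n_markers)
  bits[unique(markers) + 1L] <- "1"
  paste(bits, collapse = "")
}

#' @rdname cmp_encode
#' @param cmp A CMP bitstring (characters `0`/`1` only).
#' @return `cmp_decode()`: sorted integer vector of 0-based marker indices.
#' @export
cmp_decode <- function(cmp) {
  stopifnot(is.character(cmp), length(cmp) == 1L)
  if (grepl("[^01]", cmp)) {
    stop("CMP bitstrings may contain only '0' and '1'.", call. = FALSE)
  }
  which(strsplit(cmp, "", fixed = TRUE)[[1]] == "1") - 1L
}

# Integer-code representation used internally for images: marker m (0-based)
# contributes 2^m, so codes fit in an R integer for panels up to 30 markers.
codes_to_cmp <- function(code, n_markers) {
  stopifnot(n_markers <= 30)
  out <- character(length(code))
  bits <- matrix("0", length(code), n_markers)
  for (m in seq_len(n_markers) - 1L) {
    bits[bitwAnd(code, bitwShiftL(1L, m)) != 0L, m + 1L] <- "1"
  }
  do.call(paste0, asplit(bits, 2))
}

cmp_to_codes <- function(cmp) {
  n <- unique(nchar(cmp))
  if (length(n) > 1L) stop("CMP bitstrings have unequal lengths.", call. = FALSE)
  if (!length(cmp)) return(integer(0))
  mat <- matrix(as.integer(unlist(strsplit(cmp, "", fixed = TRUE))),
                ncol = n, byrow = TRUE)
  as.integer(mat %*% bitwShiftL(1L, seq_len(n) - 1L))
}

# Does bitstring `cmp` contain 0-based marker m? Vectorised over cmp.
cmp_has_marker <- function(cmp, marker) {
  substr(cmp, marker + 1L, marker + 1L) == "1"
}
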