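#' CMPs conserved in every sample of a group (3-of-3)
#'
#' A CMP is conserved at the strict level when its exact bitstring appears
#' in the top-N list of every replicate sample of a group.
#'
#' @param tables List (length >= 2) of top-N `cmp_table`s, one per sample.
#' @return Character vector of conserved CMP bitstrings (sorted).
#' @export
conserved_3of3 <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2)
  sort(Reduce(intersect, lapply(tables, function(t) t$cmp)))
}

#' CMPs conserved in exactly two of three samples (2-of-3)
#'
#' The relaxed conservation measure: three pairwise comparisons are made
#' among the group's samples (1 vs 2, 1 vs 3, 2 vs 3); each comparison
#' counts the CMPs shared by that pair but not by all three. The value
#' reported alongside the strict count is the mean of the three pairwise
#' counts, which may be fractional.
#'
#' @param tables List of exactly 3 top-N `cmp_table`s.
#' @return List with `pair_counts` (named integer vector, one entry per
#'   pairwise comparison), `cmps` (the distinct 2-of-3 CMPs) and `mean`
#'   (sum of pair counts / 3, kept unrounded).
#' @export
conserved_2of3 <- function(tables) {
  if (!is.list(tables) || length(tables) != 3L) {
    stop("2-of-3 conservation is defined for groups of exactly 3 samples.",
         call. = FALSE)
  }
  sets <- lapply(tables, function(t) t$cmp)
  triple <- Reduce(intersect, sets)
  pairs <- utils::combn(3L, 2L, simplify = FALSE)
  per_pair <- lapply(pairs, function(p) {
    setdiff(intersect(sets[[p[1]]], sets[[p[2]]]), triple)
  })
  counts <- vapply(per_pair, length, integer(1))
  names(counts) <- vapply(pairs, paste, character(1), collapse = "v")
  list(pair_counts = counts,
       cmps = sort(unique(unlist(per_pair))),
       mean = sum(counts) / 3)
}

#' Cross-sample CMP conservation summary
#'
#' For two experimental groups of 3 samples each, tabulates conserved CMPs
#' per column: the `All` column uses each sample's top-N list over the full
#' panel; each marker column uses the marker-specific (lead protein) top-N
#' list. Per group and column it reports the strict 3-of-3 count, the mean
#' 2-of-3 count, and their total; the `Common` row counts CMPs conserved in
#' both groups.
#'
#' @param groups Named list of exactly two groups; each group is a list of
#'   3 full (untruncated) `cmp_table`s, one per sample.
#' @param n Top-N cut applied per column (default 54).
#' @param common How group conservation is defined for the Common row:
#'   `"3of3"` (default; a CMP must be in all samples of both groups) or
#'   `"union23"` (in at least 2 of 3 samples of both groups).
#' @return Object of class `conservation_summary`: list with `summary`
#'   (tibble: column, group, n_3of3, mean_2of3, total), `common` (tibble:
#'   column, n_common) and `n_markers`.
#' @export
conservation_summary <- function(groups, n = 54L,
                                 common = c("3of3", "union23")) {
  common <- match.arg(common)
  stopifnot(is.list(groups), length(groups) == 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named list of two groups.", call. = FALSE)
  }
  M <- unique(unlist(lapply(groups, function(g)
    vapply(g, function(t) attr(t, "n_markers"), integer(1)))))
  if (length(M) != 1L) stop("mixed marker panels across samples.",
                            call. = FALSE)
  columns <- c("All", as.character(seq_len(M) - 1L))

  col_tables <- function(full_tables, column) {
    if (column == "All") {
      lapply(full_tables, cmp_top_n, n = n)
    } else {
      lapply(full_tables, marker_table, marker = as.integer(column), n = n)
    }
  }

  rows <- list(); commons <- list()
  for (column in columns) {
    per_group <- lapply(groups, col_tables, column = column)
    stats3 <- lapply(per_group, conserved_3of3)
    stats2 <- lapply(per_group, conserved_2of3)
    for (g in names(groups)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        column = column, group = g,
        n_3of3 = length(stats3[[g]]),
        mean_2of3 = stats2[[g]]$mean,
        total = length(stats3[[g]]) + stats2[[g]]$mean)
    }
    conserved_sets <- switch(common,
      "3of3" = stats3,
      "union23" = Map(function(a, b) union(a$cmps, b), stats2, stats3))
    commons[[length(commons) + 1L]] <- tibble::tibble(
      column = column,
      n_common = length(intersect(conserved_sets[[1]], conserved_sets[[2]])))
  }
  structure(
    list(summary = dplyr::bind_rows(rows),
         common = dplyr::bind_rows(commons),
         n_markers = M, n = n, common_rule = common),
    class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf("<conservation_summary> top-%d lists, %d-marker panel\n",
              x$n, x$n_markers))
  print(tidyr::pivot_wider(x$summary, names_from = "column",
                           values_from = c("n_3of3", "mean_2of3", "total")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a conservation summary
#'
#' @param x A [conservation_summary()] object.
#' @param ... Unused.
#' @return Tibble with one row per (column, group).
#' @exportS3Method generics::tidy
tidy.conservation_summary <- function(x, ...) x$summary

#' @rdname tidy.conservation_summary
#' @exportS3Method generics::glance
glance.conservation_summary <- function(x, ...) {
  test <- conservation_rank_sum(x)
  tibble::tibble(n_markers = x$n_markers, top_n = x$n,
                 n_columns = nrow(x$common),
                 statistic = test$statistic, p_value = test$p_value)
}

#' Compare the two groups' conservation totals
#'
#' Applies the two-sided Wilcoxon rank-sum test to the per-column
#' conservation totals (3-of-3 + mean 2-of-3) of the two groups, treating
#' the 13 column totals of each group as the two samples. The columns
#' share pixels (every marker column is a subset of All), so this is
#' pseudo-replication and the p-value is descriptive.
#'
#' @param x A [conservation_summary()] object.
#' @return Tibble from [rank_sum_test()].
#' @export
conservation_rank_sum <- function(x) {
  stopifnot(inherits(x, "conservation_summary"))
  groups <- unique(x$summary$group)
  a <- x$summary$total[x$summary$group == groups[1]]
  b <- x$summary$total[x$summary$group == groups[2]]
  rank_sum_test(a, b)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()] that uses the exact null
#' distribution when both samples have at most 25 observations and no ties
#' are present, and the normal approximation with tie correction
#' otherwise; the method actually used is reported.
#'
#' @param a,b Numeric vectors (two independent samples).
#' @return Tibble with `statistic` (Mann-Whitney U of `a`), `p_value`
#'   and `method` (`"exact"` or `"normal_approx"`).
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty input.", call. = FALSE)
  exact <- length(a) <= 25 && length(b) <= 25 && !anyDuplicated(c(a, b))
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = !exact))
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = res$p.value,
                 method = if (exact) "exact" else "normal_approx")
}
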