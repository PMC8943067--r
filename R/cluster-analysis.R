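#' Hierarchical clustering of cell marker profiles
#'
#' Agglomerative clustering of per-cell top-20-CMP marker-fraction
#' vectors, cut to exactly `k` clusters. Defaults are Ward linkage
#' (`"ward.D2"`) on Euclidean distance, a standard choice for compact
#' profile clusters; both are configurable, as is `k` (7 was used for a
#' 12-marker panel and 12 for a 7-marker cross-study comparison in the
#' analyses this reproduces). The result is deterministic given the input
#' order.
#'
#' @param profiles Long profile tibble ([cell_profiles()] format) or a
#'   cell-by-marker numeric matrix.
#' @param k Number of clusters.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param metric Distance metric for [stats::dist()].
#' @param id Cell-id column when `profiles` is a tibble.
#' @return Object of class `profile_clustering`: `assignments` tibble
#'   (`cell_id`, `cluster`), the `hclust` tree, and the parameters.
#' @export
hclust_profiles <- function(profiles, k, linkage = "ward.D2",
                            metric = "euclidean", id = "cell_id") {
  m <- if (is.matrix(profiles)) profiles else profiles_matrix(profiles, id = id)
  if (k < 1L || k > nrow(m)) {
    stop("`k` must be between 1 and the number of cells.", call. = FALSE)
  }
  tree <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  cl <- stats::cutree(tree, k = k)
  structure(
    list(assignments = tibble::tibble(cell_id = rownames(m),
                                      cluster = as.integer(cl)),
         tree = tree, k = as.integer(k), linkage = linkage, metric = metric),
    class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("<profile_clustering> %d cells, k = %d (%s, %s)\n",
              nrow(x$assignments), x$k, x$linkage, x$metric))
  print(table(cluster = x$assignments$cluster))
  invisible(x)
}

#' @rdname hclust_profiles
#' @param x A `profile_clustering` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.profile_clustering <- function(x, ...) x$assignments

#' @rdname hclust_profiles
#' @exportS3Method generics::glance
glance.profile_clustering <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$assignments), k = x$k,
                 linkage = x$linkage, metric = x$metric,
                 max_height = max(x$tree$height))
}

#' Export a clustering dendrogram as Newick text
#'
#' @param x A `profile_clustering` object.
#' @param path Output file; `NULL` returns the Newick string.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_dendrogram <- function(x, path = NULL) {
  stopifnot(inherits(x, "profile_clustering"))
  phy <- ape::as.phylo(x$tree)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Cross-tabulate cluster membership against a factor
#'
#' @param assignment A `profile_clustering` object or its `assignments`
#'   tibble.
#' @param metadata Data frame with `cell_id` and the factor column.
#' @param factor Name of the metadata column (e.g. `"group"` or `"sex"`).
#' @return Long tibble of class `composition_table`: `level`, `cluster`,
#'   `n` (one row per factor level x cluster, zeros included).
#' @export
composition_table <- function(assignment, metadata, factor) {
  asg <- if (inherits(assignment, "profile_clustering"))
    assignment$assignments else tibble::as_tibble(assignment)
  stopifnot(factor %in% names(metadata), "cell_id" %in% names(metadata))
  joined <- dplyr::inner_join(asg, metadata, by = "cell_id")
  if (nrow(joined) < nrow(asg)) {
    stop("metadata does not cover all clustered cells.", call. = FALSE)
  }
  counts <- joined |>
    dplyr::count(level = .data[[factor]], cluster = .data$cluster) |>
    dplyr::mutate(level = as.character(.data$level))
  out <- tidyr::expand_grid(level = sort(unique(counts$level)),
                            cluster = sort(unique(counts$cluster))) |>
    dplyr::left_join(counts, by = c("level", "cluster")) |>
    dplyr::mutate(n = as.integer(dplyr::coalesce(.data$n, 0L)))
  class(out) <- c("composition_table", class(out))
  out
}

#' Build a composition table from a matrix of counts
#'
#' @param counts Numeric matrix: rows = factor levels (named), columns =
#'   clusters.
#' @return Long `composition_table` tibble.
#' @export
as_composition_table <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  out <- tibble::as_tibble(counts, rownames = "level") |>
    tidyr::pivot_longer(-"level", names_to = "cluster", values_to = "n") |>
    dplyr::mutate(cluster = match(.data$cluster, colnames(counts)),
                  n = as.integer(.data$n))
  class(out) <- c("composition_table", class(out))
  out
}

composition_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "table")) return(unclass(x))
  stopifnot(is.data.frame(x), all(c("level", "cluster", "n") %in% names(x)))
  wide <- tidyr::pivot_wider(x, names_from = "cluster", values_from = "n",
                             values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$level
  m
}

#' Score cluster composition with the 1/3-2/3 rule
#'
#' Labels each cluster by the fraction of its cells carrying the reference
#' factor level: `predominant-<reference>` when the fraction is >= 2/3,
#' `predominant-<other>` when <= 1/3, `mixed` otherwise. Thresholds are
#' compared as exact rationals (a 2-of-6 cluster, exactly 1/3, counts as
#' predominantly-other, not mixed). Aggregates per label the number of
#' clusters, cells, and percent of all cells.
#'
#' @param x A `composition_table` (long tibble), 2-row counts matrix, or
#'   `table` with two factor levels.
#' @param reference Factor level whose fraction drives the rule.
#' @param lo,hi Lower / upper thresholds (defaults 1/3 and 2/3).
#' @return Object of class `cluster_scoring`: `clusters` tibble (cluster,
#'   n_reference, n_total, frac_reference, label) and `summary` tibble
#'   (label, n_clusters, n_cells, pct_cells).
#' @export
score_clusters <- function(x, reference, lo = 1 / 3, hi = 2 / 3) {
  m <- composition_matrix(x)
  if (nrow(m) != 2L) {
    stop("cluster scoring requires a factor with exactly 2 levels.",
         call. = FALSE)
  }
  stopifnot(lo > 0, lo < hi, hi < 1)
  if (!reference %in% rownames(m)) {
    stop("`reference` is not a level of the table.", call. = FALSE)
  }
  other <- setdiff(rownames(m), reference)
  n_ref <- m[reference, ]
  n_tot <- colSums(m)
  if (any(n_tot == 0)) stop("empty cluster in composition table.",
                            call. = FALSE)
  frac <- n_ref / n_tot
  near <- function(a, b) vapply(a, function(v)
    isTRUE(all.equal(v, b)), logical(1))
  label <- dplyr::case_when(
    frac > hi | near(frac, hi) ~ paste0("predominant-", reference),
    frac < lo | near(frac, lo) ~ paste0("predominant-", other),
    .default = "mixed")
  clusters <- tibble::tibble(
    cluster = colnames(m) %||% as.character(seq_len(ncol(m))),
    n_reference = as.integer(n_ref), n_total = as.integer(n_tot),
    frac_reference = frac, label = label)
  lvls <- c(paste0("predominant-", reference), paste0("predominant-", other),
            "mixed")
  summary <- clusters |>
    dplyr::mutate(label = base::factor(.data$label, levels = lvls)) |>
    dplyr::group_by(.data$label, .drop = FALSE) |>
    dplyr::summarise(n_clusters = dplyr::n(),
                     n_cells = sum(.data$n_total), .groups = "drop") |>
    dplyr::mutate(label = as.character(.data$label),
                  pct_cells = 100 * .data$n_cells / sum(.data$n_cells))
  structure(list(clusters = clusters, summary = summary,
                 reference = reference, other = other, lo = lo, hi = hi),
            class = "cluster_scoring")
}

#' @export
print.cluster_scoring <- function(x, ...) {
  cat(sprintf("<cluster_scoring> reference = %s (thresholds %.3f / %.3f)\n",
              x$reference, x$lo, x$hi))
  print(x$summary)
  invisible(x)
}

#' @rdname score_clusters
#' @exportS3Method generics::tidy
tidy.cluster_scoring <- function(x, ...) x$clusters

#' @rdname score_clusters
#' @exportS3Method generics::glance
glance.cluster_scoring <- function(x, ...) {
  tibble::tibble(reference = x$reference,
                 n_clusters = sum(x$summary$n_clusters),
                 n_cells = sum(x$summary$n_cells))
}

#' Cramér's V association between two nominal variables
#'
#' `V = sqrt(chi^2 / (n * (min(r, c) - 1)))` with the Pearson chi-square
#' statistic (no continuity correction); 0 means independence, 1 perfect
#' association. For a 2x2 table V equals the absolute phi coefficient.
#'
#' @param x A `composition_table`, counts matrix, or `table`.
#' @return Numeric scalar in \[0, 1\].
#' @export
cramers_v <- function(x) {
  m <- composition_matrix(x)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: zero row or column margin.", call. = FALSE)
  }
  chi <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic)
  unname(sqrt(chi / (sum(m) * (min(dim(m)) - 1L))))
}

#' Group means of marker fractions
#'
#' Mean per-marker fraction `f` across cells, per grouping (use `by =
#' character()` for the overall "All" row).
#'
#' @param profiles Long profile tibble with metadata columns.
#' @param by Character vector of grouping columns (e.g. `"group"`,
#'   `c("group", "sex")`).
#' @return Tibble: grouping columns, `marker`, `mean_f`, `n_cells`.
#' @export
group_marker_means <- function(profiles, by = character()) {
  stopifnot(all(by %in% names(profiles)))
  profiles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "marker")))) |>
    dplyr::summarise(mean_f = mean(.data$f), n_cells = dplyr::n(),
                     .groups = "drop")
}

#' Default contrast set for marker-mean comparisons
#'
#' The six group pairs compared marker-by-marker in a two-treatment,
#' two-sex design: treatment within all cells, within each sex, and sex
#' within each treatment and overall. `NA` means "any". With a 7-marker
#' panel this yields the canonical 6 x 7 = 42 comparisons.
#'
#' @param treatment_levels,sex_levels Factor level names, reference first.
#' @return Tibble: `contrast`, `a_group`, `a_sex`, `b_group`, `b_sex`.
#' @export
default_contrasts <- function(treatment_levels = c("Vehicle", "Rescue"),
                              sex_levels = c("Female", "Male")) {
  t1 <- treatment_levels[1]; t2 <- treatment_levels[2]
  s1 <- sex_levels[1]; s2 <- sex_levels[2]
  tibble::tribble(
    ~contrast,                   ~a_group, ~a_sex, ~b_group, ~b_sex,
    paste0(t1, " vs ", t2),       t1,      NA,     t2,       NA,
    paste0(s1, ": ", t1, " vs ", t2), t1,  s1,     t2,       s1,
    paste0(s2, ": ", t1, " vs ", t2), t1,  s2,     t2,       s2,
    paste0(t1, ": ", s1, " vs ", s2), t1,  s1,     t1,       s2,
    paste0(t2, ": ", s1, " vs ", s2), t2,  s1,     t2,       s2,
    paste0(s1, " vs ", s2),       NA,      s1,     NA,       s2)
}

#' Pairwise marker comparisons with FDR control
#'
#' For each contrast and marker, a two-sided Wilcoxon rank-sum test on the
#' per-cell fractions `f`; p-values are Benjamini-Hochberg adjusted across
#' the full set of contrast x marker tests jointly, with significance
#' flagged at adjusted p < 0.05.
#'
#' @param profiles Long profile tibble with `group` and `sex` columns.
#' @param contrasts Contrast tibble in [default_contrasts()] format.
#' @param alpha Significance level on the adjusted scale.
#' @return Tibble: `contrast`, `marker`, `n_a`, `n_b`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
pairwise_marker_tests <- function(profiles, contrasts = default_contrasts(),
                                  alpha = 0.05) {
  pick <- function(g, s) {
    keep <- rep(TRUE, nrow(profiles))
    if (!is.na(g)) keep <- keep & profiles$group == g
    if (!is.na(s)) keep <- keep & profiles$sex == s
    profiles[keep, ]
  }
  markers <- sort(unique(profiles$marker))
  rows <- purrr::pmap(contrasts, function(contrast, a_group, a_sex,
                                          b_group, b_sex) {
    a <- pick(a_group, a_sex); b <- pick(b_group, b_sex)
    purrr::map(markers, function(m) {
      fa <- a$f[a$marker == m]; fb <- b$f[b$marker == m]
      if (length(fa) < 2 || length(fb) < 2) {
        stop("contrast '", contrast, "' has fewer than 2 cells per side.",
             call. = FALSE)
      }
      p <- suppressWarnings(
        stats::wilcox.test(fa, fb, alternative = "two.sided")$p.value)
      if (is.nan(p)) p <- 1   # fully tied samples carry no evidence
      tibble::tibble(contrast = contrast, marker = m,
                     n_a = length(fa), n_b = length(fb), p_value = p)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  rows |>
    dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_value, method = "BH"),
                  significant = .data$p_adjusted < alpha)
}
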