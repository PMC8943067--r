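#' Run the full CMP analysis pipeline on a cohort
#'
#' Chains every stage on a simulated (or loaded) cohort: preprocessing of
#' each sample's channel stack into a CMP image (registration, background
#' subtraction, binarization, merge), whole-image CMP catalogs,
#' cross-sample conservation (when the design is two groups of three),
#' single-cell top-`top_k` profiles, hierarchical clustering, 1/3-2/3
#' composition scoring, and Cramér's V for each available factor. Cell
#' ROIs are taken from each sample's label mask. Reruns on the same
#' inputs produce byte-identical artifacts.
#'
#' @param cohort A [simulate_cohort()] result (samples may be
#'   ground-truth-only, in which case preprocessing is skipped and the
#'   true CMP images are used).
#' @param top_n Top-N cut for whole-image conservation (default 54).
#' @param top_k Top-K CMPs per cell profile (default 20).
#' @param k Number of clusters.
#' @param policy Binarization policy, see [binarize_channel()].
#' @param reference Reference level for scoring; default the first group
#'   level in the design.
#' @param out_dir Optional directory; when given, all tabular artifacts
#'   plus a JSON run manifest are written there.
#' @return List of class `toponome_run`: `images`, `tables`,
#'   `conservation`, `profiles`, `clustering`, `compositions`, `scorings`,
#'   `cramers_v`, `manifest`.
#' @export
run_pipeline <- function(cohort, top_n = 54L, top_k = 20L, k = 7L,
                         policy = "otsu", reference = NULL, out_dir = NULL) {
  stopifnot(inherits(cohort, "tis_cohort"))
  design <- cohort$design

  images <- lapply(cohort$samples, function(s) {
    if (is.null(s$signal)) {
      ground_truth_cmp_image(s)
    } else {
      prep_channels(s$signal, s$background, s$markers,
                    shift_max = cohort$config$shift_max, policy = policy,
                    margin = s$margin)
    }
  })
  tables <- lapply(images, compile_cmp_table)

  conservation <- NULL
  grp_sizes <- table(design$group)
  if (length(grp_sizes) == 2L && all(grp_sizes == 3L)) {
    groups <- lapply(split(design$sample_id, design$group),
                     function(ids) tables[ids])
    conservation <- conservation_summary(groups, n = top_n)
  }

  profiles <- dplyr::bind_rows(lapply(cohort$samples, function(s) {
    prof <- cell_profiles(images[[s$sample_id]], s$truth$labels,
                          top = top_k,
                          meta = tibble::tibble(sample_id = s$sample_id,
                                                group = s$group,
                                                sex = s$sex))
    dplyr::mutate(prof,
                  cell_id = paste(s$sample_id, .data$cell_id, sep = "_"))
  }))

  clustering <- hclust_profiles(profiles, k = k)
  meta <- dplyr::distinct(profiles, .data$cell_id, .data$sample_id,
                          .data$group, .data$sex)
  factors <- c("group", "sex")
  factors <- factors[vapply(factors,
                            function(f) length(unique(meta[[f]])) == 2L,
                            logical(1))]
  compositions <- lapply(stats::setNames(factors, factors), function(f)
    composition_table(clustering, meta, f))
  reference <- reference %||% design$group[1]
  scorings <- lapply(compositions, function(ct) {
    ref <- if (reference %in% ct$level) reference else ct$level[1]
    score_clusters(ct, reference = ref)
  })
  v <- vapply(compositions, cramers_v, numeric(1))

  manifest <- list(
    package = "toponome",
    version = as.character(utils::packageVersion("toponome")),
    seed = cohort$config$seed,
    params = list(top_n = top_n, top_k = top_k, k = k, policy = policy,
                  n_markers = cohort$config$n_markers,
                  field_size = cohort$config$field_size),
    design = design,
    config_hash = rlang::hash(cohort$config[setdiff(names(cohort$config),
                                                    "weights_fn")]),
    artifacts = character())

  run <- structure(
    list(images = images, tables = tables, conservation = conservation,
         profiles = profiles, clustering = clustering,
         compositions = compositions, scorings = scorings,
         cramers_v = v, manifest = manifest),
    class = "toponome_run")

  if (!is.null(out_dir)) run <- write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(x, p)
    paths <<- c(paths, name)
  }
  for (id in names(run$tables)) {
    put(run$tables[[id]], paste0("cmp_table_", id, ".csv"))
  }
  put(run$profiles, "cell_profiles.csv")
  put(tidy(run$clustering), "cluster_assignments.csv")
  writeLines(write_dendrogram(run$clustering),
             file.path(out_dir, "dendrogram.nwk"))
  paths <- c(paths, "dendrogram.nwk")
  if (!is.null(run$conservation)) {
    put(run$conservation$summary, "conservation_summary.csv")
    put(run$conservation$common, "conservation_common.csv")
  }
  for (f in names(run$compositions)) {
    put(run$compositions[[f]], paste0("composition_", f, ".csv"))
    put(tidy(run$scorings[[f]]), paste0("scoring_", f, ".csv"))
    put(run$scorings[[f]]$summary, paste0("scoring_summary_", f, ".csv"))
  }
  put(tibble::tibble(factor = names(run$cramers_v),
                     cramers_v = unname(run$cramers_v)),
      "cramers_v.csv")
  run$manifest$artifacts <- c(paths, "manifest.json")
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run
}

#' @export
print.toponome_run <- function(x, ...) {
  cat(sprintf("<toponome_run> %d samples, %d cells, k = %d\n",
              length(x$images),
              length(unique(x$profiles$cell_id)), x$clustering$k))
  if (length(x$cramers_v)) {
    cat("Cramér's V:",
        paste(names(x$cramers_v), round(x$cramers_v, 3),
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bundled example cluster-composition tables
#'
#' Three cluster-by-factor composition tables of alveolar macrophages
#' (AM) from an SP-A knockout rescue design, shipped as plain CSV under
#' `inst/extdata` and used in examples and validation tests of the
#' scoring rule and Cramér's V:
#' `"treatment_k7"` — 103 female AM in 7 clusters, Vehicle vs SP-A1;
#' `"sex_k12"` — 217 AM (both sexes, 7-marker panel) in 12 clusters,
#' Female vs Male;
#' `"treatment_k12"` — the same 217 AM by treatment.
#'
#' @param which One of `"treatment_k7"`, `"sex_k12"`, `"treatment_k12"`.
#' @return A `composition_table` tibble (`level`, `cluster`, `n`).
#' @examples
#' score_clusters(example_composition("treatment_k7"), reference = "Vehicle")
#' @export
example_composition <- function(which = c("treatment_k7", "sex_k12",
                                          "treatment_k12")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("am_clusters_", which, ".csv"),
                      package = "toponome", mustWork = TRUE)
  wide <- readr::read_csv(path, show_col_types = FALSE)
  out <- wide |>
    tidyr::pivot_longer(-"cluster", names_to = "level", values_to = "n") |>
    dplyr::mutate(n = as.integer(.data$n),
                  cluster = as.integer(.data$cluster)) |>
    dplyr::select("level", "cluster", "n") |>
    dplyr::arrange(.data$level, .data$cluster)
  class(out) <- c("composition_table", class(out))
  out
}
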