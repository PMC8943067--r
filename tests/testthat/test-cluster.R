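blob_profiles <- function(centers, n_per, sd = 0.02, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (b in seq_along(centers)) {
    for (i in seq_len(n_per)) {
      f <- pmin(pmax(centers[[b]] + rnorm(length(centers[[b]]), 0, sd), 0), 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cell_id = sprintf("b%d_c%d", b, i), blob = b,
        marker = seq_along(f) - 1L, k = round(f * 20), f = f)
    }
  }
  dplyr::bind_rows(rows)
}

test_that("hierarchical clustering cuts to k and recovers separated blobs", {
  profs <- blob_profiles(list(c(0.9, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.9, 0.9)),
                         n_per = 8)
  cl <- hclust_profiles(profs, k = 2)
  asg <- tidy(cl)
  expect_identical(nrow(asg), 16L)
  truth <- dplyr::distinct(profs, cell_id, blob)
  joined <- dplyr::inner_join(asg, truth, by = "cell_id")
  expect_identical(length(unique(joined$cluster[joined$blob == 1])), 1L)
  expect_identical(length(unique(joined$cluster[joined$blob == 2])), 1L)
  expect_false(joined$cluster[joined$blob == 1][1] ==
                 joined$cluster[joined$blob == 2][1])

  # k = n gives singletons; k > n errors
  cl_n <- hclust_profiles(profs, k = 16)
  expect_identical(sort(unique(tidy(cl_n)$cluster)), 1:16)
  expect_error(hclust_profiles(profs, k = 17), "between 1")
  expect_identical(glance(cl)$k, 2L)
})

test_that("dendrograms export as valid Newick with one tip per cell", {
  profs <- blob_profiles(list(c(0.8, 0.2, 0.3), c(0.2, 0.7, 0.6)), n_per = 4)
  cl <- hclust_profiles(profs, k = 2)
  nwk <- write_dendrogram(cl)
  phy <- ape::read.tree(text = nwk)
  expect_identical(sort(phy$tip.label), sort(unique(profs$cell_id)))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(cl, path)
  expect_identical(readLines(path), nwk)
})

test_that("composition tables cross-tabulate with zero-filled cells", {
  asg <- tibble::tibble(cell_id = as.character(1:8),
                        cluster = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L))
  meta <- tibble::tibble(cell_id = as.character(1:8),
                         group = c("V", "V", "R", "V", "V", "R", "R", "R"))
  ct <- composition_table(asg, meta, "group")
  expect_identical(nrow(ct), 6L)
  m <- toponome:::composition_matrix(ct)
  expect_equal(unname(m["V", ]), c(2, 2, 0))
  expect_equal(unname(m["R", ]), c(1, 0, 3))
  expect_equal(sum(m), 8)
  expect_error(composition_table(asg, meta[1:3, ], "group"),
               "does not cover")

  set.seed(79)
  for (case in 1:20) {
    n <- sample(10:60, 1)
    asg <- tibble::tibble(cell_id = as.character(seq_len(n)),
                          cluster = sample(1:5, n, TRUE))
    meta <- tibble::tibble(cell_id = asg$cell_id,
                           sex = sample(c("F", "M"), n, TRUE))
    m <- toponome:::composition_matrix(composition_table(asg, meta, "sex"))
    want <- unclass(table(meta$sex, asg$cluster))
    expect_equal(unname(m[rownames(want), ]), unname(want))
  }
})

test_that("bundled composition tables carry the published margins", {
  ct <- example_composition("treatment_k7")
  m <- toponome:::composition_matrix(ct)
  expect_equal(unname(colSums(m)), c(11, 17, 23, 14, 20, 10, 8))
  expect_equal(sum(m), 103)
  expect_equal(sum(toponome:::composition_matrix(
    example_composition("sex_k12"))), 217)
  expect_equal(sum(toponome:::composition_matrix(
    example_composition("treatment_k12"))), 217)
})

test_that("the 1/3-2/3 rule labels boundaries exactly and aggregates correctly", {
  m <- rbind(V = c(4, 2, 3, 1), R = c(2, 4, 3, 5))
  sc <- score_clusters(m, reference = "V")
  expect_identical(sc$clusters$label,
                   c("predominant-V", "predominant-R", "mixed",
                     "predominant-R"))
  # 2 of 6 is exactly 1/3: predominantly the other level, not mixed
  expect_identical(sc$clusters$label[2], "predominant-R")
  # 50/50 is mixed
  expect_identical(sc$clusters$label[3], "mixed")
  expect_equal(sum(sc$summary$n_cells), sum(m))
  expect_equal(sum(sc$summary$pct_cells), 100)

  # scale invariance
  sc10 <- score_clusters(m * 10L, reference = "V")
  expect_identical(sc10$clusters$label, sc$clusters$label)

  expect_error(score_clusters(rbind(a = 1, b = 1, c = 1), "a"), "2 levels")
  expect_error(score_clusters(m, "X"), "not a level")
})

test_that("Cramér's V behaves at the extremes and equals |phi| for 2x2", {
  expect_equal(cramers_v(rbind(a = c(10, 0), b = c(0, 10))), 1)
  expect_equal(cramers_v(rbind(a = c(5, 5), b = c(5, 5))), 0)
  set.seed(83)
  for (case in 1:20) {
    m <- matrix(sample(1:30, 4), 2, 2,
                dimnames = list(c("a", "b"), NULL))
    phi <- (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) /
      sqrt(prod(rowSums(m)) * prod(colSums(m)))
    expect_equal(cramers_v(m), unname(abs(phi)))
    # permutation invariance
    expect_equal(cramers_v(m[2:1, 2:1]), cramers_v(m))
  }
  expect_error(cramers_v(rbind(a = c(0, 0), b = c(1, 2))), "degenerate")
})

test_that("group marker means equal brute-force means per stratum", {
  set.seed(89)
  profs <- dplyr::bind_rows(lapply(1:12, function(i)
    tibble::tibble(cell_id = i, group = c("V", "R")[i %% 2 + 1],
                   sex = c("F", "M")[(i %/% 2) %% 2 + 1],
                   marker = 0:4, k = sample(0:20, 5, TRUE), f = runif(5))))
  all_means <- group_marker_means(profs)
  for (m in 0:4) {
    expect_equal(all_means$mean_f[all_means$marker == m],
                 mean(profs$f[profs$marker == m]))
  }
  by_g <- group_marker_means(profs, by = "group")
  expect_identical(nrow(by_g), 10L)
  expect_equal(by_g$mean_f[by_g$group == "V" & by_g$marker == 0],
               mean(profs$f[profs$group == "V" & profs$marker == 0]))
  # identical groups give identical rows
  profs2 <- dplyr::mutate(profs, group = "V")
  by_one <- group_marker_means(profs2, by = "group")
  expect_equal(by_one$mean_f, all_means$mean_f)
})

test_that("pairwise marker tests flag only planted differences after FDR", {
  set.seed(97)
  n <- 40
  mk_group <- function(group, sex, shift) {
    dplyr::bind_rows(lapply(seq_len(n), function(i)
      tibble::tibble(cell_id = paste(group, sex, i), group = group,
                     sex = sex, marker = 0:6,
                     k = 0L,
                     f = pmin(pmax(0.4 + c(shift, rep(0, 6)) +
                                     rnorm(7, 0, 0.05), 0), 1))))
  }
  profs <- dplyr::bind_rows(
    mk_group("Vehicle", "Female", 0), mk_group("Vehicle", "Male", 0),
    mk_group("Rescue", "Female", 0.3), mk_group("Rescue", "Male", 0.3))
  res <- pairwise_marker_tests(profs)
  expect_identical(nrow(res), 42L)   # 6 contrasts x 7 markers
  sig <- res[res$significant, ]
  # marker 0 is shifted between treatments; only treatment contrasts at
  # marker 0 should be flagged
  expect_true(all(sig$marker == 0))
  expect_setequal(
    sig$contrast,
    c("Vehicle vs Rescue", "Female: Vehicle vs Rescue",
      "Male: Vehicle vs Rescue"))

  # identical groups: nothing significant, raw p = 1 under exact ties
  profs0 <- dplyr::bind_rows(
    mk_group("Vehicle", "Female", 0), mk_group("Vehicle", "Male", 0),
    mk_group("Rescue", "Female", 0), mk_group("Rescue", "Male", 0))
  profs0$f <- 0.5
  res0 <- pairwise_marker_tests(profs0)
  expect_false(any(res0$significant))
  expect_true(all(res0$p_value == 1))
})
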