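tiny_image <- function() {
  # 20x20, margin 2, 3 markers; a 3x3 block of "010" at rows 10:12,
  # a pixel of "011" at (15, 15), background elsewhere
  code <- matrix(0L, 20, 20)
  code[10:12, 10:12] <- 2L
  code[15, 15] <- 6L
  new_cmp_image(code, paste0("m", 0:2), margin = 2)
}

test_that("cell pixel extraction drops background and respects the margin", {
  img <- tiny_image()
  roi <- expand.grid(row = 9:11, col = 9:11)   # 0-based: rows 10:12 in R
  cmps <- extract_cell_pixels(img, roi)
  expect_identical(sort(unique(cmps)), "010")
  expect_length(cmps, 9)
  expect_identical(attr(cmps, "n_background"), 0L)

  # ROI overlapping margin and background: those pixels are dropped
  roi2 <- expand.grid(row = 0:11, col = 0:11)
  cmps2 <- extract_cell_pixels(img, roi2)
  expect_length(cmps2, 9)
  expect_identical(attr(cmps2, "n_background"), 144L - 9L)

  expect_error(extract_cell_pixels(img, data.frame(row = 25, col = 1)),
               "out of image bounds")
  expect_warning(extract_cell_pixels(img, data.frame(row = 0, col = 0)),
                 "no foreground")
})

test_that("label-mask extraction equals brute-force per-pixel lookup", {
  set.seed(53)
  cfg <- noiseless_config(field_size = 96, n_cells = 4, seed = 53)
  s <- simulate_field(cfg, images = FALSE)
  img <- ground_truth_cmp_image(s)
  for (id in s$truth$cells$cell_id) {
    got <- suppressWarnings(extract_cell_pixels(img, s$truth$labels,
                                                label = id))
    want_codes <- s$truth$code[s$truth$labels == id]
    want_codes <- want_codes[want_codes != 0L]
    expect_setequal(got, toponome:::codes_to_cmp(want_codes, 12))
    expect_length(got, length(want_codes))
  }
})

test_that("cell profiles count marker occurrences in the top-20 CMPs", {
  # every one of the 20 most abundant CMPs contains marker 5
  set.seed(59)
  with5 <- unique(vapply(1:200, function(i) {
    cmp_encode(unique(c(5, sample(0:11, sample(0:4, 1)))), 12)
  }, character(1)))[1:20]
  without5 <- "100000000000"
  multiset <- c(rep(with5, times = 21:2), rep(without5, 1))
  prof <- cell_profile(multiset, top = 20)
  expect_identical(prof$k[prof$marker == 5], 20L)
  expect_identical(attr(prof, "n_used"), 20L)
  expect_equal(prof$f, prof$k / 20)

  # worked example: a marker present in 10 of the top 20 CMPs scores k = 10
  with1 <- vapply(2:11, function(i) cmp_encode(c(1, i), 12), character(1))
  wo1 <- vapply(2:11, function(i) cmp_encode(c(0, i), 12), character(1))
  top20 <- c(with1, wo1)
  prof2 <- cell_profile(rep(top20, times = 21 - seq_along(top20)), top = 20)
  expect_identical(prof2$k[prof2$marker == 1], 10L)

  expect_error(cell_profile(character()), "no foreground")
})

test_that("profiles equal a brute-force recount over the selected rows", {
  set.seed(61)
  for (case in 1:30) {
    M <- sample(4:12, 1)
    multiset <- random_cmps(sample(30:200, 1), M, n_patterns = sample(5:40, 1))
    top <- sample(c(5, 20), 1)
    prof <- cell_profile(multiset, top = top)
    sel <- oracle_compile(multiset)
    sel <- sel$cmp[seq_len(min(top, nrow(sel)))]
    for (m in 0:(M - 1)) {
      expect_identical(prof$k[prof$marker == m],
                       sum(substr(sel, m + 1, m + 1) == "1"))
    }
    expect_equal(prof$f, prof$k / length(sel))
    # invariant: sum_m k_m bounded by (CMPs used) x M
    expect_lte(sum(prof$k), length(sel) * M)
    expect_gte(sum(prof$k), max(prof$k))
  }
})

test_that("cells with fewer than top distinct CMPs normalize by the number used", {
  multiset <- c(rep("1000", 5), rep("0100", 2), "0010")
  prof <- cell_profile(multiset, top = 20)
  expect_identical(attr(prof, "n_used"), 3L)
  expect_equal(prof$f, prof$k / 3)
})

test_that("profiles are invariant to duplicating every pixel", {
  set.seed(67)
  multiset <- random_cmps(120, 6, n_patterns = 15)
  p1 <- cell_profile(multiset, top = 10)
  p2 <- cell_profile(rep(multiset, 2), top = 10)
  expect_equal(p1, p2, ignore_attr = TRUE)
})

test_that("mean profiles equal brute-force column means", {
  prof_a <- tibble::tibble(cell_id = "a", marker = 0:3, k = c(2, 0, 4, 1),
                           f = c(0.2, 0.2, 0.2, 0.2))
  prof_b <- dplyr::mutate(prof_a, cell_id = "b", f = 0.4)
  m <- cluster_mean_profile(dplyr::bind_rows(prof_a, prof_b))
  expect_equal(m$f, rep(0.3, 4))
  expect_equal(m$k, prof_a$k)
  expect_identical(unique(m$n_cells), 2L)

  single <- cluster_mean_profile(prof_a)
  expect_equal(single$f, prof_a$f)

  set.seed(71)
  profs <- dplyr::bind_rows(lapply(1:7, function(i)
    tibble::tibble(cell_id = i, marker = 0:5, k = sample(0:20, 6, TRUE),
                   f = runif(6))))
  got <- cluster_mean_profile(profs)
  fw <- profiles_matrix(profs, "f")
  expect_equal(got$f, unname(colMeans(fw)))
})

test_that("reduced-panel profiles come from re-merged pixels, not projected tables", {
  cfg <- noiseless_config(field_size = 96, n_cells = 4, seed = 73)
  s <- simulate_field(cfg, images = FALSE)
  img <- ground_truth_cmp_image(s)
  keep <- c(0L, 1L, 4L, 6L, 7L, 9L, 11L)
  red <- subset_panel(img, keep)
  profs <- suppressWarnings(cell_profiles(red, s$truth$labels, top = 20))

  # oracle: recompute each cell's reduced multiset from the truth matrix
  for (id in unique(profs$cell_id)) {
    codes <- s$truth$code[s$truth$labels == id]
    cmps12 <- toponome:::codes_to_cmp(codes[codes != 0L], 12)
    reduced <- vapply(cmps12, function(cmp)
      paste(strsplit(cmp, "")[[1]][keep + 1], collapse = ""), character(1))
    reduced <- reduced[grepl("1", reduced)]
    want <- cell_profile(reduced, top = 20)
    got <- profs[profs$cell_id == id, c("marker", "k", "f")]
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
  }
})
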