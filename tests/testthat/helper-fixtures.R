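# Shared fixtures and independent oracles used across the suite.

# Build a cmp_table directly from an explicit (cmp, count) spec, bypassing
# compile_cmp_table, for tests that need full control over the ranking.
make_table <- function(cmps, counts) {
  stopifnot(length(cmps) == length(counts))
  tab <- compile_cmp_table(rep(cmps, counts))
  tab
}

# Random CMP bitstrings over an M-marker panel (never all-zero).
random_cmps <- function(n, M, n_patterns = NULL) {
  pool <- if (is.null(n_patterns)) NULL else
    replicate(n_patterns, random_cmp(M))
  if (is.null(pool)) {
    replicate(n, random_cmp(M))
  } else {
    sample(pool, n, replace = TRUE)
  }
}

random_cmp <- function(M) {
  repeat {
    bits <- sample(0:1, M, replace = TRUE, prob = c(0.7, 0.3))
    if (any(bits == 1)) return(paste(bits, collapse = ""))
  }
}

# Brute-force compile oracle: dictionary count + documented tie order,
# built with base R only.
oracle_compile <- function(cmps) {
  cmps <- cmps[grepl("1", cmps, fixed = TRUE)]
  if (!length(cmps)) {
    return(data.frame(rank = integer(), cmp = character(),
                      count = integer()))
  }
  u <- unique(cmps)
  cnt <- vapply(u, function(p) sum(cmps == p), integer(1))
  o <- order(-cnt, u)
  data.frame(rank = seq_along(u) - 1L, cmp = u[o], count = unname(cnt[o]),
             stringsAsFactors = FALSE)
}

# Exhaustive-enumeration oracle for the two-sided rank-sum test: iterate
# over every assignment of ranks to group A, build the exact null
# distribution of the Mann-Whitney U statistic, and apply the standard
# two-sided tail doubling.
enum_ranksum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small noiseless simulation config shared by oracle-equivalence tests.
noiseless_config <- function(field_size = 128, n_cells = 5, seed = 11,
                             shift_max = 0, n_markers = 12) {
  sim_config(field_size = field_size, n_cells = n_cells,
             cell_radius_range = c(6, 10), n_markers = n_markers,
             noise_sd = 0, bleach_residual = 0, shift_max = shift_max,
             af_puncta_rate = 3, seed = seed)
}

# Phenotype library with disjoint high-probability marker blocks, for
# planted-cluster recovery tests.
separated_library <- function(n_markers = 12, n_phenotypes = 3) {
  lib <- matrix(0.02, n_phenotypes, n_markers)
  inner <- setdiff(seq_len(n_markers), c(1, n_markers))
  blocks <- split(inner, cut(seq_along(inner), n_phenotypes, labels = FALSE))
  for (p in seq_len(n_phenotypes)) lib[p, blocks[[p]]] <- 0.85
  lib[, 1] <- 0
  lib[, n_markers] <- 0.9
  lib
}
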