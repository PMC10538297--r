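# Independent oracles and small fixture builders. Everything here is
# deliberately brute-force and avoids the code paths it checks.

# Build a pop_sample from a plain character matrix (loci as columns).
make_sample <- function(name, cells, panel = NULL) {
  pop_sample(name, sprintf("%s%03d", name, seq_len(nrow(cells))), cells,
             panel = panel)
}

# One-locus, single-copy population from a numeric allele vector.
one_locus_pop <- function(name, alleles, locus = "L1") {
  m <- matrix(as.character(alleles), ncol = 1,
              dimnames = list(NULL, locus))
  make_sample(name, m)
}

# Brute-force haplotype grouping by pairwise equality of rows.
brute_group_counts <- function(cells) {
  n <- nrow(cells)
  assigned <- rep(NA_integer_, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    g <- g + 1L
    assigned[i] <- g
    if (i < n) for (j in (i + 1L):n) {
      if (is.na(assigned[j]) && all(cells[i, ] == cells[j, ])) assigned[j] <- g
    }
  }
  as.integer(table(assigned))
}

# Brute-force forensic statistics by enumerating ordered pairs.
brute_match_probability <- function(counts) {
  n <- sum(counts)
  matches <- sum(counts^2)       # ordered pairs, including self-pairs
  matches / n^2
}

# Brute-force haploid AMOVA from per-population numeric value matrices,
# written directly from the SSD definitions with explicit loops.
brute_amova <- function(mats) {
  X <- do.call(rbind, mats)
  N <- nrow(X)
  P <- length(mats)
  n_p <- vapply(mats, nrow, 0L)
  grp <- rep(seq_len(P), n_p)
  d <- function(i, j) sum((X[i, ] - X[j, ])^2)
  ssd_total <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    ssd_total <- ssd_total + d(i, j)
  }
  ssd_total <- ssd_total / N
  ssd_within <- 0
  for (p in seq_len(P)) {
    idx <- which(grp == p)
    acc <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b) acc <- acc + d(idx[a], idx[b])
    }
    ssd_within <- ssd_within + acc / n_p[p]
  }
  ssd_among <- ssd_total - ssd_within
  msd_among <- ssd_among / (P - 1)
  s2_within <- ssd_within / (N - P)
  n0 <- (N - sum(n_p^2) / N) / (P - 1)
  s2_among <- (msd_among - s2_within) / n0
  list(ssd_total = ssd_total, ssd_within = ssd_within,
       ssd_among = ssd_among, sigma2_among = s2_among,
       sigma2_within = s2_within,
       rst = if (s2_among + s2_within > 0) s2_among / (s2_among + s2_within)
             else 0)
}

# Random unrooted binary tree with positive branch lengths, plus its
# additive (path-length) distance matrix.
random_additive_case <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 2)
  list(tree = tr, d = dist_matrix(ape::cophenetic.phylo(tr)))
}

# Tiny three-locus panel used across tests.
toy_panel <- function() {
  panel_def("toy", c("DYS19", "DYS385", "rs1"),
            multi_copy = "DYS385", indel_loci = "rs1")
}

# Random small single-copy sample over `nloci` loci (integer alleles).
random_str_sample <- function(name, n, nloci, seed,
                              range = 8:14) {
  set.seed(seed)
  cells <- matrix(as.character(sample(range, n * nloci, replace = TRUE)),
                  n, nloci,
                  dimnames = list(NULL, paste0("L", seq_len(nloci))))
  make_sample(name, cells)
}
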