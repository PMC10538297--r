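#' Squared repeat-difference distance between two haplotypes
#'
#' The Rst-defining molecular distance: the sum over loci of the squared
#' difference in repeat counts. Microvariant fractions enter numerically
#' (14.1 vs 14 differs by 0.1). Only single-copy STR loci are admissible;
#' a multi-allele call has no defined repeat difference.
#'
#' @param h1,h2 Named character vectors (or single rows of a
#'   [pop_sample()] `cells` matrix) of canonical calls.
#' @param loci Loci to sum over; must be typed in both haplotypes.
#' @return Non-negative number.
#' @examples
#' haplotype_sq_distance(c(DYS19 = "10", DYS391 = "14.1"),
#'                       c(DYS19 = "11", DYS391 = "14"),
#'                       c("DYS19", "DYS391"))
#' @export
haplotype_sq_distance <- function(h1, h2, loci) {
  v1 <- repeat_values(h1[loci], loci)
  v2 <- repeat_values(h2[loci], loci)
  sum((v1 - v2)^2)
}

# Numeric repeat values for single-copy STR calls; errors on multi-allele
# cells and on missing calls.
repeat_values <- function(cells, loci) {
  cells <- as.character(cells)
  if (anyNA(cells)) {
    stop(sprintf("missing call at locus '%s'; exclude the locus or individual",
                 loci[which(is.na(cells))[1L]]), call. = FALSE)
  }
  multi <- grepl(",", cells, fixed = TRUE)
  if (any(multi)) {
    stop(sprintf(
      "multi-allele call '%s' at locus '%s': repeat differences are undefined for unordered multi-copy states; exclude this locus (or individual) from Rst",
      cells[multi][1L], loci[multi][1L]), call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(cells))
  if (anyNA(v)) {
    stop(sprintf("non-numeric call '%s' at locus '%s': InDel loci cannot enter repeat-difference distances",
                 cells[is.na(v)][1L], loci[is.na(v)][1L]), call. = FALSE)
  }
  v
}

#' Loci of a panel admissible for Rst distances
#'
#' Multi-copy loci and Y-InDels are excluded by default: repeat differences
#' are undefined for unordered multi-allele states, and InDels are not
#' STRs. This mirrors the usual practice of restricting Rst to comparable
#' single-copy Y-STRs.
#'
#' @param panel A [panel_def()].
#' @return Character vector of single-copy STR loci.
#' @export
rst_loci <- function(panel) {
  setdiff(panel$loci, c(panel$multi_copy, panel$indel_loci))
}

# Individuals x loci numeric repeat matrix; individuals with missing or
# multi-allele calls at any included locus are dropped listwise.
rst_value_matrix <- function(sample, loci) {
  cells <- sample$cells[, loci, drop = FALSE]
  ok <- apply(cells, 1L, function(r) {
    !anyNA(r) && !any(grepl(",", r, fixed = TRUE)) &&
      !anyNA(suppressWarnings(as.numeric(r)))
  })
  kept <- cells[ok, , drop = FALSE]
  m <- matrix(as.numeric(kept), nrow = nrow(kept),
              dimnames = dimnames(kept))
  attr(m, "n_dropped") <- sum(!ok)
  m
}

#' Haploid AMOVA and Rst for a set of population samples
#'
#' Partitions the squared repeat-difference distances among all N
#' individuals into within- and among-population components. The total sum
#' of squared deviations is the sum of d over all unordered pairs divided
#' by N; the within component sums, per population, the within-population
#' pair distances divided by that population's size; the among component is
#' their difference. With `df_among = P - 1` and `df_within = N - P`, the
#' variance components are `sigma2_within = SSD_within / df_within` and
#' `sigma2_among = (MSD_among - sigma2_within) / n0` where
#' `n0 = (N - sum(n_p^2)/N) / (P - 1)`, and
#' `Rst = sigma2_among / (sigma2_among + sigma2_within)`.
#'
#' A negative Rst (sampling noise around zero differentiation) is reported
#' as computed in `rst`, with the zero-clamped value in `distance` for use
#' as a dissimilarity.
#'
#' @param samples List of [pop_sample()] objects (>= 2), each with n >= 2
#'   usable individuals after listwise exclusion of missing/anomalous calls.
#' @param loci Single-copy STR loci to include (see [rst_loci()]).
#' @return Object of class `"amova_rst"`: list with `ssd_total`,
#'   `ssd_within`, `ssd_among`, `df_among`, `df_within`, `n0`,
#'   `sigma2_among`, `sigma2_within`, `rst`, `distance`, `n_per_pop`.
#' @export
amova_rst <- function(samples, loci) {
  if (length(samples) < 2L) stop("need >= 2 population samples", call. = FALSE)
  if (!length(loci)) stop("empty locus list", call. = FALSE)
  mats <- lapply(samples, rst_value_matrix, loci = loci)
  n_p <- vapply(mats, nrow, 0L)
  names(n_p) <- vapply(samples, `[[`, "", "name")
  if (any(n_p < 2L)) {
    stop(sprintf("population '%s' has fewer than 2 usable individuals at the included loci",
                 names(n_p)[n_p < 2L][1L]), call. = FALSE)
  }
  X <- do.call(rbind, mats)
  N <- nrow(X)
  P <- length(mats)
  grp <- rep(seq_len(P), n_p)

  d2 <- as.matrix(stats::dist(X))^2            # squared repeat differences
  ssd_total <- sum(d2[upper.tri(d2)]) / N
  ssd_within <- sum(vapply(seq_len(P), function(p) {
    dp <- d2[grp == p, grp == p, drop = FALSE]
    sum(dp[upper.tri(dp)]) / n_p[p]
  }, 0))
  ssd_among <- ssd_total - ssd_within

  df_among <- P - 1L
  df_within <- N - P
  msd_among <- ssd_among / df_among
  sigma2_within <- ssd_within / df_within
  n0 <- (N - sum(n_p^2) / N) / (P - 1L)
  sigma2_among <- (msd_among - sigma2_within) / n0
  denom <- sigma2_among + sigma2_within
  rst <- if (denom > 0) sigma2_among / denom else 0
  structure(list(ssd_total = ssd_total, ssd_within = ssd_within,
                 ssd_among = ssd_among, df_among = df_among,
                 df_within = df_within, n0 = n0,
                 sigma2_among = sigma2_among,
                 sigma2_within = sigma2_within,
                 rst = rst, distance = max(0, rst),
                 n_per_pop = n_p),
            class = "amova_rst")
}

#' @export
print.amova_rst <- function(x, ...) {
  cat("<amova_rst> haploid AMOVA\n")
  cat(sprintf("  SSD among/within/total: %.4f / %.4f / %.4f\n",
              x$ssd_among, x$ssd_within, x$ssd_total))
  cat(sprintf("  df among/within: %d / %d, n0 = %.3f\n",
              x$df_among, x$df_within, x$n0))
  cat(sprintf("  sigma2 among/within: %.5f / %.5f\n",
              x$sigma2_among, x$sigma2_within))
  cat(sprintf("  Rst = %.5f (distance %.5f)\n", x$rst, x$distance))
  invisible(x)
}

#' Pairwise Rst distance matrix
#'
#' Entry (a, b) is the zero-clamped Rst from a two-population AMOVA of
#' samples a and b; the matrix is symmetric with zero diagonal.
#'
#' @param samples List of >= 2 [pop_sample()] objects with distinct names.
#' @param loci Single-copy STR loci to include.
#' @return A [dist_matrix()] labelled by population names.
#' @export
pairwise_rst <- function(samples, loci) {
  labels <- vapply(samples, `[[`, "", "name")
  if (anyDuplicated(labels)) {
    stop("population names must be distinct", call. = FALSE)
  }
  P <- length(samples)
  if (P < 2L) stop("need >= 2 population samples", call. = FALSE)
  m <- matrix(0, P, P, dimnames = list(labels, labels))
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      r <- amova_rst(samples[c(i, j)], loci)$distance
      m[i, j] <- m[j, i] <- r
    }
  }
  dist_matrix(m)
}

#' Permutation test for Rst between two populations
#'
#' Permutes population labels over the pooled individuals and recomputes
#' Rst; the p-value is the fraction of permutations with Rst at least the
#' observed value, with the standard +1 correction
#' `(1 + #[Rst_perm >= Rst_obs]) / (n_perm + 1)`.
#'
#' @param sample_a,sample_b Two [pop_sample()] objects.
#' @param loci Single-copy STR loci to include.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return List with `rst` (observed), `p_value`, `n_perm`.
#' @export
rst_permutation_p <- function(sample_a, sample_b, loci, n_perm = 999,
                              seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  ma <- rst_value_matrix(sample_a, loci)
  mb <- rst_value_matrix(sample_b, loci)
  X <- rbind(ma, mb)
  na <- nrow(ma); N <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  rst_of <- function(idx_a) {
    grp <- rep(2L, N); grp[idx_a] <- 1L
    rst_from_d2(d2, grp)
  }
  obs <- rst_of(seq_len(na))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (rst_of(sample.int(N, na)) >= obs - 1e-12) hits <- hits + 1L
  }
  list(rst = obs, p_value = (1L + hits) / (n_perm + 1L), n_perm = n_perm)
}

# Rst from a precomputed squared-distance matrix and a group vector.
rst_from_d2 <- function(d2, grp) {
  N <- nrow(d2)
  tab <- tabulate(grp)
  P <- length(tab)
  ssd_total <- sum(d2[upper.tri(d2)]) / N
  ssd_within <- sum(vapply(seq_len(P), function(p) {
    dp <- d2[grp == p, grp == p, drop = FALSE]
    sum(dp[upper.tri(dp)]) / tab[p]
  }, 0))
  msd_among <- (ssd_total - ssd_within) / (P - 1L)
  sigma2_within <- ssd_within / (N - P)
  n0 <- (N - sum(tab^2) / N) / (P - 1L)
  sigma2_among <- (msd_among - sigma2_within) / n0
  denom <- sigma2_among + sigma2_within
  if (denom > 0) sigma2_among / denom else 0
}
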