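#' Frequency spectrum of allelic or haplotype states
#'
#' Direct-count frequencies: each distinct state (an allele call at one
#' locus, or a whole haplotype over a panel) is counted over the n
#' observations that carry it, and Pi = count / n.
#'
#' @param counts Named integer vector of state counts (names = state labels).
#' @return Object of class `"freq_spectrum"`: data.frame with columns
#'   `state`, `count`, `freq`, plus attribute `n` = sum of counts.
#' @export
freq_spectrum <- function(counts) {
  counts <- counts[order(names(counts))]
  n <- sum(counts)
  if (n < 1L) stop("empty frequency spectrum", call. = FALSE)
  if (any(counts < 1L)) stop("all state counts must be >= 1", call. = FALSE)
  out <- data.frame(state = names(counts), count = as.integer(counts),
                    freq = as.numeric(counts) / n,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, n = n, class = c("freq_spectrum", "data.frame"))
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat(sprintf("<freq_spectrum> %d states over n = %d observations\n",
              nrow(x), attr(x, "n")))
  NextMethod()
}

#' Allele frequency spectrum at one locus
#'
#' The allelic state of a multi-copy locus (or of an anomalous bi-/tri-
#' allelic pattern) is the entire canonical call: the unordered pair
#' `"13,16"` at DYS385 counts as one combined state, which is how per-locus
#' allele counts in the forties arise at multi-copy loci. n is the number of
#' individuals typed at the locus.
#'
#' @param sample A [pop_sample()].
#' @param locus Marker name.
#' @return A [freq_spectrum()].
#' @export
allele_spectrum <- function(sample, locus) {
  if (!locus %in% sample_loci(sample)) {
    stop(sprintf("locus '%s' not typed in sample '%s'", locus, sample$name),
         call. = FALSE)
  }
  cells <- sample$cells[, locus]
  cells <- cells[!is.na(cells)]
  if (!length(cells)) {
    stop(sprintf("locus '%s' missing in every individual of '%s'",
                 locus, sample$name), call. = FALSE)
  }
  freq_spectrum(table(cells))
}

#' Haplotype frequency spectrum over a panel
#'
#' States are whole haplotypes under panel equality (canonical calls at the
#' panel's loci). Individuals missing any panel locus are excluded from the
#' haplotype-level spectrum (direct-counting semantics); they still
#' contribute to per-locus allele spectra at the loci they carry.
#'
#' @param sample A [pop_sample()].
#' @param panel Optional [panel_def()]; defaults to all typed loci.
#' @return A [freq_spectrum()].
#' @export
haplotype_spectrum <- function(sample, panel = NULL) {
  s <- if (is.null(panel)) sample else subset_panel(sample, panel)
  keys <- haplotype_keys(s)
  keys <- keys[!is.na(keys)]
  if (!length(keys)) {
    stop(sprintf("no complete haplotypes in sample '%s' over the panel",
                 sample$name), call. = FALSE)
  }
  freq_spectrum(table(keys))
}

#' Gene / haplotype diversity
#'
#' The small-sample-corrected diversity `n (1 - sum(Pi^2)) / (n - 1)`, where
#' Pi is the frequency of the i-th allele or haplotype and n the number of
#' samples. Applied to a per-locus allele spectrum it is gene diversity
#' (GD); applied to a whole-haplotype spectrum it is haplotype diversity
#' (HD).
#'
#' @param spec A [freq_spectrum()].
#' @return Number in \[0, 1\].
#' @export
gene_diversity <- function(spec) {
  n <- attr(spec, "n")
  if (n < 2L) stop("gene diversity undefined for n < 2", call. = FALSE)
  n * (1 - sum(spec$freq^2)) / (n - 1)
}

#' Haplotype match probability
#'
#' `HMP = sum(Pi^2)`: the probability that two randomly chosen individuals
#' share a state. Bounded below by 1/n, with equality when all states are
#' singletons.
#'
#' @param spec A [freq_spectrum()].
#' @return Number in (0, 1\].
#' @export
match_probability <- function(spec) sum(spec$freq^2)

#' Discrimination capacity
#'
#' `DC = Ndiff / N`: the number of different haplotypes divided by the
#' sample size.
#'
#' @param spec A [freq_spectrum()].
#' @return Number in (0, 1\].
#' @export
discrimination_capacity <- function(spec) nrow(spec) / attr(spec, "n")

#' Count of distinct states in a spectrum
#' @param spec A [freq_spectrum()].
#' @return Integer.
#' @export
n_distinct_states <- function(spec) nrow(spec)

#' Count of unique (singleton) states in a spectrum
#' @param spec A [freq_spectrum()].
#' @return Integer.
#' @export
n_unique_states <- function(spec) sum(spec$count == 1L)

#' All forensic summary statistics of a spectrum
#'
#' @param spec A [freq_spectrum()].
#' @return One-row data.frame with `n`, `n_distinct`, `n_unique`,
#'   `diversity` (GD/HD), `match_prob` (HMP), `disc_capacity` (DC).
#' @export
diversity_stats <- function(spec) {
  data.frame(n = attr(spec, "n"),
             n_distinct = n_distinct_states(spec),
             n_unique = n_unique_states(spec),
             diversity = gene_diversity(spec),
             match_prob = match_probability(spec),
             disc_capacity = discrimination_capacity(spec))
}

#' Per-locus allele counts and gene diversities
#'
#' One row per panel locus: number of distinct allelic states and GD, the
#' layout of a per-marker diversity table.
#'
#' @param sample A [pop_sample()].
#' @param panel Optional [panel_def()]; defaults to all typed loci.
#' @return data.frame with columns `locus`, `n`, `n_alleles`, `gd`.
#' @export
locus_report <- function(sample, panel = NULL) {
  loci <- if (is.null(panel)) sample_loci(sample) else panel$loci
  rows <- lapply(loci, function(l) {
    spec <- allele_spectrum(sample, l)
    data.frame(locus = l, n = attr(spec, "n"),
               n_alleles = nrow(spec), gd = gene_diversity(spec),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare forensic efficacy across marker panels
#'
#' One row per panel, in input order: haplotype count, DC, HD and HMP over
#' the sample projected onto that panel. For nested panels the projection
#' coarsens the haplotype partition, so DC and HD are non-decreasing and
#' HMP non-increasing as loci are added.
#'
#' @param sample A [pop_sample()] typed at every panel's loci.
#' @param panels List of [panel_def()] objects.
#' @return data.frame with columns `panel`, `n_loci`, `n`, `n_haplotypes`,
#'   `dc`, `hd`, `hmp`.
#' @export
panel_report <- function(sample, panels) {
  if (inherits(panels, "panel_def")) panels <- list(panels)
  rows <- lapply(panels, function(p) {
    spec <- haplotype_spectrum(sample, p)
    data.frame(panel = p$name, n_loci = length(p$loci),
               n = attr(spec, "n"), n_haplotypes = nrow(spec),
               dc = discrimination_capacity(spec),
               hd = gene_diversity(spec),
               hmp = match_probability(spec),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
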