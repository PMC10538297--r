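#' Run the diversity stage of the pipeline
#'
#' Reproduces the forensic-descriptive analysis flow for one population:
#' per-locus allele spectra and gene diversities, the haplotype list with
#' direct-count frequencies, a panel-by-panel forensic efficacy comparison,
#' and a machine-readable JSON summary. Diversity statistics are written at
#' full precision; the JSON summary additionally carries report-style
#' rounded values (HD and HMP to 5 decimal places, DC to 4).
#'
#' @param input A [pop_sample()] or a haplotype-table path.
#' @param panel [panel_def()] governing the input table.
#' @param panels List of panels for the efficacy comparison; defaults to
#'   the built-in kit ladder restricted to panels covered by `panel`.
#' @param out_dir Output directory (created if needed).
#' @param sep Field separator for the written tables.
#' @return Invisibly, a list with `summary`, `locus_report`,
#'   `panel_report`, and the written `paths`.
#' @export
run_diversity <- function(input, panel, panels = NULL, out_dir,
                          sep = "\t") {
  sample <- if (inherits(input, "pop_sample")) input else
    read_haplotype_table(input, panel, sep = sep)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(panels)) {
    panels <- Filter(function(p) all(p$loci %in% panel$loci),
                     default_panels())
  }

  loc <- locus_report(sample, panel)
  spec <- haplotype_spectrum(sample, panel)
  pan <- panel_report(sample, panels)

  hap_tab <- data.frame(
    do.call(rbind, strsplit(spec$state, "|", fixed = TRUE)),
    Count = spec$count, Frequency = spec$freq,
    stringsAsFactors = FALSE, check.names = FALSE)
  names(hap_tab) <- c(panel$loci, "Count", "Frequency")

  stats <- diversity_stats(spec)
  summary <- list(
    population = sample$name, n = stats$n,
    n_haplotypes = stats$n_distinct, n_unique = stats$n_unique,
    hd = stats$diversity, hmp = stats$match_prob, dc = stats$disc_capacity,
    hd_printed = round(stats$diversity, 5),
    hmp_printed = round(stats$match_prob, 5),
    dc_printed = round(stats$disc_capacity, 4))

  paths <- file.path(out_dir, c("locus_diversity.tsv",
                                "haplotype_frequencies.tsv",
                                "panel_comparison.tsv", "summary.json"))
  utils::write.table(loc, paths[1], sep = sep, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(hap_tab, paths[2], sep = sep, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pan, paths[3], sep = sep, quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(summary, paths[4], auto_unbox = TRUE, digits = NA)
  message(sprintf(
    "%s: n = %d, %d haplotypes (%d unique); HD %.5f, HMP %.5f, DC %.4f",
    sample$name, stats$n, stats$n_distinct, stats$n_unique,
    stats$diversity, stats$match_prob, stats$disc_capacity))
  invisible(list(summary = summary, locus_report = loc, panel_report = pan,
                 haplotypes = hap_tab, paths = paths))
}

#' Run the population-structure stage of the pipeline
#'
#' Computes the pairwise Rst matrix over the given populations, a classical
#' MDS of that matrix, and (for three or more populations) a
#' Neighbor-Joining tree, writing the matrix in both labelled-TSV and
#' PHYLIP square dialects, the MDS coordinates as a table, and the tree as
#' Newick. Output label ordering is the input population order throughout.
#'
#' @param inputs List of [pop_sample()] objects or haplotype-table paths.
#' @param panel [panel_def()] governing input tables.
#' @param loci Loci for the Rst distances; default [rst_loci()] of `panel`
#'   (single-copy STRs only).
#' @param out_dir Output directory.
#' @param dims MDS dimensions.
#' @param sep Field separator for table inputs.
#' @return Invisibly, a list with `dist` ([dist_matrix()]), `mds`
#'   (`"ordination"`), `tree` (`"phylo"` or `NULL`), and written `paths`.
#' @export
run_structure <- function(inputs, panel, loci = rst_loci(panel), out_dir,
                          dims = 2L, sep = "\t") {
  samples <- lapply(inputs, function(x) {
    if (inherits(x, "pop_sample")) x else
      read_haplotype_table(x, panel, sep = sep)
  })
  if (length(samples) < 2L) stop("need >= 2 populations", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  d <- pairwise_rst(samples, loci)
  mds <- classical_mds(d, k = min(dims, nrow(d) - 1L))
  paths <- file.path(out_dir, c("rst_matrix.tsv", "rst_matrix.phy",
                                "mds_coordinates.tsv"))
  write_dist_matrix(d, paths[1], "tsv")
  write_dist_matrix(d, paths[2], "phylip")
  coords <- data.frame(Population = mds$labels, mds$points,
                       check.names = FALSE)
  names(coords)[-1] <- paste0("Dim", seq_len(ncol(mds$points)))
  utils::write.table(coords, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  tree <- NULL
  if (nrow(d) >= 3L) {
    tree <- neighbor_joining(d)
    nwk <- file.path(out_dir, "nj_tree.nwk")
    writeLines(to_newick(tree), nwk)
    paths <- c(paths, nwk)
  } else {
    warning("fewer than 3 populations: Rst matrix and MDS only, tree skipped",
            call. = FALSE)
  }
  message(sprintf("structure: %d populations, mean off-diagonal Rst %.4f",
                  nrow(d), mean(d[upper.tri(d)])))
  invisible(list(dist = d, mds = mds, tree = tree, paths = paths))
}
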