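#' Construct a population sample of Y-marker haplotypes
#'
#' A sample stores one haplotype per individual as a character matrix of
#' canonical allele-call strings (rows = individuals, columns = loci;
#' `NA` = marker not typed). Cells are canonicalized on construction, so two
#' samples with the same genotypes compare identical regardless of the
#' original allele ordering inside multi-allele cells.
#'
#' @param name Population name.
#' @param ids Character vector of unique sample identifiers.
#' @param cells Character matrix (or data.frame) of allele tokens, one
#'   column per locus, with column names.
#' @param panel Optional [panel_def()] used to classify loci as STR/InDel;
#'   loci not covered default to STR.
#' @return Object of class `"pop_sample"` with fields `name`, `ids`,
#'   `cells`, `kinds`; `n` individuals = `nrow(cells)`.
#' @export
pop_sample <- function(name, ids, cells, panel = NULL) {
  cells <- as.matrix(cells)
  mode(cells) <- "character"
  ids <- as.character(ids)
  if (length(ids) != nrow(cells)) {
    stop("length(ids) must equal nrow(cells)", call. = FALSE)
  }
  if (nrow(cells) < 1L) stop("a population sample needs n >= 1", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  loci <- colnames(cells)
  if (is.null(loci) || any(!nzchar(loci))) {
    stop("cells must have locus column names", call. = FALSE)
  }
  kinds <- stats::setNames(rep("str", length(loci)), loci)
  if (!is.null(panel)) {
    shared <- intersect(loci, panel$loci)
    kinds[shared] <- locus_kinds(panel)[shared]
  }
  for (j in seq_along(loci)) {
    cells[, j] <- vapply(cells[, j], canonical_cell, "",
                         kind = kinds[[j]], locus = loci[j],
                         USE.NAMES = FALSE)
  }
  rownames(cells) <- ids
  structure(list(name = name, ids = ids, cells = cells, kinds = kinds),
            class = "pop_sample")
}

#' @export
print.pop_sample <- function(x, ...) {
  cat(sprintf("<pop_sample> %s: %d individuals x %d loci (%d cells missing)\n",
              x$name, nrow(x$cells), ncol(x$cells), sum(is.na(x$cells))))
  invisible(x)
}

#' Number of individuals in a sample
#' @param sample A `"pop_sample"`.
#' @return Integer sample size n.
#' @export
sample_size <- function(sample) nrow(sample$cells)

#' Loci typed in a sample
#' @param sample A `"pop_sample"`.
#' @return Character vector of locus names.
#' @export
sample_loci <- function(sample) colnames(sample$cells)

#' Read a haplotype table
#'
#' Expects a delimited text table with a header row naming a sample-ID
#' column plus one column per marker; multi-allele cells are comma-joined
#' inside the field (`"13,14"`). Empty cells are recorded as missing
#' markers.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param panel [panel_def()] whose loci must all be present as columns.
#' @param name Population name; defaults to the file base name.
#' @param id_col Name of the sample-identifier column.
#' @param sep Field separator; `"\t"` default, `","` accepted.
#' @return A [pop_sample()] restricted to `id_col` + `panel$loci`.
#' @export
read_haplotype_table <- function(path, panel, name = NULL,
                                 id_col = "SampleID", sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!id_col %in% names(df)) {
    stop(sprintf("schema error in %s: missing sample-ID column '%s'",
                 path, id_col), call. = FALSE)
  }
  absent <- setdiff(panel$loci, names(df))
  if (length(absent)) {
    stop(sprintf("schema error in %s: missing panel column(s): %s",
                 path, paste(absent, collapse = ", ")), call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pop_sample(name, df[[id_col]],
             as.matrix(df[, panel$loci, drop = FALSE]), panel = panel)
}

#' Write a haplotype table
#'
#' Inverse of [read_haplotype_table()]: writing then reading reproduces the
#' sample exactly (cells are stored canonically, so the round trip is the
#' identity). Microvariant labels keep their printed text (`"14.1"`).
#'
#' @param sample A [pop_sample()].
#' @param path Output path.
#' @param id_col Sample-identifier column name.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(sample, path, id_col = "SampleID",
                                  sep = "\t") {
  df <- data.frame(sample$ids, sample$cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(sample$cells))
  utils::write.table(df, path, sep = sep, quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Restrict a sample to the loci of a panel
#'
#' Haplotypes are projected onto `panel$loci`; the number of individuals is
#' unchanged. Projection can only merge haplotypes, never split them, so the
#' distinct-haplotype count under a sub-panel is at most that of the full
#' panel.
#'
#' @param sample A [pop_sample()].
#' @param panel Target [panel_def()]; all its loci must be typed in `sample`.
#' @return A [pop_sample()] over `panel$loci`.
#' @export
subset_panel <- function(sample, panel) {
  absent <- setdiff(panel$loci, sample_loci(sample))
  if (length(absent)) {
    stop(sprintf("panel '%s' loci absent from sample '%s': %s",
                 panel$name, sample$name, paste(absent, collapse = ", ")),
         call. = FALSE)
  }
  out <- sample
  out$cells <- sample$cells[, panel$loci, drop = FALSE]
  out$kinds <- sample$kinds[panel$loci]
  out
}

# One string key per individual over the given loci; NA if any locus missing.
haplotype_keys <- function(sample, loci = sample_loci(sample)) {
  cells <- sample$cells[, loci, drop = FALSE]
  keys <- apply(cells, 1L, paste, collapse = "|")
  keys[apply(cells, 1L, anyNA)] <- NA_character_
  keys
}
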