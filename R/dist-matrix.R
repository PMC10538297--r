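#' Labelled symmetric distance matrix
#'
#' Container for pairwise population distances (e.g. Rst): a symmetric
#' numeric matrix with zero diagonal and non-negative entries, labelled by
#' population names.
#'
#' @param values Square numeric matrix with matching dimnames (or none, in
#'   which case `labels` must be given).
#' @param labels Optional character vector of labels.
#' @param tol Symmetry tolerance.
#' @return Object of class `"dist_matrix"` (a labelled matrix).
#' @export
dist_matrix <- function(values, labels = NULL, tol = 1e-9) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square", call. = FALSE)
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  if (is.null(rownames(values))) stop("labels required", call. = FALSE)
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column labels differ", call. = FALSE)
  }
  if (max(abs(values - t(values))) > tol) {
    stop("matrix is not symmetric", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (any(values < 0)) stop("negative distances not allowed", call. = FALSE)
  structure(values, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d populations\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Labels of a distance matrix
#' @param d A [dist_matrix()].
#' @return Character vector.
#' @export
dist_labels <- function(d) rownames(d)

#' Write a distance matrix
#'
#' `"tsv"` writes a square labelled table (header row + label column);
#' `"phylip"` writes the PHYLIP square-matrix dialect (count line, then one
#' row per taxon with the name in a 10-character field).
#'
#' @param d A [dist_matrix()].
#' @param path Output path.
#' @param format `"tsv"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(Population = rownames(d), unclass(d),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    nm <- gsub("[ \t]", "_", rownames(d))
    for (i in seq_len(nrow(d))) {
      writeLines(paste0(formatC(substr(nm[i], 1, 10), width = -10),
                        paste(formatC(d[i, ], format = "f", digits = 6),
                              collapse = "  ")), con)
    }
  }
  invisible(path)
}

#' Read a distance matrix written by [write_dist_matrix()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"phylip"`.
#' @return A [dist_matrix()].
#' @export
read_dist_matrix <- function(path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    return(dist_matrix(m, tol = 1e-6))
  }
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  labs <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- lines[i + 1L]
    labs[i] <- trimws(substr(row, 1, 10))
    m[i, ] <- as.numeric(strsplit(trimws(substring(row, 11)),
                                  "[ \t]+")[[1]])
  }
  dimnames(m) <- list(labs, labs)
  dist_matrix(m, tol = 1e-6)
}
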