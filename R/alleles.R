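#' Parse a forensic allele token into a canonical locus call
#'
#' Y-STR alleles are named by repeat count, with microvariants written as a
#' decimal with one fractional digit (`"14.1"` is 14 full repeats plus 1 bp).
#' Multi-copy loci (e.g. DYS385, DYS527) yield several alleles per male,
#' printed comma-separated (`"19,21,22"`); copy-number anomalies such as a
#' bi-allelic pattern at a nominally single-copy locus are parsed the same
#' way. Y-InDel markers carry categorical two-state labels with no numeric
#' repeat semantics.
#'
#' The returned call is canonical: STR alleles are sorted ascending by
#' numeric value (ties broken by the printed label), so parsing `"22,19,21"`
#' and `"19,21,22"` yields equal calls. The printed label text is preserved
#' exactly (`"14.1"` stays `"14.1"`, `"13"` stays `"13"`).
#'
#' @param token Non-empty character scalar, e.g. `"13"`, `"14.1"`,
#'   `"19,21,22"`. A hyphen is accepted as an alternative multi-allele
#'   separator on input.
#' @param locus_kind `"str"` for repeat-numbered STR alleles, `"indel"` for
#'   categorical insertion/deletion states.
#' @param locus Marker name, used in error messages and stored on the call.
#' @param delim Multi-allele delimiter (default comma).
#' @return An object of class `"locus_call"`: a list with elements `locus`,
#'   `kind`, `labels` (canonical order), and `values` (numeric repeat counts,
#'   `NA` for InDel states).
#' @examples
#' parse_allele("14.1", "str", locus = "DYS458")
#' parse_allele("19,21,22", "str", locus = "DYS527")
#' @export
parse_allele <- function(token, locus_kind = c("str", "indel"), locus = "",
                         delim = ",") {
  locus_kind <- match.arg(locus_kind)
  if (length(token) != 1L || is.na(token) || !nzchar(trimws(token))) {
    stop(sprintf("empty allele token at locus '%s'", locus), call. = FALSE)
  }
  token <- trimws(token)
  parts <- trimws(strsplit(token, delim, fixed = TRUE)[[1L]])
  if (length(parts) == 1L && locus_kind == "str" && grepl("-", parts)) {
    # hyphen accepted as an input alternative for multi-allele tokens
    parts <- trimws(strsplit(token, "-", fixed = TRUE)[[1L]])
  }
  if (length(parts) == 0L || any(!nzchar(parts))) {
    stop(sprintf("malformed allele token '%s' at locus '%s': empty item",
                 token, locus), call. = FALSE)
  }
  if (locus_kind == "str") {
    ok <- grepl("^[0-9]+(\\.[0-9])?$", parts)
    if (!all(ok)) {
      stop(sprintf(
        "malformed STR allele '%s' at locus '%s' (token '%s'): labels must be a repeat count with at most one fractional digit",
        parts[!ok][1L], locus, token), call. = FALSE)
    }
    values <- as.numeric(parts)
    if (any(values <= 0)) {
      stop(sprintf("non-positive STR allele '%s' at locus '%s'",
                   parts[values <= 0][1L], locus), call. = FALSE)
    }
    ord <- order(values, parts)
    call <- list(locus = locus, kind = "str",
                 labels = parts[ord], values = values[ord])
  } else {
    if (length(parts) > 1L) {
      stop(sprintf("InDel locus '%s' admits a single binary state, got '%s'",
                   locus, token), call. = FALSE)
    }
    call <- list(locus = locus, kind = "indel",
                 labels = parts, values = NA_real_)
  }
  class(call) <- "locus_call"
  call
}

#' Canonical printed form of a locus call
#'
#' @param call A `"locus_call"`.
#' @param delim Delimiter used to join multi-allele labels.
#' @return Character scalar, e.g. `"19,21,22"`.
#' @export
format_call <- function(call, delim = ",") {
  stopifnot(inherits(call, "locus_call"))
  paste(call$labels, collapse = delim)
}

#' @export
print.locus_call <- function(x, ...) {
  cat(sprintf("<locus_call> %s [%s]: %s\n", x$locus, x$kind, format_call(x)))
  invisible(x)
}

#' @export
`==.locus_call` <- function(e1, e2) {
  identical(e1$kind, e2$kind) && identical(e1$labels, e2$labels)
}

#' Number of allele copies in a call
#' @param call A `"locus_call"`.
#' @return Integer copy count (e.g. 3 for a tri-allelic pattern).
#' @export
n_alleles <- function(call) length(call$labels)

# Canonicalize one table cell; NA / "" -> NA (missing marker).
canonical_cell <- function(cell, kind, locus, delim = ",") {
  if (is.na(cell) || !nzchar(trimws(cell))) return(NA_character_)
  format_call(parse_allele(cell, kind, locus = locus, delim = delim))
}
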