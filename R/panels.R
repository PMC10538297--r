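#' Define a Y-marker panel
#'
#' A panel is an ordered set of marker names together with two annotations:
#' which loci are multi-copy (amplified from duplicated Y regions, so a
#' single male yields two or more alleles treated as one unordered state)
#' and which are binary Y-InDels.
#'
#' @param name Panel name.
#' @param loci Character vector of unique marker names, in reporting order.
#' @param multi_copy Subset of `loci` expected to yield more than one allele.
#' @param indel_loci Subset of `loci` with two categorical states.
#' @return Object of class `"panel_def"`.
#' @examples
#' panel_def("toy", c("DYS391", "DYS385"), multi_copy = "DYS385")
#' @export
panel_def <- function(name, loci, multi_copy = character(),
                      indel_loci = character()) {
  loci <- as.character(loci)
  if (anyDuplicated(loci)) {
    stop("panel loci must be unique: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "), call. = FALSE)
  }
  if (!all(multi_copy %in% loci)) {
    stop("multi_copy loci not in panel: ",
         paste(setdiff(multi_copy, loci), collapse = ", "), call. = FALSE)
  }
  if (!all(indel_loci %in% loci)) {
    stop("indel loci not in panel: ",
         paste(setdiff(indel_loci, loci), collapse = ", "), call. = FALSE)
  }
  if (length(intersect(multi_copy, indel_loci))) {
    stop("multi_copy and indel_loci must be disjoint", call. = FALSE)
  }
  structure(list(name = name, loci = loci,
                 multi_copy = as.character(multi_copy),
                 indel_loci = as.character(indel_loci)),
            class = "panel_def")
}

#' @export
print.panel_def <- function(x, ...) {
  cat(sprintf("<panel_def> %s: %d loci (%d multi-copy, %d InDel)\n",
              x$name, length(x$loci), length(x$multi_copy),
              length(x$indel_loci)))
  invisible(x)
}

#' Locus kind lookup for a panel
#' @param panel A `"panel_def"`.
#' @return Named character vector mapping locus -> `"str"` / `"indel"`.
#' @export
locus_kinds <- function(panel) {
  kinds <- stats::setNames(rep("str", length(panel$loci)), panel$loci)
  kinds[panel$indel_loci] <- "indel"
  kinds
}

#' Built-in commercial Y-marker panel definitions
#'
#' Shipped defaults for the classic forensic kits: the 9-STR minimal
#' haplotype, PowerPlex Y (12), Yfiler (17), PowerPlex Y23, Yfiler Plus (27)
#' and a 44-marker extended panel (41 Y-STRs + 3 Y-InDels) of the kind used
#' by six-dye megaplex kits. Multi-copy loci (DYS385, DYF387S1, DYS527,
#' DYF404S1) are counted once in the locus list; marker counts in kit names
#' count their amplicons. The 44-marker roster is configuration-driven: edit
#' it or supply your own via [read_panel_config()] to match a specific kit.
#'
#' @return Named list of [panel_def()] objects.
#' @export
default_panels <- function() {
  minimal <- c("DYS19", "DYS385", "DYS389I", "DYS389II", "DYS390",
               "DYS391", "DYS392", "DYS393")
  ppy12 <- c(minimal, "DYS437", "DYS438", "DYS439")
  yfiler17 <- c(ppy12, "DYS448", "DYS456", "DYS458", "DYS635", "YGATAH4")
  ppy23 <- c(yfiler17, "DYS481", "DYS533", "DYS549", "DYS570", "DYS576",
             "DYS643")
  yfp27 <- c(yfiler17, "DYS449", "DYS460", "DYS481", "DYS518", "DYS533",
             "DYS570", "DYS576", "DYS627", "DYF387S1")
  ext44 <- c(union(yfp27, ppy23),
             "DYS388", "DYS527", "DYF404S1", "DYS557", "DYS596", "DYS645",
             "DYS444", "DYS447", "DYS522", "DYS593",
             "rs199815934", "rs759551978", "rs771783753")
  mc <- function(loci) intersect(c("DYS385", "DYF387S1", "DYS527",
                                   "DYF404S1"), loci)
  ind <- function(loci) intersect(c("rs199815934", "rs759551978",
                                    "rs771783753"), loci)
  list(
    minimal      = panel_def("Minimal",       minimal,  mc(minimal)),
    powerplex_y  = panel_def("PowerPlex Y",   ppy12,    mc(ppy12)),
    yfiler       = panel_def("Yfiler",        yfiler17, mc(yfiler17)),
    powerplex_y23 = panel_def("PowerPlex Y23", ppy23,   mc(ppy23)),
    yfiler_plus  = panel_def("Yfiler Plus",   yfp27,    mc(yfp27)),
    extended_44  = panel_def("Extended 44",   ext44,    mc(ext44), ind(ext44))
  )
}

#' Read panel definitions from a YAML config file
#'
#' One panel per top-level key; each panel maps `loci` to a list of marker
#' names and optionally `multi_copy` and `indel` to sublists.
#'
#' @param path Path to the YAML file.
#' @return Named list of [panel_def()] objects.
#' @export
read_panel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    p <- cfg[[nm]]
    if (is.null(p$loci)) {
      stop(sprintf("panel '%s' in %s has no 'loci' entry", nm, path),
           call. = FALSE)
    }
    panel_def(nm, unlist(p$loci),
              multi_copy = as.character(unlist(p$multi_copy)),
              indel_loci = as.character(unlist(p$indel)))
  })
  stats::setNames(out, names(cfg))
}

#' Write panel definitions to a YAML config file
#' @param panels Named list of [panel_def()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_config <- function(panels, path) {
  cfg <- lapply(panels, function(p) {
    list(loci = as.list(p$loci),
         multi_copy = as.list(p$multi_copy),
         indel = as.list(p$indel_loci))
  })
  names(cfg) <- vapply(panels, `[[`, "", "name")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
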