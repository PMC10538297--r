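#' Classical (Torgerson) metric multidimensional scaling
#'
#' Embeds a population distance matrix in k Euclidean dimensions by double
#' centering the squared distances and eigendecomposing (via
#' [stats::cmdscale()]); coordinates are eigenvectors scaled by the square
#' root of their (non-negative) eigenvalues, so negative eigenvalues are
#' truncated. A deterministic sign convention is applied: the first
#' non-zero entry of each axis is made positive. The reported stress is the
#' normalized residual `sqrt(sum((d - dhat)^2) / sum(d^2))` between input
#' and reconstructed distances.
#'
#' @param d A [dist_matrix()] (symmetric, non-negative, zero diagonal).
#' @param k Number of dimensions, `k < nrow(d)`.
#' @return Object of class `"ordination"`: list with `labels`, `points`
#'   (n x k, columns centered), `eigenvalues` (non-increasing), `stress`.
#' @export
classical_mds <- function(d, k = 2L) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (k >= n) stop("k must be smaller than the number of populations",
                   call. = FALSE)
  if (all(m == 0)) {
    return(structure(list(labels = rownames(m),
                          points = matrix(0, n, k,
                                          dimnames = list(rownames(m), NULL)),
                          eigenvalues = rep(0, n), stress = 0),
                     class = "ordination"))
  }
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = k,
                                          eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) == 0L) pts <- matrix(0, n, 0)
  if (ncol(pts) < k) {          # fewer positive eigenvalues than k axes
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  for (j in seq_len(ncol(pts))) {
    i <- which(abs(pts[, j]) > 1e-12)[1L]
    if (!is.na(i) && pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(m)
  dhat <- as.matrix(stats::dist(pts))
  denom <- sum(m^2)
  stress <- if (denom > 0) sqrt(sum((m - dhat)^2) / denom) else 0
  structure(list(labels = rownames(m), points = pts,
                 eigenvalues = sort(fit$eig, decreasing = TRUE),
                 stress = stress),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d populations in %d dimensions, stress %.4g\n",
              length(x$labels), ncol(x$points), x$stress))
  print(x$points, ...)
  invisible(x)
}

#' @export
plot.ordination <- function(x, ...) {
  graphics::plot(x$points[, 1], x$points[, 2], xlab = "Dimension 1",
                 ylab = "Dimension 2", ...)
  graphics::text(x$points[, 1], x$points[, 2], labels = x$labels, pos = 3,
                 cex = 0.8)
  invisible(x)
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Standard NJ agglomeration: at each step the pair minimizing the Q
#' criterion `(m - 2) d(i,j) - r_i - r_j` is joined, with ties broken
#' deterministically by the lowest pair of node indices (tips in input
#' label order, then internal nodes in creation order). Branch lengths use
#' the canonical formulas; a negative branch length is clamped to zero with
#' the subtraction transferred to its sibling edge, so the pair's summed
#' length is preserved. On an additive matrix NJ recovers the generating
#' topology and branch lengths exactly.
#'
#' @param d A [dist_matrix()] with at least 3 labels.
#' @return An unrooted `"phylo"` tree (ape) whose tip set equals the matrix
#'   labels.
#' @export
neighbor_joining <- function(d) {
  m0 <- as.matrix(d)
  n <- nrow(m0)
  if (n < 3L) stop("Neighbor-Joining needs >= 3 populations", call. = FALSE)
  labels <- rownames(m0)
  # node ids: 1..n tips, internal nodes numbered onward in creation order
  active <- seq_len(n)
  D <- m0
  next_id <- n + 1L
  kids <- list()   # internal id -> list(child ids, lengths)

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    c(li, lj)
  }

  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    best_q <- Inf; bi <- bj <- 0L
    for (i in 1:(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < best_q - 1e-12) { best_q <- q; bi <- i; bj <- j }
      }
    }
    dij <- D[bi, bj]
    li <- dij / 2 + (r[bi] - r[bj]) / (2 * (m - 2))
    lens <- clamp_pair(li, dij - li)
    u <- next_id; next_id <- next_id + 1L
    kids[[as.character(u)]] <- list(children = active[c(bi, bj)],
                                    lengths = lens)
    dn <- (D[bi, ] + D[bj, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(bi, bj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    active <- c(active[keep], u)
  }
  # final trifurcation via the three-point formulas
  x <- D[1, 2]; y <- D[1, 3]; z <- D[2, 3]
  lens <- pmax(0, c((x + y - z) / 2, (x + z - y) / 2, (y + z - x) / 2))
  root <- next_id
  kids[[as.character(root)]] <- list(children = active, lengths = lens)

  render <- function(id) {
    if (id <= n) return(quote_newick_label(labels[id]))
    k <- kids[[as.character(id)]]
    parts <- vapply(seq_along(k$children), function(i) {
      sprintf("%s:%.12g", render(k$children[i]), k$lengths[i])
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  from_newick(paste0(render(root), ";"))
}

# Quote a Newick label when it contains structural characters or blanks.
quote_newick_label <- function(lab) {
  if (grepl("[][ \t(),:;']", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else {
    lab
  }
}

#' Parse Newick text into a tree
#'
#' Thin wrapper over [ape::read.tree()] that additionally strips the
#' Newick-convention single quotes from tip labels, so
#' `from_newick(to_newick(t))` restores the original labels.
#'
#' @param text Newick character scalar.
#' @return A `"phylo"` object.
#' @export
from_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  quoted <- grepl("^'.*'$", tr$tip.label)
  tr$tip.label[quoted] <- gsub("''", "'",
                               sub("^'(.*)'$", "\\1",
                                   tr$tip.label[quoted]))
  tr
}

#' Serialize a tree to Newick text
#'
#' Writes branch lengths and quotes labels containing spaces or Newick
#' structural characters (single quotes doubled inside, per the Newick
#' convention); the string re-parses (e.g. with [ape::read.tree()]) to an
#' isomorphic topology.
#'
#' @param tree A `"phylo"` object.
#' @return Newick character scalar terminated by `";"`.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1L]
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  render <- function(node) {
    if (node <= ntip) return(quote_newick_label(tree$tip.label[node]))
    parts <- vapply(kids[[as.character(node)]], function(e) {
      sub <- render(tree$edge[e, 2])
      if (is.null(tree$edge.length)) sub else
        sprintf("%s:%.12g", sub, tree$edge.length[e])
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(render(root), ";")
}
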