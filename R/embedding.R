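#' Embed a gene tree as points by classical multidimensional scaling
#'
#' Computes the patristic (path-length) distance matrix between leaves and
#' applies classical (Torgerson) MDS: double-center -1/2 D^2, eigendecompose
#' and keep every axis whose eigenvalue is positive (greater than 1e-9 of
#' the largest). Pairwise Euclidean distances between the embedded points
#' approximate the patristic distances, exactly so when the tree metric is
#' Euclidean; truncation error comes only from genuinely negative
#' eigenvalues.
#'
#' @param gtree Gene tree with branch lengths ([ape::phylo]).
#' @return Object of class `tree_embedding`: `$points` (matrix, one row per
#'   leaf, rownames are leaf labels) and `$eigenvalues` (descending).
#' @export
embed_tree <- function(gtree) {
  if (is.null(gtree$edge.length)) {
    warning("gene tree has no branch lengths; all points coincide")
    gtree$edge.length <- rep(0, nrow(gtree$edge))
  }
  D <- ape::cophenetic.phylo(gtree)
  if (!all(is.finite(D))) stop("non-finite patristic distance")
  n <- nrow(D)
  if (all(D == 0)) {
    warning("all patristic distances are zero; embedding is degenerate")
    pts <- matrix(0, n, 1L, dimnames = list(rownames(D), NULL))
    return(structure(list(points = pts, eigenvalues = rep(0, n)),
                     class = "tree_embedding"))
  }
  mds <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1L, eig = TRUE))
  ev <- mds$eig
  tol <- 1e-9 * max(ev)
  navail <- ncol(mds$points)
  keep <- which(ev[seq_len(navail)] > tol)
  pts <- mds$points[, keep, drop = FALSE]
  rownames(pts) <- rownames(D)
  structure(list(points = pts, eigenvalues = sort(ev, decreasing = TRUE)),
            class = "tree_embedding")
}

#' Spread of a group of embedded points
#'
#' The spread sigma of a MIG is the root-mean-square Euclidean distance of
#' its member points from their centroid (the total standard deviation of
#' the point cloud). For an exact embedding it satisfies the pairwise
#' identity sigma^2 = sum_ij d_ij^2 / (2 n^2). Singletons have spread 0.
#'
#' @param embedding A `tree_embedding` from [embed_tree()].
#' @param members Character vector of leaf labels (non-empty, all embedded).
#' @return Non-negative scalar, in branch-length units.
#' @export
mig_sigma <- function(embedding, members) {
  stopifnot(inherits(embedding, "tree_embedding"))
  if (!length(members)) stop("empty member set")
  miss <- setdiff(members, rownames(embedding$points))
  if (length(miss)) stop("member not in embedding: ", miss[1])
  if (length(members) == 1L) return(0)
  pts <- embedding$points[members, , drop = FALSE]
  ctr <- colMeans(pts)
  sqrt(mean(rowSums(sweep(pts, 2L, ctr)^2)))
}

#' Relative spread of a MIG
#'
#' `P = sigma / sigma_bar - 1`, where `sigma_bar` is the median spread over
#' non-singleton MIGs. P = 1.0 means the MIG is spread 100% wider than the
#' median; P = -0.3 means 30% tighter. Degenerate cases (singleton MIGs, or
#' no positive median spread) are handled by the clustering layer, which
#' sets P to 0 there.
#'
#' @param sigma Spread of the MIG (vectorized).
#' @param sigma_bar Median spread of non-singleton MIGs; must be positive.
#' @return Dimensionless relative spread, >= -1.
#' @export
relative_spread <- function(sigma, sigma_bar) {
  if (!is.finite(sigma_bar) || sigma_bar <= 0) {
    stop("sigma_bar must be positive; degenerate medians make P = 0 upstream")
  }
  sigma / sigma_bar - 1
}

# Spread of every clade of the gene tree (vector indexed by node).
.clade_sigmas <- function(rec, embedding) {
  labs <- rec$gtree$tip.label
  nn <- length(rec$event)
  vapply(seq_len(nn), function(v) {
    mig_sigma(embedding, labs[rec$clade_tips[[v]]])
  }, numeric(1))
}

# Median spread over non-singleton MIGs of a partition; NA when degenerate.
.median_sigma <- function(sigmas, sizes) {
  ns <- sigmas[sizes >= 2L]
  if (!length(ns)) return(NA_real_)
  m <- stats::median(ns)
  if (m <= 0) NA_real_ else m
}
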