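#' Correlation distance between expression profiles
#'
#' \eqn{d(i, j) = 1 - r_{ij}} with Pearson correlation over all genes, so
#' distances lie in \eqn{[0, 2]}: identical profiles at 0, perfectly
#' anti-correlated profiles at 2. The standard metric for expression
#' dendrograms.
#'
#' @param m An `ExpressionMatrix`; profiles are columns (typically
#'   [subset_mean_profile()] output).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 2L) stop("need >= 2 profiles")
  if (nrow(m$values) < 2L) stop("need >= 2 genes")
  sds <- apply(m$values, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance profile(s): ",
         paste(colnames(m$values)[sds == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(m$values)
  d <- pmin(pmax(d, 0), 2)   # guard rounding at the boundaries
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering of profiles
#'
#' Average (UPGMA) or complete linkage over a distance matrix. Leaves are
#' sorted lexicographically before clustering so the dendrogram is
#' deterministic and invariant to the input order of profiles; with
#' average or complete linkage merge heights are nondecreasing toward the
#' root.
#'
#' @param d Symmetric distance matrix with labelled rows and columns.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return An object of class `hclust`.
#' @export
hcluster <- function(d, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(d)) stop("`d` must be a distance matrix")
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-10))) {
    stop("distance matrix must be symmetric")
  }
  if (is.null(rownames(d))) stop("distance matrix needs profile labels")
  ord <- order(rownames(d), method = "radix")
  d <- d[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Export a dendrogram as Newick
#'
#' Converts the merge tree to a phylogeny (branch lengths derived from
#' merge heights) and writes Newick text.
#'
#' @param h An `hclust` object from [hcluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(h, path) {
  stopifnot(inherits(h, "hclust"))
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Leaf labels forming an exclusive clade?
#'
#' Checks whether a set of leaves appears as one complete subtree of the
#' dendrogram (no other leaf inside). A two-leaf clade means the leaves
#' are siblings.
#'
#' @param h An `hclust` object.
#' @param leaves Character vector of leaf labels.
#' @return `TRUE` or `FALSE`.
#' @export
is_clade <- function(h, leaves) {
  stopifnot(inherits(h, "hclust"))
  if (!all(leaves %in% h$labels)) stop("unknown leaf label(s)")
  if (length(leaves) == length(h$labels)) return(TRUE)
  phy <- ape::as.phylo(h)
  ape::is.monophyletic(phy, leaves)
}
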