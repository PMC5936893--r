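#' Read a sample of trees from Newick or NEXUS
#'
#' Reads one or more rooted trees with branch lengths (time units) from a
#' file, validating them for use in the phylogenetic covariance model: every
#' tree must have at least two uniquely labelled tips, non-negative edge
#' lengths, and all trees in a file must share the same tip set (the usual
#' situation for a posterior sample over a fixed taxon set).
#'
#' @param path Path to a tree file.
#' @param format `"newick"` (one tree per semicolon-terminated statement) or
#'   `"nexus"` (TREES block). Quoted labels and square-bracket comments are
#'   handled by the underlying ape readers.
#' @return A list of `phylo` objects (class `multiPhylo`), in file order.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' trees <- read_trees(tf)
#' length(trees)
#' @export
read_trees <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  trees <- switch(format,
    newick = ape::read.tree(path),
    nexus  = ape::read.nexus(path)
  )
  if (is.null(trees)) stop("no trees could be parsed from ", path)
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  for (i in seq_along(trees)) validate_phylogeny(trees[[i]], where = paste0("tree ", i))
  tips1 <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), tips1)) {
      stop("tip sets differ between tree 1 and tree ", i)
    }
  }
  trees
}

#' Validate a tree for covariance construction
#'
#' Checks the invariants assumed throughout the package: at least two tips,
#' unique non-empty tip labels, branch lengths present and non-negative.
#' Called internally by [read_trees()] and [phylo_covariance()].
#'
#' @param tree A `phylo` object.
#' @param where Label used in error messages.
#' @return The tree, invisibly.
#' @export
validate_phylogeny <- function(tree, where = "tree") {
  if (!inherits(tree, "phylo")) stop(where, " is not a 'phylo' object")
  if (ape::Ntip(tree) < 2) stop(where, " must have at least 2 tips")
  lab <- tree$tip.label
  if (anyDuplicated(lab)) {
    stop(where, " has duplicate tip labels: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  }
  if (any(!nzchar(lab))) stop(where, " has empty tip labels")
  if (is.null(tree$edge.length)) stop(where, " has no branch lengths")
  if (any(tree$edge.length < 0)) stop(where, " has negative branch lengths")
  invisible(tree)
}

#' Phylogenetic covariance (shared path lengths) from a tree
#'
#' Builds the matrix of shared root-to-MRCA path lengths between tip pairs —
#' the expected trait covariance (up to scale) under Brownian motion on the
#' tree — together with the root-to-tip depths. Entry (i, j) is the distance
#' from the root to the most recent common ancestor of tips i and j; the
#' diagonal holds the tip depths.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param taxa Character vector giving the output row/column order; must be a
#'   permutation of the tree's tip labels. Mismatch is an error, never a
#'   silent reorder.
#' @return An object of class `phylo_cov`: a list with `taxa`, `sigma`
#'   (n x n shared-path-length matrix) and `depths` (root-to-tip distances).
#' @seealso [normalize_covariance()] for the unit-diagonal form the GLS model
#'   consumes; [is_ultrametric()].
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' pc <- phylo_covariance(tr, c("A", "B", "C"))
#' pc$sigma
#' @export
phylo_covariance <- function(tree, taxa = tree$tip.label) {
  validate_phylogeny(tree)
  tips <- tree$tip.label
  if (!setequal(taxa, tips) || length(taxa) != length(tips)) {
    stop("'taxa' must be a permutation of the tree's tip labels")
  }
  n <- length(tips)
  depth_all <- ape::node.depth.edgelength(tree)   # root-to-node distances
  mrca_mat <- ape::mrca(tree)                     # tip x tip MRCA node ids
  sigma <- matrix(depth_all[mrca_mat], n, n, dimnames = dimnames(mrca_mat))
  diag(sigma) <- depth_all[seq_len(n)]
  sigma <- sigma[taxa, taxa, drop = FALSE]
  structure(
    list(taxa = taxa, sigma = sigma, depths = diag(sigma)),
    class = "phylo_cov"
  )
}

#' Normalize a phylogenetic covariance to unit diagonal
#'
#' Rescales the shared-path-length matrix so that every diagonal entry is 1:
#' `sigma[i, j] / sqrt(depths[i] * depths[j])`. For an ultrametric tree with
#' constant depth h this is simply `sigma / h`. The GLS model consumes this
#' unit-diagonal form so that the independent, phylogenetic and spatial
#' covariance components share a common variance scale (the global scale is
#' profiled out as sigma^2).
#'
#' @param pc A `phylo_cov` object.
#' @return A `phylo_cov` with unit diagonal (`depths` all 1).
#' @export
normalize_covariance <- function(pc) {
  stopifnot(inherits(pc, "phylo_cov"))
  if (any(pc$depths <= 0)) stop("zero or negative root-to-tip depth; cannot normalize")
  s <- sqrt(pc$depths)
  sigma <- pc$sigma / outer(s, s)
  diag(sigma) <- 1
  structure(list(taxa = pc$taxa, sigma = sigma, depths = rep(1, length(pc$depths))),
            class = "phylo_cov")
}

#' Test whether a tree is ultrametric within tolerance
#'
#' True when the largest and smallest root-to-tip depths differ by at most
#' `tol` relative to the largest depth. The spatial-phylogenetic model
#' assumes contemporaneous tips (no extinct taxa), so this is the standard
#' sanity check before analysis.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance (default `1e-8`).
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  validate_phylogeny(tree)
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) <= tol * max(d)
}

#' @export
print.phylo_cov <- function(x, ...) {
  n <- length(x$taxa)
  cat("Phylogenetic covariance (shared path lengths): ", n, " taxa\n", sep = "")
  cat("  depths: [", format(min(x$depths), digits = 6), ", ",
      format(max(x$depths), digits = 6), "]\n", sep = "")
  invisible(x)
}
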