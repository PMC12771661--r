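#' Read a rooted, branch-length-bearing Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree must be rooted
#' and every edge must carry a non-negative branch length; tip labels must be
#' unique and non-empty. Internal polytomies are accepted. Note that a basal
#' trichotomy in a Newick string is indistinguishable from an unrooted tree
#' and is therefore rejected as unrooted.
#'
#' @param path Path to a Newick file.
#' @return An object of class `phylo` (see \pkg{ape}).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick in '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick in '", path, "'")
  validate_phylogeny(tree)
  tree
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  validate_phylogeny(tree, require_rooted = FALSE)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate a phylogeny for use in diversity partitioning
#'
#' Checks tip-label uniqueness, presence and non-negativity of all branch
#' lengths, and (by default) rootedness.
#'
#' @param tree A `phylo` object.
#' @param require_rooted Reject unrooted trees (default `TRUE`).
#' @return `tree`, invisibly.
#' @export
validate_phylogeny <- function(tree, require_rooted = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  tips <- tree$tip.label
  if (any(is.na(tips)) || any(!nzchar(tips)))
    stop("empty or missing tip labels")
  dup <- unique(tips[duplicated(tips)])
  if (length(dup) > 0)
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (length(tree$edge.length) != nrow(tree$edge) || anyNA(tree$edge.length))
    stop("missing branch length on one or more edges")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (require_rooted && !ape::is.rooted(tree))
    stop("tree must be rooted (a basal polytomy reads as unrooted)")
  invisible(tree)
}

#' Cophenetic (tip-to-tip path length) distances
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' tips i and j; the diagonal is zero. Rows and columns follow the tree's
#' tip-label order.
#'
#' @param tree A rooted `phylo` object with >= 2 tips and branch lengths.
#' @return A symmetric species x species distance matrix.
#' @export
cophenetic_distances <- function(tree) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) < 2)
    stop("cophenetic distances need at least 2 tips")
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label, drop = FALSE]
  diag(d) <- 0
  d
}

#' Scale a dissimilarity matrix to the unit interval
#'
#' Divides every entry by the global maximum so that the largest
#' dissimilarity equals 1. Rank order is preserved; an all-zero matrix is
#' returned unchanged with a warning. Used to put phylogenetic cophenetic
#' distances on the same 0-1 scale as the taxonomic (0/1) dissimilarity.
#'
#' @param dm Symmetric non-negative dissimilarity matrix.
#' @return The rescaled matrix.
#' @export
scale_unit <- function(dm) {
  dm <- as.matrix(dm)
  if (any(dm < 0)) stop("dissimilarities must be non-negative")
  m <- max(dm)
  if (m == 0) {
    warning("all-zero dissimilarity matrix; returned unchanged")
    return(dm)
  }
  dm / m
}

# Symmetry / zero-diagonal guard shared by the beta and dispersion stages.
check_dissimilarity <- function(dm, tol = 1e-12) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) stop("dissimilarity matrix must be square")
  if (max(abs(dm - t(dm))) > tol * max(1, max(abs(dm))))
    stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(dm)) > tol)) stop("dissimilarity matrix must have a zero diagonal")
  dm
}
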