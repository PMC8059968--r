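#' Read a phylogeny from a Newick file
#'
#' Reads a rooted tree with branch lengths and puts its tips in a
#' deterministic (lexicographic) order, so that every matrix derived from
#' the tree is reproducible across runs regardless of how the file was
#' written.
#'
#' @param path Path to a Newick file. Branch lengths are required.
#' @return An object of class `"phylo"` (see [ape::read.tree()]) whose tip
#'   order is lexicographic by label.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_newick(tf)
#' tr$tip.label
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick in '", path,
                                            "': ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick in '", path, "'")
  validate_phylogeny(tree)
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A `"phylo"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate and canonicalize a phylogeny
#'
#' Checks tip-label uniqueness, presence and non-negativity of branch
#' lengths, and rotates the tree so tips appear in lexicographic order.
#'
#' @param tree A `"phylo"` object.
#' @return The validated tree with lexicographic tip order.
#' @export
validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths")
  sort_tips(tree)
}

# Rotate a phylo object so the tip numbering follows sorted labels.
sort_tips <- function(tree) {
  ord <- order(tree$tip.label)
  if (identical(ord, seq_along(tree$tip.label))) return(tree)
  old2new <- integer(length(ord))
  old2new[ord] <- seq_along(ord)
  ntip <- length(tree$tip.label)
  tip_rows <- tree$edge[, 2] <= ntip
  tree$edge[tip_rows, 2] <- old2new[tree$edge[tip_rows, 2]]
  tree$tip.label <- tree$tip.label[ord]
  tree
}

#' Root-to-tip depths
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Named numeric vector of root-to-tip path lengths.
#' @export
tip_depths <- function(tree) {
  nd <- ape::node.depth.edgelength(tree)
  stats::setNames(nd[seq_along(tree$tip.label)], tree$tip.label)
}

#' Test whether a tree is ultrametric within a relative tolerance
#'
#' A tree is accepted as ultrametric when the spread of root-to-tip depths
#' does not exceed `tol` times the maximum depth.
#'
#' @param tree A `"phylo"` object.
#' @param tol Relative tolerance (default `1e-8`).
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- tip_depths(tree)
  (max(d) - min(d)) <= tol * max(d)
}

#' Inflate zero-length branches and re-ultrametricize
#'
#' Polytomies in time-calibrated trees are often resolved with zero-length
#' branches, which break methods that need a positive-definite phylogenetic
#' covariance. Every zero-length branch is set to `fraction` times the
#' median of the *positive* branch lengths (zeros are excluded from the
#' median so they cannot bias it downward), and the tree is then made
#' ultrametric again by extending terminal branches so that all tips reach
#' the maximum root-to-tip depth.
#'
#' The operation is idempotent: a tree without zero branches is returned
#' bit-identical.
#'
#' @param tree A `"phylo"` object.
#' @param fraction Fraction of the median positive branch length used for
#'   inflation; default `1e-4` (i.e. 0.01 percent).
#' @return The repaired tree; all branch lengths positive and, if the input
#'   was ultrametric up to the inflation, ultrametric again.
#' @export
resolve_zero_branches <- function(tree, fraction = 1e-4) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 2)
  pos <- tree$edge.length[tree$edge.length > 0]
  if (length(pos) == 0) stop("degenerate tree: all branches zero")
  zero <- tree$edge.length == 0
  if (!any(zero)) return(tree)
  tree$edge.length[zero] <- fraction * stats::median(pos)
  # extend terminal branches so every tip reaches the maximum depth
  d <- tip_depths(tree)
  ntip <- length(tree$tip.label)
  tip_edge <- match(seq_len(ntip), tree$edge[, 2])
  tree$edge.length[tip_edge] <- tree$edge.length[tip_edge] + (max(d) - d)
  tree
}

#' Phylogenetic variance-covariance matrix
#'
#' Builds the matrix C implied by Brownian motion on the tree: entry (i, j)
#' is the branch-length distance from the root to the most recent common
#' ancestor of tips i and j, and the diagonal holds root-to-tip depths.
#' Rows and columns follow the tree's tip order.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param tol Ultrametricity tolerance used only to decide whether to warn;
#'   the matrix is returned either way (Brownian motion does not require an
#'   ultrametric tree).
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (!is_ultrametric(tree, tol))
    warning("tree is not ultrametric within tolerance; ",
            "covariance returned anyway")
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Export a phylogenetic covariance matrix as CSV
#'
#' @param C Matrix from [phylo_vcv()].
#' @param path Output path. Taxa appear as header row and first column.
#' @return `path`, invisibly.
#' @export
write_vcv_csv <- function(C, path) {
  df <- data.frame(taxon = rownames(C), C, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
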