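#' Normalize taxon labels
#'
#' Spaces and underscores are treated as interchangeable in tip labels
#' (Newick dialects differ; supermatrix trees typically use underscored
#' binomials). Matching is case-sensitive otherwise.
#'
#' @param x character vector of labels.
#' @return character vector with leading/trailing whitespace stripped and
#'   underscores replaced by single spaces.
#' @export
normalize_label <- function(x) {
  x <- gsub("_", " ", as.character(x))
  trimws(gsub(" +", " ", x))
}

#' Parse a rooted Newick tree
#'
#' Reads a single rooted Newick statement with branch lengths and validates
#' it for comparative analysis: unique tip labels (after whitespace/underscore
#' normalization), non-negative branch lengths, and strictly positive
#' root-to-tip path lengths. Unlabelled internal nodes and polytomies are
#' allowed; ultrametricity is not required.
#'
#' @param text a single Newick string terminated by ';'.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(paste(text, collapse = ""))
  if (!nzchar(text) || !endsWith(text, ";")) {
    stop("Newick parse error: statement must be terminated by ';'")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf("Newick parse error: unbalanced parentheses (%d '(' vs %d ')')",
                 n_open, n_close))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("Newick parse error: could not parse tree text")
  }
  validate_tree(tree)
  tree
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; branch lengths are required")
  }
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1L]
    stop(sprintf("negative branch length (%g) on edge %d",
                 tree$edge.length[bad], bad))
  }
  labs <- normalize_label(tree$tip.label)
  if (anyDuplicated(labs)) {
    dups <- unique(labs[duplicated(labs)])
    stop("duplicate tip labels after normalization: ",
         paste(dups, collapse = ", "))
  }
  depths <- tip_depths(tree)
  if (any(depths <= 0)) {
    stop("zero-length root-to-tip path for tip(s): ",
         paste(tree$tip.label[depths <= 0], collapse = ", "))
  }
  invisible(tree)
}

# root-to-tip path lengths, in tip order
tip_depths <- function(tree) {
  ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
}

#' Prune a tree to a set of tips
#'
#' Restricts the tree to `keep`, collapsing degree-2 internal nodes and
#' summing their branch lengths, so that all pairwise tip-to-tip path
#' lengths are preserved exactly. Labels are matched with
#' whitespace/underscore normalization.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `phylo` object.
#' @export
prune_tree <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(as.character(keep))
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  idx <- match(normalize_label(keep), normalize_label(tree$tip.label))
  if (anyNA(idx)) {
    stop("tip labels absent from tree: ",
         paste(keep[is.na(idx)], collapse = ", "))
  }
  labels <- tree$tip.label[idx]
  if (length(labels) == length(tree$tip.label)) return(tree)
  pruned <- ape::keep.tip(tree, labels)
  # record the stem between the original root and the MRCA of the kept tips
  # as root.edge, so covariances relative to the original root are preserved
  mrca <- ape::getMRCA(tree, labels)
  stem <- ape::node.depth.edgelength(tree)[mrca] +
    (if (is.null(tree$root.edge)) 0 else tree$root.edge)
  if (stem > 0) pruned$root.edge <- stem
  pruned
}

#' Brownian phylogenetic covariance matrix
#'
#' Builds the taxon-ordered variance-covariance matrix C expected under
#' Brownian motion on the tree: `C[i, j]` is the branch length shared by the
#' root-to-tip paths of tips i and j (the depth of their most recent common
#' ancestor) and `C[i, i]` is the root-to-tip depth of tip i. Works for
#' non-ultrametric trees and polytomies.
#'
#' @param tree a `phylo` object with at least 2 tips.
#' @return an n x n matrix with tip labels as dimnames and attribute
#'   `lambda` (`NULL` until [lambda_transform()] is applied).
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (n < 2L) stop("need at least 2 tips to build a covariance matrix")
  node_depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree)                       # n x n matrix of MRCA node ids
  C <- matrix(node_depth[M], n, n, dimnames = list(tree$tip.label,
                                                   tree$tip.label))
  diag(C) <- node_depth[seq_len(n)]
  if (!is.null(tree$root.edge) && tree$root.edge > 0) {
    C <- C + tree$root.edge      # stem retained by prune: shared by all tips
  }
  attr(C, "lambda") <- NULL
  C
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of C by `lam`, leaving the diagonal
#' (tip depths) unchanged. `lam = 1` returns C unchanged (full Brownian
#' covariance); `lam = 0` removes all phylogenetic covariance (star-like
#' independence).
#'
#' @param C covariance matrix from [phylo_vcv()] (or any symmetric matrix).
#' @param lam scalar in \[0, 1\].
#' @return the transformed matrix, with attribute `lambda = lam`.
#' @export
lambda_transform <- function(C, lam) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam < 0 || lam > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  d <- diag(C)
  Cl <- C * lam
  diag(Cl) <- d
  attr(Cl, "lambda") <- lam
  Cl
}
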