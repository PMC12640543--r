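#' Read a newick tree
#'
#' Thin wrapper around [ape::read.tree()] that validates tip uniqueness.
#' Support values, when present as internal node labels, are carried
#' through unchanged.
#'
#' @param path Path to a newick file (or a newick string via `text`).
#' @param text Optional newick string instead of a file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) abort(paste0("newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tr)) abort("newick parse error: no tree found")
  if (anyDuplicated(tr$tip.label)) {
    abort(paste0(
      "duplicate tip labels: ",
      paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", ")
    ))
  }
  tr
}

#' Write a tree to newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining via [ape::nj()]. Negative estimated branch
#' lengths (a known NJ artefact on noisy matrices) are clamped to zero.
#'
#' @param d A distance-mode [distance_matrix()] result, `dist` object, or
#'   square symmetric matrix; must be complete (no `NA`).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (anyNA(m)) vp_abort("distance matrix has missing entries", "viropop_error_matrix")
  if (nrow(m) < 3L) abort("need at least 3 taxa for neighbour joining")
  if (!is.null(attr(d, "mode")) && attr(d, "mode") == "identity") {
    abort("nj_tree needs a distance-mode matrix, not identities")
  }
  tr <- ape::nj(as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path
#' (via [phangorn::midpoint()]). Tip-to-tip path lengths are unchanged.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A rooted tree.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths: midpoint undefined")
  if (all(tree$edge.length == 0)) abort("all branch lengths zero: midpoint undefined")
  phangorn::midpoint(tree)
}

#' Collapse short internal branches into polytomies
#'
#' Internal branches shorter than `epsilon` are removed and their child
#' clades promoted, producing polytomies. Terminal (tip) branches are
#' never removed. Used to suppress false-positive discordance signals
#' from near-zero branches before cophylogeny comparison.
#'
#' @param tree An [ape::phylo] tree.
#' @param epsilon Length threshold (same units as the branch lengths,
#'   substitutions per site for the trees this package builds);
#'   default 0.001.
#' @return The collapsed tree.
#' @export
collapse_short_branches <- function(tree, epsilon = 0.001) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    abort("epsilon must be a single non-negative number")
  }
  ape::di2multi(tree, tol = epsilon)
}

#' Is a set of tips monophyletic?
#'
#' `TRUE` iff some node of the rooted tree has exactly `tips` as its tip
#' descendants. Singletons and the full tip set are monophyletic by
#' convention.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param tips Character vector of tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("tips not in tree: ", paste(unknown, collapse = ", ")))
  }
  if (length(tips) <= 1L || length(tips) == length(tree$tip.label)) {
    return(TRUE)
  }
  ape::is.monophyletic(tree, tips)
}

# Tip-to-tip path-length matrix, ordered by tip label.
tip_distances <- function(tree) {
  m <- cophenetic(tree)
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}
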