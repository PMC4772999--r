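#' Neighbour-joining tree from a p-distance matrix
#'
#' Standard NJ agglomeration (via \code{ape::nj}) with a post-pass that
#' clamps negative branch lengths to zero and transfers the excess to the
#' sibling branch, preserving path lengths between tips as far as possible.
#' The result is unrooted and stored with an arbitrary root; use
#' [root_on()] to root it on an outgroup.
#'
#' @param m A `pdist` object with no undefined entries and at least 3 taxa.
#' @return A `phylo` tree with tip labels equal to the matrix ids.
#' @export
nj_tree <- function(m) {
  stopifnot(inherits(m, "pdist"))
  if (length(m$ids) < 3L) stop("argument error: need >= 3 taxa for NJ")
  if (anyNA(m$d)) stop("argument error: undefined entries in distance matrix")
  tr <- ape::nj(m$d)
  clamp_negative_branches(tr)
}

# internal: set negative edges to 0, moving the excess to the sibling edge
clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    excess <- tree$edge.length[e]
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent & seq_along(tree$edge.length) != e)
    tree$edge.length[e] <- 0
    if (length(sibs) > 0L)
      tree$edge.length[sibs[1]] <- max(0, tree$edge.length[sibs[1]] + excess)
  }
  tree
}

#' UPGMA tree from a p-distance matrix
#'
#' Average-linkage agglomeration; the output is ultrametric by
#' construction (tips contemporaneous), which makes it a convenient
#' desk-scale stand-in for externally dated ultrametric trees when running
#' GMYC-style delimitation.
#'
#' @param m A `pdist` object with no undefined entries and at least 2 taxa.
#' @return An ultrametric `phylo` tree.
#' @export
upgma_tree <- function(m) {
  stopifnot(inherits(m, "pdist"))
  if (length(m$ids) < 2L) stop("argument error: need >= 2 taxa")
  if (anyNA(m$d)) stop("argument error: undefined entries in distance matrix")
  hc <- stats::hclust(stats::as.dist(m$d), method = "average")
  ape::as.phylo(hc)
}

#' Collapse identical sequences to unique haplotypes
#'
#' Reduces the record set to one representative per identical sequence
#' string (the first occurrence), returning the membership map so entities
#' delimited on the collapsed set can be re-expanded to all sequences.
#' This is the standard preprocessing step before tree-based species
#' delimitation, where zero-length terminal branches are uninformative.
#'
#' @param records Record `data.frame`.
#' @return A list: `records` (unique-haplotype subset, original order) and
#'   `map` (named list: representative id -> character vector of all member
#'   ids, representative included).
#' @export
collapse_identical <- function(records) {
  check_records(records)
  grp <- match(records$sequence, unique(records$sequence))
  reps <- !duplicated(grp)
  map <- split(records$id, grp)
  names(map) <- records$id[reps]
  list(records = records[reps, , drop = FALSE], map = map)
}

#' Root a tree on an outgroup tip
#'
#' @param tree A `phylo` tree.
#' @param outgroup_tip Tip label to root on.
#' @return The rooted `phylo` tree (rooted on the branch subtending the
#'   outgroup tip).
#' @export
root_on <- function(tree, outgroup_tip) {
  if (!outgroup_tip %in% tree$tip.label)
    stop("argument error: outgroup tip not in tree: ", outgroup_tip)
  ape::root(tree, outgroup = outgroup_tip, resolve.root = TRUE)
}

#' Is a tree ultrametric?
#'
#' All root-to-tip path lengths equal within an absolute tolerance.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param tol Absolute tolerance on path-length differences.
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)
  tipd <- depths[seq_along(tree$tip.label)]
  diff(range(tipd)) <= tol
}
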