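#' Unweighted UniFrac distances between samples
#'
#' For each pair of samples the tree is restricted to the union of their
#' observed tips; the distance is the branch length leading exclusively
#' to tips of one sample, divided by the branch length of the whole
#' restricted tree. Presence is any nonzero entry of the supplied table
#' (by convention the 25%-breadth-cutoff abundance table), so the metric
#' depends only on presence/absence, never on coverage magnitudes.
#'
#' Implementation note: the pairwise restriction is computed on the full
#' tree by excluding branches with no descendant in either sample, which
#' is equivalent to pruning (collapsed unbranched paths contribute the
#' same summed length and the same exclusivity status). The basal root
#' edge, if any, is ignored.
#'
#' @param presence samples x GVMAGs matrix (numeric or logical); nonzero
#'   means present. Every GVMAG present in any sample must be a tree tip.
#' @param tree a rooted `phylo` tree with non-negative branch lengths.
#' @return a `dist` object with attribute `metric =
#'   "unweighted_unifrac"`.
#' @export
unweighted_unifrac <- function(presence, tree) {
  p <- as.matrix(presence) != 0
  observed <- colnames(p)[colSums(p) > 0]
  missing <- setdiff(observed, tree$tip.label)
  if (length(missing)) {
    stop("GVMAG(s) present in samples but missing from the tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  empty <- rownames(p)[rowSums(p) == 0]
  if (length(empty) >= 2) {
    stop("sample(s) with no GVMAG present: ",
         paste(empty, collapse = ", "),
         "; UniFrac is undefined for an empty pair", call. = FALSE)
  }
  inc <- edge_tip_incidence(tree)          # edges x tips (logical)
  # tips x samples presence restricted to tree tips (absent tips = FALSE)
  tp <- matrix(FALSE, length(tree$tip.label), nrow(p),
               dimnames = list(tree$tip.label, rownames(p)))
  shared_tips <- intersect(colnames(p), tree$tip.label)
  tp[shared_tips, ] <- t(p[, shared_tips, drop = FALSE])
  leads_to <- (inc %*% tp) > 0             # edges x samples
  len <- tree$edge.length
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      u <- leads_to[, i]
      v <- leads_to[, j]
      union_len <- sum(len[u | v])
      d[i, j] <- d[j, i] <- if (union_len == 0) 0 else
        sum(len[xor(u, v)]) / union_len
    }
  }
  out <- stats::as.dist(d)
  attr(out, "metric") <- "unweighted_unifrac"
  out
}

# Logical edges x tips matrix: inc[e, t] is TRUE when edge e lies on the
# path from the root to tip t.
edge_tip_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  node_tips <- vector("list", max(edge))
  for (i in seq_len(ntip)) node_tips[[i]] <- i
  inc <- matrix(FALSE, nrow(edge), ntip,
                dimnames = list(NULL, tree$tip.label))
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2]
    inc[e, node_tips[[child]]] <- TRUE
    parent <- edge[e, 1]
    node_tips[[parent]] <- c(node_tips[[parent]], node_tips[[child]])
  }
  # reorder() permutes edges; edge.length used by callers must match, so
  # return rows in the caller tree's edge order.
  ord <- match(paste(tree$edge[, 1], tree$edge[, 2]),
               paste(edge[, 1], edge[, 2]))
  inc[ord, , drop = FALSE]
}

#' WPGMA ("mcquitty") dendrogram of samples
#'
#' Weighted pair-group agglomerative clustering: the distance from a
#' merged cluster (i, j) to any cluster k is `(d(i,k) + d(j,k)) / 2`.
#' Labels are ordered lexicographically before clustering so that ties
#' between equidistant pairs break deterministically by label.
#'
#' @param d a `dist` object (no missing values).
#' @return an [stats::hclust] object (method `"mcquitty"`).
#' @export
wpgma <- function(d) {
  if (anyNA(as.vector(d))) stop("wpgma: distances contain NA/NaN",
                                call. = FALSE)
  m <- as.matrix(d)
  if (nrow(m) < 2) stop("wpgma: need at least 2 samples", call. = FALSE)
  ord <- order(rownames(m))
  stats::hclust(stats::as.dist(m[ord, ord]), method = "mcquitty")
}

#' Export a dendrogram as newick with merge heights as branch lengths
#' @param h an [stats::hclust] object.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}
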