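#' Random rooted tree generator
#'
#' Draws a random rooted topology with labelled leaves, optionally
#' collapsing internal edges into multifurcations (each internal edge is
#' collapsed independently with the given probability), mirroring the
#' treatment of contested nodes as multifurcations rather than forcing
#' an arbitrary binary resolution.
#'
#' @param n_leaves number of leaves (>= 2); labels are `t1..tn`.
#' @param seed optional integer seed.
#' @param collapse_p probability of collapsing each internal edge into a
#'   multifurcation (default 0: binary tree).
#' @return an `indexed_tree`.
#' @export
random_tree <- function(n_leaves, seed = NULL, collapse_p = 0) {
  stopifnot(n_leaves >= 2, collapse_p >= 0, collapse_p < 1)
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(n_leaves, rooted = TRUE,
                    tip.label = paste0("t", seq_len(n_leaves)))
  phy$node.label <- NULL
  if (collapse_p > 0 && phy$Nnode > 1L) {
    internal <- phy$edge[, 2L] > length(phy$tip.label)
    phy$edge.length[] <- 1
    phy$edge.length[internal] <-
      ifelse(stats::runif(sum(internal)) < collapse_p, 0, 1)
    phy <- ape::di2multi(phy, tol = 0.5)
  }
  phy$edge.length <- NULL
  index_tree(phy)
}
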