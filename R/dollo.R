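#' Edge cost model for copy-number changes
#'
#' The score of changing the paralog count from `k` (parent) to `j`
#' (child) along an edge. The default is the simple counting score
#' `|k - j|`: one unit per copy inserted by duplication or deleted.
#' Duplications and losses may be weighted differently, and a per-node
#' multiplier can rescale all changes on the edge entering a given node.
#'
#' @param dup_weight cost per copy gained on an edge (default 1).
#' @param loss_weight cost per copy lost on an edge (default 1).
#' @param node_weights optional named numeric vector (node label ->
#'   multiplier) applied to the edge entering that node; unnamed nodes
#'   get multiplier 1.
#' @return an object of class `cost_model`.
#' @export
cost_model <- function(dup_weight = 1, loss_weight = 1, node_weights = NULL) {
  stopifnot(dup_weight >= 0, loss_weight >= 0)
  if (!is.null(node_weights)) {
    stopifnot(is.numeric(node_weights), !is.null(names(node_weights)),
              all(node_weights >= 0))
  }
  structure(list(dup_weight = dup_weight, loss_weight = loss_weight,
                 node_weights = node_weights),
            class = "cost_model")
}

#' Evaluate the edge cost delta(j, k) of a cost model
#'
#' @param cost a [cost_model()].
#' @param k parent count.
#' @param j child count.
#' @param node label of the child node (for node-dependent weights).
#' @return nonnegative score; `delta(k, k)` is 0 for all `k`.
#' @export
edge_delta <- function(cost, k, j, node = NULL) {
  w <- 1
  if (!is.null(cost$node_weights) && !is.null(node)) {
    hit <- match(node, names(cost$node_weights))
    if (!is.na(hit)) w <- cost$node_weights[[hit]]
  }
  ifelse(j > k, cost$dup_weight * w * (j - k),
         cost$loss_weight * w * (k - j))
}

#' Subtree maxima of observed paralog counts
#'
#' For every node `v`, the maximum observed count over the leaves of the
#' subtree rooted at `v` (`P_v`); the value at a leaf is its own count.
#' `P_v = 0` identifies the maximal all-absent subtrees, and `P` at the
#' family origin bounds the count any ancestor can be assigned.
#'
#' @param tree an `indexed_tree`.
#' @param profile a count profile (named nonnegative integers over leaf
#'   labels; see [count_profile()]).
#' @return named integer vector over all nodes of the tree.
#' @export
subtree_maxima <- function(tree, profile) {
  cnt <- leaf_counts_vector(tree, profile)
  P <- integer(tree$n_node)
  P[tree$is_leaf] <- cnt[tree$is_leaf]
  for (v in tree$postorder) {
    kids <- tree$children[[v]]
    if (length(kids)) P[v] <- max(P[kids])
  }
  names(P) <- tree$labels
  P
}

# expand a profile to a full per-node count vector (0 for absent species)
leaf_counts_vector <- function(tree, profile) {
  cnt <- integer(tree$n_node)
  idx <- match(names(profile), tree$labels)
  if (anyNA(idx))
    stop("profile species not on the tree: ",
         paste(names(profile)[is.na(idx)], collapse = ", "), call. = FALSE)
  if (any(!tree$is_leaf[idx]))
    stop("profile keys must be leaf labels", call. = FALSE)
  cnt[idx] <- as.integer(profile)
  cnt
}

# last common ancestor of a set of node indices via the preorder
# first/last shortcut: take the first (p) and last (q) member in preorder,
# then the first node at which their root paths coincide
lca_idx <- function(tree, idx) {
  if (length(idx) == 1L) return(idx)
  pre <- tree$preorder_index[idx]
  p <- idx[which.min(pre)]
  q <- idx[which.max(pre)]
  on_path <- logical(tree$n_node)
  v <- p
  repeat {
    on_path[v] <- TRUE
    if (v == tree$root) break
    v <- tree$parent[v]
  }
  v <- q
  while (!on_path[v]) v <- tree$parent[v]
  v
}

# build the postorder-local arrays for the family subtree rooted at m
local_subtree <- function(tree, m, cnt) {
  member <- logical(tree$n_node)
  member[subtree_nodes(tree, m)] <- TRUE
  nodes <- tree$postorder[member[tree$postorder]]
  loc <- integer(tree$n_node)
  loc[nodes] <- seq_along(nodes)
  parent_loc <- loc[tree$parent[nodes]] - 1L
  parent_loc[length(parent_loc)] <- -1L   # m is last in the postorder
  leafcount <- cnt[nodes]
  leafcount[!tree$is_leaf[nodes]] <- -1L
  list(nodes = nodes, parent = as.integer(parent_loc),
       leafcount = as.integer(leafcount))
}

node_weight_vector <- function(tree, nodes, cost) {
  w <- rep(1, length(nodes))
  if (!is.null(cost$node_weights)) {
    hit <- match(tree$labels[nodes], names(cost$node_weights))
    w[!is.na(hit)] <- cost$node_weights[hit[!is.na(hit)]]
  }
  w
}

#' Most-parsimonious paralog history of one family
#'
#' Reconstructs ancestral paralog counts for a single gene family under
#' Dollo-constrained Sankoff parsimony. The family's origin is the last
#' common ancestor `m` of all species carrying it; all computation is
#' restricted to the subtree rooted at `m`, since the family does not
#' exist outside it. On the leaves the score table is initialised by the
#' observed counts; interior nodes whose subtree contains at least one
#' copy cannot be assigned zero copies (the Dollo constraint), and counts
#' are bounded above by the maximum observed leaf count. Interior counts
#' are recovered by backtracing; ties are broken toward the smallest
#' optimal count, applied top-down at the origin and then independently
#' per child, giving a deterministic, conservative (fewest inferred
#' ancestral paralogs) assignment. The number of co-optimal assignments
#' is also reported. Loss edges are the edges whose parent holds at least
#' one copy while the child holds none.
#'
#' @param tree an `indexed_tree`.
#' @param profile a [count_profile()] (named counts over leaf labels);
#'   at least one species must carry the family.
#' @param cost a [cost_model()]; default is the unit counting score.
#' @param family_id identifier for the reconstruction; defaults to the
#'   profile's `family_id` attribute.
#' @param k_max optional widening of the count range searched by the
#'   dynamic program beyond the maximum observed count (the optimum can
#'   never use it; exposed for verification).
#' @return an object of class `dollo_reconstruction`: `family_id`,
#'   `origin` (node label), `origin_at_root` (flag: the gain can only be
#'   placed at or before the root, since the root has no parent branch),
#'   `counts` (named integer vector over all nodes; 0 outside the family
#'   subtree), `total_score`, `n_optima`, `loss_edges` (two-column
#'   character matrix parent/child), `present_leaves`, `subtree_max`.
#' @examples
#' tr <- parse_newick("((A,B)N1,(C,D)N2)R;")
#' rec <- reconstruct_family(tr, count_profile(c(A = 1, B = 1, C = 0, D = 1)))
#' rec$total_score     # one family lost on the edge into C
#' rec$loss_edges
#' @export
reconstruct_family <- function(tree, profile, cost = cost_model(),
                               family_id = NULL, k_max = NULL) {
  cnt <- leaf_counts_vector(tree, profile)
  present <- which(cnt >= 1L & tree$is_leaf)
  if (!length(present))
    stop("family observed in no species; all-zero profiles are inadmissible",
         call. = FALSE)
  if (is.null(family_id))
    family_id <- attr(profile, "family_id") %||% "family"

  m <- lca_idx(tree, present)
  sub <- local_subtree(tree, m, cnt)
  nw <- node_weight_vector(tree, sub$nodes, cost)
  km <- if (is.null(k_max)) -1L else as.integer(k_max)
  dp <- .dollo_dp(sub$parent, sub$leafcount, km,
                  cost$dup_weight, cost$loss_weight, nw)

  counts <- integer(tree$n_node)
  counts[sub$nodes] <- dp$counts
  names(counts) <- tree$labels

  # loss edges: parent holds copies, child holds none, both inside T_m
  child_in <- sub$nodes[sub$parent >= 0L]
  par_of <- tree$parent[child_in]
  is_loss <- counts[par_of] > 0L & counts[child_in] == 0L
  loss_edges <- cbind(parent = tree$labels[par_of[is_loss]],
                      child = tree$labels[child_in[is_loss]])

  Pm <- integer(tree$n_node)
  Pm[sub$nodes] <- dp$P
  names(Pm) <- tree$labels

  structure(
    list(family_id = family_id,
         origin = tree$labels[m],
         origin_at_root = (m == tree$root),
         counts = counts,
         total_score = dp$score,
         n_optima = dp$n_optima,
         loss_edges = loss_edges,
         present_leaves = tree$labels[present],
         subtree_max = Pm,
         tree_signature = tree_signature(tree)),
    class = "dollo_reconstruction"
  )
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat("dollo_reconstruction '", x$family_id, "': origin ", x$origin,
      if (x$origin_at_root) " (at-or-before root)", ", score ",
      x$total_score, ", ", nrow(x$loss_edges), " loss edge(s), ",
      format(x$n_optima), " co-optimal assignment(s)\n", sep = "")
  invisible(x)
}

#' Reconstruct every family of a profile set
#'
#' @param tree an `indexed_tree`.
#' @param profiles list of [count_profile()] objects.
#' @param cost a [cost_model()].
#' @return list of `dollo_reconstruction` objects, one per family.
#' @export
reconstruct_families <- function(tree, profiles, cost = cost_model()) {
  lapply(profiles, reconstruct_family, tree = tree, cost = cost)
}

#' Exhaustive reference score for a family (validation aid)
#'
#' Enumerates every Dollo-feasible assignment of interior counts in
#' `0..P_m` over the family subtree and returns the minimum summed edge
#' cost and the number of assignments attaining it. Exponential in the
#' number of interior nodes: intended only for verifying the dynamic
#' program on small trees.
#'
#' @inheritParams reconstruct_family
#' @return list with `total_score`, `n_optima`, `counts` (one optimal
#'   assignment, named, 0 outside the family subtree), `origin`.
#' @export
enumerate_family <- function(tree, profile, cost = cost_model()) {
  cnt <- leaf_counts_vector(tree, profile)
  present <- which(cnt >= 1L & tree$is_leaf)
  if (!length(present)) stop("family observed in no species", call. = FALSE)
  m <- lca_idx(tree, present)
  sub <- local_subtree(tree, m, cnt)
  nw <- node_weight_vector(tree, sub$nodes, cost)
  en <- .dollo_enum(sub$parent, sub$leafcount,
                    cost$dup_weight, cost$loss_weight, nw)
  counts <- integer(tree$n_node)
  counts[sub$nodes] <- en$counts
  names(counts) <- tree$labels
  list(total_score = en$score, n_optima = en$n_optima,
       counts = counts, origin = tree$labels[m])
}

# cheap identity check so census refuses to mix reconstructions from
# different trees (precomputed at indexing time)
tree_signature <- function(tree) tree$signature

`%||%` <- function(a, b) if (is.null(a)) b else a
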