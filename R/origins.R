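#' Last common ancestor of a set of leaves
#'
#' Computes the LCA using the preorder shortcut: among the given leaves,
#' only the first (`p`) and last (`q`) in the fixed depth-first preorder
#' matter; the LCA of the whole set is the first node at which the paths
#' from `p` and `q` to the root coincide. Linear time per query. A
#' single-member set returns the leaf itself (a species-specific family
#' originates on the terminal branch).
#'
#' @param tree an `indexed_tree`.
#' @param present nonempty character vector of leaf labels.
#' @return the label of the LCA node.
#' @examples
#' tr <- parse_newick("((A,B)N1,(C,D)N2)R;")
#' find_lca_preorder(tr, c("A", "B"))   # "N1"
#' find_lca_preorder(tr, c("A", "B", "C"))  # "R"
#' @export
find_lca_preorder <- function(tree, present) {
  if (length(present) == 0L)
    stop("present set is empty", call. = FALSE)
  idx <- node_index(tree, present)
  if (any(!tree$is_leaf[idx]))
    stop("present set must contain only leaf labels", call. = FALSE)
  tree$labels[lca_idx(tree, idx)]
}

#' Date the origin of each family by its last common ancestor
#'
#' The origin of a family is estimated as the branch leading to the LCA
#' of all species in which it is observed (count >= 1): the Dollo
#' assumption places the single gain of the family on that branch. This
#' is a conservative (latest-possible) estimate of the true origin. For
#' families whose LCA is the global root, the gain is attributed to the
#' root itself and flagged `at_root`, since no parent branch exists.
#'
#' @param tree an `indexed_tree`.
#' @param profiles list of [count_profile()] objects.
#' @return data frame with columns `family_id`, `origin_node`,
#'   `n_present` (species carrying the family), `at_root`.
#' @export
assign_origins <- function(tree, profiles) {
  rows <- lapply(profiles, function(p) {
    cnt <- leaf_counts_vector(tree, p)
    present <- which(cnt >= 1L & tree$is_leaf)
    if (!length(present))
      stop("family '", attr(p, "family_id"),
           "' observed in no species", call. = FALSE)
    m <- lca_idx(tree, present)
    data.frame(family_id = attr(p, "family_id") %||% NA_character_,
               origin_node = tree$labels[m],
               n_present = length(present),
               at_root = (m == tree$root),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
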