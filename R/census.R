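#' Per-branch gain/loss census across a family set
#'
#' Aggregates per-family reconstructions into node-level statistics: how
#' many families are present at each node of the tree, how many
#' originated there (gains), how many were lost on the branch entering
#' it (losses), and the relative rates. The relative gain at a node is
#' the number of gained families divided by the number of families
#' present at that node (gains included); the relative loss on the
#' branch into a node is the number of families lost there divided by
#' the number of families present at its parent. Rates with a zero
#' denominator, and the root's relative loss (no parent branch), are
#' reported as `NA` — "no families to lose" is not the same as "no
#' losses". Per-edge copy turnover (paralogs gained/lost by duplication
#' and deletion) is tallied alongside.
#'
#' @param tree an `indexed_tree`.
#' @param reconstructions list of `dollo_reconstruction` objects, all on
#'   `tree`.
#' @return data frame in preorder with columns `node`, `parent`,
#'   `is_leaf`, `families_present`, `gains`, `losses`, `relative_gain`,
#'   `relative_loss`, `copies_gained`, `copies_lost`.
#' @examples
#' tr <- parse_newick("((A,B)N1,(C,D)N2)R;")
#' pr <- list(count_profile(c(A = 1, B = 1), "f1"),
#'            count_profile(c(A = 1, B = 2, C = 0, D = 1), "f2"))
#' branch_census(tr, reconstruct_families(tr, pr))
#' @export
branch_census <- function(tree, reconstructions) {
  check_same_tree(tree, reconstructions)
  n <- tree$n_node
  present <- integer(n); gains <- integer(n); losses <- integer(n)
  cg <- numeric(n); cl <- numeric(n)
  for (rec in reconstructions) {
    cnt <- rec$counts
    present <- present + (cnt >= 1L)
    gi <- match(rec$origin, tree$labels)
    gains[gi] <- gains[gi] + 1L
    if (nrow(rec$loss_edges)) {
      li <- match(rec$loss_edges[, "child"], tree$labels)
      losses[li] <- losses[li] + 1L
    }
    kids <- which(!is.na(tree$parent))
    d <- cnt[kids] - cnt[tree$parent[kids]]
    d[kids == gi] <- 0L   # the gain edge into the origin is not copy flux
    cg[kids] <- cg[kids] + pmax(0, d)
    cl[kids] <- cl[kids] + pmax(0, -d)
  }
  ord <- tree$preorder
  par <- tree$parent[ord]
  present_par <- ifelse(is.na(par), NA_integer_, present[par])
  data.frame(
    node = tree$labels[ord],
    parent = ifelse(is.na(par), NA_character_, tree$labels[par]),
    is_leaf = tree$is_leaf[ord],
    families_present = present[ord],
    gains = gains[ord],
    losses = losses[ord],
    relative_gain = ifelse(present[ord] > 0, gains[ord] / present[ord],
                           NA_real_),
    relative_loss = ifelse(!is.na(present_par) & present_par > 0,
                           losses[ord] / present_par, NA_real_),
    copies_gained = cg[ord],
    copies_lost = cl[ord],
    stringsAsFactors = FALSE
  )
}

#' Per-edge paralog copy turnover
#'
#' For every edge of the tree, sums over families the copies gained
#' (`max(0, child - parent)`) and copies lost (`max(0, parent - child)`)
#' by the reconstructed counts, and returns the raw
#' (ancestor count, descendant count) pairs needed to tabulate an
#' ancestor-versus-descendant paralog scatter (e.g. around a genome
#' duplication). Under the default unit cost model the summed flux of a
#' family over all edges equals its parsimony score. Edges outside a
#' family's subtree carry no events for it.
#'
#' @inheritParams branch_census
#' @return list with `flux` (data frame: `parent`, `child`,
#'   `copies_gained`, `copies_lost`) and `pairs` (data frame: `family_id`,
#'   `parent`, `child`, `parent_count`, `child_count`; one row per edge
#'   per family, restricted to edges inside the family's subtree).
#' @export
paralog_flux <- function(tree, reconstructions) {
  check_same_tree(tree, reconstructions)
  kids <- which(!is.na(tree$parent))
  par <- tree$parent[kids]
  cg <- numeric(length(kids)); cl <- numeric(length(kids))
  pair_list <- vector("list", length(reconstructions))
  for (i in seq_along(reconstructions)) {
    rec <- reconstructions[[i]]
    cnt <- rec$counts
    m <- match(rec$origin, tree$labels)
    d <- cnt[kids] - cnt[par]
    d[kids == m] <- 0L    # the gain edge into the origin is not copy flux
    cg <- cg + pmax(0, d)
    cl <- cl + pmax(0, -d)
    inside <- logical(tree$n_node)
    inside[subtree_nodes(tree, m)] <- TRUE
    sel <- inside[kids] & kids != m
    if (any(sel))
      pair_list[[i]] <- data.frame(
        family_id = rec$family_id,
        parent = tree$labels[par[sel]],
        child = tree$labels[kids[sel]],
        parent_count = unname(cnt[par[sel]]),
        child_count = unname(cnt[kids[sel]]),
        stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, c(pair_list[!vapply(pair_list, is.null, logical(1))],
                            list(make.row.names = FALSE)))
  if (is.null(pairs))
    pairs <- data.frame(family_id = character(0), parent = character(0),
                        child = character(0), parent_count = integer(0),
                        child_count = integer(0))
  list(flux = data.frame(parent = tree$labels[par],
                         child = tree$labels[kids],
                         copies_gained = cg, copies_lost = cl,
                         stringsAsFactors = FALSE),
       pairs = pairs)
}

check_same_tree <- function(tree, reconstructions) {
  sig <- tree_signature(tree)
  ok <- vapply(reconstructions, function(r)
    identical(r$tree_signature, sig), logical(1))
  if (!all(ok))
    stop("reconstruction(s) refer to a different tree: ",
         paste(vapply(reconstructions[!ok], `[[`, character(1), "family_id"),
               collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Census as node annotations for annotated newick output
#'
#' @param census a data frame from [branch_census()].
#' @return named list suitable for [write_annotated()] (keys `count`,
#'   `gains`, `losses`; `count` holds families present).
#' @export
census_annotations <- function(census) {
  out <- lapply(seq_len(nrow(census)), function(i)
    c(count = census$families_present[i],
      gains = census$gains[i],
      losses = census$losses[i]))
  names(out) <- census$node
  out
}

#' Write a census table as TSV
#' @param census data frame from [branch_census()].
#' @param file output path.
#' @export
write_census_tsv <- function(census, file) {
  utils::write.table(census, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(file)
}
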