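# Shared test machinery: exhaustive tree-shape enumeration, an
# independent path-intersection LCA oracle, and small tree utilities.

# All rooted tree shapes with n unlabelled leaves, internal nodes having
# >= 2 children (multifurcations included), up to isomorphism. Shapes are
# newick-like strings with "x" for a leaf. Children are kept in a fixed
# canonical (pool-index) order so each shape appears exactly once.
# Counts by n: 1, 1, 2, 5, 12, 33, 90, ...
tree_shapes <- local({
  memo <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (n == 1L) {
      memo[[key]] <<- "x"
      return("x")
    }
    pool_shape <- character(0)
    pool_size <- integer(0)
    for (k in seq_len(n - 1L)) {
      sk <- tree_shapes(k)
      pool_shape <- c(pool_shape, sk)
      pool_size <- c(pool_size, rep(k, length(sk)))
    }
    out <- character(0)
    # nonincreasing pool indices -> each child multiset once
    pick <- function(remaining, max_idx, acc) {
      if (remaining == 0L) {
        if (length(acc) >= 2L)
          out[[length(out) + 1L]] <<-
            paste0("(", paste(pool_shape[acc], collapse = ","), ")")
        return(invisible(NULL))
      }
      for (i in seq_len(max_idx)) {
        if (pool_size[i] <= remaining)
          pick(remaining - pool_size[i], i, c(acc, i))
      }
    }
    pick(n, length(pool_shape), integer(0))
    memo[[key]] <<- out
    out
  }
})

# turn a shape string into a parsed tree with leaves t1..tn
shape_to_tree <- function(shape) {
  n <- lengths(regmatches(shape, gregexpr("x", shape, fixed = TRUE)))
  for (i in seq_len(n))
    shape <- sub("x", paste0("t", i), shape, fixed = TRUE)
  parse_newick(paste0(shape, ";"))
}

# independent LCA oracle: intersect the root paths of every member and
# take the deepest node of the intersection
path_lca_oracle <- function(tree, labels) {
  idx <- match(labels, tree$labels)
  paths <- lapply(idx, function(v) {
    p <- v
    while (!is.na(tree$parent[p[length(p)]]))
      p <- c(p, tree$parent[p[length(p)]])
    p
  })
  common <- Reduce(intersect, paths)
  tree$labels[common[which.max(tree$preorder_index[common])]]
}

# rebuild the same tree with children in randomly permuted order
shuffle_children <- function(tree) {
  rec <- function(v) {
    kids <- tree$children[[v]]
    if (!length(kids)) return(tree$labels[v])
    kids <- sample(kids)
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
           ")", tree$labels[v])
  }
  parse_newick(paste0(rec(tree$root), ";"))
}

# perfectly balanced binary tree of given depth (2^depth leaves)
balanced_tree <- function(depth) {
  build <- function(d, prefix) {
    if (d == 0L) return(prefix)
    paste0("(", build(d - 1L, paste0(prefix, "a")), ",",
           build(d - 1L, paste0(prefix, "b")), ")")
  }
  parse_newick(paste0(build(depth, "L"), ";"))
}

# random admissible profile (not all zero) on a tree
rand_profile <- function(tree, max_count = 3L) {
  tips <- tip_labels(tree)
  repeat {
    cnt <- sample(0:max_count, length(tips), replace = TRUE)
    if (any(cnt >= 1L)) break
  }
  names(cnt) <- tips
  cnt
}

# recomputed cost of an assignment over the edges of the family subtree,
# independent of the DP internals
assignment_cost <- function(tree, counts, origin, dup_w = 1, loss_w = 1) {
  m <- match(origin, tree$labels)
  pos <- tree$preorder_index[m]
  sub <- tree$preorder[pos:(pos + tree$subtree_size[m] - 1L)]
  kids <- setdiff(sub, m)
  if (!length(kids)) return(0)
  d <- counts[kids] - counts[tree$parent[kids]]
  sum(ifelse(d > 0, dup_w * d, -loss_w * d))
}
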