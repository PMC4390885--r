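#' @useDynLib dollotrace, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Parse a rooted phylogeny from newick text
#'
#' Builds an indexed tree from a newick string: parent/child pointers, a
#' fixed depth-first preorder of the ordered representation, subtree sizes,
#' and stable node identifiers. The tree is taken as rooted at the newick
#' outermost node; no rerooting is attempted (the reconstruction is
#' direction-dependent). Multifurcations are first-class. Branch lengths,
#' if present, are parsed and discarded: all downstream computations are
#' cladogram-based.
#'
#' Interior nodes without a name in the input receive deterministic
#' synthetic identifiers `N<preorder rank>`, so results are reproducible
#' across runs and annotated output can be re-read unambiguously.
#'
#' @param text a single newick string (terminating `;` optional).
#' @return an object of class `indexed_tree` with components
#'   `labels` (node id per node), `parent`, `children`, `root`, `is_leaf`,
#'   `preorder` (node indices in preorder), `preorder_index`, `postorder`,
#'   `subtree_size`, `n_tip`, `n_node`.
#' @examples
#' tr <- parse_newick("((A,B)N1,C)R;")
#' tr$labels[tr$root]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_paren_balance(text)
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed newick: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(phy)) stop("malformed newick: not a tree", call. = FALSE)
  index_tree(phy)
}

#' Read a rooted phylogeny from a newick file
#'
#' @param file path to a newick file (first tree is used).
#' @return an `indexed_tree`; see [parse_newick()].
#' @export
read_newick <- function(file) {
  txt <- paste(readLines(file, warn = FALSE), collapse = "")
  parse_newick(txt)
}

# report the offset of the first unbalanced parenthesis so malformed input
# fails with a position, which ape alone does not provide
check_paren_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unmatched ')' at offset ", i, call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("malformed newick: ", depth, " unclosed '(' at end of input",
         call. = FALSE)
  invisible(TRUE)
}

#' Index an ape phylogeny for traversal
#'
#' Converts an `ape::phylo` object into the indexed representation used
#' throughout the package. Child order is preserved as given; the preorder
#' is the DFS order of that ordered representation.
#'
#' @param phy an object of class `phylo` (rooted; multifurcations allowed).
#' @return an `indexed_tree`.
#' @export
index_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(phy$tip.label)))
    stop("empty leaf label", call. = FALSE)

  parent <- rep(NA_integer_, n_node)
  children <- vector("list", n_node)
  for (i in seq_len(nrow(phy$edge))) {
    v <- phy$edge[i, 1L]; u <- phy$edge[i, 2L]
    parent[u] <- v
    children[[v]] <- c(children[[v]], u)
  }
  root <- which(is.na(parent))
  if (length(root) != 1L)
    stop("tree must have exactly one root", call. = FALSE)
  is_leaf <- seq_len(n_node) <= n_tip

  # iterative DFS preorder, children visited in stored order
  preorder <- integer(n_node)
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    preorder[k] <- v
    kids <- children[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  preorder_index <- integer(n_node)
  preorder_index[preorder] <- seq_len(n_node)

  # postorder: children before parent, reverse-DFS trick
  post <- integer(n_node)
  stack <- root
  k <- n_node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    post[k] <- v
    k <- k - 1L
    kids <- children[[v]]
    if (length(kids)) stack <- c(stack, kids)
  }

  subtree_size <- rep(1L, n_node)
  for (v in post) {
    kids <- children[[v]]
    if (length(kids)) subtree_size[v] <- 1L + sum(subtree_size[kids])
  }

  labels <- character(n_node)
  labels[seq_len(n_tip)] <- phy$tip.label
  interior <- which(!is_leaf)
  if (!is.null(phy$node.label)) {
    labels[interior] <- phy$node.label
  }
  need <- interior[!nzchar(labels[interior])]
  labels[need] <- paste0("N", preorder_index[need])
  if (anyDuplicated(labels)) {
    dup <- unique(labels[duplicated(labels)])
    stop("node identifiers are not unique: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  structure(
    list(labels = labels, parent = parent, children = children,
         root = root, is_leaf = is_leaf,
         preorder = preorder, preorder_index = preorder_index,
         postorder = post, subtree_size = subtree_size,
         n_tip = n_tip, n_node = n_node,
         signature = paste(n_node, paste(labels[preorder], collapse = ","),
                           sep = "|")),
    class = "indexed_tree"
  )
}

#' @export
print.indexed_tree <- function(x, ...) {
  cat("indexed_tree:", x$n_tip, "leaves,", x$n_node - x$n_tip,
      "interior nodes, root =", x$labels[x$root], "\n")
  cat("leaves:", paste(utils::head(x$labels[x$is_leaf], 8), collapse = ", "),
      if (x$n_tip > 8) "..." else "", "\n")
  invisible(x)
}

#' Leaf labels of an indexed tree
#' @param tree an `indexed_tree`.
#' @return character vector of leaf labels in node-index order.
#' @export
tip_labels <- function(tree) tree$labels[tree$is_leaf]

node_index <- function(tree, labels) {
  idx <- match(labels, tree$labels)
  if (anyNA(idx))
    stop("unknown node label(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

# node indices of the subtree rooted at v: a contiguous preorder block
subtree_nodes <- function(tree, v) {
  pos <- tree$preorder_index[v]
  tree$preorder[pos:(pos + tree$subtree_size[v] - 1L)]
}

#' Serialize an indexed tree to newick, optionally with node annotations
#'
#' Writes the tree in a documented annotated-newick dialect: every node
#' carries its identifier, and annotated nodes are followed by a comment
#' block `[&key=value,key=value]`. Annotation keys are restricted to the
#' fixed vocabulary `count`, `gains`, `losses`. With an empty annotation
#' map the output is plain newick of the topology. `parse_annotated()`
#' recovers topology and annotations exactly.
#'
#' @param tree an `indexed_tree`.
#' @param annotations named list: node label -> named vector/list of
#'   key=value pairs, or `NULL` for plain newick.
#' @return a single newick string (with trailing `;`).
#' @examples
#' tr <- parse_newick("((A,B)N1,C)R;")
#' write_annotated(tr, list(A = c(count = 2), N1 = c(count = 1)))
#' @export
write_annotated <- function(tree, annotations = NULL) {
  ann <- character(tree$n_node)
  if (!is.null(annotations)) {
    if (is.null(names(annotations)) || any(!nzchar(names(annotations))))
      stop("annotations must be named by node label", call. = FALSE)
    idx <- match(names(annotations), tree$labels)
    if (anyNA(idx))
      stop("annotation for unknown node(s): ",
           paste(names(annotations)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    for (i in seq_along(annotations)) {
      kv <- annotations[[i]]
      if (length(kv) == 0L) next
      keys <- names(kv)
      bad <- setdiff(keys, c("count", "gains", "losses"))
      if (length(bad))
        stop("annotation key(s) outside vocabulary: ",
             paste(bad, collapse = ", "), call. = FALSE)
      ann[idx[i]] <- paste0("[&", paste0(keys, "=", unlist(kv),
                                         collapse = ","), "]")
    }
  }
  rec <- function(v) {
    kids <- tree$children[[v]]
    core <- if (length(kids))
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
             ")", tree$labels[v])
    else tree$labels[v]
    paste0(core, ann[v])
  }
  paste0(rec(tree$root), ";")
}

#' Parse annotated newick written by [write_annotated()]
#'
#' @param text annotated newick string.
#' @return list with `tree` (an `indexed_tree`) and `annotations`
#'   (named list: node label -> named character vector; empty list when
#'   the input carries no comments).
#' @export
parse_annotated <- function(text) {
  m <- gregexpr("([^(),;\\[\\]]+)\\[&([^\\]]*)\\]", text, perl = TRUE)
  ann <- list()
  hits <- regmatches(text, m)[[1]]
  for (h in hits) {
    lab <- sub("\\[.*$", "", h)
    body <- sub("^.*\\[&", "", sub("\\]$", "", h))
    pairs <- strsplit(body, ",", fixed = TRUE)[[1]]
    kv <- strsplit(pairs, "=", fixed = TRUE)
    vals <- vapply(kv, `[`, character(1), 2L)
    names(vals) <- vapply(kv, `[`, character(1), 1L)
    ann[[lab]] <- vals
  }
  plain <- gsub("\\[&[^\\]]*\\]", "", text)
  list(tree = parse_newick(plain), annotations = ann)
}

#' Drop species from a tree
#'
#' Removes the given leaves and collapses any resulting single-child
#' interior nodes, e.g. to exclude species without usable genome
#' assemblies from the analysis.
#'
#' @param tree an `indexed_tree`.
#' @param drop character vector of leaf labels to remove.
#' @return a re-indexed `indexed_tree`.
#' @export
prune_tree <- function(tree, drop) {
  keep <- setdiff(tip_labels(tree), drop)
  if (length(keep) < 2L)
    stop("pruning would leave fewer than two leaves", call. = FALSE)
  phy <- ape::read.tree(text = write_annotated(tree))
  phy2 <- ape::drop.tip(phy, setdiff(tip_labels(tree), keep),
                        collapse.singles = TRUE)
  index_tree(phy2)
}
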