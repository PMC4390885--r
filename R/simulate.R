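#' Simulate one family history with known ground truth
#'
#' Evolves a gene family down the tree under the same model the
#' reconstruction assumes: the family arises exactly once, as a single
#' copy at its origin node, and thereafter copies duplicate and are lost
#' independently along each edge of the subtree below the origin. On an
#' edge entered with `c` copies, the number of duplications is
#' `Binomial(c, p_dup)`; losses are then drawn `Binomial(c', p_loss)`
#' from the post-duplication count `c'` (duplications before losses, in
#' a fixed order, so replay is deterministic; within-edge event ordering
#' beyond that is not modelled). Histories in which the family drifts to
#' extinction in every species are redrawn, since all-zero profiles are
#' inadmissible; the number of redraws is reported.
#'
#' @param tree an `indexed_tree`.
#' @param origin node label where the family arises, or `"random"` to
#'   draw one uniformly over all nodes.
#' @param p_dup per-copy per-edge duplication probability, in [0, 1).
#' @param p_loss per-copy per-edge loss probability, in [0, 1).
#' @param family_id identifier for the simulated family.
#' @param seed optional integer; when given, the draw is a deterministic
#'   function of it.
#' @param max_tries redraw limit before giving up on a non-extinct
#'   history.
#' @return an object of class `simulated_family`: `family_id`,
#'   `true_origin`, `event_log` (data frame `parent`, `child`, `type`
#'   in dup/loss, `copies`), `leaf_counts` (a [count_profile()]),
#'   `node_counts` (true counts at every node), `seed`, `resamples`.
#' @export
evolve_family <- function(tree, origin = "random", p_dup = 0.05,
                          p_loss = 0.05, family_id = "sim", seed = NULL,
                          max_tries = 1000L) {
  stopifnot(p_dup >= 0, p_dup < 1, p_loss >= 0, p_loss < 1)
  if (!is.null(seed)) set.seed(seed)
  m <- if (identical(origin, "random"))
    sample.int(tree$n_node, 1L)
  else
    node_index(tree, origin)

  for (try in seq_len(max_tries)) {
    cnt <- integer(tree$n_node)
    cnt[m] <- 1L
    ev <- list()
    for (v in subtree_nodes(tree, m)) {
      if (v == m) next
      c0 <- cnt[tree$parent[v]]
      if (c0 == 0L) next
      ndup <- stats::rbinom(1L, c0, p_dup)
      c1 <- c0 + ndup
      nloss <- stats::rbinom(1L, c1, p_loss)
      cnt[v] <- c1 - nloss
      if (ndup > 0L)
        ev[[length(ev) + 1L]] <- data.frame(
          parent = tree$labels[tree$parent[v]], child = tree$labels[v],
          type = "dup", copies = ndup, stringsAsFactors = FALSE)
      if (nloss > 0L)
        ev[[length(ev) + 1L]] <- data.frame(
          parent = tree$labels[tree$parent[v]], child = tree$labels[v],
          type = "loss", copies = nloss, stringsAsFactors = FALSE)
    }
    leaf <- cnt[tree$is_leaf]
    names(leaf) <- tip_labels(tree)
    if (any(leaf >= 1L)) {
      log <- if (length(ev))
        do.call(rbind, c(ev, list(make.row.names = FALSE)))
      else
        data.frame(parent = character(0), child = character(0),
                   type = character(0), copies = integer(0))
      names(cnt) <- tree$labels
      return(structure(
        list(family_id = family_id, true_origin = tree$labels[m],
             event_log = log, leaf_counts = count_profile(leaf, family_id),
             node_counts = cnt, seed = seed, resamples = try - 1L),
        class = "simulated_family"))
    }
  }
  stop("family went extinct in every draw (", max_tries,
       " tries); lower p_loss or pick a deeper origin", call. = FALSE)
}

#' @export
print.simulated_family <- function(x, ...) {
  cat("simulated_family '", x$family_id, "': origin ", x$true_origin,
      ", ", nrow(x$event_log), " event(s), ",
      sum(x$leaf_counts), " leaf copies, ", x$resamples,
      " resample(s)\n", sep = "")
  invisible(x)
}

#' Replay an event log from the origin
#'
#' Recomputes node counts by starting one copy at the origin and
#' applying the logged per-edge duplications and losses top-down;
#' the result must match the counts the simulator reported.
#'
#' @param tree an `indexed_tree`.
#' @param origin origin node label.
#' @param event_log data frame as in [evolve_family()].
#' @return named integer vector of counts at every node.
#' @export
replay_events <- function(tree, origin, event_log) {
  m <- node_index(tree, origin)
  cnt <- integer(tree$n_node)
  cnt[m] <- 1L
  for (v in subtree_nodes(tree, m)) {
    if (v == m) next
    p <- tree$parent[v]
    c0 <- cnt[p]
    sel <- event_log$parent == tree$labels[p] &
      event_log$child == tree$labels[v]
    ndup <- sum(event_log$copies[sel & event_log$type == "dup"])
    nloss <- sum(event_log$copies[sel & event_log$type == "loss"])
    stopifnot(c0 + ndup - nloss >= 0L)
    cnt[v] <- c0 + ndup - nloss
  }
  names(cnt) <- tree$labels
  cnt
}

#' Simulate a batch of families
#'
#' Reproducible batch generation: a single seed fixes the whole batch
#' (per-family seeds are derived from it), and the leaf counts are
#' returned both as profiles and as the same families-by-species matrix
#' layout [read_count_matrix()] consumes.
#'
#' @param tree an `indexed_tree`.
#' @param n_families number of families to simulate.
#' @param origin passed to [evolve_family()].
#' @param p_dup,p_loss per-copy per-edge event probabilities.
#' @param seed integer seed for the whole batch.
#' @param prefix family id prefix.
#' @return list with `families` (list of `simulated_family`),
#'   `profiles` (list of [count_profile()]), and `matrix` (data frame,
#'   first column `family`).
#' @export
simulate_batch <- function(tree, n_families, origin = "random",
                           p_dup = 0.05, p_loss = 0.05, seed = 1L,
                           prefix = "fam") {
  set.seed(seed)
  seeds <- sample.int(2147483646L, max(n_families, 1L))
  fams <- lapply(seq_len(n_families), function(i)
    evolve_family(tree, origin = origin, p_dup = p_dup, p_loss = p_loss,
                  family_id = sprintf("%s%04d", prefix, i), seed = seeds[i]))
  profiles <- lapply(fams, `[[`, "leaf_counts")
  species <- tip_labels(tree)
  mat <- if (n_families > 0L)
    data.frame(family = vapply(fams, `[[`, character(1), "family_id"),
               t(vapply(profiles, function(p) p[species],
                        integer(length(species)))),
               check.names = FALSE, stringsAsFactors = FALSE)
  else
    stats::setNames(
      data.frame(matrix(integer(0), nrow = 0, ncol = length(species) + 1L)),
      c("family", species))
  if (n_families > 0L) colnames(mat)[-1L] <- species
  list(families = fams, profiles = profiles, matrix = mat)
}

#' Write a simulated batch to disk
#'
#' Emits the count matrix as TSV plus a JSON sidecar holding the ground
#' truth (origin, event log, seed) per family.
#'
#' @param batch result of [simulate_batch()].
#' @param counts_file TSV output path.
#' @param events_file JSON sidecar path (optional).
#' @export
write_batch <- function(batch, counts_file, events_file = NULL) {
  utils::write.table(batch$matrix, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(events_file)) {
    truth <- lapply(batch$families, function(f)
      list(family_id = f$family_id, true_origin = f$true_origin,
           seed = f$seed, resamples = f$resamples,
           events = f$event_log))
    jsonlite::write_json(truth, events_file, auto_unbox = TRUE,
                         dataframe = "rows", digits = NA)
  }
  invisible(counts_file)
}
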