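#' @importFrom jsonlite write_json read_json
NULL

write_manifest <- function(out_dir, mode, inputs, params, seed = NULL) {
  manifest <- list(
    tool = "dollotrace",
    version = as.character(utils::packageVersion("dollotrace")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = mode,
    inputs = inputs,
    parameters = params,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# run a mode body with cleanup: partial outputs are removed on failure
with_out_dir <- function(out_dir, body) {
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  before <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  tryCatch(body(), error = function(e) {
    after <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    unlink(setdiff(after, before))
    if (created && !length(before)) unlink(out_dir, recursive = TRUE)
    stop(e)
  })
}

as_tree <- function(tree) {
  if (inherits(tree, "indexed_tree")) tree else read_newick(tree)
}

#' Parsimony mode: reconstruct every family and write per-family output
#'
#' For each family, writes `families/<id>.tsv` (node, assigned count,
#' loss-edge flag) and `families/<id>.nwk` (count-annotated newick of
#' the tree), plus a `families.tsv` summary (origin, score, number of
#' co-optimal assignments, losses) and a machine-readable run manifest.
#'
#' @param tree an `indexed_tree` or path to a newick file.
#' @param counts list of [count_profile()]s, or path to a count-matrix
#'   TSV, or (with `fasta = TRUE`) character vector of per-family FASTA
#'   paths.
#' @param out_dir output directory (created if needed; partial outputs
#'   are removed on failure).
#' @param cost a [cost_model()].
#' @param exclude species labels excluded from all profiles.
#' @param fasta interpret `counts` as FASTA paths.
#' @param taxon_rule taxon-extraction rule for FASTA input.
#' @return (invisibly) the list of reconstructions.
#' @export
run_parsimony <- function(tree, counts, out_dir, cost = cost_model(),
                          exclude = NULL, fasta = FALSE,
                          taxon_rule = "^([^-]+)-") {
  tr <- as_tree(tree)
  profiles <- load_profiles(counts, tr, exclude, fasta, taxon_rule)
  with_out_dir(out_dir, function() {
    fam_dir <- file.path(out_dir, "families")
    dir.create(fam_dir, showWarnings = FALSE)
    recs <- reconstruct_families(tr, profiles, cost = cost)
    for (rec in recs) {
      write_family_tsv(tr, rec, file.path(fam_dir,
                                          paste0(rec$family_id, ".tsv")))
      ann <- lapply(rec$counts, function(k) c(count = k))
      writeLines(write_annotated(tr, ann),
                 file.path(fam_dir, paste0(rec$family_id, ".nwk")))
    }
    summary <- data.frame(
      family_id = vapply(recs, `[[`, character(1), "family_id"),
      origin_node = vapply(recs, `[[`, character(1), "origin"),
      at_root = vapply(recs, `[[`, logical(1), "origin_at_root"),
      total_score = vapply(recs, `[[`, numeric(1), "total_score"),
      n_optima = vapply(recs, `[[`, numeric(1), "n_optima"),
      n_loss_edges = vapply(recs, function(r) nrow(r$loss_edges),
                            integer(1)),
      n_present = vapply(recs, function(r) length(r$present_leaves),
                         integer(1)),
      stringsAsFactors = FALSE)
    utils::write.table(summary, file.path(out_dir, "families.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "parsimony",
                   inputs = list(tree = if (is.character(tree)) tree else
                     "in-memory", counts = if (is.character(counts))
                       counts else "in-memory"),
                   params = list(dup_weight = cost$dup_weight,
                                 loss_weight = cost$loss_weight,
                                 exclude = exclude))
    invisible(recs)
  })
}

load_profiles <- function(counts, tr, exclude, fasta, taxon_rule) {
  if (is.list(counts) && !is.data.frame(counts)) return(counts)
  if (isTRUE(fasta))
    profiles_from_fasta(counts, tree = tr, taxon_rule = taxon_rule,
                        exclude = exclude)
  else
    read_count_matrix(counts, tr, exclude = exclude)
}

write_family_tsv <- function(tree, rec, file) {
  ord <- tree$preorder
  loss_child <- if (nrow(rec$loss_edges)) rec$loss_edges[, "child"] else
    character(0)
  df <- data.frame(node = tree$labels[ord],
                   count = unname(rec$counts[ord]),
                   loss_edge = tree$labels[ord] %in% loss_child,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# rebuild the minimal reconstruction objects census needs from the text
# output of a parsimony run
read_parsimony_output <- function(tree, dir) {
  summary <- utils::read.table(file.path(dir, "families.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  sig <- tree_signature(tree)
  lapply(seq_len(nrow(summary)), function(i) {
    fam <- summary$family_id[i]
    tab <- utils::read.table(file.path(dir, "families", paste0(fam, ".tsv")),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    counts <- stats::setNames(as.integer(tab$count), tab$node)[tree$labels]
    loss_child <- tab$node[tab$loss_edge]
    loss_edges <- cbind(
      parent = tree$labels[tree$parent[match(loss_child, tree$labels)]],
      child = loss_child)
    structure(list(family_id = fam, origin = summary$origin_node[i],
                   origin_at_root = summary$at_root[i],
                   counts = counts,
                   total_score = summary$total_score[i],
                   n_optima = summary$n_optima[i],
                   loss_edges = loss_edges,
                   present_leaves = tab$node[tab$count >= 1 &
                                               tab$node %in%
                                               tip_labels(tree)],
                   tree_signature = sig),
              class = "dollo_reconstruction")
  })
}

#' Summarizing mode: per-branch census over a family set
#'
#' Aggregates parsimony reconstructions into the per-branch gain/loss
#' census and writes `census.tsv` plus a gains/losses-annotated newick
#' (`census.nwk`). Input is either the output directory of a previous
#' [run_parsimony()] call (`parsimony_dir`) or count input, in which
#' case the parsimony computation is run implicitly in memory; the two
#' routes give identical censuses.
#'
#' @inheritParams run_parsimony
#' @param parsimony_dir directory written by [run_parsimony()].
#' @return (invisibly) the census data frame.
#' @export
run_summarize <- function(tree, counts = NULL, out_dir,
                          parsimony_dir = NULL, cost = cost_model(),
                          exclude = NULL, fasta = FALSE,
                          taxon_rule = "^([^-]+)-") {
  tr <- as_tree(tree)
  recs <- if (!is.null(parsimony_dir))
    read_parsimony_output(tr, parsimony_dir)
  else {
    profiles <- load_profiles(counts, tr, exclude, fasta, taxon_rule)
    reconstruct_families(tr, profiles, cost = cost)
  }
  with_out_dir(out_dir, function() {
    census <- branch_census(tr, recs)
    write_census_tsv(census, file.path(out_dir, "census.tsv"))
    writeLines(write_annotated(tr, census_annotations(census)),
               file.path(out_dir, "census.nwk"))
    flux <- paralog_flux(tr, recs)
    utils::write.table(flux$flux, file.path(out_dir, "flux.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "summarize",
                   inputs = list(tree = if (is.character(tree)) tree else
                     "in-memory",
                     parsimony_dir = parsimony_dir %||% "implicit"),
                   params = list(dup_weight = cost$dup_weight,
                                 loss_weight = cost$loss_weight))
    invisible(census)
  })
}

#' Simulate mode: write a reproducible synthetic batch
#'
#' @inheritParams run_parsimony
#' @param n_families number of families.
#' @param p_dup,p_loss per-copy per-edge event probabilities.
#' @param seed batch seed (fixes the output byte-for-byte).
#' @param origin origin node or `"random"`.
#' @return (invisibly) the batch list.
#' @export
run_simulate <- function(tree, n_families, out_dir, p_dup = 0.05,
                         p_loss = 0.05, seed = 1L, origin = "random") {
  tr <- as_tree(tree)
  with_out_dir(out_dir, function() {
    batch <- simulate_batch(tr, n_families, origin = origin, p_dup = p_dup,
                            p_loss = p_loss, seed = seed)
    write_batch(batch, file.path(out_dir, "sim_counts.tsv"),
                file.path(out_dir, "sim_events.json"))
    write_manifest(out_dir, "simulate",
                   inputs = list(tree = if (is.character(tree)) tree else
                     "in-memory"),
                   params = list(n_families = n_families, p_dup = p_dup,
                                 p_loss = p_loss, origin = origin),
                   seed = seed)
    invisible(batch)
  })
}

#' Filter mode: curate homology hits into family counts
#'
#' Applies the hit filter (E-value, query coverage, mature containment)
#' and the family admission rules (zero recovery, per-species copy cap),
#' writing `accepted_hits.tsv`, `family_counts.tsv` (families x species,
#' the input of the parsimony mode) and `dropped_families.tsv`.
#'
#' Family membership of a hit is taken from its query identifier via
#' `family_rule`; the species holding a hit is resolved through
#' `subject_species` (named vector or two-column data frame mapping
#' subject sequence id to species label); unmapped subjects keep their
#' raw id as species.
#'
#' @param hits data frame (see [read_blast_hits()]) or path to a
#'   tabular hit file.
#' @param precursors named character vector / `XStringSet` of query
#'   precursor sequences, or FASTA path.
#' @param matures named character vector / `XStringSet` of mature
#'   sequences, or FASTA path.
#' @param out_dir output directory.
#' @param config a [filter_config()].
#' @param subject_species mapping subject id -> species label.
#' @param family_rule regular expression with one capture group
#'   extracting the family id from a query id (default: the part after
#'   the species prefix, without a trailing copy number).
#' @return (invisibly) list with `accepted`, `counts` (matrix),
#'   `admission`.
#' @export
run_filter <- function(hits, precursors, matures, out_dir,
                       config = filter_config(), subject_species = NULL,
                       family_rule = "^[^-]+-([A-Za-z]+-[A-Za-z0-9]+)") {
  if (is.character(hits)) hits <- read_blast_hits(hits)
  precursors <- load_seqs(precursors)
  matures <- load_seqs(matures)
  if (is.data.frame(subject_species))
    subject_species <- stats::setNames(as.character(subject_species[[2L]]),
                                       as.character(subject_species[[1L]]))
  with_out_dir(out_dir, function() {
    qlen <- stats::setNames(nchar(precursors), names(precursors))
    ivs <- match_matures(precursors, matures)
    has_iv <- !vapply(ivs, is.null, logical(1))
    acc <- filter_hits(hits, qlen, ivs[has_iv], config = config)

    fam <- extract_family(acc$qseqid, family_rule)
    sp <- acc$sseqid
    if (!is.null(subject_species)) {
      hit <- match(sp, names(subject_species))
      sp[!is.na(hit)] <- subject_species[hit[!is.na(hit)]]
    }
    counts <- if (nrow(acc)) as.matrix(table(fam, sp)) else
      matrix(integer(0), 0, 0)
    adm <- family_admission(
      stats::setNames(lapply(seq_len(nrow(counts)),
                             function(i) counts[i, ]),
                      rownames(counts)),
      config = config)

    utils::write.table(acc, file.path(out_dir, "accepted_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    kept <- adm$family_id[adm$keep]
    cnt_df <- data.frame(family = rownames(counts),
                         as.data.frame.matrix(counts),
                         check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(cnt_df[cnt_df$family %in% kept, , drop = FALSE],
                       file.path(out_dir, "family_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(adm[!adm$keep, , drop = FALSE],
                       file.path(out_dir, "dropped_families.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "filter", inputs = list(),
                   params = list(max_evalue = config$max_evalue,
                                 min_query_coverage =
                                   config$min_query_coverage,
                                 max_copies_per_species =
                                   config$max_copies_per_species))
    invisible(list(accepted = acc, counts = counts, admission = adm))
  })
}

load_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("Biostrings is required to read FASTA input", call. = FALSE)
    x <- Biostrings::readBStringSet(x)
  }
  stats::setNames(as.character(x), names(x))
}

extract_family <- function(ids, family_rule) {
  m <- regexec(family_rule, ids)
  fam <- vapply(regmatches(ids, m), function(g)
    if (length(g) >= 2L) g[2L] else NA_character_, character(1))
  fam[is.na(fam)] <- ids[is.na(fam)]
  fam
}

#' Dispatch a run configuration (single entry point)
#'
#' Thin dispatcher over the mode functions, used by the shipped
#' command-line script. `mode` selects the computation; remaining
#' arguments are passed through.
#'
#' @param mode one of `"parsimony"`, `"summarize"`, `"simulate"`,
#'   `"filter"`.
#' @param ... mode-specific arguments.
#' @return the mode function's value, invisibly.
#' @export
run_tool <- function(mode = c("parsimony", "summarize", "simulate",
                              "filter"), ...) {
  mode <- match.arg(mode)
  switch(mode,
         parsimony = run_parsimony(...),
         summarize = run_summarize(...),
         simulate = run_simulate(...),
         filter = run_filter(...))
}
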