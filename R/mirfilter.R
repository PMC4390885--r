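#' Curation thresholds for homology hits
#'
#' The filter that turns raw homology-search hits into accepted family
#' members: an E-value cap, a minimum fraction of the query precursor
#' that the hit must cover, and a per-species copy-number cap above
#' which a whole family is excluded (large copy numbers within a single
#' genome indicate repeat-derived pseudo-families).
#'
#' @param max_evalue maximum E-value (default `1e-10`).
#' @param min_query_coverage minimum fraction of the query length the
#'   hit must span, in (0, 1] (default 0.90).
#' @param max_copies_per_species families with strictly more copies than
#'   this in any single species are dropped (default 100).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(max_evalue = 1e-10, min_query_coverage = 0.90,
                          max_copies_per_species = 100L) {
  stopifnot(max_evalue >= 0,
            min_query_coverage > 0, min_query_coverage <= 1,
            max_copies_per_species >= 0)
  structure(list(max_evalue = max_evalue,
                 min_query_coverage = min_query_coverage,
                 max_copies_per_species = as.numeric(max_copies_per_species)),
            class = "filter_config")
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Standard 12-column tabular hit format: qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore.
#'
#' @param file path to the tabular file.
#' @return data frame with the standard column names.
#' @export
read_blast_hits <- function(file) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.table(file, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 12L)
    stop("expected >= 12 tab-separated columns (outfmt 6)", call. = FALSE)
  colnames(tab)[1:12] <- cols
  tab
}

#' Locate a mature sequence on its precursor
#'
#' Returns the 1-based inclusive interval of the leftmost exact
#' occurrence of the mature sequence within the precursor hairpin.
#' Sequences are compared case-insensitively with T and U identified,
#' so DNA- and RNA-alphabet inputs can be mixed.
#'
#' @param precursor precursor (hairpin) sequence, one string.
#' @param mature mature sequence, one string.
#' @return integer vector `c(start, end)`.
#' @examples
#' locate_mature("AAAUGCUGAAA", "UGCUGA")  # c(4, 9)
#' @export
locate_mature <- function(precursor, mature) {
  pre <- chartr("Tt", "Uu", toupper(precursor))
  mat <- chartr("Tt", "Uu", toupper(mature))
  hit <- regexpr(mat, pre, fixed = TRUE)
  if (hit == -1L)
    stop("mature sequence not found within precursor; ",
         "flag this precursor/mature pair for manual mapping", call. = FALSE)
  c(start = as.integer(hit), end = as.integer(hit) + nchar(mat) - 1L)
}

#' Filter homology hits by E-value, query coverage and mature containment
#'
#' A hit is accepted iff (i) its E-value does not exceed the cap,
#' (ii) the aligned query span `qend - qstart + 1` covers at least the
#' required fraction of the query precursor length, and (iii) the span
#' contains every annotated mature interval of the query (a valid
#' homolog must carry the mature product; precursors with both miR and
#' miR* annotated must span both). Acceptance depends only on the hit
#' and its query's metadata; all comparisons are inclusive, so hits
#' exactly at a threshold pass.
#'
#' @param hits data frame with at least `qseqid`, `qstart`, `qend`,
#'   `evalue` (see [read_blast_hits()]).
#' @param query_lengths named integer vector: query id -> precursor
#'   length.
#' @param mature_intervals named list: query id -> two-column matrix (or
#'   list of `c(start, end)` vectors) of mature intervals on the
#'   precursor.
#' @param config a [filter_config()].
#' @param keep_rejected if `TRUE`, return all hits with `accepted` and
#'   `reason` columns instead of the accepted subset.
#' @return data frame of accepted hits (default), or annotated hits.
#' @export
filter_hits <- function(hits, query_lengths, mature_intervals,
                        config = filter_config(), keep_rejected = FALSE) {
  need <- c("qseqid", "qstart", "qend", "evalue")
  if (!all(need %in% colnames(hits)))
    stop("hits must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(unique(hits$qseqid), names(query_lengths))
  if (length(unknown))
    stop("hit(s) reference unknown query: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  no_mat <- setdiff(unique(hits$qseqid), names(mature_intervals))
  if (length(no_mat))
    stop("query without mature interval(s): ",
         paste(no_mat, collapse = ", "), call. = FALSE)

  qlen <- query_lengths[hits$qseqid]
  span <- hits$qend - hits$qstart + 1L
  ok_e <- hits$evalue <= config$max_evalue
  ok_cov <- span >= config$min_query_coverage * qlen
  ok_mat <- vapply(seq_len(nrow(hits)), function(i) {
    iv <- mature_intervals[[hits$qseqid[i]]]
    if (is.list(iv)) iv <- do.call(rbind, iv)
    iv <- matrix(as.integer(iv), ncol = 2L)
    all(iv[, 1L] >= hits$qstart[i] & iv[, 2L] <= hits$qend[i])
  }, logical(1))

  accepted <- ok_e & ok_cov & ok_mat
  if (!keep_rejected) return(hits[accepted, , drop = FALSE])
  reason <- character(nrow(hits))
  reason[!ok_mat] <- "mature not contained"
  reason[!ok_cov] <- "query coverage below threshold"
  reason[!ok_e] <- "E-value above threshold"
  cbind(hits, accepted = accepted, reason = reason)
}

#' Decide whether a family enters the analysis
#'
#' A family is dropped if it was recovered in no species at all
#' (`not recovered`), or if any single species holds strictly more than
#' the copy cap (`copy cap`; the cap itself is still admissible).
#'
#' @param counts named list of per-species count vectors (one element
#'   per family), a list of [count_profile()]s, or a families-by-species
#'   integer matrix with family row names.
#' @param config a [filter_config()].
#' @return data frame with columns `family_id`, `keep`, `reason`,
#'   `max_copies`.
#' @export
family_admission <- function(counts, config = filter_config()) {
  if (is.matrix(counts)) {
    fam <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
    counts <- lapply(seq_len(nrow(counts)), function(i) counts[i, ])
    names(counts) <- fam
  }
  fam <- names(counts) %||% vapply(counts, function(p)
    attr(p, "family_id") %||% NA_character_, character(1))
  rows <- lapply(seq_along(counts), function(i) {
    v <- as.integer(counts[[i]])
    mx <- if (length(v)) max(v) else 0L
    if (sum(v) == 0L)
      data.frame(family_id = fam[i], keep = FALSE,
                 reason = "not recovered", max_copies = mx)
    else if (mx > config$max_copies_per_species)
      data.frame(family_id = fam[i], keep = FALSE,
                 reason = "copy cap", max_copies = mx)
    else
      data.frame(family_id = fam[i], keep = TRUE,
                 reason = "", max_copies = mx)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pair mature sequences with their precursors by name
#'
#' miRBase-style names differ between precursor and mature records in
#' case (`mir` vs `miR`) and in arm suffixes (`-5p`, `-3p`). This
#' helper normalises both sides (case-folded, arm suffix stripped) and
#' assigns each mature to every precursor whose normalised name equals,
#' or is the normalised mature name plus a trailing `-<number>` copy
#' suffix. Matures that match no precursor are reported.
#'
#' @param precursors named character vector (or `XStringSet`) of
#'   precursor sequences.
#' @param matures named character vector (or `XStringSet`) of mature
#'   sequences.
#' @return named list: precursor id -> two-column matrix of mature
#'   intervals located with [locate_mature()]; attribute `unmatched`
#'   lists mature ids with no precursor.
#' @export
match_matures <- function(precursors, matures) {
  pre_seq <- stats::setNames(as.character(precursors), names(precursors))
  mat_seq <- stats::setNames(as.character(matures), names(matures))
  norm <- function(x) sub("-(5p|3p)$", "", tolower(x))
  pre_norm <- norm(names(pre_seq))
  mat_norm <- norm(names(mat_seq))
  out <- stats::setNames(vector("list", length(pre_seq)), names(pre_seq))
  matched <- logical(length(mat_seq))
  for (i in seq_along(pre_seq)) {
    hit <- which(mat_norm == pre_norm[i] |
                   vapply(mat_norm, function(mn)
                     grepl(paste0("^", gsub("([.\\\\|()^$*+?{}\\[\\]])",
                                            "\\\\\\1", mn), "-[0-9]+$"),
                           pre_norm[i]), logical(1)))
    if (length(hit)) {
      matched[hit] <- TRUE
      ivs <- t(vapply(hit, function(j)
        locate_mature(pre_seq[i], mat_seq[j]), integer(2)))
      colnames(ivs) <- c("start", "end")
      out[[i]] <- ivs
    }
  }
  attr(out, "unmatched") <- names(mat_seq)[!matched]
  out
}
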