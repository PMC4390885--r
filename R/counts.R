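#' Construct a paralog count profile
#'
#' A count profile records, for one gene family, the number of paralogs
#' observed in each species (leaf of the companion tree). Species not
#' named in `counts` are implicitly absent (count 0). A family observed
#' nowhere is inadmissible and rejected.
#'
#' @param counts named vector of nonnegative integers; names are leaf
#'   (species) labels.
#' @param family_id identifier of the family.
#' @return a named integer vector of class `count_profile` with a
#'   `family_id` attribute.
#' @export
count_profile <- function(counts, family_id = "family") {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by species label", call. = FALSE)
  if (anyDuplicated(names(counts)))
    stop("duplicated species in profile", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (!any(counts >= 1))
    stop("family '", family_id, "' observed in no species", call. = FALSE)
  structure(as.integer(round(counts)), names = names(counts),
            family_id = family_id, class = "count_profile")
}

#' Count family members per species from sequence identifiers
#'
#' Builds a count profile by extracting a taxon token from each sequence
#' identifier and tallying records per taxon. Sequences themselves are
#' not inspected: one record is one gene copy. The default taxon rule is
#' the miRBase convention of a species prefix before the first `-`
#' (e.g. `hsa-mir-1-2` -> `hsa`); any regular expression with one capture
#' group may be supplied instead.
#'
#' @param ids character vector of sequence identifiers, or a named
#'   `Biostrings::XStringSet` (names are used).
#' @param tree optional `indexed_tree`; when given, taxon tokens are
#'   validated against the leaf labels and missing species filled with 0.
#' @param taxon_rule regular expression with one capture group yielding
#'   the taxon token.
#' @param family_id identifier of the family.
#' @param exclude species labels to drop from the profile (e.g. species
#'   whose genomes are unavailable and were removed from the analysis).
#' @return a [count_profile()].
#' @examples
#' counts_from_sequences(c("hsa-mir-1-1", "hsa-mir-1-2", "mmu-mir-1"))
#' @export
counts_from_sequences <- function(ids, tree = NULL,
                                  taxon_rule = "^([^-]+)-",
                                  family_id = "family",
                                  exclude = NULL) {
  if (!is.character(ids)) ids <- names(ids)
  if (length(ids) == 0L)
    stop("no records: family '", family_id,
         "' observed nowhere", call. = FALSE)
  m <- regexec(taxon_rule, ids)
  tok <- vapply(regmatches(ids, m), function(g)
    if (length(g) >= 2L) g[2L] else NA_character_, character(1))
  if (anyNA(tok))
    stop("no taxon token extractable from identifier(s): ",
         paste(ids[is.na(tok)], collapse = ", "), call. = FALSE)
  if (!is.null(exclude)) {
    keep <- !(tok %in% exclude)
    tok <- tok[keep]
    if (!length(tok))
      stop("family '", family_id,
           "' observed only in excluded species", call. = FALSE)
  }
  tab <- table(tok)
  cnt <- as.integer(tab)
  names(cnt) <- names(tab)
  if (!is.null(tree)) {
    tips <- tip_labels(tree)
    unmatched <- setdiff(names(cnt), tips)
    if (length(unmatched))
      stop("taxon token(s) not found among tree leaves: ",
           paste(unmatched, collapse = ", "), call. = FALSE)
    full <- integer(length(tips))
    names(full) <- tips
    full[names(cnt)] <- cnt
    cnt <- full
  }
  count_profile(cnt, family_id = family_id)
}

#' Build count profiles from per-family FASTA files
#'
#' One file per family (aligned or unaligned; gaps are irrelevant to
#' counting); the family id is the file base name. Requires the
#' Biostrings package.
#'
#' @param files paths to FASTA files.
#' @inheritParams counts_from_sequences
#' @return list of [count_profile()] objects.
#' @export
profiles_from_fasta <- function(files, tree = NULL,
                                taxon_rule = "^([^-]+)-", exclude = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to read FASTA input", call. = FALSE)
  out <- lapply(files, function(f) {
    seqs <- Biostrings::readBStringSet(f)
    fam <- sub("\\.(fa|fasta|fna|aln)$", "", basename(f))
    counts_from_sequences(names(seqs), tree = tree, taxon_rule = taxon_rule,
                          family_id = fam, exclude = exclude)
  })
  names(out) <- vapply(out, attr, character(1), "family_id")
  out
}

#' Read a families-by-species count matrix
#'
#' TSV format: one row per family, one column per species; the first
#' column (`family`) carries family identifiers and the header row the
#' species labels. Species present on the tree but absent from the table
#' get count 0 in every profile. All-zero rows are rejected.
#'
#' @param file path to the TSV, or a data frame in the same layout.
#' @param tree an `indexed_tree`; column labels are validated against
#'   its leaves.
#' @param exclude species labels to drop before validation.
#' @return list of [count_profile()] objects, named by family id.
#' @export
read_count_matrix <- function(file, tree, exclude = NULL) {
  tab <- if (is.data.frame(file)) file else
    utils::read.table(file, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("count matrix needs a family column and at least one species",
         call. = FALSE)
  fams <- as.character(tab[[1L]])
  species <- colnames(tab)[-1L]
  if (!is.null(exclude)) {
    keep <- !(species %in% exclude)
    tab <- tab[, c(TRUE, keep), drop = FALSE]
    species <- species[keep]
  }
  tips <- tip_labels(tree)
  off_tree <- setdiff(species, tips)
  if (length(off_tree))
    stop("column label(s) not on the tree: ",
         paste(off_tree, collapse = ", "), call. = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-integer cell at family '", fams[bad[1L, 1L]],
         "', species '", species[bad[1L, 2L]], "'", call. = FALSE)
  zero <- rowSums(mat) == 0
  if (any(zero))
    stop("all-zero family row(s): ",
         paste(fams[zero], collapse = ", "), call. = FALSE)
  missing_sp <- setdiff(tips, species)
  out <- lapply(seq_along(fams), function(i) {
    cnt <- c(as.integer(mat[i, ]),
             stats::setNames(integer(length(missing_sp)), missing_sp))
    names(cnt)[seq_along(species)] <- species
    count_profile(cnt, family_id = fams[i])
  })
  names(out) <- fams
  out
}

#' Write count profiles as a families-by-species TSV matrix
#'
#' Inverse of [read_count_matrix()] up to column order.
#'
#' @param profiles list of [count_profile()] objects.
#' @param file output path.
#' @param species column order; defaults to the union of profile species.
#' @export
write_count_matrix <- function(profiles, file, species = NULL) {
  if (is.null(species))
    species <- Reduce(union, lapply(profiles, names), character(0))
  if (length(profiles) == 0L) {
    df <- stats::setNames(
      data.frame(matrix(integer(0), nrow = 0, ncol = length(species) + 1L)),
      c("family", species))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(file))
  }
  mat <- t(vapply(profiles, function(p) {
    v <- stats::setNames(integer(length(species)), species)
    v[intersect(names(p), species)] <- p[intersect(names(p), species)]
    v
  }, integer(length(species))))
  df <- data.frame(family = vapply(profiles, attr, character(1), "family_id"),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a species exclusion list (one label per line)
#' @param file path; blank lines and `#` comments ignored.
#' @return character vector of species labels.
#' @export
read_species_exclusion <- function(file) {
  x <- trimws(readLines(file, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
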