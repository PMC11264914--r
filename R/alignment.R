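#' Alignment parameters
#'
#' Scoring and filtering parameters for semi-global alignment of amplicon
#' reads against type-strain genes. Terminal gaps on either sequence are
#' always free (zero cost), so a short read aligns within a full-length
#' gene without penalty for the unsequenced flanks. Defaults use
#' match +5 / mismatch -4 with a linear gap cost of 8 per gapped position.
#'
#' @param min_identity Candidate species must align with identity strictly
#'   greater than this fraction (default 0.90).
#' @param max_candidates Keep at most this many candidates per read
#'   (default all that pass).
#' @param match,mismatch,gap Alignment scores; `gap` is the (negative)
#'   score per internal gap position.
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(min_identity = 0.90, max_candidates = Inf,
                             match = 5, mismatch = -4, gap = -8) {
  stopifnot(min_identity > 0, min_identity <= 1, max_candidates >= 1,
            match > 0, mismatch < match, gap < 0)
  structure(list(min_identity = min_identity,
                 max_candidates = max_candidates,
                 match = match, mismatch = mismatch, gap = gap),
            class = "alignment_params")
}

.aln_cache <- new.env(parent = emptyenv())

# Substitution matrix over IUPAC codes: two codes score `match` when their
# base sets intersect (so degenerate reference or primer bases never count
# as mismatches), `mismatch` otherwise.
iupac_substitution_matrix <- function(match, mismatch) {
  key <- paste0("sm_", match, "_", mismatch)
  if (!is.null(.aln_cache[[key]])) return(.aln_cache[[key]])
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  m <- matrix(mismatch, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (i in seq_along(codes)) {
    for (j in seq_along(codes)) {
      if (length(intersect(sets[[i]], sets[[j]])) > 0L) m[i, j] <- match
    }
  }
  .aln_cache[[key]] <- m
  m
}

# 16x16 logical: do two alignment column characters (IUPAC or "-") match?
iupac_match_table <- function() {
  if (!is.null(.aln_cache$mt)) return(.aln_cache$mt)
  codes <- c(names(Biostrings::IUPAC_CODE_MAP), "-")
  sets <- c(strsplit(Biostrings::IUPAC_CODE_MAP, ""), list(character(0)))
  mt <- matrix(FALSE, 16L, 16L, dimnames = list(codes, codes))
  for (i in 1:16) {
    for (j in 1:16) {
      mt[i, j] <- length(intersect(sets[[i]], sets[[j]])) > 0L
    }
  }
  .aln_cache$mt <- mt
  mt
}

count_column_mismatches <- function(aln_query, aln_subject) {
  mt <- iupac_match_table()
  codes <- rownames(mt)
  qi <- match(strsplit(aln_query, "")[[1]], codes)
  si <- match(strsplit(aln_subject, "")[[1]], codes)
  sum(!mt[cbind(qi, si)])
}

# Align many reads against one reference record in a single
# pairwiseAlignment call; returns one pairwise_alignment per read.
align_batch <- function(reads, ref, params) {
  seqs <- vapply(reads, `[[`, "", "sequence")
  seqs <- normalize_sequence(seqs, what = "query reads")
  sseq <- normalize_sequence(ref$sequence, what = ref$accession)
  sm <- iupac_substitution_matrix(params$match, params$mismatch)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), Biostrings::DNAString(sseq),
    type = "overlap", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = -params$gap
  )
  aq <- as.character(Biostrings::alignedPattern(al))
  as_ <- as.character(Biostrings::alignedSubject(al))
  sstart <- Biostrings::start(Biostrings::subject(al))
  send <- Biostrings::end(Biostrings::subject(al))
  scores <- Biostrings::score(al)
  lapply(seq_along(reads), function(i) {
    n_columns <- nchar(aq[i])
    mismatches <- if (n_columns > 0L) {
      count_column_mismatches(aq[i], as_[i])
    } else 0L
    structure(
      list(read_id = reads[[i]]$read_id,
           accession = ref$accession,
           species_name = ref$species_name,
           n_columns = n_columns,
           mismatches = mismatches,
           identity = if (n_columns > 0L) {
             (n_columns - mismatches) / n_columns
           } else 0,
           score = scores[i],
           subject_start = sstart[i] - 1L,
           subject_end = send[i],
           subject_length = nchar(sseq),
           aligned_query = aq[i],
           aligned_subject = as_[i]),
      class = "pairwise_alignment"
    )
  })
}

#' Semi-global alignment of a read to a type strain
#'
#' Global alignment with zero-cost terminal gaps on both sequences
#' (vsearch-style semi-global alignment). The observed region size `n` is
#' the number of alignment columns excluding terminal gaps; the mismatch
#' count `x` includes substitution columns and internal gap columns.
#' Degenerate IUPAC codes match any base they denote.
#'
#' @param read A `query_read` (or list with `read_id`, `sequence`).
#' @param ref A `type_strain_record` (or list with `accession`,
#'   `species_name`, `sequence`).
#' @param params [alignment_params()].
#' @return A `pairwise_alignment`: read_id, accession, species_name,
#'   n_columns, mismatches, identity, score, subject_start / subject_end
#'   (0-based half-open on the full-length gene), subject_length, and the
#'   gapped alignment strings.
#' @export
semiglobal_align <- function(read, ref, params = alignment_params()) {
  align_batch(list(read), ref, params)[[1]]
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("%s vs %s (%s): %d mismatches / %d columns (%.2f%% id), subject [%d, %d) of %d\n",
              x$read_id, x$accession, x$species_name, x$mismatches,
              x$n_columns, 100 * x$identity, x$subject_start,
              x$subject_end, x$subject_length))
  invisible(x)
}

#' Search a database for candidate species
#'
#' Aligns a read against every record and keeps those with identity
#' strictly above `min_identity`, sorted by descending identity with ties
#' broken by ascending accession.
#'
#' @param read A `query_read`.
#' @param db A `ref_db`.
#' @param params [alignment_params()].
#' @return List of `pairwise_alignment` objects (possibly empty).
#' @export
search_candidates <- function(read, db, params = alignment_params()) {
  alns <- lapply(db$records, function(rec) semiglobal_align(read, rec, params))
  ident <- vapply(alns, `[[`, 0, "identity")
  keep <- ident > params$min_identity
  alns <- alns[keep]
  if (length(alns) == 0L) return(alns)
  acc <- vapply(alns, `[[`, "", "accession")
  ord <- order(-vapply(alns, `[[`, 0, "identity"), acc)
  alns <- alns[ord]
  if (is.finite(params$max_candidates)) {
    alns <- head(alns, params$max_candidates)
  }
  alns
}

#' Tabulate alignments
#'
#' @param alignments List of `pairwise_alignment` objects.
#' @return data.frame in BLAST-like tabular form (read_id, accession,
#'   species_name, identity_pct, n_columns, mismatches, subject_start,
#'   subject_end).
#' @export
alignments_to_df <- function(alignments) {
  data.frame(
    read_id = vapply(alignments, `[[`, "", "read_id"),
    accession = vapply(alignments, `[[`, "", "accession"),
    species_name = vapply(alignments, `[[`, "", "species_name"),
    identity_pct = 100 * vapply(alignments, `[[`, 0, "identity"),
    n_columns = vapply(alignments, function(a) as.integer(a$n_columns), 1L),
    mismatches = vapply(alignments, function(a) as.integer(a$mismatches), 1L),
    subject_start = vapply(alignments,
                           function(a) as.integer(a$subject_start), 1L),
    subject_end = vapply(alignments,
                         function(a) as.integer(a$subject_end), 1L),
    stringsAsFactors = FALSE
  )
}

#' Write alignments as TSV
#'
#' @param alignments List of `pairwise_alignment` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  write.table(alignments_to_df(alignments), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
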