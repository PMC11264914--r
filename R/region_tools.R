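#' A PCR primer pair
#'
#' The reverse primer is given as published, i.e. in reverse-complement
#' orientation relative to the gene; it is reverse-complemented internally
#' before searching the forward strand. Common 16S pairs: F27/R228
#' (V1-V2), F27/R534 (V1-V3), F515/R806 (V4).
#'
#' @param forward,reverse IUPAC nucleotide strings.
#' @param name Label, e.g. `"V1-V2"`.
#' @return A `primer_pair` list.
#' @export
primer_pair <- function(forward, reverse, name = "") {
  forward <- normalize_sequence(forward, what = "forward primer")
  reverse <- normalize_sequence(reverse, what = "reverse primer")
  stopifnot(nchar(forward) > 0, nchar(reverse) > 0)
  structure(list(forward = forward, reverse = reverse, name = name),
            class = "primer_pair")
}

#' Built-in 16S region primer pairs
#'
#' @return Named list of [primer_pair()] objects for the V1-V2 (F27/R228),
#'   V1-V3 (F27/R534) and V4 (F515/R806) regions.
#' @export
builtin_primer_pairs <- function() {
  list(
    "V1-V2" = primer_pair("AGAGTTTGATCCTGGCTCAG", "TGCTGCCTCCCGTAGGAGT",
                          "V1-V2"),
    "V1-V3" = primer_pair("AGAGTTTGATCCTGGCTCAG", "ATTACCGCGGCTGCTGG",
                          "V1-V3"),
    "V4" = primer_pair("GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT", "V4")
  )
}

#' Find the best ungapped primer match in a sequence
#'
#' Scans every ungapped offset, scoring a position by Hamming distance
#' with IUPAC-aware matching (intersecting base sets match). Returns the
#' leftmost offset achieving the minimum distance, provided that distance
#' does not exceed `max_mismatches`.
#'
#' @param sequence Target nucleotide string.
#' @param primer IUPAC primer string.
#' @param max_mismatches Maximum tolerated mismatches (default 1).
#' @return List with `start` (0-based offset of the match), `end`
#'   (half-open), and `mismatches`; or `NULL` if no offset qualifies
#'   (including when the primer is longer than the sequence).
#' @export
primer_match <- function(sequence, primer, max_mismatches = 1L) {
  stopifnot(max_mismatches >= 0)
  sequence <- normalize_sequence(sequence)
  primer <- normalize_sequence(primer, what = "primer")
  ls <- nchar(sequence)
  lp <- nchar(primer)
  if (lp > ls) return(NULL)
  mm <- Biostrings::neditStartingAt(
    Biostrings::DNAString(primer), Biostrings::DNAString(sequence),
    starting.at = seq_len(ls - lp + 1L), with.indels = FALSE, fixed = FALSE
  )
  best <- min(mm)
  if (best > max_mismatches) return(NULL)
  at <- which(mm == best)[1]
  list(start = at - 1L, end = at - 1L + lp, mismatches = as.integer(best))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract the amplified region between two primers
#'
#' Locates the forward primer and the reverse-complemented reverse primer
#' on the forward strand and returns the bases strictly between them
#' (primer bases excluded), mimicking primer trimming of full-length
#' type-strain genes into a variable region.
#'
#' @param sequence Full-length gene sequence.
#' @param pair A [primer_pair()].
#' @param max_mismatches Per-primer mismatch tolerance (default 1).
#' @return The insert subsequence, or `NULL` if either primer is not
#'   found or the reverse site does not lie downstream of the forward
#'   site.
#' @export
extract_region <- function(sequence, pair, max_mismatches = 1L) {
  stopifnot(inherits(pair, "primer_pair"))
  sequence <- normalize_sequence(sequence)
  fwd <- primer_match(sequence, pair$forward, max_mismatches)
  if (is.null(fwd)) return(NULL)
  rev <- primer_match(sequence, revcomp(pair$reverse), max_mismatches)
  if (is.null(rev)) return(NULL)
  if (rev$start < fwd$end) return(NULL)
  if (rev$start == fwd$end) return("")
  substr(sequence, fwd$end + 1L, rev$start)
}

#' Trim a database to a primer-delimited region
#'
#' @param db A `ref_db`.
#' @param pair A [primer_pair()].
#' @param max_mismatches Per-primer mismatch tolerance.
#' @return List with `db` (a `ref_db` of successfully trimmed records) and
#'   `skipped` (accessions where a primer site was not found).
#' @export
trim_database <- function(db, pair, max_mismatches = 1L) {
  kept <- list()
  skipped <- character(0)
  for (rec in db$records) {
    insert <- extract_region(rec$sequence, pair, max_mismatches)
    if (is.null(insert) || nchar(insert) == 0L) {
      skipped <- c(skipped, rec$accession)
    } else {
      kept[[length(kept) + 1L]] <- type_strain_record(
        rec$accession, rec$species_name, insert, rec$description)
    }
  }
  list(db = reference_db(kept), skipped = skipped)
}

#' Species indistinguishable within a sequenced region
#'
#' All-vs-all semi-global alignment of the database records (terminal
#' gaps free); a species pair is flagged when any record pair across the
#' two species aligns with at most `max_mismatches` differences. Species
#' with the same sequence in a short region cannot be separated by marker
#' gene sequencing of that region.
#'
#' @param db A `ref_db` of same-region trims or full-length genes.
#' @param max_mismatches Indistinguishability threshold (default 1,
#'   i.e. 0 or 1 mismatches).
#' @param params [alignment_params()] for the pairwise alignments.
#' @return List with `pairs` (data.frame: species_a, species_b,
#'   mismatches — the minimum over record pairs; species_a < species_b)
#'   and `species` (data.frame: species_name, indistinguishable — TRUE
#'   when the species has at least one flagged neighbor).
#' @export
indistinguishable_pairs <- function(db, max_mismatches = 1L,
                                    params = alignment_params()) {
  stopifnot(length(db) > 0L)
  nrec <- length(db)
  sp <- db_species(db)
  pair_min <- list()
  for (i in seq_len(nrec - 1L)) {
    for (j in (i + 1L):nrec) {
      if (sp[i] == sp[j]) next
      read_i <- query_read(db$records[[i]]$accession,
                           db$records[[i]]$sequence)
      al <- semiglobal_align(read_i, db$records[[j]], params)
      key <- paste(sort(c(sp[i], sp[j])), collapse = "\t")
      prev <- pair_min[[key]]
      if (is.null(prev) || al$mismatches < prev) {
        pair_min[[key]] <- al$mismatches
      }
    }
  }
  keys <- names(pair_min)
  mism <- unlist(pair_min, use.names = FALSE)
  flagged <- if (length(keys)) mism <= max_mismatches else logical(0)
  ab <- if (length(keys)) do.call(rbind, strsplit(keys, "\t")) else
    matrix(character(0), ncol = 2)
  pairs <- data.frame(species_a = ab[flagged, 1], species_b = ab[flagged, 2],
                      mismatches = as.integer(mism[flagged]),
                      stringsAsFactors = FALSE)
  species <- data.frame(species_name = sort(unique(sp)),
                        stringsAsFactors = FALSE)
  species$indistinguishable <- species$species_name %in%
    c(pairs$species_a, pairs$species_b)
  list(pairs = pairs, species = species)
}
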