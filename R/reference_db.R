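#' @importFrom stats optimize runif setNames
#' @importFrom utils head write.table read.delim
NULL

IUPAC_CODES <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                 "V", "H", "D", "B", "N")

#' Normalize a nucleotide sequence
#'
#' Uppercases, maps U to T, and validates that every character is an IUPAC
#' nucleotide code.
#'
#' @param seq Character vector of sequences.
#' @param what Label used in error messages (e.g. the record id).
#' @return Normalized character vector.
#' @keywords internal
normalize_sequence <- function(seq, what = "sequence") {
  seq <- chartr("u", "T", toupper(seq))
  seq <- chartr("U", "T", seq)
  bad <- grepl(paste0("[^", paste(IUPAC_CODES, collapse = ""), "]"), seq)
  if (any(bad)) {
    stop("non-IUPAC characters in ", what, ": ",
         paste(head(which(bad), 3L), collapse = ", "), call. = FALSE)
  }
  seq
}

#' Construct a type-strain record
#'
#' @param accession Unique identifier of the type-strain sequence.
#' @param species_name Binomial species name.
#' @param sequence Full-length 16S gene sequence (IUPAC codes allowed).
#' @param description Free-text header description (optional metadata).
#' @return A `type_strain_record` (a named list).
#' @export
type_strain_record <- function(accession, species_name, sequence,
                               description = species_name) {
  sequence <- normalize_sequence(sequence, what = accession)
  if (nchar(sequence) == 0L) {
    stop("empty sequence for record ", accession, call. = FALSE)
  }
  structure(
    list(accession = as.character(accession),
         species_name = as.character(species_name),
         sequence = sequence,
         description = as.character(description)),
    class = "type_strain_record"
  )
}

#' Construct a query read
#'
#' @param read_id Read identifier.
#' @param sequence Nucleotide sequence.
#' @return A `query_read` (a named list).
#' @export
query_read <- function(read_id, sequence) {
  sequence <- normalize_sequence(sequence, what = read_id)
  if (nchar(sequence) == 0L) {
    stop("empty sequence for read ", read_id, call. = FALSE)
  }
  structure(list(read_id = as.character(read_id), sequence = sequence),
            class = "query_read")
}

#' Construct a type-strain reference database
#'
#' A reference database holds one record per type-strain sequence. Several
#' records may carry the same species name (multiple deposited type-strain
#' genes); they are kept separate, never merged.
#'
#' @param records List of [type_strain_record()] objects.
#' @return A `ref_db` object.
#' @export
reference_db <- function(records = list()) {
  acc <- vapply(records, `[[`, "", "accession")
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  structure(list(records = records), class = "ref_db")
}

#' @export
length.ref_db <- function(x) length(x$records)

#' @export
print.ref_db <- function(x, ...) {
  cat("Type-strain reference database:", length(x), "record(s),",
      length(unique(db_species(x))), "species\n")
  invisible(x)
}

#' Species names of all records, in record order
#' @param db A `ref_db`.
#' @return Character vector, one name per record.
#' @export
db_species <- function(db) {
  vapply(db$records, `[[`, "", "species_name")
}

#' Accessions of all records, in record order
#' @param db A `ref_db`.
#' @return Character vector.
#' @export
db_accessions <- function(db) {
  vapply(db$records, `[[`, "", "accession")
}

#' Index records by species name
#'
#' @param db A `ref_db`.
#' @return Named list mapping each species name to the integer indices of
#'   its records.
#' @export
species_index <- function(db) {
  split(seq_along(db$records), db_species(db))
}

read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(character(0))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  setNames(as.character(set), names(set))
}

#' Read a type-strain database from FASTA
#'
#' Headers are expected to carry an accession (first whitespace-delimited
#' token) followed by a description. Under the `"ltp"` dialect the binomial
#' species name is the first two tokens of the description (the convention
#' of the Living Tree Project releases); under `"plain"` the whole
#' description is the species name.
#'
#' @param path FASTA file.
#' @param header_dialect `"ltp"` or `"plain"`.
#' @return A `ref_db`. An empty file yields an empty database.
#' @export
read_type_strain_fasta <- function(path, header_dialect = c("ltp", "plain")) {
  header_dialect <- match.arg(header_dialect)
  seqs <- read_fasta_raw(path)
  records <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    tokens <- strsplit(trimws(header), "\\s+")[[1]]
    accession <- tokens[1]
    desc <- if (length(tokens) > 1L) paste(tokens[-1], collapse = " ") else ""
    species <- if (header_dialect == "ltp") {
      dtok <- strsplit(desc, "\\s+")[[1]]
      if (length(dtok) >= 2L) paste(dtok[1:2], collapse = " ") else desc
    } else {
      desc
    }
    if (nchar(seqs[[i]]) == 0L) {
      stop("empty sequence for record ", accession, " in ", path,
           call. = FALSE)
    }
    records[[i]] <- type_strain_record(accession, species, seqs[[i]],
                                       description = desc)
  }
  reference_db(records)
}

#' Write a type-strain database to FASTA
#'
#' Headers are written as `>accession species_name`; a subsequent
#' [read_type_strain_fasta()] round-trips accession, species name and
#' sequence exactly.
#'
#' @param db A `ref_db`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_type_strain_fasta <- function(db, path) {
  lines <- unlist(lapply(db$records, function(r) {
    c(paste0(">", r$accession, " ", r$species_name), r$sequence)
  }))
  writeLines(as.character(lines), path)
  invisible(path)
}

#' Read query reads from FASTA
#'
#' @param path FASTA file of amplicon reads or ASVs.
#' @return List of `query_read` objects, in file order. Read ids are the
#'   first whitespace-delimited header token and must be unique.
#' @export
read_query_fasta <- function(path) {
  seqs <- read_fasta_raw(path)
  ids <- vapply(names(seqs),
                function(h) strsplit(trimws(h), "\\s+")[[1]][1], "")
  if (anyDuplicated(ids)) {
    stop("duplicate read id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for read ", ids[which(nchar(seqs) == 0L)[1]],
         call. = FALSE)
  }
  unname(Map(query_read, ids, seqs))
}

#' Write query reads to FASTA
#'
#' @param reads List of `query_read` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_query_fasta <- function(reads, path) {
  lines <- unlist(lapply(reads, function(r) {
    c(paste0(">", r$read_id), r$sequence)
  }))
  writeLines(as.character(lines), path)
  invisible(path)
}
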