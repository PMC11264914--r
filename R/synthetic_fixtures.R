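#' Simulation configuration for synthetic fixtures
#'
#' Bundles the parameters of the synthetic type-strain database, amplicon
#' reads, and per-position mismatch-rate profiles. Defaults describe a
#' desk-scale study: 10 species whose full-length genes (1500 nt, the
#' canonical 16S length) diverge from a common ancestor by 10% per site,
#' sequenced over a 322 nt window resembling the V1-V2 region, with a
#' within-species per-site mismatch rate of 0.002 inside the window and
#' 0.001 outside.
#'
#' @param n_species Number of species (>= 1).
#' @param gene_length Full gene length L in nt.
#' @param between_species_divergence Per-site substitution probability used
#'   to derive each non-ancestral species from the ancestral gene.
#' @param region_start,region_end 0-based half-open coordinates of the
#'   simulated amplicon on the gene.
#' @param inside_rate Per-site mismatch probability applied to reads within
#'   the amplified region (sequencing error plus within-species divergence).
#' @param outside_rate Per-site mismatch rate outside the region, used only
#'   for rate-profile fixtures.
#' @param n_reads Number of reads to simulate.
#' @param seed Integer seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_species = 10L, gene_length = 1500L,
                              between_species_divergence = 0.10,
                              region_start = 100L, region_end = 422L,
                              inside_rate = 0.002, outside_rate = 0.001,
                              n_reads = 100L, seed = 1L) {
  stopifnot(n_species >= 1L, gene_length >= 1L,
            between_species_divergence >= 0, between_species_divergence <= 1,
            inside_rate >= 0, inside_rate <= 1,
            outside_rate >= 0, outside_rate <= 1,
            region_start >= 0L, region_start < region_end,
            region_end <= gene_length, n_reads >= 0L)
  structure(list(n_species = as.integer(n_species),
                 gene_length = as.integer(gene_length),
                 between_species_divergence = between_species_divergence,
                 region_start = as.integer(region_start),
                 region_end = as.integer(region_end),
                 inside_rate = inside_rate, outside_rate = outside_rate,
                 n_reads = as.integer(n_reads), seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

BASES <- c("A", "C", "G", "T")

mutate_sites <- function(chars, idx) {
  # each substituted site draws uniformly from the three other bases
  if (length(idx) == 0L) return(chars)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  old <- match(chars[idx], BASES)
  chars[idx] <- BASES[((old - 1L + shift) %% 4L) + 1L]
  chars
}

#' Simulate a type-strain reference database
#'
#' Species 1 is a uniform-random gene of length `gene_length`; every other
#' species substitutes each site of that ancestor independently with
#' probability `between_species_divergence`, the replacement base drawn
#' uniformly from the three alternatives.
#'
#' @param config A [simulation_config()].
#' @return A `ref_db` with accessions `SYN0001, ...` and species names
#'   `Simulibacter sp001, ...`. Deterministic under `config$seed`.
#' @export
simulate_database <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- config$gene_length
    ancestor <- sample(BASES, L, replace = TRUE)
    records <- vector("list", config$n_species)
    for (i in seq_len(config$n_species)) {
      chars <- ancestor
      if (i > 1L) {
        idx <- which(runif(L) < config$between_species_divergence)
        chars <- mutate_sites(chars, idx)
      }
      records[[i]] <- type_strain_record(
        accession = sprintf("SYN%04d", i),
        species_name = sprintf("Simulibacter sp%03d", i),
        sequence = paste(chars, collapse = "")
      )
    }
    reference_db(records)
  })
}

#' Simulate amplicon reads with known ground truth
#'
#' Each read is the `[region_start, region_end)` slice of a uniformly
#' chosen database record, with independent per-site substitutions at
#' `inside_rate`. The truth table records the exact number of introduced
#' mismatches per read.
#'
#' @param db A `ref_db`, typically from [simulate_database()].
#' @param config A [simulation_config()]; reads use `config$seed + 1` so
#'   that database and reads are independently reproducible.
#' @return List with `reads` (list of `query_read`) and `truth`
#'   (data.frame: read_id, accession, species_name, mismatches).
#' @export
simulate_reads <- function(db, config) {
  stopifnot(inherits(db, "ref_db"), inherits(config, "sim_config"))
  if (config$region_end > config$gene_length) {
    stop("region does not fit in gene_length", call. = FALSE)
  }
  with_seed(config$seed + 1L, {
    n <- config$n_reads
    src <- sample.int(length(db), n, replace = TRUE)
    reads <- vector("list", n)
    mism <- integer(n)
    for (i in seq_len(n)) {
      rec <- db$records[[src[i]]]
      slice <- substr(rec$sequence, config$region_start + 1L,
                      config$region_end)
      chars <- strsplit(slice, "")[[1]]
      idx <- which(runif(length(chars)) < config$inside_rate)
      mutated <- mutate_sites(chars, idx)
      mism[i] <- sum(mutated != chars)
      reads[[i]] <- query_read(sprintf("read%05d", i),
                               paste(mutated, collapse = ""))
    }
    truth <- data.frame(
      read_id = vapply(reads, `[[`, "", "read_id"),
      accession = db_accessions(db)[src],
      species_name = db_species(db)[src],
      mismatches = mism,
      stringsAsFactors = FALSE
    )
    list(reads = reads, truth = truth)
  })
}

#' Simulate a per-position mismatch-rate profile
#'
#' A step profile: `inside_rate` on `[region_start, region_end)` and
#' `outside_rate` elsewhere. Used to exercise the variable-mismatch-rate
#' algorithm with a known inside/outside rate ratio.
#'
#' @param gene_length Gene length L.
#' @param inside_rate,outside_rate Per-position mismatch probabilities.
#' @param region_start,region_end 0-based half-open region coordinates.
#' @return A `rate_profile`: numeric vector of length `gene_length`.
#' @export
simulate_rate_profile <- function(gene_length, inside_rate, outside_rate,
                                  region_start, region_end) {
  stopifnot(inside_rate >= 0, inside_rate <= 1,
            outside_rate >= 0, outside_rate <= 1,
            region_start >= 0, region_start < region_end,
            region_end <= gene_length)
  rates <- rep(outside_rate, gene_length)
  rates[(region_start + 1L):region_end] <- inside_rate
  structure(rates, class = "rate_profile")
}

#' Write a simulated truth table to TSV
#'
#' @param truth Truth data.frame from [simulate_reads()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
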