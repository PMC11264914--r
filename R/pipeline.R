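#' Compute species rule-out probabilities for a set of reads
#'
#' The full pipeline: for each read, search the database for candidate
#' species aligning above the identity floor, extrapolate each candidate's
#' observed mismatches to the full-length gene, and convert the resulting
#' total-mismatch distribution into a rule-out probability under the
#' configured criterion. A read with no candidate species yields a single
#' sentinel row with empty species fields and probability 1.0.
#'
#' With `rate_mode = "variable"`, `rate_profiles` must supply a
#' per-position mismatch-rate profile (named by accession) for each
#' candidate; candidates lacking a profile fall back to the constant-rate
#' algorithm with a warning.
#'
#' @param reads List of `query_read` objects.
#' @param db A `ref_db`.
#' @param config [ruleout_config()].
#' @param params [alignment_params()].
#' @param rate_profiles Optional named list of `rate_profile` vectors.
#' @return data.frame with one row per (read, candidate species):
#'   read_id, species_name, accession, observed_mismatches,
#'   observed_columns, subject_length, observed_identity,
#'   ruleout_probability, compatible, threshold_mode, rate_mode. Rows for
#'   one read are sorted by ascending probability, ties by species name.
#' @export
unassign <- function(reads, db, config = ruleout_config(),
                     params = alignment_params(), rate_profiles = NULL) {
  if (inherits(reads, "query_read")) reads <- list(reads)
  if (config$rate_mode == "variable" && is.null(rate_profiles)) {
    warning("rate_mode = 'variable' but no rate_profiles supplied; ",
            "all candidates fall back to constant rate")
  }
  # align all reads against each record in one vectorized call, then
  # regroup per read and apply the candidate filter/sort of
  # search_candidates
  by_record <- lapply(db$records, function(rec) align_batch(reads, rec, params))
  per_read <- lapply(seq_along(reads), function(ri) {
    read <- reads[[ri]]
    alns <- lapply(by_record, `[[`, ri)
    ident <- vapply(alns, `[[`, 0, "identity")
    cands <- alns[ident > params$min_identity]
    if (length(cands) > 0L) {
      acc <- vapply(cands, `[[`, "", "accession")
      ord <- order(-vapply(cands, `[[`, 0, "identity"), acc)
      cands <- cands[ord]
      if (is.finite(params$max_candidates)) {
        cands <- head(cands, params$max_candidates)
      }
    }
    if (length(cands) == 0L) {
      return(data.frame(
        read_id = read$read_id, species_name = "", accession = "",
        observed_mismatches = NA_integer_, observed_columns = NA_integer_,
        subject_length = NA_integer_, observed_identity = NA_real_,
        ruleout_probability = 1.0, compatible = FALSE,
        threshold_mode = config$threshold_mode,
        rate_mode = config$rate_mode, stringsAsFactors = FALSE))
    }
    rows <- lapply(cands, function(al) {
      posterior <- posterior_from_observation(al$mismatches, al$n_columns)
      rate_mode_used <- "constant"
      if (config$rate_mode == "variable") {
        prof <- rate_profiles[[al$accession]]
        if (is.null(prof)) {
          warning("no rate profile for ", al$accession,
                  "; using constant rate for this candidate")
        } else {
          rho <- rate_log_ratio(prof, al$subject_start, al$subject_end)
          posterior <- adjust_posterior(posterior, rho$ratio)
          rate_mode_used <- "variable"
        }
      }
      dist <- total_mismatch_distribution(al$mismatches, al$n_columns,
                                          al$subject_length,
                                          posterior = posterior)
      p <- ruleout_probability(dist, config)
      data.frame(
        read_id = al$read_id, species_name = al$species_name,
        accession = al$accession,
        observed_mismatches = as.integer(al$mismatches),
        observed_columns = as.integer(al$n_columns),
        subject_length = as.integer(al$subject_length),
        observed_identity = al$identity,
        ruleout_probability = p,
        compatible = p < config$compatibility_cutoff,
        threshold_mode = config$threshold_mode,
        rate_mode = rate_mode_used, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[order(out$ruleout_probability, out$species_name), , drop = FALSE]
  })
  res <- do.call(rbind, per_read)
  rownames(res) <- NULL
  res
}

#' Best species call for one read
#'
#' Among the rows of one read, selects the compatible species with the
#' lowest rule-out probability (ties broken by lexicographically smallest
#' species name), or none if no species is compatible.
#'
#' @param rows data.frame of [unassign()] rows belonging to a single read.
#' @param cutoff Compatibility cutoff on the rule-out probability.
#' @return One-row data.frame (read_id, species_name, accession,
#'   ruleout_probability); species fields are `NA` when every species is
#'   ruled out.
#' @export
best_species_call <- function(rows, cutoff = 0.5) {
  stopifnot(length(unique(rows$read_id)) == 1L)
  ok <- rows[!is.na(rows$observed_identity) &
             rows$ruleout_probability < cutoff, , drop = FALSE]
  if (nrow(ok) == 0L) {
    return(data.frame(read_id = rows$read_id[1],
                      species_name = NA_character_,
                      accession = NA_character_,
                      ruleout_probability = NA_real_,
                      stringsAsFactors = FALSE))
  }
  ok <- ok[order(ok$ruleout_probability, ok$species_name), , drop = FALSE]
  data.frame(read_id = ok$read_id[1], species_name = ok$species_name[1],
             accession = ok$accession[1],
             ruleout_probability = ok$ruleout_probability[1],
             stringsAsFactors = FALSE)
}

#' Best species calls for all reads
#'
#' @param results Full [unassign()] output.
#' @param cutoff Compatibility cutoff.
#' @return data.frame with one row per read, in first-appearance order.
#' @export
best_species_calls <- function(results, cutoff = 0.5) {
  ids <- unique(results$read_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    best_species_call(results[results$read_id == id, , drop = FALSE], cutoff)
  }))
  rownames(out) <- NULL
  out
}

format_prob <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.6g", p))
}

#' Write the full rule-out table to TSV
#'
#' Probabilities are printed with 6 significant digits; ordering is the
#' deterministic ordering of [unassign()].
#'
#' @param rows [unassign()] output.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(rows, path) {
  out <- rows
  out$observed_identity <- format_prob(out$observed_identity)
  out$ruleout_probability <- format_prob(out$ruleout_probability)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-read best species calls to TSV
#'
#' @param calls [best_species_calls()] output.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls
  out$ruleout_probability <- format_prob(out$ruleout_probability)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
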