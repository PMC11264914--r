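#' Posterior mismatch-rate distribution from an observed alignment
#'
#' Under a Jeffreys Beta(0.5, 0.5) prior on the per-position mismatch
#' rate, observing `x` mismatches in `n` aligned columns gives the
#' posterior Beta(x + 0.5, n - x + 0.5). For the worked two-species
#' example, (2, 322) gives (2.5, 320.5) and (83, 322) gives (83.5, 239.5).
#'
#' @param x Observed mismatch count.
#' @param n Observed alignment columns.
#' @return A `mismatch_posterior` with fields `alpha`, `beta`.
#' @export
posterior_from_observation <- function(x, n) {
  stopifnot(length(x) == 1L, length(n) == 1L)
  if (x < 0 || n < 0 || x > n) {
    stop("require 0 <= x <= n; got x = ", x, ", n = ", n, call. = FALSE)
  }
  structure(list(alpha = x + 0.5, beta = n - x + 0.5),
            class = "mismatch_posterior")
}

#' Beta-binomial probability mass function
#'
#' P(K = k) for K mismatches among m unobserved positions when the
#' mismatch rate is Beta(alpha, beta) distributed:
#' C(m,k) B(k + alpha, m - k + beta) / B(alpha, beta), evaluated in log
#' space for numerical stability.
#'
#' @param k Mismatch count(s), each in 0..m (vectorized).
#' @param m Number of unobserved positions.
#' @param posterior A `mismatch_posterior`.
#' @return Probability vector, same length as `k`.
#' @export
beta_binomial_pmf <- function(k, m, posterior) {
  stopifnot(inherits(posterior, "mismatch_posterior"), m >= 0)
  if (any(k < 0 | k > m)) {
    stop("k must lie in [0, m]", call. = FALSE)
  }
  a <- posterior$alpha
  b <- posterior$beta
  exp(lchoose(m, k) + lbeta(k + a, m - k + b) - lbeta(a, b))
}

#' Distribution of total full-gene mismatches
#'
#' Extrapolates the observed (x, n) alignment to a full-length gene of
#' length L: the remaining m = L - n positions carry K additional
#' mismatches with K beta-binomially distributed under the posterior from
#' [posterior_from_observation()], so the total mismatch count is x + K.
#'
#' @param x Observed mismatches.
#' @param n Observed alignment columns (n <= L).
#' @param L Full gene length.
#' @param posterior Optional `mismatch_posterior` overriding the default
#'   Jeffreys update, e.g. the adjusted posterior of the
#'   variable-mismatch-rate algorithm.
#' @return A `total_mismatch_distribution` with fields `x`, `n`, `L`, `m`
#'   and `prob` (vector over k = 0..m; sums to 1).
#' @export
total_mismatch_distribution <- function(x, n, L, posterior = NULL) {
  if (n > L) stop("observed columns n exceed gene length L", call. = FALSE)
  if (is.null(posterior)) posterior <- posterior_from_observation(x, n)
  m <- L - n
  prob <- beta_binomial_pmf(0:m, m, posterior)
  structure(list(x = x, n = n, L = L, m = m,
                 posterior = posterior, prob = prob),
            class = "total_mismatch_distribution")
}

#' @export
print.total_mismatch_distribution <- function(x, ...) {
  cat(sprintf("Total-mismatch distribution: x = %d observed in n = %d, m = %d unobserved of L = %d; E[total] = %.2f\n",
              x$x, x$n, x$m, x$L, x$x + sum((0:x$m) * x$prob)))
  invisible(x)
}

#' Estimate per-position mismatch rates for one type strain
#'
#' Given semi-global alignments of full-length variant sequences (e.g.
#' database sequences of related strains) against a single type strain,
#' estimates the mismatch rate at each subject position as a
#' pseudocount-regularized frequency, (mismatching + 0.5) / (covering + 1).
#' Positions never covered by any alignment receive the mean rate of the
#' covered positions.
#'
#' @param alignments List of `pairwise_alignment` objects, all against the
#'   same subject accession.
#' @return A `rate_profile`: numeric vector of length `subject_length`,
#'   with the accession as attribute.
#' @export
estimate_position_rates <- function(alignments) {
  if (length(alignments) == 0L) {
    stop("at least one alignment is required", call. = FALSE)
  }
  accs <- unique(vapply(alignments, `[[`, "", "accession"))
  if (length(accs) != 1L) {
    stop("all alignments must share one subject; got: ",
         paste(accs, collapse = ", "), call. = FALSE)
  }
  L <- alignments[[1]]$subject_length
  cover <- numeric(L)
  mism <- numeric(L)
  mt <- iupac_match_table()
  codes <- rownames(mt)
  for (al in alignments) {
    q <- strsplit(al$aligned_query, "")[[1]]
    s <- strsplit(al$aligned_subject, "")[[1]]
    on_subject <- s != "-"
    pos <- al$subject_start + cumsum(on_subject)  # 1-based subject position
    qi <- match(q, codes)
    si <- match(s, codes)
    col_mismatch <- !mt[cbind(qi, si)]
    idx <- pos[on_subject]
    cover[idx] <- cover[idx] + 1
    mm <- idx[col_mismatch[on_subject]]
    if (length(mm)) {
      tab <- tabulate(mm, nbins = L)
      mism <- mism + tab
    }
  }
  rates <- (mism + 0.5) / (cover + 1)
  covered <- cover > 0
  if (any(!covered)) {
    if (!any(covered)) stop("no covered positions", call. = FALSE)
    rates[!covered] <- mean(rates[covered])
  }
  structure(rates, class = "rate_profile",
            accession = alignments[[1]]$accession)
}

#' Inside/outside mismatch-rate ratio for a gene region
#'
#' The variable-mismatch-rate statistic: the log ratio of the mean
#' mismatch rate outside the aligned region to the mean rate inside it.
#' A ratio above 1 means the unobserved remainder of the gene is more
#' variable than the sequenced window, so the constant-rate extrapolation
#' would understate full-gene mismatches.
#'
#' @param profile A `rate_profile` (length L).
#' @param region_start,region_end 0-based half-open region on the gene;
#'   must leave at least one position outside.
#' @return List with `log_ratio` and `ratio` (= exp(log_ratio)).
#' @export
rate_log_ratio <- function(profile, region_start, region_end) {
  L <- length(profile)
  stopifnot(region_start >= 0, region_start < region_end, region_end <= L)
  inside <- rep(FALSE, L)
  inside[(region_start + 1L):region_end] <- TRUE
  if (all(inside)) {
    stop("region covers the entire gene; no outside positions",
         call. = FALSE)
  }
  mean_in <- mean(profile[inside])
  mean_out <- mean(profile[!inside])
  if (mean_in <= 0) {
    stop("mean mismatch rate inside the region is zero", call. = FALSE)
  }
  lr <- log(mean_out) - log(mean_in)
  list(log_ratio = lr, ratio = exp(lr))
}

#' Adjust a mismatch posterior by a rate ratio
#'
#' Rescales the posterior mean by `ratio` while preserving the total
#' concentration alpha + beta, clamping the mean just below 1. With
#' `ratio = 1` the posterior is unchanged, recovering the
#' constant-mismatch-rate algorithm exactly.
#'
#' @param posterior A `mismatch_posterior`.
#' @param ratio Positive rate ratio (outside / inside), e.g. from
#'   [rate_log_ratio()].
#' @return Adjusted `mismatch_posterior`.
#' @export
adjust_posterior <- function(posterior, ratio) {
  stopifnot(inherits(posterior, "mismatch_posterior"))
  if (ratio <= 0) stop("ratio must be positive", call. = FALSE)
  eps <- 1e-6
  total <- posterior$alpha + posterior$beta
  alpha2 <- min(ratio * posterior$alpha, total - eps)
  structure(list(alpha = alpha2, beta = total - alpha2),
            class = "mismatch_posterior")
}

#' Read per-type-strain rate profiles from a sidecar TSV
#'
#' @param path TSV with columns `accession`, `position` (0-based), `rate`.
#' @return Named list of `rate_profile` vectors, one per accession;
#'   positions must form a complete 0..(L-1) range per accession.
#' @export
read_rate_profiles <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("accession", "position", "rate")
  if (!all(req %in% names(tab))) {
    stop("rate-profile TSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(tab, tab$accession), function(d) {
    d <- d[order(d$position), ]
    if (!identical(d$position, 0:(nrow(d) - 1L)) &&
        !identical(as.integer(d$position), 0:(nrow(d) - 1L))) {
      stop("positions for ", d$accession[1],
           " must cover 0..L-1 exactly", call. = FALSE)
    }
    if (any(d$rate < 0 | d$rate > 1)) {
      stop("rates must lie in [0, 1]", call. = FALSE)
    }
    structure(d$rate, class = "rate_profile", accession = d$accession[1])
  })
  out
}

#' Write rate profiles to a sidecar TSV
#'
#' @param profiles Named list of `rate_profile` vectors (names are
#'   accessions).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rate_profiles <- function(profiles, path) {
  tabs <- lapply(names(profiles), function(acc) {
    data.frame(accession = acc,
               position = seq_along(profiles[[acc]]) - 1L,
               rate = as.numeric(profiles[[acc]]),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
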