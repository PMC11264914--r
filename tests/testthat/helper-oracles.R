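# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and Biostrings) so that agreement is evidence,
# not tautology.

# Ends-free (semi-global) alignment score by exhaustive dynamic
# programming with linear gap costs: terminal gaps on either sequence are
# free, internal gaps cost `gap` per position.
oracle_semiglobal_score <- function(a, b, match = 5, mismatch = -4,
                                    gap = -8) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  H <- matrix(-Inf, n + 1, m + 1)
  H[1, ] <- 0  # free leading gaps
  H[, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      H[i + 1, j + 1] <- max(H[i, j] + s,
                             H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
    }
  }
  max(H[n + 1, ], H[, m + 1])  # free trailing gaps
}

# Per-site mismatch count of two equal-length ungapped sequences.
oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

# Beta-binomial pmf by the telescoping product
# P(k) = C(m,k) * prod_{i<k}(a+i) * prod_{i<m-k}(b+i) / prod_{i<m}(a+b+i),
# written without lbeta/lchoose cancellation tricks.
oracle_bb_pmf <- function(k, m, a, b) {
  num <- c(if (k > 0) a + 0:(k - 1), if (m - k > 0) b + 0:(m - k - 1))
  den <- a + b + 0:(m - 1)
  if (m == 0) return(1)
  exp(lchoose(m, k) + sum(log(num)) - sum(log(den)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Plant exactly k substitutions at distinct interior positions.
plant_substitutions <- function(seq, k, positions = NULL) {
  chars <- strsplit(seq, "")[[1]]
  if (is.null(positions)) {
    positions <- sample(seq_along(chars), k)
  }
  for (p in positions) {
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[sample.int(3, 1)]
  }
  paste(chars, collapse = "")
}

small_fixture_db <- function(n_species = 3, divergence = 0.2, seed = 42,
                             gene_length = 600) {
  cfg <- simulation_config(n_species = n_species, gene_length = gene_length,
                           between_species_divergence = divergence,
                           region_start = 50, region_end = 250,
                           inside_rate = 0, n_reads = 0, seed = seed)
  list(config = cfg, db = simulate_database(cfg))
}
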