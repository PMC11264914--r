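#' Rule-out configuration
#'
#' @param threshold_identity Hard-threshold gene identity below which a
#'   species is ruled out (default 0.975, the conventional criterion for
#'   separating bacterial species by 16S similarity).
#' @param soft_half_max Identity at which the soft species-probability
#'   curve reaches one half (default 0.991, the half-maximum of the
#'   exponential fit of species-level ANI probability against 16S
#'   identity).
#' @param threshold_mode `"hard"` or `"soft"`.
#' @param rate_mode `"constant"` or `"variable"` mismatch-rate
#'   extrapolation.
#' @param compatibility_cutoff A read is called compatible with a species
#'   when its rule-out probability is below this cutoff (default 0.5).
#' @return A `ruleout_config` list.
#' @export
ruleout_config <- function(threshold_identity = 0.975,
                           soft_half_max = 0.991,
                           threshold_mode = c("hard", "soft"),
                           rate_mode = c("constant", "variable"),
                           compatibility_cutoff = 0.5) {
  threshold_mode <- match.arg(threshold_mode)
  rate_mode <- match.arg(rate_mode)
  stopifnot(threshold_identity > 0, threshold_identity < 1,
            soft_half_max > 0, soft_half_max < 1,
            compatibility_cutoff >= 0, compatibility_cutoff <= 1)
  structure(list(threshold_identity = threshold_identity,
                 soft_half_max = soft_half_max,
                 threshold_mode = threshold_mode,
                 rate_mode = rate_mode,
                 compatibility_cutoff = compatibility_cutoff),
            class = "ruleout_config")
}

#' Hard-threshold rule-out probability
#'
#' Probability that the total full-gene mismatch count exceeds the
#' mismatch budget (1 - threshold_identity) * L, i.e. that full-gene
#' identity falls strictly below the threshold. The bound is kept
#' real-valued (no rounding) and the inequality is strict, so a total
#' landing exactly on the budget is not ruled out. Computed as one minus
#' the (typically small) probability of the compatible outcomes, so a
#' rule-out of 1.0 is returned exactly when no outcome is compatible.
#'
#' @param dist A `total_mismatch_distribution`.
#' @param threshold_identity Identity threshold in (0, 1).
#' @return Probability in [0, 1].
#' @export
hard_ruleout_probability <- function(dist, threshold_identity = 0.975) {
  stopifnot(inherits(dist, "total_mismatch_distribution"),
            threshold_identity > 0, threshold_identity < 1)
  budget <- (1 - threshold_identity) * dist$L
  kmax <- floor(budget - dist$x)   # largest k with x + k <= budget
  if (kmax < 0) return(1.0)
  if (kmax >= dist$m) return(0.0)
  p_keep <- sum(dist$prob[1:(kmax + 1L)])
  min(max(1 - p_keep, 0), 1)
}

#' Probability of species-level genome identity given 16S identity
#'
#' The soft species criterion: an exponential curve in 16S gene identity
#' d, f(d) = 2^(-(1 - d) / (1 - d_half)), equal to 1 at d = 1 and to 1/2
#' at d = d_half. It approximates the empirical probability that two
#' genomes with 16S identity d are the same species by average nucleotide
#' identity.
#'
#' @param d 16S gene identity (vectorized), typically in [0, 1].
#' @param d_half Identity at half-maximum (default 0.991).
#' @return Probability vector.
#' @export
species_probability_curve <- function(d, d_half = 0.991) {
  if (d_half >= 1) stop("d_half must be < 1", call. = FALSE)
  2^(-(1 - d) / (1 - d_half))
}

#' Soft-threshold rule-out probability
#'
#' One minus the expected species probability under the total-mismatch
#' distribution: 1 - sum_k P(K = k) f((L - x - k) / L), with f the
#' [species_probability_curve()]. Integrates the soft criterion over the
#' full posterior of full-gene identity rather than evaluating it at a
#' point estimate.
#'
#' @param dist A `total_mismatch_distribution`.
#' @param d_half Identity at half-maximum for the soft curve.
#' @return Probability in [0, 1].
#' @export
soft_ruleout_probability <- function(dist, d_half = 0.991) {
  stopifnot(inherits(dist, "total_mismatch_distribution"))
  k <- 0:dist$m
  identity <- (dist$L - dist$x - k) / dist$L
  p_species <- sum(dist$prob * species_probability_curve(identity, d_half))
  min(max(1 - p_species, 0), 1)
}

#' Fit the soft-curve half-maximum from labeled identity data
#'
#' Maximum-likelihood fit of the Bernoulli model
#' P(same species | d) = 2^(-(1 - d) / (1 - d_half)) over d_half, by
#' one-dimensional optimization of the log likelihood.
#'
#' @param identity Numeric vector of 16S identities in [0, 1].
#' @param same_species Logical (or 0/1) vector of labels.
#' @return Fitted `d_half` in (0, 1).
#' @export
fit_half_max <- function(identity, same_species) {
  same_species <- as.logical(same_species)
  stopifnot(length(identity) == length(same_species),
            all(identity >= 0 & identity <= 1))
  if (length(unique(identity)) < 2L) {
    stop("need at least two distinct identity values", call. = FALSE)
  }
  if (all(same_species) || !any(same_species)) {
    stop("labels are degenerate (all identical)", call. = FALSE)
  }
  eps <- 1e-12
  negll <- function(h) {  # h = 1 - d_half
    p <- pmin(pmax(2^(-(1 - identity) / h), eps), 1 - eps)
    -sum(ifelse(same_species, log(p), log1p(-p)))
  }
  fit <- optimize(negll, interval = c(1e-6, 0.5))
  1 - fit$minimum
}

#' Rule-out probability under a configuration
#'
#' Dispatches to the hard or soft criterion named in `config`.
#'
#' @param dist A `total_mismatch_distribution`.
#' @param config A [ruleout_config()].
#' @return Probability in [0, 1].
#' @export
ruleout_probability <- function(dist, config = ruleout_config()) {
  switch(config$threshold_mode,
         hard = hard_ruleout_probability(dist, config$threshold_identity),
         soft = soft_ruleout_probability(dist, config$soft_half_max))
}
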