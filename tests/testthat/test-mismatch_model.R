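test_that("the Jeffreys update reproduces the worked posteriors", {
  p <- posterior_from_observation(2, 322)
  expect_equal(p$alpha, 2.5)
  expect_equal(p$beta, 320.5)
  p2 <- posterior_from_observation(83, 322)
  expect_equal(p2$alpha, 83.5)
  expect_equal(p2$beta, 239.5)
  p0 <- posterior_from_observation(0, 0)
  expect_equal(c(p0$alpha, p0$beta), c(0.5, 0.5))
  expect_error(posterior_from_observation(5, 4), "0 <= x <= n")
})

test_that("beta-binomial pmf matches the telescoping-product oracle", {
  p <- posterior_from_observation(2, 322)
  expect_equal(beta_binomial_pmf(0, 3, p),
               (320.5 * 321.5 * 322.5) / (323 * 324 * 325))
  set.seed(17)
  for (i in 1:20) {
    m <- sample(0:40, 1)
    a <- runif(1, 0.2, 50)
    b <- runif(1, 0.2, 400)
    post <- structure(list(alpha = a, beta = b),
                      class = "mismatch_posterior")
    k <- if (m > 0) sample(0:m, 1) else 0
    expect_equal(beta_binomial_pmf(k, m, post), oracle_bb_pmf(k, m, a, b),
                 tolerance = 1e-12)
  }
})

test_that("pmf is normalized, symmetric for alpha = beta, and guarded", {
  set.seed(23)
  for (i in 1:15) {
    m <- sample(1:300, 1)
    post <- structure(list(alpha = runif(1, 0.3, 20),
                           beta = runif(1, 0.3, 300)),
                      class = "mismatch_posterior")
    expect_equal(sum(beta_binomial_pmf(0:m, m, post)), 1,
                 tolerance = 1e-9)
  }
  sym <- structure(list(alpha = 3.5, beta = 3.5),
                   class = "mismatch_posterior")
  expect_equal(beta_binomial_pmf(0:10, 10, sym),
               rev(beta_binomial_pmf(0:10, 10, sym)))
  expect_equal(beta_binomial_pmf(0, 0, sym), 1)
  expect_error(beta_binomial_pmf(5, 4, sym), "k must lie")
})

test_that("the total-mismatch distribution has the analytic mean and edge cases", {
  d <- total_mismatch_distribution(2, 322, 1500)
  expect_equal(d$m, 1178)
  expect_equal(sum(d$prob), 1, tolerance = 1e-9)
  expect_equal(sum((0:d$m) * d$prob), 1178 * 2.5 / 323, tolerance = 1e-9)
  # fully observed gene: point mass at zero extra mismatches
  d2 <- total_mismatch_distribution(3, 400, 400)
  expect_equal(d2$prob, 1)
  # one unobserved position: closed form 0.5/323
  d3 <- total_mismatch_distribution(0, 322, 323)
  expect_equal(d3$prob[2], 0.5 / 323)
  expect_error(total_mismatch_distribution(0, 500, 400), "exceed")
})

test_that("total-mismatch distribution matches Monte-Carlo sampling", {
  set.seed(29)
  m <- 40
  d <- total_mismatch_distribution(2, 322, 322 + m)
  nsim <- 2e5
  theta <- rbeta(nsim, 2.5, 320.5)
  k <- rbinom(nsim, m, theta)
  emp <- tabulate(k + 1L, nbins = m + 1) / nsim
  se <- sqrt(d$prob * (1 - d$prob) / nsim)
  expect_true(all(abs(emp - d$prob) <= 4 * se + 1e-12))
})

test_that("total mismatches are stochastically increasing in x", {
  survivals <- function(x) {
    d <- total_mismatch_distribution(x, 322, 700)
    rev(cumsum(rev(d$prob)))  # P(K >= k)
  }
  s0 <- survivals(0); s5 <- survivals(5); s20 <- survivals(20)
  expect_true(all(s5 - s0 >= -1e-12))
  expect_true(all(s20 - s5 >= -1e-12))
})

test_that("posterior mean recovers the simulated mismatch rate", {
  cfg <- simulation_config(n_species = 1, gene_length = 500,
                           region_start = 100, region_end = 422,
                           inside_rate = 0.01, n_reads = 1000, seed = 37)
  db <- simulate_database(cfg)
  sim <- simulate_reads(db, cfg)
  # the pseudocount shrinks the posterior mean toward 1/2, so its
  # expectation is (n r + 0.5)/(n + 1), not r itself
  post_means <- (sim$truth$mismatches + 0.5) / (322 + 1)
  se <- sqrt(0.01 * 0.99 / 322 / 1000)
  expect_lt(abs(mean(post_means) - (322 * 0.01 + 0.5) / 323), 3 * se)
  expect_lt(abs(mean(sim$truth$mismatches / 322) - 0.01), 3 * se)
})

test_that("per-position rates use +0.5/+1 regularization", {
  ref <- type_strain_record("S1", "Testus exemplaris", random_dna(200))
  identical10 <- lapply(1:10, function(i) {
    semiglobal_align(query_read(paste0("v", i), ref$sequence), ref)
  })
  prof <- estimate_position_rates(identical10)
  expect_length(prof, 200)
  expect_true(all(abs(prof - 0.5 / 11) < 1e-12))
  # a single sequence mismatching everywhere gives (1 + 0.5)/(1 + 1);
  # free end gaps would refuse such an alignment, so construct it directly
  all_mm <- structure(list(
    read_id = "v", accession = "S1", species_name = "Testus exemplaris",
    n_columns = 200L, mismatches = 200L, identity = 0, score = 0,
    subject_start = 0L, subject_end = 200L, subject_length = 200L,
    aligned_query = chartr("ACGT", "GTAC", ref$sequence),
    aligned_subject = ref$sequence), class = "pairwise_alignment")
  prof2 <- estimate_position_rates(list(all_mm))
  expect_true(all(prof2 == 0.75))
  expect_error(estimate_position_rates(list()), "at least one")
})

test_that("estimated rates recover a simulated inside rate", {
  set.seed(41)
  ref <- type_strain_record("S1", "Testus exemplaris", random_dna(400))
  n_var <- 60
  rate <- 0.02
  variants <- lapply(1:n_var, function(i) {
    chars <- strsplit(ref$sequence, "")[[1]]
    idx <- which(runif(400) < rate)
    for (p in idx) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    semiglobal_align(query_read(paste0("v", i),
                                paste(chars, collapse = "")), ref)
  })
  prof <- estimate_position_rates(variants)
  se <- sqrt(rate * (1 - rate) / n_var / 400) * 20  # mean over positions
  expect_lt(abs(mean(prof) - rate), 3 * se + 0.5 / (n_var + 1))
})

test_that("rate log-ratio recovers analytic inside/outside ratios", {
  uni <- simulate_rate_profile(1000, 0.02, 0.02, 100, 400)
  r <- rate_log_ratio(uni, 100, 400)
  expect_equal(r$log_ratio, 0)
  expect_equal(r$ratio, 1)
  r2 <- rate_log_ratio(simulate_rate_profile(1000, 0.01, 0.02, 100, 400),
                       100, 400)
  expect_equal(r2$ratio, 2)
  r3 <- rate_log_ratio(simulate_rate_profile(1000, 0.02, 0.01, 100, 400),
                       100, 400)
  expect_equal(r3$ratio, 0.5)
  expect_error(rate_log_ratio(uni, 0, 1000), "entire gene")
  zero <- structure(rep(0, 100), class = "rate_profile")
  expect_error(rate_log_ratio(zero, 10, 50), "zero")
})

test_that("posterior adjustment scales the mean and preserves concentration", {
  p <- posterior_from_observation(2, 322)
  same <- adjust_posterior(p, 1)
  expect_equal(same$alpha, p$alpha)
  expect_equal(same$beta, p$beta)
  doubled <- adjust_posterior(p, 2)
  expect_equal(doubled$alpha, 5.0)
  expect_equal(doubled$beta, 318.0)
  expect_equal(doubled$alpha + doubled$beta, 323)
  huge <- adjust_posterior(p, 1e9)
  expect_lt(huge$alpha / (huge$alpha + huge$beta), 1)
  expect_gt(huge$alpha / (huge$alpha + huge$beta), 1 - 1e-5)
  expect_error(adjust_posterior(p, 0), "positive")
})

test_that("rate-profile TSV sidecars round-trip", {
  profs <- list(ACC1 = simulate_rate_profile(50, 0.01, 0.02, 10, 30),
                ACC2 = simulate_rate_profile(40, 0.05, 0.01, 5, 20))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_rate_profiles(profs, tsv)
  back <- read_rate_profiles(tsv)
  expect_equal(as.numeric(back$ACC1), as.numeric(profs$ACC1))
  expect_equal(as.numeric(back$ACC2), as.numeric(profs$ACC2))
})
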