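test_that("hard rule-out is exactly 1 when observed mismatches bust the budget", {
  for (x in c(82, 83)) {
    d <- total_mismatch_distribution(x, 322, 1500)
    expect_identical(hard_ruleout_probability(d, 0.975), 1.0)
  }
  # any gene length where x alone exceeds (1 - theta) * L
  d2 <- total_mismatch_distribution(82, 322, 3200)
  expect_identical(hard_ruleout_probability(d2, 0.975), 1.0)
})

test_that("a fully observed gene gives an exact 0/1 indicator", {
  under <- total_mismatch_distribution(30, 1500, 1500)
  expect_identical(hard_ruleout_probability(under, 0.975), 0.0)
  over <- total_mismatch_distribution(38, 1500, 1500)
  expect_identical(hard_ruleout_probability(over, 0.975), 1.0)
  # a total landing exactly on the real-valued budget is not ruled out
  boundary <- total_mismatch_distribution(25, 1000, 1000)
  expect_identical(hard_ruleout_probability(boundary, 0.975), 0.0)
})

test_that("the worked low-mismatch example lands near 0.003 and matches an independent sum", {
  d <- total_mismatch_distribution(2, 322, 1500)
  p <- hard_ruleout_probability(d, 0.975)
  expect_gt(p, 0.001)
  expect_lt(p, 0.01)
  # independent oracle: telescoping-product pmf summed over the ruled-out
  # totals x + k > 37.5, i.e. k >= 36
  oracle <- sum(vapply(36:1178, oracle_bb_pmf, 0, m = 1178,
                       a = 2.5, b = 320.5))
  expect_equal(p, oracle, tolerance = 1e-9)
  # modest sensitivity to the assumed gene length
  for (L in c(1450, 1550)) {
    pL <- hard_ruleout_probability(
      total_mismatch_distribution(2, 322, L), 0.975)
    expect_gt(pL, 0.001); expect_lt(pL, 0.01)
  }
})

test_that("hard rule-out is monotone in x and in the threshold direction", {
  ps <- vapply(0:40, function(x) {
    hard_ruleout_probability(total_mismatch_distribution(x, 322, 1500))
  }, 0)
  expect_true(all(diff(ps) >= -1e-12))
  d <- total_mismatch_distribution(5, 322, 1500)
  thetas <- c(0.95, 0.975, 0.99)
  pt <- vapply(thetas, function(t) hard_ruleout_probability(d, t), 0)
  expect_true(all(diff(pt) >= -1e-12))  # stricter threshold, higher rule-out
})

test_that("the soft species curve passes through its anchor points", {
  expect_equal(species_probability_curve(1.0), 1.0)
  expect_equal(species_probability_curve(0.991, 0.991), 0.5)
  expect_equal(species_probability_curve(0.982, 0.991), 0.25)
  d <- seq(0.9, 1, by = 0.001)
  expect_true(all(diff(species_probability_curve(d)) > 0))
  expect_error(species_probability_curve(0.99, d_half = 1), "d_half")
})

test_that("soft rule-out handles point masses by construction", {
  # x = 0 over a fully observed gene: identity 1, rule-out 0
  d0 <- total_mismatch_distribution(0, 1000, 1000)
  expect_equal(soft_ruleout_probability(d0), 0)
  # identity exactly at the half-max point: rule-out one half
  dh <- total_mismatch_distribution(9, 1000, 1000)
  expect_equal(soft_ruleout_probability(dh, d_half = 0.991), 0.5)
})

test_that("soft rule-out integrates the curve over the mismatch distribution", {
  d <- total_mismatch_distribution(2, 322, 1500)
  p <- soft_ruleout_probability(d, 0.991)
  set.seed(47)
  nsim <- 2e5
  theta <- rbeta(nsim, 2.5, 320.5)
  k <- rbinom(nsim, d$m, theta)
  mc <- 1 - mean(2^(-(1 - (1500 - 2 - k) / 1500) / (1 - 0.991)))
  expect_equal(p, mc, tolerance = 0.005)
  # monotone in x
  ps <- vapply(0:30, function(x) {
    soft_ruleout_probability(total_mismatch_distribution(x, 322, 1500))
  }, 0)
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("hard rule-out is the sharp-curve limit of the soft rule-out", {
  # a curve whose half-max hugs the hard threshold from above behaves
  # like the step indicator at 97.5% identity
  sharp <- 1 - 1e-6
  for (x in c(10, 25, 45)) {
    d <- total_mismatch_distribution(x, 800, 1500)
    hard <- hard_ruleout_probability(d, 0.975)
    # evaluate the step directly: curve ~ 0 below threshold, ~1 above
    k <- 0:d$m
    identity <- (d$L - d$x - k) / d$L
    step <- sum(d$prob * as.numeric(identity < 0.975))
    expect_equal(hard, step, tolerance = 1e-9)
  }
})

test_that("fit_half_max recovers the generating half-maximum", {
  set.seed(53)
  n <- 5000
  d <- runif(n, 0.95, 1.0)
  p <- 2^(-(1 - d) / (1 - 0.991))
  lab <- runif(n) < p
  fit <- fit_half_max(d, lab)
  expect_lt(abs(fit - 0.991), 0.002)
})

test_that("fit_half_max contracts: separable data, shuffled labels, degenerate input", {
  d <- c(rep(1, 50), rep(0.9, 50))
  lab <- c(rep(TRUE, 50), rep(FALSE, 50))
  fit <- fit_half_max(d, lab)
  expect_true(fit > 0 && fit < 1)
  set.seed(59)
  shuffled <- sample(lab)
  fit2 <- fit_half_max(d, shuffled)
  expect_true(fit2 > 0 && fit2 < 1)
  expect_error(fit_half_max(c(1, 1), c(TRUE, FALSE)), "distinct")
  expect_error(fit_half_max(c(1, 0.9), c(TRUE, TRUE)), "degenerate")
})

test_that("ruleout_probability dispatches on the configured criterion", {
  d <- total_mismatch_distribution(2, 322, 1500)
  expect_equal(ruleout_probability(d, ruleout_config(threshold_mode = "hard")),
               hard_ruleout_probability(d, 0.975))
  expect_equal(ruleout_probability(d, ruleout_config(threshold_mode = "soft")),
               soft_ruleout_probability(d, 0.991))
})
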