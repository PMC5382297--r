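test_that("Hardy-Weinberg generation matches the genotype law", {
  n <- 1e5
  G <- gen_genotypes_hwe(n, 1, maf = 0.5, seed = 31)
  freq <- tabulate(G + 1, 3) / n
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / n)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))
  expect_lt(abs(mean(G) - 1), 3 * sqrt(0.5 / n))

  G2 <- gen_genotypes_hwe(n, 2, maf = c(0.1, 0.3), seed = 32)
  expect_lt(max(abs(colMeans(G2) / 2 - c(0.1, 0.3))), 0.01)
  expect_true(all(gen_genotypes_hwe(50, 2, maf = 0, seed = 1) == 0))
})

test_that("continuous phenotypes follow the generative equation", {
  sc0 <- simulation_scenario("continuous", n_subjects = 200,
                             a_vector = rep(0, 8), noise_variance = 0)
  b0 <- simulate_continuous(sc0, seed = 33)
  expect_equal(b0$Y, 0.64 * b0$E, tolerance = 1e-12)

  # noise variance recovery
  sc1 <- simulation_scenario("continuous", n_subjects = 1e5,
                             a_vector = rep(0, 8), noise_variance = 4)
  b1 <- simulate_continuous(sc1, seed = 34)
  expect_lt(abs(var(b1$Y - 0.64 * b1$E) / 4 - 1), 0.02)

  # interaction coefficients recovered by a full-model OLS refit
  bvec <- c(1, 1, -1, -1, 0, 0, 0, 0) * 1
  sc2 <- simulation_scenario("continuous", n_subjects = 1e5,
                             a_vector = rep(0.5, 8), b_vector = bvec,
                             noise_variance = 1)
  b2 <- simulate_continuous(sc2, seed = 35)
  fit <- lm(b2$Y ~ b2$E + b2$G + I(b2$E * b2$G))
  bhat <- coef(fit)[(2 + 8 + 1):(2 + 8 + 8)]
  expect_lt(max(abs(bhat - bvec)), 0.05)
})

test_that("binary accrual meets quotas and recovers the exposure effect", {
  sc <- simulation_scenario("binary", n_cases = 2000, n_controls = 2000,
                            a_vector = rep(0, 8))
  b <- simulate_binary(sc, seed = 36)
  expect_equal(sum(b$Y == 1), 2000)
  expect_equal(sum(b$Y == 0), 2000)
  expect_equal(b$m, 1L)                      # intercept-only covariates
  # case-control sampling preserves the logistic slope on E
  slope <- coef(glm(b$Y ~ b$E, family = binomial()))[2]
  expect_lt(abs(slope - 0.64), 0.15)
  # unreachable quota errors out at the accrual cap
  sc_bad <- simulation_scenario("binary", n_cases = 5000, n_controls = 10,
                                a_vector = rep(0, 8), intercept = -40)
  expect_error(simulate_binary(sc_bad, seed = 37, max_accrual = 2e4),
               "quota")
})

test_that("rejection-rate runs are reproducible and respect alpha", {
  sc <- scenario_presets("type1", "continuous", "small", reps = 30, seed = 41)
  r1 <- run_rejection_rate(sc)
  r2 <- run_rejection_rate(sc)
  expect_identical(r1$pvalues, r2$pvalues)
  expect_identical(r1$rejection_rate, r2$rejection_rate)
  r3 <- run_rejection_rate(sc, reps = 30, alpha = 0)
  expect_equal(unname(r3$rates), rep(0, 4))
  expect_equal(r1$monte_carlo_se,
               sqrt(r1$rates * (1 - r1$rates) / 30), tolerance = 1e-12)
  # a custom single-p test is accepted
  r4 <- run_rejection_rate(sc, test = function(b) c(p = 0.01), reps = 5)
  expect_equal(unname(r4$rejection_rate), 1)
})

test_that("study presets expose the published grids and effect templates", {
  p1 <- scenario_presets("burden", "binary", "large")
  expect_equal(p1$grid, c(0.05, 0.1, 0.15, 0.2, 0.25))
  expect_equal(p1$b_vector, 0.05 * rep(1, 8))
  p2 <- scenario_presets("variance", "binary", "small", C = 2)
  expect_equal(p2$grid, c(0.4, 0.8, 1.2, 1.6, 2))
  expect_equal(p2$b_vector, 2 * c(1, 1, -1, -1, 0, 0, 0, 0))
  expect_equal(sum(p2$b_vector), 0)
  p3 <- scenario_presets("mixed", "continuous", "small")
  expect_equal(p3$grid, c(2, 4, 6, 8, 10))
  expect_equal(p3$C, 1)                      # continuous runs fix C = 1
  expect_equal(p3$b_vector, c(1, 1, 0, 0, 0.5, 0.5, 0.5, 0.5))
  p4 <- scenario_presets("type1", "binary", "small")
  expect_equal(p4$a_vector, c(1, 1, -1, -1, 0, 0, 0, 0))
  expect_equal(p4$b_vector, rep(0, 8))
  expect_equal(p4$n_cases, 100)
  expect_equal(scenario_presets("type1", "binary", "large")$n_cases, 1000)
  expect_equal(p4$intercept, log(0.01 / 0.99))
  expect_equal(p4$env_coeff, 0.64)
  expect_error(scenario_presets("nope", "binary", "small"))
})
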