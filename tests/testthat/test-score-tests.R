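test_that("quadratic forms equal naive triple-loop arithmetic on small bundles", {
  # fixed general-position toys: polymorphic columns, non-constant burden,
  # interaction column outside the span of the full-null design
  toys <- list(
    list(G = matrix(c(0, 1, 2, 1, 0, 2, 1, 0, 1, 2, 2, 0), 6, 2),
         E = c(1.3, 0.6, 0.2, -1, -0.8, -0.3),
         Y = c(2.3, -1.2, 4.1, 1.4, -3.1, 3.2)),
    list(G = matrix(c(0, 1, 2, 1, 0, 2, 1, 0,
                      1, 0, 1, 2, 2, 0, 0, 1,
                      2, 1, 0, 0, 1, 1, 2, 0), 8, 3),
         E = c(1, -1, 2, 0.5, -2, 1, -0.5, 1.5),
         Y = c(2.3, -1.2, 4.1, 1.4, -3.1, 3.2, 0.4, -0.8)))
  set.seed(11)
  for (toy in toys) {
    G <- toy$G; E <- toy$E; Y <- toy$Y
    n <- nrow(G); p <- ncol(G)
    b <- mixge_bundle(Y = Y, E = E, G = G)

    ft <- fit_null_tau(b, "identity")
    st <- score_tau(ft, b)
    expect_equal(st$statistic, triple_loop_quadform(ft$residuals, E, G),
                 tolerance = 1e-10)

    omega <- runif(p, 0.2, 2)
    stw <- score_tau(ft, b, omega = omega)
    expect_equal(stw$statistic,
                 triple_loop_quadform(ft$residuals, E, G, omega),
                 tolerance = 1e-10)

    ff <- fit_null_full(b, "identity")
    sr <- score_tau_skat_variant(ff, b)
    expect_equal(sr$statistic, triple_loop_quadform(ff$residuals, E, G),
                 tolerance = 1e-10)

    # q = 1 burden: U is the hand-computable weighted sum
    sp <- score_pi(ff, b)
    u_hand <- 0
    for (i in seq_len(n))
      u_hand <- u_hand + E[i] * mean(G[i, ]) * ff$residuals[i]
    expect_equal(unname(sp$score_vector), u_hand, tolerance = 1e-10)
    expect_equal(sp$df, 1L)
    expect_gte(sp$quadratic_stat, 0)
  }
})

test_that("tau p-value agrees with a Monte-Carlo simulation of the fitted null", {
  set.seed(12)
  n <- 8
  G <- matrix(c(0, 1, 2, 1, 0, 2, 1, 0,
                1, 0, 1, 2, 2, 0, 0, 1), n, 2)
  E <- c(1, -1, 2, 0.5, -2, 1, -0.5, 1.5)
  Y <- c(2.3, -1.2, 4.1, 1.4, -3.1, 3.2, 0.4, -0.8)
  b <- mixge_bundle(Y = Y, E = E, G = G)
  ft <- fit_null_tau(b, "identity")
  st <- score_tau(ft, b)

  # Under the fitted Gaussian null, the refit residual of Y* = mu + s Z is
  # s (I - H) Z, so the statistic is a deterministic map of Z.
  qrM <- qr(ft$design)
  A <- E * G
  s <- sqrt(ft$sigma2)
  reps <- 1e6
  exceed <- 0
  for (chunk in 1:5) {
    Z <- matrix(rnorm(n * reps / 5), n, reps / 5)
    Smc <- colSums(crossprod(A, qr.resid(qrM, Z) * s)^2)
    exceed <- exceed + sum(Smc >= st$statistic)
  }
  expect_lt(abs(st$p_value - exceed / reps), 0.01)
})

test_that("pi quadratic statistic is chi-square distributed under the null", {
  set.seed(13)
  reps <- 2000
  stats <- numeric(reps)
  for (i in seq_len(reps)) {
    b <- make_null_bundle(n = 120, p = 4)
    stats[i] <- score_pi(fit_null_full(b, "identity"), b)$quadratic_stat
  }
  ks <- ks.test(stats, pchisq, df = 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("scores respect column permutation, W recombination and E rescaling", {
  set.seed(14)
  n <- 100
  G <- gen_genotypes_hwe(n, 4, maf = c(0.2, 0.3, 0.4, 0.25))
  E <- rnorm(n)
  Y <- rnorm(n) + 0.3 * E
  b <- mixge_bundle(Y = Y, E = E, G = G)

  # SNP order invariance of the tau statistic
  perm <- c(3, 1, 4, 2)
  bp <- mixge_bundle(Y = Y, E = E, G = G[, perm])
  s1 <- score_tau(fit_null_tau(b, "identity"), b)
  s2 <- score_tau(fit_null_tau(bp, "identity"), bp)
  expect_equal(s1$statistic, s2$statistic, tolerance = 1e-10)
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-8)

  # invertible recombination of W's columns leaves the pi statistic unchanged
  W <- cbind(c(1, 1, 0, 0) / 2, c(0, 0, 1, 1) / 2)
  R <- matrix(c(2, 1, 0.5, 1.5), 2, 2)
  bw <- mixge_bundle(Y = Y, E = E, G = G, W = W)
  bwr <- mixge_bundle(Y = Y, E = E, G = G, W = W %*% R)
  q1 <- score_pi(fit_null_full(bw, "identity"), bw)
  q2 <- score_pi(fit_null_full(bwr, "identity"), bwr)
  expect_equal(q1$quadratic_stat, q2$quadratic_stat, tolerance = 1e-8)
  expect_equal(q1$df, q2$df)

  # rescaling E by c multiplies the tau statistic by c^2, p-values unchanged
  cc <- 3.7
  bs <- mixge_bundle(Y = Y, E = cc * E, G = G)
  s3 <- score_tau(fit_null_tau(bs, "identity"), bs)
  expect_equal(s3$statistic / s1$statistic, cc^2, tolerance = 1e-8)
  expect_equal(sort(s3$eigenvalues) / sort(s1$eigenvalues),
               rep(cc^2, length(s1$eigenvalues)), tolerance = 1e-8)
  # quadrature noise dominates the comparison of the two tail evaluations
  expect_equal(s3$p_value, s1$p_value, tolerance = 1e-6)
})

test_that("degenerate exposures and perfect fits give p-values of one", {
  set.seed(15)
  n <- 40
  G <- gen_genotypes_hwe(n, 2, maf = c(0.3, 0.4))
  Y <- rnorm(n)
  b0 <- mixge_bundle(Y = Y, E = rep(0, n), G = G)
  r <- mixge_test(b0, link = "identity")
  expect_true(r$diagnostics$degenerate_tau)
  expect_equal(r$p_tau, 1)
  expect_equal(r$p_pi, 1)
  expect_equal(r$p_fisher, 1)
  expect_equal(r$p_tippett, 1)

  # noiseless phenotype: zero residuals, zero statistics
  E <- rnorm(n)
  b1 <- mixge_bundle(Y = 1 + 0.5 * E, E = E, G = G)
  ft <- fit_null_tau(b1, "identity")
  st <- score_tau(ft, b1)
  expect_equal(st$statistic, 0, tolerance = 1e-12)
  expect_equal(st$p_value, 1)
  sp <- score_pi(fit_null_full(b1, "identity"), b1)
  expect_equal(sp$quadratic_stat, 0, tolerance = 1e-12)
  expect_equal(sp$p_value, 1)
})

test_that("homogeneous interactions are caught mainly by the fixed-effect score", {
  set.seed(16)
  sc <- simulation_scenario("continuous", n_subjects = 200,
                            a_vector = rep(0, 8),
                            b_vector = rep(0.5, 8), noise_variance = 1)
  wins <- 0
  reps <- 100
  for (i in seq_len(reps)) {
    b <- simulate_continuous(sc)
    r <- mixge_test(b, link = "identity", compute_random = FALSE)
    wins <- wins + (r$p_pi < r$p_tau)
  }
  expect_gt(wins / reps, 0.5)
})

test_that("null-kind mismatches are rejected", {
  b <- toy_bundle()
  ft <- fit_null_tau(b, "identity")
  ff <- fit_null_full(b, "identity")
  expect_error(score_tau(ff, b), "tau_null")
  expect_error(score_pi(ft, b), "full_null")
  expect_error(score_tau_skat_variant(ft, b), "full_null")
})

test_that("MAF beta weights up-weight rarer variants", {
  w <- maf_beta_weights(c(0.01, 0.1, 0.4))
  expect_true(all(diff(w) < 0))
  G <- gen_genotypes_hwe(200, 3, maf = c(0.05, 0.2, 0.45), seed = 9)
  expect_length(maf_beta_weights(G), 3)
})
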