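test_that("noiseless linear phenotypes are recovered exactly by both null fits", {
  set.seed(1)
  n <- 14
  G <- gen_genotypes_hwe(n, 2, maf = c(0.3, 0.4))
  E <- rnorm(n)
  X <- cbind(1, rnorm(n))
  W <- matrix(1 / 2, 2, 1)
  GW <- G %*% W
  theta_tau <- c(1.5, -0.7, 0.64, 2, -1)       # X1 X2 E GW E:GW
  M <- cbind(X, E, GW, E * GW)
  b <- mixge_bundle(Y = drop(M %*% theta_tau), X = X, E = E, G = G, W = W)

  ft <- fit_null_tau(b, "identity")
  expect_equal(unname(ft$coefficients), theta_tau, tolerance = 1e-10)
  expect_equal(ft$residuals, rep(0, n), tolerance = 1e-10)
  expect_equal(ft$sigma2_diag, rep(0, n), tolerance = 1e-12)

  V <- cbind(X, E, GW)
  theta_full <- theta_tau[1:4]
  b2 <- mixge_bundle(Y = drop(V %*% theta_full), X = X, E = E, G = G, W = W)
  ff <- fit_null_full(b2, "identity")
  expect_equal(unname(ff$coefficients), theta_full, tolerance = 1e-10)
  expect_equal(ff$residuals, rep(0, n), tolerance = 1e-10)
})

test_that("identity-link coefficients match the normal-equations oracle", {
  b <- toy_bundle()
  d <- mixge:::build_designs(b)
  for (pair in list(list(fit_null_tau(b, "identity"), d$M),
                    list(fit_null_full(b, "identity"), d$V))) {
    fit <- pair[[1]]
    Dm <- pair[[2]]
    oracle <- solve(crossprod(Dm), crossprod(Dm, b$Y))
    expect_equal(unname(fit$coefficients), as.numeric(oracle),
                 tolerance = 1e-10)
    expect_equal(fit$mu, drop(Dm %*% oracle), tolerance = 1e-10)
    # residuals sum to zero: intercept present
    expect_lt(abs(sum(fit$residuals)), 1e-10)
  }
})

test_that("intercept-only logistic fit has the closed-form MLE", {
  Y <- c(rep(1, 3), rep(0, 7))
  design <- matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- mixge:::fit_mean_model(design, Y, "logit")
  expect_equal(unname(fit$coefficients), log(3 / 7), tolerance = 1e-8)
  expect_equal(fit$mu, rep(0.3, 10), tolerance = 1e-8)
  expect_equal(fit$sigma2_diag, rep(0.3 * 0.7, 10), tolerance = 1e-8)
})

test_that("score equations hold at both converged fits", {
  set.seed(42)
  for (rep in 1:5) {
    b <- make_null_bundle(n = 120, p = 3)
    for (fit in list(fit_null_tau(b, "identity"), fit_null_full(b, "identity"))) {
      sc <- crossprod(fit$design, fit$residuals)
      expect_lt(max(abs(sc)) / sqrt(sum(b$Y^2)), 1e-8)
    }
    # logistic: canonical-link score is design' (Y - mu)
    Yb <- rbinom(120, 1, plogis(0.3 * b$E))
    bb <- mixge_bundle(Y = Yb, E = b$E, G = b$G)
    for (fit in list(fit_null_tau(bb, "logit"), fit_null_full(bb, "logit"))) {
      sc <- crossprod(fit$design, fit$residuals)
      expect_lt(max(abs(sc)), 1e-6 * length(Yb))
      expect_true(all(fit$mu > 0 & fit$mu < 1))
    }
  }
})

test_that("fitted means are invariant to covariate rescaling", {
  set.seed(3)
  b <- make_null_bundle(n = 80, p = 2)
  X2 <- cbind(1, rnorm(80))
  b1 <- mixge_bundle(Y = b$Y, X = X2, E = b$E, G = b$G, add_intercept = FALSE)
  X2s <- X2 %*% diag(c(1, 10))
  b2 <- mixge_bundle(Y = b$Y, X = X2s, E = b$E, G = b$G, add_intercept = FALSE)
  f1 <- fit_null_tau(b1, "identity")
  f2 <- fit_null_tau(b2, "identity")
  expect_equal(f1$mu, f2$mu, tolerance = 1e-10)
  expect_equal(unname(f2$coefficients[2]) * 10, unname(f1$coefficients[2]),
               tolerance = 1e-8)
})

test_that("with a zero exposure the two null fits coincide on shared terms", {
  set.seed(4)
  b0 <- make_null_bundle(n = 60, p = 2)
  bz <- mixge_bundle(Y = b0$Y, E = rep(0, 60), G = b0$G)
  ft <- fit_null_tau(bz, "identity")
  ff <- fit_null_full(bz, "identity")
  # interaction and E columns vanish; shared coefficients agree
  expect_equal(ft$mu, ff$mu, tolerance = 1e-10)
  shared <- intersect(names(ft$coefficients), names(ff$coefficients))
  expect_equal(ft$coefficients[shared], ff$coefficients[shared],
               tolerance = 1e-10)
  expect_true(length(ft$dropped) >= 1)   # E-derived columns pruned
})

test_that("variance diagonals follow the link-specific definitions", {
  set.seed(5)
  b <- make_null_bundle(n = 100, p = 2)
  fit <- fit_null_tau(b, "identity")
  df_res <- 100 - ncol(fit$design)
  expect_equal(variance_diag(fit),
               rep(sum(fit$residuals^2) / df_res, 100), tolerance = 1e-12)
  expect_true(all(variance_diag(fit) >= 0))

  Yb <- rbinom(100, 1, 0.4)
  bb <- mixge_bundle(Y = Yb, E = b$E, G = b$G)
  fitb <- fit_null_tau(bb, "logit")
  expect_equal(variance_diag(fitb), fitb$mu * (1 - fitb$mu), tolerance = 1e-12)
})

test_that("degenerate inputs raise the documented estimability errors", {
  set.seed(6)
  G <- gen_genotypes_hwe(40, 2, maf = c(0.3, 0.2))
  E <- rnorm(40)
  Y <- rnorm(40)
  expect_error(mixge_bundle(Y = Y, E = E, G = G, W = matrix(c(1, 1, 0, 0), 2)),
               "all-zero column")
  b_mono <- mixge_bundle(Y = Y, E = E, G = matrix(0, 40, 2))
  expect_true(all(b_mono$monomorphic))
  expect_error(fit_null_tau(b_mono, "identity"), "monomorphic")
  # duplicated SNP column: pruned, not an error
  b_dup <- mixge_bundle(Y = Y, E = E, G = cbind(G, G[, 1]),
                        W = diag(3))
  fit <- fit_null_tau(b_dup, "identity")
  expect_true(length(fit$dropped) >= 1)
  # logistic separation: a perfectly predictive genotype column (own
  # weight column, so it enters the mean model on its own)
  Yb <- rep(c(0, 1), each = 20)
  Gs <- cbind(Yb, G[, 1])
  bs <- mixge_bundle(Y = Yb, E = E, G = Gs, W = diag(2))
  expect_error(fit_null_full(bs, "logit"), "separation")
  # ... unless pruning is requested
  fitp <- fit_null_full(bs, "logit", separation = "prune")
  expect_true(any(grepl("GW", fitp$dropped)))
})

test_that("missing genotypes are mean-imputed and monomorphic SNPs flagged", {
  G <- matrix(c(0, 1, 2, NA, 1,
                0, 0, 0, 0, 0), ncol = 2)
  b <- mixge_bundle(Y = rnorm(5) + 10, E = rnorm(5),
                    G = cbind(G, c(1, 0, 1, 0, 1)))
  expect_equal(b$n_imputed, 1L)
  expect_equal(b$G[4, 1], 1)            # mean of 0,1,2,1
  expect_true(b$monomorphic[2])
  b_round <- mixge_bundle(Y = rnorm(5) + 10, E = rnorm(5),
                          G = matrix(c(0, 1, 2, NA, 2), 5, 1),
                          impute_round = TRUE)
  expect_true(b_round$G[4, 1] %in% c(0, 1, 2))
  expect_error(mixge_bundle(Y = rnorm(5) + 10, E = rnorm(5),
                            G = matrix(c(0, 1, 3, 0, 1), 5, 1)),
               "0, 1 or 2")
})
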