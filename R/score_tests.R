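# Score statistics for the two components of the MixGE test.
#
# Variance-component score (tau^2):
#   S = r' diag(E) G omega G' diag(E) r,  r = Y - mu_hat (tau_null fit);
#   null law: sum_i lambda_i chisq_1 with lambda_i the non-zero eigenvalues
#   of P K, P = D - D M (M' D M)^-1 M' D the variance-projection matrix and
#   K = diag(E) G omega G' diag(E) the interaction kernel. The eigenvalues
#   are computed economically from the p x p matrix B' P B, B = diag(E) G
#   omega^{1/2}, which shares the non-zero spectrum of P K.
#
# Fixed-effect interaction score (pi2):
#   U = (diag(E) G W)' (Y - mu_tilde) (full_null fit);
#   Sigma = C' {D - D V (V' D V)^-1 V' D} C,  C = diag(E) G W;
#   U' Sigma^-1 U  ~  chisq_q under the null.

EIG_TOL <- 1e-10

# Shared quadratic-form machinery for the variance-component score; the two
# exported variants differ only in which null fit supplies mu and D.
tau_score_engine <- function(fit, bundle, omega = NULL) {
  n <- bundle$n
  p <- bundle$p
  if (is.null(omega)) omega <- rep(1, p)
  omega <- as.numeric(omega)
  if (length(omega) != p || any(omega < 0) || any(!is.finite(omega)))
    stop("omega must be a length-p vector of non-negative finite weights")

  A <- bundle$E * bundle$G                       # diag(E) G, N x p
  r <- fit$residuals
  u <- drop(crossprod(A, r))                     # G' diag(E) r
  statistic <- sum(omega * u^2)

  degenerate <- FALSE
  eigenvalues <- numeric(0)
  if (all(bundle$E == 0)) {
    degenerate <- TRUE
    statistic <- 0
  } else if (max(fit$sigma2_diag) <=
             1e-16 * (stats::var(bundle$Y) + .Machine$double.eps)) {
    # perfect fit: residual variance at rounding-noise level
    degenerate <- TRUE
  } else {
    B <- sweep(A, 2L, sqrt(omega), "*")
    D <- fit$sigma2_diag
    M <- fit$design
    DB <- D * B
    MtDM <- crossprod(M, D * M)
    MtDB <- crossprod(M, DB)
    K <- crossprod(B, DB) - crossprod(MtDB, solve(MtDM, MtDB))
    K <- (K + t(K)) / 2
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    eigenvalues <- ev[ev > EIG_TOL * max(ev, 0)]
    if (length(eigenvalues) == 0L) degenerate <- TRUE
  }
  p_value <- if (degenerate) 1 else mixture_sf(statistic, eigenvalues)

  structure(
    list(statistic = statistic,
         eigenvalues = eigenvalues,
         p_value = p_value,
         degenerate = degenerate,
         omega_used = omega,
         null_kind = fit$null_kind),
    class = "mixge_tau_score")
}

#' Variance-component interaction score (sequential construction)
#'
#' Computes the quadratic score statistic for the variance `tau^2` of the
#' per-SNP random interaction effects, under the null `tau^2 = 0` with the
#' fixed interaction effect `pi2` retained in the mean model (the fit from
#' [fit_null_tau()]). The statistic is referred to its mixture-of-chi-squares
#' null law through [mixture_sf()].
#'
#' @param fit A `mixge_null_fit` with `null_kind = "tau_null"`.
#' @param bundle The [mixge_bundle()] the fit was computed from.
#' @param omega Optional non-negative per-SNP variance weights (length `p`);
#'   identity weights when omitted. See [maf_beta_weights()] for a
#'   MAF-adaptive choice.
#' @return A `mixge_tau_score`: `statistic` (`>= 0`), the sorted positive
#'   `eigenvalues` of the variance-projected kernel, `p_value`, a
#'   `degenerate` flag (p-value 1 when `E` is all zero or the projected
#'   kernel vanishes), and `omega_used`.
#' @export
score_tau <- function(fit, bundle, omega = NULL) {
  stopifnot(inherits(fit, "mixge_null_fit"), inherits(bundle, "mixge_bundle"))
  if (fit$null_kind != "tau_null")
    stop("score_tau requires a tau_null fit (see fit_null_tau)")
  tau_score_engine(fit, bundle, omega)
}

#' SKAT-style variance-component interaction score under the full null
#'
#' Same quadratic form as [score_tau()], but with residuals and projection
#' taken from the full null fit ([fit_null_full()], `pi2 = 0` imposed). This
#' is the interaction analogue of SKAT and is reported as `p_random` by
#' [mixge_test()].
#'
#' @param fit A `mixge_null_fit` with `null_kind = "full_null"`.
#' @inheritParams score_tau
#' @return A `mixge_tau_score`; see [score_tau()].
#' @export
score_tau_skat_variant <- function(fit, bundle, omega = NULL) {
  stopifnot(inherits(fit, "mixge_null_fit"), inherits(bundle, "mixge_bundle"))
  if (fit$null_kind != "full_null")
    stop("score_tau_skat_variant requires a full_null fit (see fit_null_full)")
  tau_score_engine(fit, bundle, omega)
}

#' Fixed-effect (burden-type) interaction score
#'
#' Computes the score vector `U = (diag(E) G W)' (Y - mu_tilde)` for the
#' fixed interaction coefficients `pi2` under the full null, its projected
#' covariance `Sigma`, and the quadratic statistic `U' Sigma^-1 U`, referred
#' to a chi-square with `q` degrees of freedom. A numerically singular
#' `Sigma` is inverted by symmetric pseudo-inverse with the degrees of
#' freedom lowered to its numerical rank.
#'
#' @param fit A `mixge_null_fit` with `null_kind = "full_null"`.
#' @param bundle The [mixge_bundle()] the fit was computed from.
#' @return A `mixge_pi_score`: `score_vector` (length `q`), `covariance`
#'   (`q x q`), `quadratic_stat`, `df` (numerical rank of `Sigma`),
#'   `p_value`, and a `degenerate` flag.
#' @export
score_pi <- function(fit, bundle) {
  stopifnot(inherits(fit, "mixge_null_fit"), inherits(bundle, "mixge_bundle"))
  if (fit$null_kind != "full_null")
    stop("score_pi requires a full_null fit (see fit_null_full)")

  C <- bundle$E * (bundle$G %*% bundle$W)        # diag(E) G W, N x q
  U <- drop(crossprod(C, fit$residuals))
  D <- fit$sigma2_diag
  V <- fit$design
  if (max(D) <= 1e-16 * (stats::var(bundle$Y) + .Machine$double.eps)) {
    # perfect fit: the score carries no information
    return(structure(
      list(score_vector = U, covariance = matrix(0, bundle$q, bundle$q),
           quadratic_stat = 0, df = 0L, p_value = 1, degenerate = TRUE),
      class = "mixge_pi_score"))
  }
  DC <- D * C
  VtDV <- crossprod(V, D * V)
  VtDC <- crossprod(V, DC)
  Sigma <- crossprod(C, DC) - crossprod(VtDC, solve(VtDV, VtDC))
  Sigma <- (Sigma + t(Sigma)) / 2

  es <- eigen(Sigma, symmetric = TRUE)
  pos <- es$values > EIG_TOL * max(es$values, 0)
  df <- sum(pos)
  if (df == 0L) {
    out <- list(score_vector = U, covariance = Sigma, quadratic_stat = 0,
                df = 0L, p_value = 1, degenerate = TRUE)
  } else {
    Uo <- drop(crossprod(es$vectors[, pos, drop = FALSE], U))
    stat <- sum(Uo^2 / es$values[pos])
    out <- list(score_vector = U, covariance = Sigma,
                quadratic_stat = stat, df = df,
                p_value = clamp_p(stats::pchisq(stat, df = df,
                                                lower.tail = FALSE)),
                degenerate = FALSE)
  }
  structure(out, class = "mixge_pi_score")
}

#' Beta-density variant weights decreasing in minor-allele frequency
#'
#' Computes `dbeta(maf, shape1, shape2)^2` weights (the usual SKAT-style
#' up-weighting of rarer variants) for use as `omega` in [score_tau()].
#' Off by default everywhere in the package.
#'
#' @param maf Per-SNP minor-allele frequencies in `(0, 0.5]`, or a genotype
#'   matrix from which sample MAFs are computed as `colMeans(G) / 2`.
#' @param shape1,shape2 Beta density parameters (defaults 1 and 25).
#' @return Non-negative weight vector of length `p`.
#' @export
maf_beta_weights <- function(maf, shape1 = 1, shape2 = 25) {
  if (is.matrix(maf)) maf <- colMeans(maf) / 2
  if (any(maf < 0 | maf > 1)) stop("maf values must lie in [0, 1]")
  stats::dbeta(pmin(maf, 1 - maf), shape1, shape2)^2
}

#' Set-based mixed-effect test of gene-environment interaction
#'
#' Runs the full sequential MixGE procedure on one variant set: fits the two
#' null mean models, computes the variance-component interaction score
#' ([score_tau()], null `tau^2 = 0` without assuming `pi2 = 0`) and the
#' fixed-effect interaction score ([score_pi()]), and combines the two
#' independent p-values by the Fisher and Tippett rules. Optionally also
#' reports the SKAT-style variance-component p-value computed under the full
#' null ([score_tau_skat_variant()]).
#'
#' @param bundle A [mixge_bundle()].
#' @param link `"identity"` or `"logit"`; chosen automatically from the
#'   phenotype coding when omitted.
#' @param omega Optional per-SNP variance weights for the quadratic kernel.
#' @param main_effects Genetic main-effect block of the null mean models:
#'   `"weighted"` (default; the collapsed `GW pi1` term of the model
#'   equation) or `"per_variant"` (one main-effect coefficient per SNP; see
#'   [fit_null_tau()]).
#' @param separation Quasi-separation policy for logistic null fits; see
#'   [fit_null_tau()].
#' @param compute_random Logical; also compute `p_random` (default `TRUE`).
#' @return A `mixge_result` with p-values `p_pi`, `p_tau`, `p_fisher`,
#'   `p_tippett`, `p_random` (or `NA`), the underlying score objects
#'   (`pi_score`, `tau_score`, `random_score`), and `diagnostics` (dropped
#'   design columns, eigenvalue count, degeneracy flags).
#' @examples
#' set.seed(7)
#' n <- 300
#' G <- gen_genotypes_hwe(n, 8, maf = runif(8, 0.05, 0.5))
#' E <- rnorm(n)
#' Y <- 0.64 * E + rowSums(G) * 0.1 + 0.4 * E * G[, 1] + rnorm(n)
#' res <- mixge_test(mixge_bundle(Y = Y, E = E, G = G))
#' res$p_fisher
#' @export
mixge_test <- function(bundle, link = NULL, omega = NULL,
                       main_effects = c("weighted", "per_variant"),
                       separation = c("error", "prune"),
                       compute_random = TRUE) {
  stopifnot(inherits(bundle, "mixge_bundle"))
  main_effects <- match.arg(main_effects)
  separation <- match.arg(separation)
  if (is.null(link)) link <- if (bundle$binary) "logit" else "identity"
  fit_tau <- fit_null_tau(bundle, link, main_effects, separation)
  fit_full <- fit_null_full(bundle, link, main_effects, separation)

  tau <- score_tau(fit_tau, bundle, omega)
  pi <- score_pi(fit_full, bundle)
  rnd <- if (compute_random) score_tau_skat_variant(fit_full, bundle, omega)

  p_tau <- tau$p_value
  p_pi <- pi$p_value
  structure(
    list(p_pi = p_pi, p_tau = p_tau,
         p_fisher = combine_fisher(p_pi, p_tau),
         p_tippett = combine_tippett(p_pi, p_tau),
         p_random = if (compute_random) rnd$p_value else NA_real_,
         pi_score = pi, tau_score = tau,
         random_score = if (compute_random) rnd,
         link = link,
         diagnostics = list(
           dropped_tau_null = fit_tau$dropped,
           dropped_full_null = fit_full$dropped,
           n_eigenvalues = length(tau$eigenvalues),
           degenerate_tau = tau$degenerate,
           degenerate_pi = pi$degenerate)),
    class = "mixge_result")
}

#' @export
print.mixge_result <- function(x, ...) {
  cat(sprintf("MixGE gene-environment interaction test (%s link)\n", x$link))
  p <- c(P_pi2 = x$p_pi, P_tau2 = x$p_tau, P_Fisher = x$p_fisher,
         P_Tippett = x$p_tippett, P_random = x$p_random)
  print(vapply(p, function(v) formatC(v, format = "e", digits = 2),
               character(1)), quote = FALSE)
  if (x$diagnostics$degenerate_tau || x$diagnostics$degenerate_pi)
    cat("note: degenerate score component(s); affected p-values set to 1\n")
  invisible(x)
}
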