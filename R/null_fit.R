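# Null-model fitting for the two sequential nulls of the MixGE test.
#
# tau_null : mean model  g{E(Y)} = X b_x + E b_e + GW pi1 + diag(E) GW pi2
#            (variance component tau^2 = 0, fixed interaction retained)
# full_null: mean model  g{E(Y)} = X b_x + E b_e + GW pi1
#            (tau^2 = 0 and pi2 = 0)

# Design matrices for both nulls, with informative column names. The
# genetic main-effect block is either the weighted collapse GW (the model
# equation as written) or the full per-variant block G, which is required
# for a valid interaction test when main effects are heterogeneous and not
# spanned by the weight columns (see the methods vignette).
build_designs <- function(bundle, main_effects = c("weighted", "per_variant")) {
  main_effects <- match.arg(main_effects)
  GW <- bundle$G %*% bundle$W
  colnames(GW) <- paste0("GW.", colnames(bundle$W))
  C <- bundle$E * GW
  colnames(C) <- paste0("E:GW.", colnames(bundle$W))
  main <- if (main_effects == "weighted") GW else {
    Gm <- bundle$G
    colnames(Gm) <- paste0("G.", if (!is.null(colnames(bundle$G)))
      colnames(bundle$G) else seq_len(bundle$p))
    Gm
  }
  V <- cbind(bundle$X, E = bundle$E, main)
  M <- cbind(V, C)
  list(M = M, V = V, GW = GW, C = C)
}

# Drop linearly dependent columns by pivoted QR (relative tolerance 1e-10).
prune_columns <- function(mat, tol = 1e-10) {
  qr_m <- qr(mat, tol = tol)
  rank <- qr_m$rank
  keep <- sort(qr_m$pivot[seq_len(rank)])
  list(mat = mat[, keep, drop = FALSE],
       dropped = colnames(mat)[setdiff(seq_len(ncol(mat)), keep)])
}

# GLM fit of Y on a pruned design: OLS for identity, IRLS for logit.
# Per-subject variances follow the common unbiased variance estimate
# RSS/(N - rank) for the identity link and mu(1-mu) for the logit link. A logit coefficient beyond
# coef_bound signals (quasi-)separation: either an error, or -- under
# separation = "prune" -- the offending columns are removed and the model
# refitted (a quasi-separated adjustment column carries no usable
# information and destabilizes the working variances).
fit_mean_model <- function(design, Y, link,
                           separation = c("error", "prune"),
                           maxit = 100L, epsilon = 1e-10, coef_bound = 30) {
  separation <- match.arg(separation)
  n <- length(Y)
  if (link == "identity") {
    qr_d <- qr(design)
    if (qr_d$rank < ncol(design))
      stop("design rank-deficient after pruning; cannot estimate the null model")
    df_res <- n - qr_d$rank
    if (df_res < 1L)
      stop("saturated design: no residual degrees of freedom")
    coef <- qr.coef(qr_d, Y)
    mu <- drop(design %*% coef)
    res <- Y - mu
    # unbiased residual-df denominator; the naive 1/N estimator biases the
    # score-statistic scale noticeably when k/N is not small
    sigma2 <- sum(res^2) / df_res
    list(coefficients = coef, mu = mu, residuals = res,
         sigma2_diag = rep(sigma2, n), sigma2 = sigma2, converged = TRUE,
         design = design, dropped_separated = character(0))
  } else {
    dropped_sep <- character(0)
    repeat {
      fit <- suppressWarnings(
        stats::glm.fit(design, Y, family = stats::binomial(),
                       control = stats::glm.control(epsilon = epsilon,
                                                    maxit = maxit)))
      coef <- fit$coefficients
      if (anyNA(coef))
        stop("design rank-deficient after pruning; cannot estimate the null model")
      if (!fit$converged && separation == "error")
        stop("logistic null model did not converge in ", maxit,
             " IRLS iterations")
      big <- abs(coef) > coef_bound
      if (!any(big) && fit$converged) break
      if (separation == "error")
        stop("logistic null model shows (quasi-)separation; offending columns: ",
             paste(colnames(design)[big], collapse = ", "))
      if (ncol(design) <= 1L)
        stop("logistic null model shows (quasi-)separation; ",
             "no stable columns remain")
      # a joint divergence direction can implicate every column; dropping
      # only the worst offender per round keeps the rest of the model
      worst <- which.max(abs(coef))
      dropped_sep <- c(dropped_sep, colnames(design)[worst])
      design <- design[, -worst, drop = FALSE]
    }
    mu <- fit$fitted.values
    list(coefficients = coef, mu = mu, residuals = Y - mu,
         sigma2_diag = mu * (1 - mu), sigma2 = NA_real_, converged = TRUE,
         design = design, dropped_separated = dropped_sep)
  }
}

new_null_fit <- function(kind, link, fit, dropped) {
  structure(
    list(null_kind = kind, link = link,
         coefficients = fit$coefficients,
         mu = fit$mu, residuals = fit$residuals,
         sigma2_diag = fit$sigma2_diag, sigma2 = fit$sigma2,
         design = fit$design,
         dropped = c(dropped, fit$dropped_separated),
         converged = fit$converged),
    class = "mixge_null_fit")
}

check_estimable <- function(bundle) {
  if (all(bundle$monomorphic))
    stop("all SNPs in the set are monomorphic; genetic effects are inestimable")
}

#' Fit the variance-component null model (tau^2 = 0)
#'
#' Fits the mean model `g{E(Y)} = X b_x + E b_e + GW pi1 + diag(E) GW pi2`,
#' i.e. the null of the variance-component interaction score in which the
#' fixed interaction effect `pi2` is retained. Ordinary least squares under
#' the identity link; binomial maximum likelihood (IRLS) under the logit
#' link. Linearly dependent design columns are dropped by pivoted QR and
#' reported in `$dropped`.
#'
#' @param bundle A [mixge_bundle()].
#' @param link `"identity"` (continuous phenotype) or `"logit"` (binary).
#' @param main_effects How genetic main effects enter the mean model:
#'   `"weighted"` (default) uses the collapsed block `GW pi1` as in the model
#'   equation; `"per_variant"` gives every SNP its own main-effect
#'   coefficient (block `G`), which keeps the interaction scores valid when
#'   main effects are heterogeneous and not spanned by the weight columns
#'   (the situation in the power/type-I study designs).
#' @param separation What to do when the logistic fit shows
#'   (quasi-)separation (`|coefficient| > 30`): `"error"` (default) or
#'   `"prune"` -- drop the offending columns, record them in `$dropped`, and
#'   refit. Pruning is what the simulation engine uses, since a
#'   quasi-separated adjustment column (e.g. a single-carrier SNP) carries
#'   no information and would otherwise abort a long replicate stream.
#' @return An object of class `mixge_null_fit` with elements `null_kind`
#'   (`"tau_null"`), `coefficients`, fitted means `mu`, `residuals`
#'   (`Y - mu`), per-subject variances `sigma2_diag` (`RSS/(N - rank)`
#'   replicated for identity, `mu (1 - mu)` for logit), the pruned `design`
#'   matrix, and
#'   `dropped` column names.
#' @seealso [fit_null_full()], [score_tau()]
#' @export
fit_null_tau <- function(bundle, link = c("identity", "logit"),
                         main_effects = c("weighted", "per_variant"),
                         separation = c("error", "prune")) {
  stopifnot(inherits(bundle, "mixge_bundle"))
  link <- check_link(link, bundle$Y)
  check_estimable(bundle)
  d <- build_designs(bundle, main_effects)
  pr <- prune_columns(d$M)
  fit <- fit_mean_model(pr$mat, bundle$Y, link, separation)
  new_null_fit("tau_null", link, fit, pr$dropped)
}

#' Fit the full null model (tau^2 = 0 and pi2 = 0)
#'
#' Fits the mean model `g{E(Y)} = X b_x + E b_e + GW pi1`, the null of the
#' fixed-effect interaction score, with no interaction term of any kind.
#'
#' @inheritParams fit_null_tau
#' @return An object of class `mixge_null_fit` with `null_kind = "full_null"`;
#'   see [fit_null_tau()] for the remaining elements.
#' @seealso [score_pi()], [score_tau_skat_variant()]
#' @export
fit_null_full <- function(bundle, link = c("identity", "logit"),
                          main_effects = c("weighted", "per_variant"),
                          separation = c("error", "prune")) {
  stopifnot(inherits(bundle, "mixge_bundle"))
  link <- check_link(link, bundle$Y)
  check_estimable(bundle)
  d <- build_designs(bundle, main_effects)
  pr <- prune_columns(d$V)
  fit <- fit_mean_model(pr$mat, bundle$Y, link, separation)
  new_null_fit("full_null", link, fit, pr$dropped)
}

#' Per-subject variance entries of a fitted null model
#'
#' Returns the diagonal of the working variance matrix `D`: the common
#' residual variance `RSS/(N - rank)` replicated over subjects for the
#' identity link,
#' or `mu (1 - mu)` elementwise for the logit link.
#'
#' @param fit A `mixge_null_fit` from [fit_null_tau()] or [fit_null_full()].
#' @return Numeric vector of length `N`, all entries `>= 0`.
#' @export
variance_diag <- function(fit) {
  stopifnot(inherits(fit, "mixge_null_fit"))
  fit$sigma2_diag
}

#' @export
print.mixge_null_fit <- function(x, ...) {
  cat(sprintf("MixGE null fit [%s, %s link]\n", x$null_kind, x$link))
  cat("  coefficients:\n")
  print(round(x$coefficients, 6))
  if (length(x$dropped))
    cat("  dropped columns:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
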