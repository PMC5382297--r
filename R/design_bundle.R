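#' Assemble an aligned design bundle for set-based G-by-E testing
#'
#' Collects the phenotype, covariates, environmental exposure, genotype
#' matrix and variant-weight matrix for `N` subjects into a single validated
#' object consumed by [fit_null_tau()], [score_tau()], [mixge_test()] and the
#' voxelwise driver.
#'
#' Genotypes are minor-allele counts in `{0, 1, 2}`. Missing calls (`NA`) are
#' imputed to the per-SNP mean of the observed calls (optionally rounded to
#' the nearest integer dosage). Monomorphic SNPs are retained -- they
#' contribute nothing to the kernels -- but flagged, and the null-model fits
#' refuse a bundle in which every SNP is monomorphic.
#'
#' @param Y Numeric phenotype vector of length `N`: continuous, or binary
#'   coded 0/1.
#' @param X Optional covariate matrix (`N x m`). When `add_intercept` is
#'   `TRUE` (default) a column of ones is prepended unless `X` already
#'   contains a constant column. `X = NULL` gives an intercept-only design.
#' @param E Environmental exposure vector of length `N` (a single variable;
#'   see [build_environment_pc1()] to condense several risk variables).
#' @param G Genotype matrix (`N x p`), entries in `{0, 1, 2}` or `NA`.
#' @param W Variant weight matrix (`p x q`). Default is the equal-weight
#'   burden vector with entries `1/p`. No column may be all zero.
#' @param impute_round Logical; round imputed genotype dosages to the nearest
#'   integer. Default `FALSE`.
#'
#' @return An object of class `mixge_bundle`: a list with elements `Y`, `X`,
#'   `E`, `G`, `W`, dimensions `n`, `m`, `p`, `q`, the logical `binary`
#'   phenotype flag, a logical `monomorphic` vector of length `p`, and the
#'   number of imputed genotype calls `n_imputed`.
#' @examples
#' set.seed(1)
#' G <- gen_genotypes_hwe(80, 4, maf = rep(0.3, 4))
#' b <- mixge_bundle(Y = rnorm(80), E = rnorm(80), G = G)
#' b$q        # one burden column by default
#' @export
mixge_bundle <- function(Y, X = NULL, E, G, W = NULL,
                         impute_round = FALSE, add_intercept = TRUE) {
  Y <- as.numeric(Y)
  n <- length(Y)
  if (anyNA(Y)) stop("Y contains missing values; subset subjects first")
  E <- as.numeric(E)
  if (length(E) != n) stop("length(E) != length(Y)")
  if (anyNA(E)) stop("E contains missing values")

  G <- as.matrix(G)
  if (nrow(G) != n) stop("nrow(G) != length(Y)")
  storage.mode(G) <- "double"
  obs <- G[!is.na(G)]
  if (!all(obs %in% c(0, 1, 2)))
    stop("observed genotype entries must be 0, 1 or 2 (minor-allele counts)")
  n_imputed <- sum(is.na(G))
  if (n_imputed > 0L) {
    for (j in seq_len(ncol(G))) {
      miss <- is.na(G[, j])
      if (!any(miss)) next
      if (all(miss)) stop("SNP column ", j, " has no observed genotypes")
      fill <- mean(G[!miss, j])
      if (impute_round) fill <- round(fill)
      G[miss, j] <- fill
    }
  }
  p <- ncol(G)
  monomorphic <- apply(G, 2L, function(g) length(unique(g)) == 1L)

  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("nrow(X) != length(Y)")
    if (anyNA(X)) stop("X contains missing values")
    storage.mode(X) <- "double"
    has_const <- any(apply(X, 2L, function(x) diff(range(x)) == 0 && x[1] != 0))
    if (add_intercept && !has_const)
      X <- cbind("(Intercept)" = 1, X)
  }
  if (is.null(colnames(X)))
    colnames(X) <- paste0("X", seq_len(ncol(X)))

  if (is.null(W)) {
    W <- matrix(1 / p, p, 1, dimnames = list(NULL, "burden"))
  } else {
    W <- as.matrix(W)
    if (nrow(W) != p) stop("nrow(W) != ncol(G)")
    storage.mode(W) <- "double"
  }
  if (any(colSums(abs(W)) == 0))
    stop("W has an all-zero column; the corresponding interaction effect is inestimable")
  if (is.null(colnames(W)))
    colnames(W) <- paste0("w", seq_len(ncol(W)))
  q <- ncol(W)
  m <- ncol(X)
  if (n <= m + 1 + 2 * q)
    stop("too few subjects (need N > m + 1 + 2q = ", m + 1 + 2 * q, ") for an estimable null model")

  structure(
    list(Y = Y, X = X, E = E, G = G, W = W,
         n = n, m = m, p = p, q = q,
         binary = all(Y %in% c(0, 1)),
         monomorphic = monomorphic,
         n_imputed = n_imputed),
    class = "mixge_bundle")
}

#' @export
print.mixge_bundle <- function(x, ...) {
  cat("MixGE design bundle\n")
  cat(sprintf("  subjects     : %d (%s phenotype)\n", x$n,
              if (x$binary) "binary" else "continuous"))
  cat(sprintf("  covariates   : %d (incl. intercept)\n", x$m))
  cat(sprintf("  SNPs         : %d (%d monomorphic, %d imputed calls)\n",
              x$p, sum(x$monomorphic), x$n_imputed))
  cat(sprintf("  weight cols  : %d\n", x$q))
  invisible(x)
}

# Validate a link choice against the phenotype coding.
check_link <- function(link, Y) {
  link <- match.arg(link, c("identity", "logit"))
  binary <- all(Y %in% c(0, 1))
  if (link == "logit" && !binary)
    stop("logit link requires a binary 0/1 phenotype")
  if (link == "identity" && binary)
    stop("identity link requires a continuous phenotype; use link = \"logit\" for 0/1 outcomes")
  link
}
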