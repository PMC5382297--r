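# Voxelwise driver: the same MixGE test at every voxel, sharing every
# voxel-independent precomputation (design factorizations, genotype
# kernels), followed by Storey FDR across voxels.

#' Run the MixGE test across a voxelwise phenotype matrix
#'
#' Applies [mixge_test()] to every column of a subjects-by-voxels phenotype
#' matrix, reusing the design-matrix factorizations and the genotype kernel
#' eigen-structure across voxels. For the identity link this makes the
#' per-voxel cost a handful of matrix-vector products: under a common
#' residual variance the projected-kernel eigenvalues at a voxel are the
#' shared unit-variance eigenvalues scaled by that voxel's variance
#' estimate, so they are computed once. Storey q-values are then computed
#' across voxels on the chosen combined p-value (Fisher by default).
#'
#' @param bundle A [mixge_bundle()] supplying the shared `X`, `E`, `G`, `W`
#'   (its `Y` slot is ignored; any placeholder phenotype works).
#' @param phenotypes Numeric matrix, subjects x voxels (column names become
#'   voxel labels), with subject count matching the bundle.
#' @param link `"identity"` (vectorized fast path) or `"logit"` (per-voxel
#'   loop; requires all-binary phenotype columns).
#' @param combine Which combined p-value feeds the FDR step: `"fisher"`
#'   (default) or `"tippett"`.
#' @param q_cutoff Significance level on the q scale (default 0.05).
#' @param omega Optional per-SNP variance weights.
#' @param main_effects Genetic main-effect block of the null models; see
#'   [fit_null_tau()].
#' @param compute_random Also report the SKAT-style `p_random` column.
#' @param exclude_degenerate Exclude zero-variance voxels (flagged, p = 1)
#'   from the FDR adjustment; their q-value is `NA`. Default `TRUE`.
#' @param lambda Storey tuning parameter passed to [storey_qvalues()].
#' @return A list: `table` (data frame with one row per voxel: `voxel`,
#'   `p_pi`, `p_tau`, `p_fisher`, `p_tippett`, optionally `p_random`,
#'   `degenerate`, `qvalue`, `significant`), `pi0`, `combine`, `q_cutoff`,
#'   `n_significant`.
#' @export
run_voxelwise <- function(bundle, phenotypes, link = "identity",
                          combine = c("fisher", "tippett"),
                          q_cutoff = 0.05, omega = NULL,
                          main_effects = c("weighted", "per_variant"),
                          compute_random = FALSE,
                          exclude_degenerate = TRUE, lambda = 0.5) {
  main_effects <- match.arg(main_effects)
  stopifnot(inherits(bundle, "mixge_bundle"))
  combine <- match.arg(combine)
  link <- match.arg(link, c("identity", "logit"))
  Yv <- as.matrix(phenotypes)
  storage.mode(Yv) <- "double"
  if (nrow(Yv) != bundle$n)
    stop("phenotype matrix has ", nrow(Yv), " rows but the bundle has ",
         bundle$n, " subjects")
  if (anyNA(Yv)) stop("voxelwise phenotypes contain missing values")
  K <- ncol(Yv)
  voxel <- colnames(Yv)
  if (is.null(voxel)) voxel <- paste0("v", seq_len(K))

  if (link == "identity") {
    res <- voxelwise_identity(bundle, Yv, omega, main_effects, compute_random)
  } else {
    res <- voxelwise_loop(bundle, Yv, link, omega, main_effects,
                          compute_random)
  }

  p_comb <- if (combine == "fisher") res$p_fisher else res$p_tippett
  qv <- rep(NA_real_, K)
  use <- if (exclude_degenerate) !res$degenerate else rep(TRUE, K)
  pi0 <- NA_real_
  if (any(use)) {
    sq <- storey_qvalues(p_comb[use], lambda = lambda)
    qv[use] <- sq$qvalues
    pi0 <- sq$pi0
  }
  sig <- !is.na(qv) & qv <= q_cutoff

  tab <- data.frame(voxel = voxel, p_pi = res$p_pi, p_tau = res$p_tau,
                    p_fisher = res$p_fisher, p_tippett = res$p_tippett,
                    stringsAsFactors = FALSE)
  if (compute_random) tab$p_random <- res$p_random
  tab$degenerate <- res$degenerate
  tab$qvalue <- qv
  tab$significant <- sig
  list(table = tab, pi0 = pi0, combine = combine,
       q_cutoff = q_cutoff, n_significant = sum(sig))
}

# Fully vectorized identity-link path: all voxels at once.
voxelwise_identity <- function(bundle, Yv, omega, main_effects,
                               compute_random) {
  n <- bundle$n
  p <- bundle$p
  K <- ncol(Yv)
  if (is.null(omega)) omega <- rep(1, p)
  check_estimable(bundle)
  d <- build_designs(bundle, main_effects)
  prM <- prune_columns(d$M)
  prV <- prune_columns(d$V)
  qrM <- qr(prM$mat)
  qrV <- qr(prV$mat)

  R_tau <- qr.resid(qrM, Yv)                     # N x K residual matrices
  R_full <- qr.resid(qrV, Yv)
  s2_tau <- colSums(R_tau^2) / (n - qrM$rank)
  s2_full <- colSums(R_full^2) / (n - qrV$rank)
  cvar <- apply(Yv, 2L, stats::var)
  degenerate <- cvar == 0 |
    s2_tau <= 1e-16 * (cvar + .Machine$double.eps) |
    all(bundle$E == 0)

  A <- bundle$E * bundle$G
  B <- sweep(A, 2L, sqrt(omega), "*")
  lam_unit <- function(qr_d) {
    Kmat <- crossprod(B, qr.resid(qr_d, B))      # B' (I - H) B
    Kmat <- (Kmat + t(Kmat)) / 2
    ev <- eigen(Kmat, symmetric = TRUE, only.values = TRUE)$values
    ev[ev > EIG_TOL * max(ev, 0)]
  }
  lam_tau <- lam_unit(qrM)

  S_tau <- colSums(crossprod(B, R_tau)^2)
  p_tau <- rep(1, K)
  ok <- !degenerate & length(lam_tau) > 0
  if (any(ok))
    p_tau[ok] <- mixture_sf(S_tau[ok] / s2_tau[ok], lam_tau)

  C <- bundle$E * (bundle$G %*% bundle$W)
  Sig0 <- crossprod(C, qr.resid(qrV, C))
  Sig0 <- (Sig0 + t(Sig0)) / 2
  es <- eigen(Sig0, symmetric = TRUE)
  pos <- es$values > EIG_TOL * max(es$values, 0)
  df <- sum(pos)
  p_pi <- rep(1, K)
  if (df > 0) {
    U <- crossprod(C, R_full)                    # q x K
    Uo <- crossprod(es$vectors[, pos, drop = FALSE], U)
    stat <- colSums(Uo^2 / es$values[pos])       # before variance scaling
    okp <- s2_full > 0
    p_pi[okp] <- clamp_p(stats::pchisq(stat[okp] / s2_full[okp], df = df,
                                       lower.tail = FALSE))
    p_pi[degenerate] <- 1
  }

  p_random <- NULL
  if (compute_random) {
    lam_rnd <- lam_unit(qrV)
    S_rnd <- colSums(crossprod(B, R_full)^2)
    p_random <- rep(1, K)
    okr <- !degenerate & length(lam_rnd) > 0
    if (any(okr))
      p_random[okr] <- mixture_sf(S_rnd[okr] / s2_full[okr], lam_rnd)
  }

  list(p_pi = p_pi, p_tau = p_tau,
       p_fisher = combine_fisher(p_pi, p_tau),
       p_tippett = combine_tippett(p_pi, p_tau),
       p_random = p_random, degenerate = degenerate)
}

# Generic per-voxel loop (logit link).
voxelwise_loop <- function(bundle, Yv, link, omega, main_effects,
                           compute_random) {
  K <- ncol(Yv)
  p_pi <- p_tau <- p_fisher <- p_tippett <- p_random <- rep(1, K)
  degenerate <- logical(K)
  for (k in seq_len(K)) {
    y <- Yv[, k]
    if (stats::var(y) == 0) {
      degenerate[k] <- TRUE
      next
    }
    bk <- bundle
    bk$Y <- y
    bk$binary <- all(y %in% c(0, 1))
    r <- mixge_test(bk, link = link, omega = omega,
                    main_effects = main_effects,
                    compute_random = compute_random)
    p_pi[k] <- r$p_pi
    p_tau[k] <- r$p_tau
    p_fisher[k] <- r$p_fisher
    p_tippett[k] <- r$p_tippett
    if (compute_random) p_random[k] <- r$p_random
    degenerate[k] <- r$diagnostics$degenerate_tau && r$diagnostics$degenerate_pi
  }
  list(p_pi = p_pi, p_tau = p_tau, p_fisher = p_fisher,
       p_tippett = p_tippett,
       p_random = if (compute_random) p_random, degenerate = degenerate)
}

#' Read a voxelwise phenotype matrix
#'
#' Reads a subjects-by-voxels matrix from delimited text, or from a 4-D
#' NIfTI volume (x, y, z, subject; requires the RNifti package) with an
#' optional 3-D mask volume selecting the voxels to test.
#'
#' @param path Path to a delimited matrix or a `.nii`/`.nii.gz` file.
#' @param mask Optional path to a 3-D mask volume (non-zero = keep); NIfTI
#'   input only.
#' @return A list: `matrix` (subjects x voxels), `voxel_index` (for image
#'   input, the linear 3-D grid index of each column; otherwise `NULL`),
#'   and `dim` (the 3-D grid dimensions, or `NULL`).
#' @export
read_voxel_phenotypes <- function(path, mask = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI input requires the RNifti package")
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L)
      stop("expected a 4-D volume (x, y, z, subject); got dims ",
           paste(d, collapse = "x"))
    nvox <- prod(d[1:3])
    m <- t(matrix(img, nrow = nvox, ncol = d[4]))
    idx <- seq_len(nvox)
    if (!is.null(mask)) {
      mk <- RNifti::readNifti(mask)
      if (!all(dim(mk)[1:3] == d[1:3]))
        stop("mask dimensions do not match the phenotype volume")
      idx <- which(as.vector(mk) != 0)
      m <- m[, idx, drop = FALSE]
    }
    list(matrix = m, voxel_index = idx, dim = d[1:3])
  } else {
    list(matrix = read_numeric_matrix(path), voxel_index = NULL, dim = NULL)
  }
}
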