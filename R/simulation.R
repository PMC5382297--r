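# Generative models for the type-I error and power study.
#
# Binary phenotype:
#   logit P(Y=1) = log(0.01/0.99) + 0.64 E + sum_j a_j G_j + sum_j b_j E G_j
#   with E ~ N(0,1), G_j Hardy-Weinberg at MAF_j ~ U(0, 0.5); subjects are
#   accrued until the case and control quotas are both met.
# Continuous phenotype:
#   Y = 0.64 E + sum_j a_j G_j + sum_j b_j E G_j + eps,  eps ~ N(0, sigma^2)
#   (no intercept; it models disease prevalence and is meaningless here).

#' Generate Hardy-Weinberg genotypes
#'
#' Draws an `n x p` matrix of minor-allele counts with per-SNP genotype
#' probabilities `(1-f)^2`, `2 f (1-f)`, `f^2` at minor-allele frequency `f`.
#'
#' @param n Number of subjects.
#' @param p Number of SNPs.
#' @param maf Minor-allele frequencies, recycled to length `p`; entries in
#'   `(0, 0.5]` (0 is allowed and yields an all-zero column).
#' @param seed Optional integer seed; when given, the draw is deterministic
#'   and the caller's random stream is left untouched.
#' @return Integer-valued `n x p` matrix with entries in `{0, 1, 2}`.
#' @export
gen_genotypes_hwe <- function(n, p, maf, seed = NULL) {
  maf <- rep_len(as.numeric(maf), p)
  if (any(maf < 0 | maf > 0.5)) stop("maf values must lie in [0, 0.5]")
  draw <- function() {
    u <- matrix(stats::runif(n * p), n, p)
    p0 <- matrix((1 - maf)^2, n, p, byrow = TRUE)
    p01 <- matrix((1 - maf)^2 + 2 * maf * (1 - maf), n, p, byrow = TRUE)
    (u > p0) + (u > p01)
  }
  G <- if (is.null(seed)) draw() else with_seed(seed, draw())
  storage.mode(G) <- "double"
  G
}

#' Define a simulation scenario
#'
#' Bundles the generative configuration for the binary and continuous
#' phenotype models: effect vectors, effect scale, sample sizes, noise
#' variance and replication settings. Usually built through
#' [scenario_presets()]; this constructor is the general entry point.
#'
#' @param phenotype_kind `"binary"` or `"continuous"`.
#' @param n_cases,n_controls Case/control quotas per replicate (binary).
#' @param n_subjects Subjects per replicate (continuous).
#' @param p_snps Number of SNPs in the set (default 8).
#' @param a_vector Main-effect coefficients: a length-`p_snps` numeric
#'   vector, or `"random"` to redraw `a_j ~ Bernoulli(0.5) x
#'   (1 - 2 Bernoulli(0.5))` each replicate (the power-study law).
#' @param b_vector Interaction coefficients (length `p_snps`; zero vector
#'   under the null).
#' @param noise_variance Gaussian noise variance `sigma^2` (continuous only).
#' @param intercept Logit intercept, default `log(0.01/0.99)` (1% baseline
#'   prevalence).
#' @param env_coeff Coefficient of the environmental exposure, default 0.64.
#' @param maf_min,maf_max Per-replicate MAFs are drawn uniformly on
#'   `(maf_min, maf_max)`; defaults 0.005 (degeneracy floor) and 0.5.
#' @param reps Default number of replicates for [run_rejection_rate()].
#' @param seed Default seed.
#' @param alpha Significance threshold, default 0.05.
#' @return A `mixge_scenario` list.
#' @export
simulation_scenario <- function(phenotype_kind = c("binary", "continuous"),
                                n_cases = 100, n_controls = 100,
                                n_subjects = 200, p_snps = 8,
                                a_vector = "random",
                                b_vector = rep(0, p_snps),
                                noise_variance = 1,
                                intercept = log(0.01 / 0.99),
                                env_coeff = 0.64,
                                maf_min = 0.005, maf_max = 0.5,
                                reps = 10000, seed = 20170406, alpha = 0.05) {
  phenotype_kind <- match.arg(phenotype_kind)
  if (is.numeric(a_vector) && length(a_vector) != p_snps)
    stop("a_vector must have length p_snps")
  if (length(b_vector) != p_snps)
    stop("b_vector must have length p_snps")
  if (noise_variance < 0) stop("noise_variance must be non-negative")
  stopifnot(n_cases >= 1, n_controls >= 1, n_subjects >= 1, reps >= 1,
            maf_min >= 0, maf_max <= 0.5, maf_min < maf_max)
  structure(
    list(phenotype_kind = phenotype_kind,
         n_cases = n_cases, n_controls = n_controls,
         n_subjects = n_subjects, p_snps = p_snps,
         a_vector = a_vector, b_vector = as.numeric(b_vector),
         noise_variance = noise_variance,
         intercept = intercept, env_coeff = env_coeff,
         maf_min = maf_min, maf_max = maf_max,
         reps = reps, seed = seed, alpha = alpha),
    class = "mixge_scenario")
}

resolve_a <- function(scenario) {
  if (is.numeric(scenario$a_vector)) return(scenario$a_vector)
  # a_j ~ Bernoulli(0.5) x (1 - 2 Bernoulli(0.5)): 0 w.p. 1/2, +-1 w.p. 1/4
  stats::rbinom(scenario$p_snps, 1, 0.5) *
    (1 - 2 * stats::rbinom(scenario$p_snps, 1, 0.5))
}

draw_maf <- function(scenario) {
  pmax(stats::runif(scenario$p_snps, 0, scenario$maf_max), scenario$maf_min)
}

# Accrual cap per replicate (see the methods vignette).
MAX_ACCRUAL <- 1e7

#' Simulate one binary-phenotype replicate
#'
#' Draws `E ~ N(0, 1)` and Hardy-Weinberg genotypes, computes the success
#' probability as the inverse logit of the binary generative model, performs
#' Bernoulli trials, and accrues subjects until the case and control quotas
#' are both met (overflow discarded). Per-SNP MAFs are drawn once per
#' replicate.
#'
#' @param scenario A `mixge_scenario` with `phenotype_kind = "binary"`.
#' @param seed Optional integer seed (deterministic, stream-preserving).
#' @param max_accrual Cap on the total number of subject draws before the
#'   quota search is declared degenerate (default `1e7`).
#' @return A [mixge_bundle()] with `n_cases + n_controls` subjects,
#'   intercept-only covariates and the default burden weights; the MAFs and
#'   main-effect vector used are attached as attributes `maf` and `a`.
#' @export
simulate_binary <- function(scenario, seed = NULL, max_accrual = MAX_ACCRUAL) {
  stopifnot(inherits(scenario, "mixge_scenario"))
  if (scenario$phenotype_kind != "binary")
    stop("scenario is not a binary-phenotype scenario")
  if (!is.null(seed))
    return(with_seed(seed, simulate_binary(scenario, max_accrual = max_accrual)))

  p <- scenario$p_snps
  maf <- draw_maf(scenario)
  a <- resolve_a(scenario)
  b <- scenario$b_vector
  need_cases <- scenario$n_cases
  need_controls <- scenario$n_controls

  E_keep <- numeric(0)
  G_keep <- matrix(0, 0, p)
  Y_keep <- numeric(0)
  drawn <- 0L
  batch <- max(1000L, 4L * (need_cases + need_controls))
  while (need_cases > 0L || need_controls > 0L) {
    if (drawn >= max_accrual)
      stop("case/control quota not reached within ", max_accrual,
           " subject draws; success probability is degenerate")
    k <- as.integer(min(batch, max_accrual - drawn))
    E <- stats::rnorm(k)
    G <- gen_genotypes_hwe(k, p, maf)
    eta <- scenario$intercept + scenario$env_coeff * E +
      drop(G %*% a) + E * drop(G %*% b)
    Y <- stats::rbinom(k, 1, stats::plogis(eta))
    drawn <- drawn + k
    take_case <- which(Y == 1)[seq_len(min(need_cases, sum(Y == 1)))]
    take_ctrl <- which(Y == 0)[seq_len(min(need_controls, sum(Y == 0)))]
    take <- sort(c(take_case, take_ctrl))
    if (length(take)) {
      E_keep <- c(E_keep, E[take])
      G_keep <- rbind(G_keep, G[take, , drop = FALSE])
      Y_keep <- c(Y_keep, Y[take])
      need_cases <- need_cases - length(take_case)
      need_controls <- need_controls - length(take_ctrl)
    }
    # scale later batches by the observed case rate
    rate <- max(sum(Y_keep), 1) / drawn
    batch <- as.integer(min(5e5, max(2000, 1.5 * need_cases / rate)))
  }
  out <- mixge_bundle(Y = Y_keep, E = E_keep, G = G_keep)
  attr(out, "maf") <- maf
  attr(out, "a") <- a
  out
}

#' Simulate one continuous-phenotype replicate
#'
#' Draws `n_subjects` rows of `Y = 0.64 E + sum a_j G_j + sum b_j E G_j +
#' eps` with `eps ~ N(0, sigma^2)`; no case/control quota applies.
#'
#' @param scenario A `mixge_scenario` with `phenotype_kind = "continuous"`.
#' @inheritParams simulate_binary
#' @return A [mixge_bundle()]; attributes as in [simulate_binary()].
#' @export
simulate_continuous <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "mixge_scenario"))
  if (scenario$phenotype_kind != "continuous")
    stop("scenario is not a continuous-phenotype scenario")
  if (!is.null(seed)) return(with_seed(seed, simulate_continuous(scenario)))

  n <- scenario$n_subjects
  p <- scenario$p_snps
  maf <- draw_maf(scenario)
  a <- resolve_a(scenario)
  b <- scenario$b_vector
  E <- stats::rnorm(n)
  G <- gen_genotypes_hwe(n, p, maf)
  Y <- scenario$env_coeff * E + drop(G %*% a) + E * drop(G %*% b) +
    stats::rnorm(n, 0, sqrt(scenario$noise_variance))
  out <- mixge_bundle(Y = Y, E = E, G = G)
  attr(out, "maf") <- maf
  attr(out, "a") <- a
  out
}

#' Estimate rejection rates of a test over simulated replicates
#'
#' Regenerates genotypes, exposure (and, for power runs, the main-effect
#' vector) for every replicate, runs a pluggable test, and reports the
#' proportion of replicates with p-value below `alpha`. The scenario seed
#' spawns an independent sub-seed per replicate, so results are bit-identical
#' for a given `(scenario, seed, reps)` regardless of chunking.
#'
#' @param scenario A `mixge_scenario`.
#' @param test Function mapping a [mixge_bundle()] to a (preferably named)
#'   vector of p-values. The default runs [mixge_test()] and returns
#'   `p_pi`, `p_tau`, `p_fisher` and `p_tippett`.
#' @param reps Number of replicates (default `scenario$reps`).
#' @param alpha Rejection threshold (default `scenario$alpha`).
#' @param seed Integer seed (default `scenario$seed`).
#' @return A `mixge_sim_result`: `rejection_rate` (the `p_fisher` rate when
#'   present, otherwise the first column), per-method `rates`,
#'   `monte_carlo_se`, the full `pvalues` matrix (`reps x methods`), `reps`
#'   and `alpha`.
#' @examples
#' sc <- scenario_presets("type1", "continuous", "small")
#' run_rejection_rate(sc, reps = 100, seed = 1)$rejection_rate
#' @export
run_rejection_rate <- function(scenario, test = NULL,
                               reps = scenario$reps,
                               alpha = scenario$alpha,
                               seed = scenario$seed) {
  stopifnot(inherits(scenario, "mixge_scenario"), reps >= 1)
  if (is.null(test)) {
    # per-variant main-effect adjustment: the generative models carry
    # heterogeneous per-SNP main effects (zero burden sum in the type-I
    # design), which the collapsed GW term cannot absorb
    link <- if (scenario$phenotype_kind == "binary") "logit" else "identity"
    test <- function(bundle) {
      r <- mixge_test(bundle, link = link, main_effects = "per_variant",
                      separation = "prune", compute_random = FALSE)
      c(p_pi = r$p_pi, p_tau = r$p_tau,
        p_fisher = r$p_fisher, p_tippett = r$p_tippett)
    }
  }
  gen <- if (scenario$phenotype_kind == "binary") simulate_binary
         else simulate_continuous

  pvals <- with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
    rows <- vector("list", reps)
    for (i in seq_len(reps)) {
      set.seed(rep_seeds[i])
      rows[[i]] <- tryCatch(test(gen(scenario)), error = function(e)
        stop("replicate ", i, ": ", conditionMessage(e), call. = FALSE))
    }
    do.call(rbind, rows)
  })
  if (is.null(colnames(pvals)) && ncol(pvals) == 1L)
    colnames(pvals) <- "p"
  rates <- colMeans(pvals < alpha)
  main <- if ("p_fisher" %in% names(rates)) rates[["p_fisher"]] else rates[[1]]
  structure(
    list(rejection_rate = main, rates = rates,
         monte_carlo_se = sqrt(rates * (1 - rates) / reps),
         pvalues = pvals, reps = reps, alpha = alpha),
    class = "mixge_sim_result")
}

#' @export
print.mixge_sim_result <- function(x, ...) {
  cat(sprintf("Rejection rates over %d replicates at alpha = %g\n",
              x$reps, x$alpha))
  tab <- rbind(rate = x$rates, se = x$monte_carlo_se)
  print(round(tab, 4))
  invisible(x)
}

#' Study-design presets for the simulation engine
#'
#' Returns a ready-made scenario for the type-I error design (fixed
#' `a = (1, 1, -1, -1, 0, 0, 0, 0)`, `b = 0`) or one of the three power
#' designs, in which `a_j` is redrawn each replicate and `b` is a scenario
#' template scaled by `C`: all-ones for `"burden"`,
#' `(1, 1, -1, -1, 0, 0, 0, 0)` (zero mean) for `"variance"`, and
#' `(1, 1, 0, 0, 0.5, 0.5, 0.5, 0.5)` for `"mixed"`. Small samples are
#' 100 cases/100 controls (binary) or 200 subjects (continuous); large
#' samples are 1,000/1,000 or 2,000. Binary power designs vary `C` over the
#' study grid (exposed as `$grid`); continuous designs fix `C = 1` and vary
#' the noise variance `sigma^2` instead.
#'
#' @param name One of `"type1"`, `"burden"`, `"variance"`, `"mixed"`.
#' @param phenotype_kind `"binary"` or `"continuous"`.
#' @param sample_size `"small"` or `"large"`.
#' @param C Effect scale; defaults to the first grid value (binary power
#'   designs; ignored for continuous, where `C = 1`).
#' @param sigma2 Noise variance; defaults to the first grid value
#'   (continuous designs).
#' @param ... Further arguments passed to [simulation_scenario()]
#'   (e.g. `reps`, `seed`, `alpha`).
#' @return A `mixge_scenario` with extra fields `preset`, `sample_size`,
#'   `C`, and `grid` (the study grid of `C` or `sigma^2` values, named
#'   accordingly).
#' @export
scenario_presets <- function(name = c("type1", "burden", "variance", "mixed"),
                             phenotype_kind = c("binary", "continuous"),
                             sample_size = c("small", "large"),
                             C = NULL, sigma2 = NULL, ...) {
  name <- match.arg(name)
  phenotype_kind <- match.arg(phenotype_kind)
  sample_size <- match.arg(sample_size)
  small <- sample_size == "small"

  template <- switch(name,
    type1 = rep(0, 8),
    burden = rep(1, 8),
    variance = c(1, 1, -1, -1, 0, 0, 0, 0),
    mixed = c(1, 1, 0, 0, 0.5, 0.5, 0.5, 0.5))

  if (phenotype_kind == "binary") {
    grid <- switch(name,
      type1 = numeric(0),
      burden = if (small) c(0.4, 0.8, 1.2, 1.6, 2)
               else c(0.05, 0.1, 0.15, 0.2, 0.25),
      variance = if (small) c(0.4, 0.8, 1.2, 1.6, 2)
                 else c(0.1, 0.2, 0.3, 0.4, 0.5),
      mixed = if (small) c(0.8, 1.6, 2.4, 3.2, 4)
              else c(0.1, 0.2, 0.3, 0.4, 0.5))
    grid_name <- "C"
    if (is.null(C)) C <- if (name == "type1") 0 else grid[1]
  } else {
    grid <- if (small) c(2, 4, 6, 8, 10) else c(8, 16, 24, 32, 40)
    grid_name <- "sigma2"
    C <- if (name == "type1") 0 else 1
    if (is.null(sigma2)) sigma2 <- grid[1]
  }

  sc <- simulation_scenario(
    phenotype_kind = phenotype_kind,
    n_cases = if (small) 100 else 1000,
    n_controls = if (small) 100 else 1000,
    n_subjects = if (small) 200 else 2000,
    p_snps = 8,
    a_vector = if (name == "type1") c(1, 1, -1, -1, 0, 0, 0, 0) else "random",
    b_vector = C * template,
    noise_variance = if (phenotype_kind == "continuous" && !is.null(sigma2))
      sigma2 else 1,
    ...)
  sc$preset <- name
  sc$sample_size <- sample_size
  sc$C <- C
  sc$grid <- grid
  sc$grid_parameter <- grid_name
  sc
}
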