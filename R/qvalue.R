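# Storey-style false discovery rate control for voxelwise (or gene-wise)
# p-value collections.

#' Storey q-values
#'
#' Estimates the null proportion `pi0 = #\{p > lambda\} / (m (1 - lambda))`
#' and converts p-values to q-values by the step-up rule
#' `q_(i) = min_{j >= i} pi0 m p_(j) / j`. With `pi0` forced to 1 this is
#' exactly the Benjamini-Hochberg adjustment. A non-positive `pi0` estimate
#' (all p-values at or below `lambda`) falls back conservatively to 1, and
#' estimates above 1 are clamped to 1.
#'
#' @param pvals P-values in `[0, 1]`, length `>= 1`.
#' @param lambda Tuning parameter in `[0, 1)` for the `pi0` estimate
#'   (default 0.5), or `"smoother"` for the spline-extrapolated automatic
#'   estimate over `lambda = 0.05, 0.10, ..., 0.95`.
#' @param pi0 Optional override for the null proportion (e.g. `pi0 = 1` for
#'   the Benjamini-Hochberg adjustment).
#' @return A `mixge_qvalue`: `qvalues` (same order as `pvals`), `pi0`, and
#'   `lambda`.
#' @references Storey, J.D. (2002). A direct approach to false discovery
#'   rates. JRSS-B 64, 479-498.
#' @examples
#' p <- c(0.001, 0.02, 0.2, 0.8)
#' storey_qvalues(p, pi0 = 1)$qvalues  # = p.adjust(p, "BH")
#' @export
storey_qvalues <- function(pvals, lambda = 0.5, pi0 = NULL) {
  pvals <- as.numeric(pvals)
  m <- length(pvals)
  if (m == 0L) stop("empty p-value vector")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1] with no missing values")

  if (is.null(pi0)) {
    if (identical(lambda, "smoother")) {
      grid <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(grid, function(l) mean(pvals > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(grid, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(grid))$y
      lambda <- NA_real_
    } else {
      stopifnot(is.numeric(lambda), lambda >= 0, lambda < 1)
      pi0 <- sum(pvals > lambda) / (m * (1 - lambda))
    }
    if (pi0 <= 0) pi0 <- 1        # conservative fallback (= BH)
    pi0 <- min(pi0, 1)
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
    lambda <- NA_real_
  }

  o <- order(pvals)
  q_sorted <- pi0 * m * pvals[o] / seq_len(m)
  q_sorted <- pmin(rev(cummin(rev(q_sorted))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(qvalues = q, pi0 = pi0, lambda = lambda),
            class = "mixge_qvalue")
}

#' Threshold a q-value map
#'
#' @param q A `mixge_qvalue` from [storey_qvalues()] (or a bare numeric
#'   vector of q-values).
#' @param cutoff Significance level on the q scale, in `(0, 1)`;
#'   default 0.05.
#' @return Logical mask, `TRUE` where `qvalue <= cutoff`.
#' @export
threshold_map <- function(q, cutoff = 0.05) {
  stopifnot(cutoff > 0, cutoff < 1)
  qv <- if (inherits(q, "mixge_qvalue")) q$qvalues else as.numeric(q)
  qv <= cutoff
}

#' @export
print.mixge_qvalue <- function(x, ...) {
  cat(sprintf("Storey q-values: m = %d, pi0 = %.4f%s\n",
              length(x$qvalues), x$pi0,
              if (is.na(x$lambda)) "" else sprintf(" (lambda = %g)", x$lambda)))
  invisible(x)
}
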