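# Shared fixtures: small hand-checkable bundles and brute-force oracles.

# N = 6, p = 2 bundle with integer entries (plus a little noise in Y so the
# fits are non-degenerate). Small enough for hand/naive-loop verification.
toy_bundle <- function() {
  G <- matrix(c(0, 1, 2, 1, 0, 2,
                1, 0, 1, 2, 2, 0), ncol = 2)
  E <- c(1, -1, 2, 0, -2, 1)
  Y <- c(2, -1, 4, 1, -3, 3) + c(0.3, -0.2, 0.1, 0.4, -0.1, 0.2)
  mixge_bundle(Y = Y, E = E, G = G)
}

# Gaussian null bundle: no interaction, optional main effects.
make_null_bundle <- function(n = 150, p = 4, a = rep(0, p), sigma = 1,
                             maf = NULL) {
  if (is.null(maf)) maf <- runif(p, 0.1, 0.5)
  G <- gen_genotypes_hwe(n, p, maf)
  E <- rnorm(n)
  Y <- 0.64 * E + drop(G %*% a) + rnorm(n, 0, sigma)
  mixge_bundle(Y = Y, E = E, G = G)
}

# Naive triple-loop evaluation of r' diag(E) G omega G' diag(E) r.
triple_loop_quadform <- function(r, E, G, omega = rep(1, ncol(G))) {
  n <- length(r)
  p <- ncol(G)
  s <- 0
  for (j in seq_len(p)) {
    uj <- 0
    for (i in seq_len(n)) uj <- uj + E[i] * G[i, j] * r[i]
    s <- s + omega[j] * uj^2
  }
  s
}

# Write a small plain-text VCF with the given genotype strings (one vector
# of sample fields per variant row).
write_toy_vcf <- function(path, rows, samples = c("S1", "S2", "S3")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}
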