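# Readers for the standard input formats, gene-set extraction and
# environment construction.

#' Read a genotype matrix from VCF or delimited text
#'
#' Produces a subjects-by-SNPs matrix of minor-allele counts 0/1/2. The
#' minor allele is defined by the sample: when the counted allele reaches a
#' frequency above 0.5 the coding is flipped to `2 - g` (ties at exactly 0.5
#' keep the ALT allele as minor). Missing calls are returned as `NA` and are
#' imputed downstream by [mixge_bundle()]. Non-biallelic VCF records are
#' skipped with a message.
#'
#' @param path Path to a VCF file (`.vcf` / `.vcf.gz`; requires the vcfR
#'   package) or a delimited text matrix (header = SNP ids, one row per
#'   subject, entries 0/1/2 or NA).
#' @param format `"auto"` (by extension), `"vcf"` or `"delimited"`.
#' @param recode_minor Logical; apply the sample-frequency flip rule
#'   (default `TRUE`).
#' @param sep Field separator for the delimited reader (default whitespace).
#' @return A list: `genotypes` (numeric matrix, subjects x SNPs), `info`
#'   (data frame with `snp_id`, `chrom`, `pos`, `ref`, `alt`, `maf`,
#'   `flipped`, `n_missing`), and `n_skipped` (non-biallelic records).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "delimited"),
                           recode_minor = TRUE, sep = "") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "delimited"
  if (!file.exists(path)) stop("file not found: ", path)

  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    bi <- vcfR::is.biallelic(v)
    n_skipped <- sum(!bi)
    if (n_skipped > 0) {
      message("skipped ", n_skipped, " non-biallelic site(s)")
      v <- v[bi, ]
    }
    fix <- vcfR::getFIX(v)
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      al <- strsplit(g, "[/|]")
      vapply(al, function(x) {
        if (any(x == "." | is.na(x))) return(NA_real_)
        sum(x == "1")
      }, numeric(1))
    }
    dos <- t(apply(gt, 1L, count_alt))          # variants x subjects
    if (nrow(gt) == 1L) dos <- matrix(dos, nrow = 1L)
    G <- t(dos)                                  # subjects x variants
    rownames(G) <- colnames(gt)
    id <- fix[, "ID"]
    noid <- is.na(id) | id == "."
    id[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
    colnames(G) <- id
    info <- data.frame(
      snp_id = id,
      chrom = fix[, "CHROM"],
      pos = as.numeric(fix[, "POS"]),
      ref = fix[, "REF"],
      alt = fix[, "ALT"],
      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE)
    G <- as.matrix(tab)
    storage.mode(G) <- "double"
    obs <- G[!is.na(G)]
    if (!all(obs %in% c(0, 1, 2)))
      stop("delimited genotype entries must be 0, 1, 2 or NA")
    if (is.null(colnames(G)))
      colnames(G) <- paste0("snp", seq_len(ncol(G)))
    info <- data.frame(
      snp_id = colnames(G),
      chrom = NA_character_, pos = NA_real_,
      ref = NA_character_, alt = NA_character_,
      stringsAsFactors = FALSE)
    n_skipped <- 0L
  }

  info$n_missing <- colSums(is.na(G))
  freq <- colMeans(G, na.rm = TRUE) / 2
  info$flipped <- FALSE
  if (recode_minor) {
    flip <- !is.na(freq) & freq > 0.5           # ties stay on ALT
    if (any(flip)) {
      G[, flip] <- 2 - G[, flip]
      info$flipped <- flip
      freq[flip] <- 1 - freq[flip]
    }
  }
  info$maf <- freq
  list(genotypes = G, info = info,
       n_skipped = if (format == "vcf") n_skipped else 0L)
}

#' Define a variant set
#'
#' A variant set is either an explicit list of SNP ids, or a genomic
#' interval (1-based, inclusive) extended by a flank on both sides -- the
#' gene +/- 20 kb convention used to build per-gene SNP sets.
#'
#' @param set_name Label for the set.
#' @param chrom,start,end Genomic interval of the gene body (1-based,
#'   inclusive, `start <= end`).
#' @param flank Flank length in bp added on both sides (default 20,000).
#' @param snp_ids Alternative to the interval: explicit SNP ids.
#' @return A `mixge_variant_set`.
#' @export
variant_set <- function(set_name, chrom = NULL, start = NULL, end = NULL,
                        flank = 20000, snp_ids = NULL) {
  if (is.null(snp_ids)) {
    if (is.null(chrom) || is.null(start) || is.null(end))
      stop("provide either snp_ids or a (chrom, start, end) interval")
    stopifnot(start <= end, flank >= 0)
  }
  structure(list(set_name = set_name, chrom = chrom,
                 start = start, end = end, flank = flank,
                 snp_ids = snp_ids),
            class = "mixge_variant_set")
}

#' Extract the genotype columns belonging to a variant set
#'
#' Interval sets select SNPs with position in `[start - flank, end + flank]`
#' (inclusive endpoints, 1-based) on the matching chromosome; id sets select
#' by exact `snp_id` match. An empty result raises a warning, not an error.
#'
#' @param snp_info Data frame with columns `snp_id`, `chrom`, `pos` (as
#'   returned by [read_genotypes()]).
#' @param definition A [variant_set()].
#' @return Integer vector of column indices into the genotype matrix.
#' @export
extract_variant_set <- function(snp_info, definition) {
  stopifnot(inherits(definition, "mixge_variant_set"))
  if (!is.null(definition$snp_ids)) {
    idx <- which(snp_info$snp_id %in% definition$snp_ids)
  } else {
    lo <- definition$start - definition$flank
    hi <- definition$end + definition$flank
    idx <- which(snp_info$chrom == definition$chrom &
                 !is.na(snp_info$pos) &
                 snp_info$pos >= lo & snp_info$pos <= hi)
  }
  if (length(idx) == 0L)
    warning("variant set '", definition$set_name, "' matched no SNPs")
  idx
}

#' Condense several risk variables into one exposure (first PC)
#'
#' Standardizes each column of a subjects-by-variables risk table to mean 0
#' and variance 1 and returns the first principal component, its loadings
#' and the fraction of total variance it explains. The score sign is fixed
#' so that the largest-magnitude loading is positive. A single exposure of
#' this kind is what the interaction model takes as `E`.
#'
#' @param env_table Numeric matrix or data frame, subjects x k risk
#'   variables, `k >= 2`, no constant column.
#' @return A list: `scores` (length N), `loadings` (length k),
#'   `variance_fraction`.
#' @examples
#' tab <- cbind(age = rnorm(50, 70, 5), bmi = rnorm(50, 26, 3))
#' e <- build_environment_pc1(tab)
#' e$variance_fraction
#' @export
build_environment_pc1 <- function(env_table) {
  Z <- as.matrix(env_table)
  storage.mode(Z) <- "double"
  if (ncol(Z) < 2) stop("need at least two risk variables")
  if (anyNA(Z)) stop("env_table contains missing values")
  sds <- apply(Z, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(Z)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant risk variable column: ", paste(bad, collapse = ", "))
  }
  Zs <- scale(Z)
  pc <- stats::prcomp(Zs, center = FALSE, scale. = FALSE)
  loadings <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  flip <- sign(loadings[which.max(abs(loadings))])
  if (flip < 0) {
    loadings <- -loadings
    scores <- -scores
  }
  list(scores = unname(scores), loadings = loadings,
       variance_fraction = pc$sdev[1]^2 / sum(pc$sdev^2))
}

# Read a numeric delimited table (header optional) as a matrix; used by the
# CLI with row-count consistency checks across files.
read_numeric_matrix <- function(path, sep = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), if (sep == "") "[ \t,]+" else sep)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(fields))))
  tab <- utils::read.table(path, header = header, sep = sep,
                           check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  m
}
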