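#' Minor-allele frequency per SNP
#'
#' Reference-allele frequencies are estimated as half the mean allele count
#' over the (optionally subset) accessions; the MAF is the smaller of the
#' two allele frequencies. Missing calls are excluded.
#'
#' @param genotypes A `geno_matrix`.
#' @param samples Optional accession ids over which to compute frequencies
#'   (e.g. only the accessions entering a scan).
#' @return Named numeric vector of MAFs, one per SNP.
#' @export
snp_maf <- function(genotypes, samples = NULL) {
  calls <- genotypes$calls
  if (!is.null(samples)) calls <- calls[samples, , drop = FALSE]
  f <- colMeans(calls, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Filter SNPs on minor-allele frequency
#'
#' Removes SNPs whose MAF is strictly below the threshold (a SNP at exactly
#' the threshold is retained). Frequencies are computed over `samples` when
#' given, so the filter can be taken over the accessions that actually enter
#' the model.
#'
#' @inheritParams snp_maf
#' @param threshold MAF cutoff (default 0.05); SNPs with `MAF < threshold`
#'   are dropped.
#' @return A `geno_matrix` restricted to passing SNPs.
#' @export
maf_filter <- function(genotypes, threshold = 0.05, samples = NULL) {
  if (threshold < 0 || threshold > 0.5) {
    abort("`threshold` must lie in [0, 0.5].")
  }
  maf <- snp_maf(genotypes, samples)
  keep <- !is.na(maf) & maf >= threshold
  geno_matrix(
    genotypes$calls[, keep, drop = FALSE],
    genotypes$map[keep, , drop = FALSE]
  )
}

#' Genomic kinship matrix
#'
#' Builds an accession-by-accession similarity matrix used both to correct
#' association scans for population structure and as a proxy for parental
#' genetic distance. Two constructions are provided:
#'
#' * `"standardized"`: allele counts are centred and scaled per SNP
#'   (`(g - 2p) / sqrt(2p(1-p))`), cross-products averaged over SNPs, and
#'   the result normalised to unit mean diagonal (a VanRaden-style
#'   realised-relationship matrix).
#' * `"ibs"`: the proportion of shared alleles,
#'   `mean(1 - |g_i - g_j| / 2)`, in `[0, 1]`.
#'
#' Missing calls are mean-imputed per SNP; monomorphic SNPs are dropped
#' (for `"standardized"`).
#'
#' @param genotypes A `geno_matrix`.
#' @param method `"standardized"` (default) or `"ibs"`.
#' @param max_missing SNPs with a higher missing fraction are dropped.
#' @return Symmetric numeric matrix with accession dimnames.
#' @export
compute_kinship <- function(genotypes, method = c("standardized", "ibs"),
                            max_missing = 0.2) {
  method <- match.arg(method)
  calls <- genotypes$calls
  if (nrow(calls) < 2) abort("Need at least 2 accessions.")
  miss <- colMeans(is.na(calls))
  calls <- calls[, miss <= max_missing, drop = FALSE]
  # mean-impute remaining missing calls per SNP
  if (anyNA(calls)) {
    mu <- colMeans(calls, na.rm = TRUE)
    idx <- which(is.na(calls), arr.ind = TRUE)
    calls[idx] <- mu[idx[, 2]]
  }
  if (method == "standardized") {
    p <- colMeans(calls) / 2
    poly <- p > 0 & p < 1
    if (!any(poly)) abort("All SNPs are monomorphic; kinship undefined.")
    g <- calls[, poly, drop = FALSE]
    p <- p[poly]
    z <- sweep(g, 2, 2 * p)
    z <- sweep(z, 2, sqrt(2 * p * (1 - p)), `/`)
    k <- tcrossprod(z) / ncol(z)
    k <- k / mean(diag(k))
  } else {
    n <- nrow(calls)
    k <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
    # proportion of shared alleles: 1 - |gi - gj| / 2 averaged over SNPs
    for (i in seq_len(n)) {
      d <- abs(sweep(calls, 2, calls[i, ]))
      k[i, ] <- rowMeans(1 - d / 2)
    }
  }
  (k + t(k)) / 2
}

#' Read / write a labelled square kinship matrix
#'
#' Tab-delimited square matrix with accession ids as both header and first
#' column.
#'
#' @param path File path.
#' @return `read_kinship()` returns a symmetric numeric matrix.
#' @export
read_kinship <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!identical(rownames(m), colnames(m))) {
    abort("Kinship file rows and columns must carry identical accession ids.")
  }
  if (max(abs(m - t(m))) > 1e-8) abort("Kinship matrix must be symmetric.")
  m
}

#' @rdname read_kinship
#' @param kinship Symmetric matrix with accession dimnames.
#' @export
write_kinship <- function(kinship, path) {
  df <- tibble::as_tibble(kinship, rownames = "accession")
  readr::write_tsv(df, path)
  invisible(path)
}
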