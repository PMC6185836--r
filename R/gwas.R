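#' Dominant and additive SNP encodings
#'
#' Builds the binary per-SNP predictors used by the association scan.
#'
#' The *dominant* encoding targets the hybrids: a SNP scores 1 where the
#' hybrid is heterozygous — i.e. where its variable parent's allele differs
#' from the common-reference parent's allele — and 0 where it is homozygous.
#' Mapping absolute mid-parent heterosis (which cancels additive gene
#' action) on this predictor estimates the dominance effect `d`.
#'
#' The *additive* encoding targets the parental accessions: a SNP scores 1
#' where the accession is homozygous for the reference parent's allele and 0
#' where it carries two copies of the non-reference allele
#' (`orientation = "reference"`; `"alternate"` flips the coding, changing
#' only the sign of effect estimates). Mapping parental trait means on this
#' predictor estimates twice the additive effect, `2a`.
#'
#' @param parents `geno_matrix` of homozygous parental accessions (including
#'   the reference parent).
#' @param pedigree Pedigree rows of a single population (one reference
#'   parent).
#' @param orientation For the additive encoding: `"reference"` codes the
#'   reference-homozygote as 1 (default), `"alternate"` the reverse.
#' @return An object of class `encoded_design`: list with `X` (samples x
#'   SNPs binary matrix), `samples`, `model`, `maf` (computed over the
#'   variable parents entering the analysis) and `map`.
#' @export
encode_dominant <- function(parents, pedigree) {
  .assert_cols(pedigree, c("hybrid_id", "parent_id", "reference_id"), "`pedigree`")
  ref <- unique(pedigree$reference_id)
  if (length(ref) != 1) {
    abort("Dominant encoding needs a single-population pedigree (one reference).")
  }
  need <- c(unique(pedigree$parent_id), ref)
  g <- subset_accessions(parents, need)
  if (any(g$calls == 1L, na.rm = TRUE)) {
    abort("Parents must be inbred (no heterozygous calls).")
  }
  pc <- g$calls[pedigree$parent_id, , drop = FALSE]
  rc <- g$calls[rep(ref, nrow(pedigree)), , drop = FALSE]
  x <- (pc != rc) * 1L
  rownames(x) <- pedigree$hybrid_id
  structure(
    list(
      X = x, samples = pedigree$hybrid_id, model = "dominant",
      maf = snp_maf(parents, samples = unique(pedigree$parent_id)),
      map = parents$map
    ),
    class = "encoded_design"
  )
}

#' @rdname encode_dominant
#' @export
encode_additive <- function(parents, pedigree,
                            orientation = c("reference", "alternate")) {
  orientation <- match.arg(orientation)
  ref <- unique(pedigree$reference_id)
  if (length(ref) != 1) {
    abort("Additive encoding needs a single-population pedigree (one reference).")
  }
  ids <- unique(pedigree$parent_id)
  g <- subset_accessions(parents, c(ids, ref))
  if (any(g$calls == 1L, na.rm = TRUE)) {
    abort("Parents must be inbred (no heterozygous calls).")
  }
  rc <- g$calls[rep(ref, length(ids)), , drop = FALSE]
  x <- (g$calls[ids, , drop = FALSE] == rc) * 1L
  if (orientation == "alternate") x <- 1L - x
  rownames(x) <- ids
  structure(
    list(
      X = x, samples = ids, model = "additive",
      maf = snp_maf(parents, samples = ids),
      map = parents$map
    ),
    class = "encoded_design"
  )
}

#' @export
print.encoded_design <- function(x, ...) {
  cat(sprintf(
    "<encoded_design> %s model: %d samples x %d SNPs\n",
    x$model, nrow(x$X), ncol(x$X)
  ))
  invisible(x)
}

# restricted log-likelihood of the variance ratio lambda = s2_g / s2_e for
# eigen-rotated data; q = ncol(X)
.reml_loglik <- function(lambda, d, yr, xr, logdet_xx) {
  n <- length(yr)
  q <- ncol(xr)
  w <- lambda * d + 1
  xw <- xr / w
  xtx <- crossprod(xr, xw)
  beta <- solve(xtx, crossprod(xw, yr))
  r <- yr - xr %*% beta
  rss <- sum(r^2 / w)
  s2 <- rss / (n - q)
  -0.5 * ((n - q) * log(2 * pi * s2) + (n - q) + sum(log(w)) +
    determinant(xtx, logarithm = TRUE)$modulus - logdet_xx)
}

#' Fit the no-SNP mixed-model null
#'
#' Restricted maximum-likelihood fit of the variance-component model
#' `y = X beta + g + e`, with `g ~ N(0, s2_g K)` and `e ~ N(0, s2_e I)`.
#' The kinship matrix is eigendecomposed once; the variance ratio
#' `lambda = s2_g / s2_e` is maximised over a 61-point log10 grid spanning
#' 1e-5..1e5 with local golden-section refinement, which is deterministic.
#' The fitted components are reused for every SNP by the scan (the
#' population-parameters-previously-determined approximation).
#'
#' @param y Named numeric vector of per-sample responses (names = sample
#'   ids matching the kinship dimnames, or unnamed if already aligned).
#' @param kinship Symmetric PSD kinship matrix covering the samples.
#' @param covariates Optional numeric matrix of additional fixed effects
#'   (an intercept is always included).
#' @return An object of class `null_model_fit`: `lambda`, `sigma2_g`,
#'   `sigma2_e`, `loglik`, `boundary` flag (optimiser at the grid edge, e.g.
#'   `lambda ~ 0` when the trait carries no kinship structure), plus the
#'   eigendecomposition and rotated data reused by [scan_gls()].
#' @export
fit_null_model <- function(y, kinship, covariates = NULL) {
  if (!is.null(names(y))) {
    missing <- setdiff(names(y), rownames(kinship))
    if (length(missing) > 0) {
      abort(sprintf(
        "Kinship rows missing for sample(s): %s",
        paste(head(missing, 5), collapse = ", ")
      ))
    }
    kinship <- kinship[names(y), names(y)]
  }
  n <- length(y)
  if (n < 5) abort("Need at least 5 samples.")
  if (nrow(kinship) != n) abort("Kinship must align with `y`.")
  x <- cbind(`(Intercept)` = rep(1, n), covariates)

  eig <- eigen((kinship + t(kinship)) / 2, symmetric = TRUE)
  d <- eig$values
  if (min(d) < -1e-6 * max(abs(d))) {
    abort("Kinship matrix is not positive semidefinite.")
  }
  d <- pmax(d, 0)
  u <- eig$vectors
  yr <- drop(crossprod(u, y))
  xr <- crossprod(u, x)
  logdet_xx <- determinant(crossprod(x), logarithm = TRUE)$modulus

  grid <- 10^seq(-5, 5, length.out = 61)
  ll <- vapply(grid, .reml_loglik, numeric(1),
    d = d, yr = yr, xr = xr, logdet_xx = logdet_xx
  )
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(
    function(l10) {
      .reml_loglik(10^l10, d = d, yr = yr, xr = xr, logdet_xx = logdet_xx)
    },
    lower = log10(lo), upper = log10(hi), maximum = TRUE, tol = 1e-6
  )
  lambda <- 10^opt$maximum
  loglik <- opt$objective
  if (ll[i] > loglik) { # grid point beats refinement (edge cases)
    lambda <- grid[i]
    loglik <- ll[i]
  }
  boundary <- i %in% c(1L, length(grid))

  w <- lambda * d + 1
  xw <- xr / w
  beta <- solve(crossprod(xr, xw), crossprod(xw, yr))
  rss <- sum((yr - xr %*% beta)^2 / w)
  s2e <- rss / (n - ncol(x))

  structure(
    list(
      lambda = lambda, sigma2_g = lambda * s2e, sigma2_e = s2e,
      loglik = as.numeric(loglik), boundary = boundary,
      n = n, eigenvalues = d, rotation = u, y_rot = yr, x_rot = xr,
      samples = names(y)
    ),
    class = "null_model_fit"
  )
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf(
    "<null_model_fit> n = %d; lambda = %.4g (s2_g = %.4g, s2_e = %.4g); REML logLik = %.3f%s\n",
    x$n, x$lambda, x$sigma2_g, x$sigma2_e, x$loglik,
    if (x$boundary) " [boundary]" else ""
  ))
  invisible(x)
}

#' @rdname fit_null_model
#' @param x A `null_model_fit`.
#' @param ... Unused.
#' @export
glance.null_model_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, lambda = x$lambda, sigma2_g = x$sigma2_g,
    sigma2_e = x$sigma2_e, loglik = x$loglik, boundary = x$boundary
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (with the usual monotonicity
#' enforcement); a thin validated wrapper so scans share one code path.
#'
#' @param p Numeric p-values in `[0, 1]` (`NA` allowed).
#' @return q-values, same length as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Per-SNP generalized-least-squares association scan
#'
#' Regresses the response on each SNP's encoded predictor (plus intercept)
#' under the covariance `s2_g K + s2_e I`, with the variance components held
#' fixed at the null-model fit — the standard two-stage mixed-model
#' approximation. Effect estimate, standard error, and a two-sided p-value
#' from the t statistic (df = n - 2) are reported per SNP, along with the
#' MAF, a Benjamini-Hochberg q-value computed across the scanned SNPs, and
#' significance flags. SNPs whose predictor is constant across samples are
#' skipped (reported with `NA` statistics and a reason). With
#' `exact = TRUE` the variance ratio is re-estimated by REML per SNP
#' (slower; used to check the approximation).
#'
#' @param y Numeric response vector aligned to `design$samples` (or named
#'   by sample id).
#' @param design An [encode_dominant()] / [encode_additive()] design.
#' @param null A [fit_null_model()] object fitted on the same samples (not
#'   needed when `exact = TRUE` and `kinship` is given).
#' @param kinship Kinship matrix, required for `exact = TRUE`.
#' @param maf_threshold SNPs with MAF strictly below this are excluded
#'   (default 0.05); set 0 to keep all.
#' @param raw_threshold Fixed -log10(p) significance cutoff (strict `>`,
#'   default 4).
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param exact Re-fit variance components per SNP instead of reusing the
#'   null fit.
#' @return A `gwas_scan` tibble: one row per scanned SNP with `snp_id`,
#'   `chromosome`, `position`, `model`, `maf`, `effect`, `se`,
#'   `neg_log10_p`, `q`, `sig_raw`, `sig_fdr`, `skipped`. The null fit is
#'   attached as attribute `"null"`.
#' @export
scan_gls <- function(y, design, null = NULL, kinship = NULL,
                     maf_threshold = 0.05, raw_threshold = 4,
                     fdr_alpha = 0.05, exact = FALSE) {
  stopifnot(inherits(design, "encoded_design"))
  if (!is.null(names(y))) y <- y[design$samples]
  n <- length(y)
  if (n != nrow(design$X)) abort("`y` must align with the design samples.")

  keep <- !is.na(design$maf) & design$maf >= maf_threshold
  x_all <- design$X[, keep, drop = FALSE]
  map <- design$map[keep, , drop = FALSE]
  maf <- design$maf[keep]
  m <- ncol(x_all)
  if (m == 0) abort("No SNPs left after MAF filtering.")

  # mean-impute missing predictor values (scan only, never in files)
  if (anyNA(x_all)) {
    mu <- colMeans(x_all, na.rm = TRUE)
    idx <- which(is.na(x_all), arr.ind = TRUE)
    x_all[idx] <- mu[idx[, 2]]
  }
  constant <- apply(x_all, 2, function(v) max(v) == min(v))

  effect <- se <- tstat <- rep(NA_real_, m)
  if (exact) {
    if (is.null(kinship)) abort("`exact = TRUE` requires `kinship`.")
    for (j in which(!constant)) {
      fit <- fit_null_model(setNames(y, design$samples), kinship,
        covariates = cbind(snp = x_all[, j])
      )
      w <- fit$lambda * fit$eigenvalues + 1
      xr <- fit$x_rot
      xw <- xr / w
      xtx <- crossprod(xr, xw)
      beta <- solve(xtx, crossprod(xw, fit$y_rot))
      rss <- sum((fit$y_rot - xr %*% beta)^2 / w)
      s2 <- rss / (n - ncol(xr))
      cov_b <- s2 * solve(xtx)
      effect[j] <- beta["snp", 1]
      se[j] <- sqrt(cov_b["snp", "snp"])
      tstat[j] <- effect[j] / se[j]
    }
    df <- n - 2
  } else {
    if (is.null(null)) abort("Provide a `null` model fit (or use `exact = TRUE`).")
    stopifnot(inherits(null, "null_model_fit"))
    if (null$n != n) abort("Null model was fitted on a different sample size.")
    w <- null$lambda * null$eigenvalues + 1
    u <- null$rotation
    yr <- null$y_rot
    ones_r <- null$x_rot[, 1]
    xr <- crossprod(u, x_all) # n x m rotated predictors
    # vectorised 2x2 GLS per SNP: [intercept, snp]
    a11 <- sum(ones_r^2 / w)
    a12 <- colSums(xr * ones_r / w)
    a22 <- colSums(xr^2 / w)
    b1 <- sum(ones_r * yr / w)
    b2 <- colSums(xr * yr / w)
    det <- a11 * a22 - a12^2
    beta2 <- (a11 * b2 - a12 * b1) / det
    beta1 <- (b1 - a12 * beta2) / a11
    ywy <- sum(yr^2 / w)
    rss <- ywy - (beta1 * b1 + beta2 * b2)
    df <- n - 2
    s2 <- pmax(rss, 0) / df
    ok <- !constant
    effect[ok] <- beta2[ok]
    se[ok] <- sqrt(s2[ok] * a11 / det[ok])
    tstat[ok] <- effect[ok] / se[ok]
  }

  p <- 2 * pt(-abs(tstat), df = df)
  out <- tibble::tibble(
    snp_id = map$snp_id,
    chromosome = map$chromosome,
    position = map$position,
    model = design$model,
    maf = unname(maf),
    effect = effect,
    se = se,
    neg_log10_p = -log10(p),
    q = bh_fdr(p),
    skipped = ifelse(constant, "constant predictor", NA_character_)
  )
  out$sig_raw <- !is.na(out$neg_log10_p) & out$neg_log10_p > raw_threshold
  out$sig_fdr <- !is.na(out$q) & out$q < fdr_alpha
  attr(out, "null") <- if (exact) NULL else null
  attr(out, "raw_threshold") <- raw_threshold
  attr(out, "fdr_alpha") <- fdr_alpha
  class(out) <- c("gwas_scan", class(out))
  out
}

#' @rdname scan_gls
#' @param x A `gwas_scan` tibble.
#' @param ... Unused.
#' @export
tidy.gwas_scan <- function(x, ...) {
  out <- x
  attr(out, "null") <- NULL
  class(out) <- setdiff(class(out), "gwas_scan")
  out
}

#' @rdname scan_gls
#' @export
glance.gwas_scan <- function(x, ...) {
  null <- attr(x, "null")
  tibble::tibble(
    model = x$model[1],
    n_snps = nrow(x),
    n_skipped = sum(!is.na(x$skipped)),
    n_sig_raw = sum(x$sig_raw, na.rm = TRUE),
    n_sig_fdr = sum(x$sig_fdr, na.rm = TRUE),
    lambda = if (is.null(null)) NA_real_ else null$lambda,
    sigma2_g = if (is.null(null)) NA_real_ else null$sigma2_g,
    sigma2_e = if (is.null(null)) NA_real_ else null$sigma2_e
  )
}

#' Significant-SNP report at fixed and FDR thresholds
#'
#' Flags SNPs by the fixed `-log10(p) > raw_threshold` rule (strict
#' inequality) and by `q < fdr_alpha` separately, and returns the flagged
#' rows sorted by position with per-criterion counts attached.
#'
#' @param result A `gwas_scan` tibble.
#' @param raw_threshold Fixed -log10(p) cutoff (default 4).
#' @param fdr_alpha FDR level (default 0.05).
#' @return A tibble of SNPs flagged by either criterion, with logical
#'   columns `sig_raw`, `sig_fdr`; counts are in attribute `"counts"` (also
#'   returned by [glance()]).
#' @export
threshold_report <- function(result, raw_threshold = 4, fdr_alpha = 0.05) {
  result$sig_raw <- !is.na(result$neg_log10_p) &
    result$neg_log10_p > raw_threshold
  result$sig_fdr <- !is.na(result$q) & result$q < fdr_alpha
  out <- result |>
    dplyr::filter(.data$sig_raw | .data$sig_fdr) |>
    dplyr::arrange(.data$chromosome, .data$position)
  attr(out, "counts") <- tibble::tibble(
    n_sig_raw = sum(result$sig_raw),
    n_sig_fdr = sum(result$sig_fdr)
  )
  out
}

#' Allele-class counts over MPH bins at one SNP
#'
#' Cross-tabulates, per population, hybrids that are heterozygous versus
#' homozygous at a chosen SNP against binned relative mid-parent heterosis,
#' the summary used to visualise how a dominant locus concentrates
#' heterozygotes in high-heterosis classes.
#'
#' @param design A dominant [encode_dominant()] design (per-hybrid 0/1
#'   heterozygosity).
#' @param mph Tibble with columns `hybrid_id`, `population`, `mph` (e.g.
#'   one trait's rows of [heterosis_table()]).
#' @param snp_id SNP identifier present in the design.
#' @param breaks Bin edges for MPH (percent); default: bins of width 20
#'   covering the data range.
#' @return A tibble with columns `population`, `bin` (ordered factor),
#'   `mid` (bin midpoint), `n_het`, `n_hom`.
#' @export
allele_class_by_mph_bins <- function(design, mph, snp_id, breaks = NULL) {
  stopifnot(inherits(design, "encoded_design"))
  if (!snp_id %in% colnames(design$X)) {
    abort(sprintf("SNP '%s' not present in the design.", snp_id))
  }
  .assert_cols(mph, c("hybrid_id", "population", "mph"), "`mph`")
  df <- mph |>
    dplyr::filter(
      is.finite(.data$mph),
      .data$hybrid_id %in% rownames(design$X)
    ) |>
    dplyr::mutate(
      het = ifelse(design$X[.data$hybrid_id, snp_id] == 1, "n_het", "n_hom")
    )
  if (is.null(breaks)) {
    lo <- floor(min(df$mph) / 20) * 20
    hi <- ceiling(max(df$mph) / 20) * 20
    if (lo == hi) hi <- lo + 20
    breaks <- seq(lo, hi, by = 20)
  }
  df$bin <- cut(df$mph, breaks = breaks, include.lowest = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- df |>
    dplyr::count(.data$population, .data$bin, .data$het) |>
    tidyr::pivot_wider(
      names_from = "het", values_from = "n",
      values_fill = 0L
    )
  for (col in c("n_het", "n_hom")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out |>
    dplyr::mutate(mid = mids[as.integer(.data$bin)], .after = "bin") |>
    dplyr::arrange(.data$population, .data$bin)
}
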