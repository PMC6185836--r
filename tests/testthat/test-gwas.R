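test_that("kinship of duplicate accessions is maximal; discordant IBS is zero", {
  calls <- rbind(
    a1 = c(0L, 2L, 0L, 2L, 0L, 2L, 0L, 2L),
    a2 = c(0L, 2L, 0L, 2L, 0L, 2L, 0L, 2L), # duplicate of a1
    a3 = c(2L, 0L, 2L, 0L, 2L, 0L, 2L, 0L) # fully discordant
  )
  g <- toy_genotypes(calls)
  ibs <- compute_kinship(g, method = "ibs")
  expect_equal(ibs["a1", "a2"], 1)
  expect_equal(ibs["a1", "a3"], 0)
  std <- compute_kinship(g, method = "standardized")
  # duplicates are as similar as an accession is to itself, and more similar
  # than any non-duplicate pair
  expect_equal(std["a1", "a2"], std["a1", "a1"])
  expect_gt(std["a1", "a2"], std["a1", "a3"])
})

test_that("standardized kinship equals a brute-force per-pair computation", {
  set.seed(5)
  calls <- matrix(2L * rbinom(40, 1, 0.4), nrow = 5, ncol = 8)
  g <- toy_genotypes(calls)
  k <- compute_kinship(g, method = "standardized")
  # independent oracle: explicit double loop over pairs and SNPs
  p <- colMeans(calls) / 2
  poly <- p > 0 & p < 1
  z <- matrix(0, 5, sum(poly))
  cols <- which(poly)
  for (j in seq_along(cols)) {
    pj <- p[cols[j]]
    z[, j] <- (calls[, cols[j]] - 2 * pj) / sqrt(2 * pj * (1 - pj))
  }
  raw <- matrix(0, 5, 5)
  for (i in 1:5) {
    for (l in 1:5) {
      raw[i, l] <- mean(z[i, ] * z[l, ])
    }
  }
  raw <- raw / mean(diag(raw))
  expect_equal(unname(k), raw, tolerance = 1e-12)
})

test_that("MAF filter applies a strict < threshold over the analysis samples", {
  # 100 accessions; 4 of 200 alleles minor at SNP 1 -> MAF 0.02, removed
  calls <- matrix(0L, nrow = 100, ncol = 3)
  calls[1:2, 1] <- 2L # MAF 0.02
  calls[1:5, 2] <- 2L # MAF 0.05 exactly -> retained
  calls[1:50, 3] <- 2L # MAF 0.5
  g <- toy_genotypes(calls)
  expect_equal(unname(snp_maf(g)), c(0.02, 0.05, 0.5))
  kept <- maf_filter(g, threshold = 0.05)
  expect_identical(colnames(kept$calls), c("s2", "s3"))
  expect_identical(maf_filter(g, threshold = 0)$calls, g$calls)
})

test_that("encodings match their definitions and flip sign only", {
  panel <- small_panel()
  ped1 <- dplyr::filter(panel$pedigree, population == "pop1")
  dom <- encode_dominant(panel$parents, ped1)
  # dominant predictor is exactly the parent-vs-reference allele difference,
  # recomputed here straight from the pedigree
  for (i in 1:5) {
    expected <- (panel$parents$calls[ped1$parent_id[i], ] !=
      panel$parents$calls[ped1$reference_id[i], ]) * 1L
    expect_identical(unname(dom$X[ped1$hybrid_id[i], ]), unname(expected))
  }
  # and equals the hybrid's heterozygosity indicator
  expect_identical(
    unname(dom$X),
    unname((panel$hybrids$calls[ped1$hybrid_id, ] == 1L) * 1L)
  )

  add_ref <- encode_additive(panel$parents, ped1, orientation = "reference")
  add_alt <- encode_additive(panel$parents, ped1, orientation = "alternate")
  expect_identical(unname(add_alt$X), unname(1L - add_ref$X))

  sums <- summarize_genotypes(panel$traits)
  y <- sums |>
    dplyr::filter(population == "pop1", trait == "HT", genotype_id %in% ped1$parent_id)
  yv <- setNames(y$mean, y$genotype_id)[add_ref$samples]
  k <- compute_kinship(subset_accessions(panel$parents, add_ref$samples))
  null <- fit_null_model(yv, k)
  s_ref <- scan_gls(unname(yv), add_ref, null, maf_threshold = 0)
  s_alt <- scan_gls(unname(yv), add_alt, null, maf_threshold = 0)
  expect_equal(s_alt$effect, -s_ref$effect, tolerance = 1e-9)
  expect_equal(s_alt$neg_log10_p, s_ref$neg_log10_p, tolerance = 1e-9)
})

test_that("null model recovers the simulated variance ratio", {
  set.seed(101)
  n <- 200
  z <- matrix(rnorm(n * 50), n, 50)
  k <- tcrossprod(z) / 50
  k <- k / mean(diag(k))
  ok <- 0
  for (seed in 1:3) {
    set.seed(seed)
    ek <- eigen(k, symmetric = TRUE)
    g <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(n)) * sqrt(3)
    y <- drop(g) + rnorm(n)
    fit <- fit_null_model(y, k)
    if (fit$lambda > 1.5 && fit$lambda < 6) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("structureless traits drive lambda to the boundary", {
  set.seed(55)
  n <- 60
  k <- diag(n)
  dimnames(k) <- list(paste0("s", 1:n), paste0("s", 1:n))
  y <- rnorm(n)
  fit <- fit_null_model(y, k)
  # K = I makes lambda unidentifiable; the optimiser lands on the grid edge
  expect_true(fit$boundary || fit$lambda <= 1e-4 || fit$lambda >= 1e4)
})

test_that("the refined optimum is no worse than any grid point", {
  panel <- small_panel()
  ped1 <- dplyr::filter(panel$pedigree, population == "pop1")
  het <- heterosis_table(panel$traits, panel$pedigree)
  y <- het |>
    dplyr::filter(population == "pop1", trait == "FT")
  k <- compute_kinship(subset_accessions(panel$parents, ped1$parent_id))
  kh <- k[ped1$parent_id, ped1$parent_id]
  dimnames(kh) <- list(ped1$hybrid_id, ped1$hybrid_id)
  fit <- fit_null_model(setNames(y$mph_abs, y$hybrid_id), kh)
  ll_at <- function(lambda) {
    w <- lambda * fit$eigenvalues + 1
    xr <- fit$x_rot
    xw <- xr / w
    xtx <- crossprod(xr, xw)
    beta <- solve(xtx, crossprod(xw, fit$y_rot))
    rss <- sum((fit$y_rot - xr %*% beta)^2 / w)
    n <- fit$n
    s2 <- rss / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi * s2) + (n - 1) + sum(log(w)) +
      determinant(xtx, TRUE)$modulus - determinant(crossprod(xr), TRUE)$modulus)
  }
  grid_ll <- vapply(10^seq(-5, 5, length.out = 61), ll_at, numeric(1))
  expect_gte(ll_at(fit$lambda) + 1e-8, max(grid_ll))
})

test_that("with identity kinship the GLS scan reduces to OLS", {
  set.seed(77)
  n <- 40
  calls <- matrix(2L * rbinom(n * 10, 1, 0.4), n, 10)
  rownames(calls) <- paste0("p", 1:n)
  parents <- toy_genotypes(rbind(calls, ref = rep(0L, 10)))
  ped <- tibble::tibble(
    hybrid_id = paste0("h", 1:n), parent_id = paste0("p", 1:n),
    reference_id = "ref", population = "pop1"
  )
  design <- encode_dominant(parents, ped)
  y <- rnorm(n) + design$X[, 3] * 1.5
  k <- diag(n)
  dimnames(k) <- list(ped$hybrid_id, ped$hybrid_id)
  null <- fit_null_model(setNames(y, ped$hybrid_id), k)
  scan <- scan_gls(y, design, null, maf_threshold = 0)
  for (j in c(1, 3, 7)) {
    ols <- summary(lm(y ~ design$X[, j]))$coefficients
    expect_equal(scan$effect[j], ols[2, "Estimate"], tolerance = 1e-8)
    expect_equal(10^(-scan$neg_log10_p[j]), ols[2, "Pr(>|t|)"], tolerance = 1e-8)
  }
})

test_that("GLS matches a brute-force matrix-inversion oracle on an 8-sample toy", {
  set.seed(88)
  n <- 8
  calls <- rbind(
    matrix(2L * rbinom(n * 6, 1, 0.5), n, 6),
    ref = rep(0L, 6)
  )
  rownames(calls)[1:n] <- paste0("p", 1:n)
  parents <- toy_genotypes(calls)
  ped <- tibble::tibble(
    hybrid_id = paste0("h", 1:n), parent_id = paste0("p", 1:n),
    reference_id = "ref", population = "pop1"
  )
  design <- encode_dominant(parents, ped)
  z <- matrix(rnorm(n * 20), n, 20)
  k <- tcrossprod(z) / 20
  dimnames(k) <- list(ped$hybrid_id, ped$hybrid_id)
  y <- rnorm(n)
  null <- fit_null_model(setNames(y, ped$hybrid_id), k)
  scan <- scan_gls(y, design, null, maf_threshold = 0)
  V <- null$sigma2_g * k + null$sigma2_e * diag(n)
  for (j in seq_len(ncol(design$X))) {
    if (!is.na(scan$skipped[j])) next
    oracle <- brute_force_gls(y, design$X[, j], V)
    expect_equal(scan$effect[j], oracle$effect, tolerance = 1e-8)
    expect_equal(scan$se[j], oracle$se, tolerance = 1e-8)
    expect_equal(10^(-scan$neg_log10_p[j]), oracle$p, tolerance = 1e-8)
  }
})

test_that("the two-stage approximation tracks the exact per-SNP REML scan", {
  # additive-only trait: MPH_ABS carries no SNP signal, the regime in which
  # reusing the null-model variance components is advertised to be accurate
  # (at a strong causal locus the two-stage fit is conservative, since the
  # null model absorbs part of the QTL effect into the genetic variance)
  traits <- tibble::tibble(trait = "HT", baseline = 50, residual_sd = 2)
  cfg <- sim_config(
    n_accessions = 200, n_snps = 30, n_replicates = 4,
    traits = traits, qtls = qtl_spec(15, a = 2, d = 0, trait = "HT"),
    reference_ids = "Col", seed = 61
  )
  panel <- simulate_panel(cfg)
  het <- heterosis_table(panel$traits, panel$pedigree)
  ped <- panel$pedigree
  design <- encode_dominant(panel$parents, ped)
  k <- compute_kinship(subset_accessions(panel$parents, unique(ped$parent_id)))
  kh <- k[ped$parent_id, ped$parent_id]
  dimnames(kh) <- list(ped$hybrid_id, ped$hybrid_id)
  y <- setNames(het$mph_abs, het$hybrid_id)[ped$hybrid_id]
  null <- fit_null_model(y, kh)
  approx <- scan_gls(unname(y), design, null, maf_threshold = 0)
  exact <- scan_gls(unname(y), design,
    kinship = kh, exact = TRUE,
    maf_threshold = 0
  )
  ok <- is.na(approx$skipped)
  expect_lt(max(abs(approx$neg_log10_p[ok] - exact$neg_log10_p[ok])), 0.2)
})

test_that("BH q-values match hand computation and a brute-force step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (n in c(10, 1000, 10000)) {
    p <- runif(n)^2
    q <- bh_fdr(p)
    expect_equal(q, brute_force_bh(p), tolerance = 1e-15)
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(!is.unsorted(q[o]))
  }
})

test_that("threshold report applies strict cutoffs per criterion", {
  res <- tibble::tibble(
    snp_id = paste0("m", 1:4), chromosome = 1L, position = 1:4,
    model = "dominant", maf = 0.2, effect = 1, se = 1,
    neg_log10_p = c(4.0, 4.1, 6, 1), q = c(0.2, 0.04, 0.001, 0.9)
  )
  rep1 <- threshold_report(res)
  expect_false("m1" %in% rep1$snp_id[rep1$sig_raw]) # exactly 4.0 not flagged
  expect_setequal(rep1$snp_id[rep1$sig_raw], c("m2", "m3"))
  expect_setequal(rep1$snp_id[rep1$sig_fdr], c("m2", "m3"))
  counts <- attr(rep1, "counts")
  expect_equal(counts$n_sig_raw, 2L)
  expect_equal(threshold_report(res[0, ]) |> nrow(), 0L)
})

test_that("FDR-flagged SNPs nest inside raw-flagged ones when more stringent", {
  panel <- small_panel()
  scan <- scan_heterosis(panel$traits, panel$parents, panel$pedigree,
    trait = "FT", model = "dominant", maf_threshold = 0
  )
  rep <- threshold_report(tidy(scan), raw_threshold = 1, fdr_alpha = 0.05)
  raw_set <- rep$snp_id[rep$sig_raw]
  fdr_set <- rep$snp_id[rep$sig_fdr]
  # q >= p always, so q < 0.05 implies p < 0.05, i.e. -log10 p > 1.3 > 1
  expect_true(all(fdr_set %in% raw_set))
})

test_that("allele classes over MPH bins conserve counts and expose dominance", {
  traits <- tibble::tibble(trait = "HT", baseline = 50, residual_sd = 2)
  cfg <- sim_config(
    n_accessions = 100, n_snps = 50, n_replicates = 10,
    traits = traits, qtls = qtl_spec(25, a = 0, d = 2, trait = "HT"),
    reference_ids = "Col", seed = 71
  )
  panel <- simulate_panel(cfg)
  het <- heterosis_table(panel$traits, panel$pedigree)
  design <- encode_dominant(panel$parents, panel$pedigree)
  snp <- colnames(design$X)[25]
  rng <- range(het$mph)
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 7)
  bins <- allele_class_by_mph_bins(design, het, snp, breaks = breaks)
  expect_equal(sum(bins$n_het + bins$n_hom), nrow(het))
  # heterozygotes should concentrate in high-MPH classes: one-sided trend
  keep <- bins$n_het + bins$n_hom > 0
  trend <- stats::prop.trend.test(
    bins$n_het[keep],
    (bins$n_het + bins$n_hom)[keep]
  )
  slope <- cor(bins$mid[keep], (bins$n_het / (bins$n_het + bins$n_hom))[keep])
  expect_gt(slope, 0)
  expect_lt(trend$p.value / 2, 0.05)

  design0 <- design
  design0$X[, 1] <- 0L # all hybrids homozygous at this SNP
  hom_only <- allele_class_by_mph_bins(design0, het, colnames(design0$X)[1],
    breaks = breaks
  )
  expect_true(all(hom_only$n_het == 0))
})
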