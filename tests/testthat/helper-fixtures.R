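# shared fixtures: all synthetic, generated in code at test time

# a small two-population panel used by many tests
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_accessions = 12, n_snps = 60, n_replicates = 4,
        seed = 42
      )
      cache <<- simulate_panel(cfg, growth_curves = FALSE)
    }
    cache
  }
})

# hand-built genotype matrix: accessions x SNPs, homozygous calls
toy_genotypes <- function(calls, chromosome = NULL) {
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("a", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- paste0("s", seq_len(ncol(calls)))
  }
  if (is.null(chromosome)) chromosome <- rep(1L, ncol(calls))
  geno_matrix(calls, tibble::tibble(
    snp_id = colnames(calls),
    chromosome = chromosome,
    position = seq_len(ncol(calls))
  ))
}

# replicate-level trait rows from a named list genotype -> values
toy_trait_table <- function(values, roles, population = "pop1", trait = "HT") {
  purrr::imap_dfr(values, function(v, id) {
    tibble::tibble(
      genotype_id = id, role = roles[[id]], population = population,
      trait = trait, replicate = seq_along(v), value = v
    )
  })
}

# one-hybrid pedigree
toy_pedigree <- function(hybrid = "h1", parent = "p1", reference = "ref",
                         population = "pop1") {
  tibble::tibble(
    hybrid_id = hybrid, parent_id = parent,
    reference_id = reference, population = population
  )
}

# independent brute-force GLS oracle: direct matrix inversion
brute_force_gls <- function(y, x, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  xtvx <- t(X) %*% Vi %*% X
  beta <- solve(xtvx, t(X) %*% Vi %*% y)
  n <- length(y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Vi %*% r) / (n - 2)
  se <- sqrt(diag(s2 * solve(xtvx)))
  tstat <- beta[2] / se[2]
  list(
    effect = unname(beta[2]), se = unname(se[2]),
    p = unname(2 * pt(-abs(tstat), df = n - 2))
  )
}

# z statistic for mean MPH_ABS against zero in a single-population,
# single-trait panel, accounting for the shared common-reference parent:
# every hybrid's MPH_ABS contains -0.5 x the same reference-mean sampling
# error, so the per-hybrid records are not independent and a naive one-
# sample t-test is anti-conservative
mean_mph_abs_z <- function(het, traits_table) {
  stopifnot(
    length(unique(het$population)) == 1,
    length(unique(het$trait)) == 1
  )
  s <- summarize_genotypes(traits_table)
  s <- s[s$population == het$population[1] & s$trait == het$trait[1], ]
  se2 <- setNames(s$variance / s$n, s$genotype_id)
  n <- nrow(het)
  var_mean <- sum(se2[het$hybrid_id]) / n^2 +
    sum(se2[het$parent_id]) / (4 * n^2) +
    se2[[unique(het$reference_id)]] / 4
  mean(het$mph_abs) / sqrt(var_mean)
}

# independent step-up BH oracle
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}
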