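test_that("generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_accessions = 6, n_snps = 30, n_replicates = 3, seed = 11)
  p1 <- simulate_panel(cfg, growth_curves = TRUE)
  p2 <- simulate_panel(cfg, growth_curves = TRUE)
  expect_identical(p1$parents$calls, p2$parents$calls)
  expect_identical(p1$traits, p2$traits)
  expect_identical(p1$curves, p2$curves)
})

test_that("parental accessions are fully homozygous inbred lines", {
  g <- simulate_parental_genotypes(
    sim_config(n_accessions = 10, n_snps = 50, n_replicates = 2, seed = 5)
  )
  expect_true(all(g$calls %in% c(0L, 2L)))
  expect_setequal(unique(g$map$chromosome), 1:5)
  for (ch in unique(g$map$chromosome)) {
    expect_false(is.unsorted(g$map$position[g$map$chromosome == ch]))
  }
})

test_that("observed allele frequencies match the configured draw", {
  # degenerate maf_range pins every SNP frequency at 0.5; binomial sampling
  # bounds the observed frequency
  cfg <- sim_config(
    n_accessions = 1000, n_snps = 20, maf_range = c(0.5, 0.5),
    n_replicates = 2, seed = 9
  )
  g <- simulate_parental_genotypes(cfg)
  obs <- colMeans(g$calls[1:1000, ]) / 2
  sd_bin <- sqrt(0.5 * 0.5 / 1000)
  expect_true(all(abs(obs - 0.5) < 3 * sd_bin))
})

test_that("hybrids are heterozygous exactly where parent and reference differ", {
  panel <- small_panel()
  ped <- panel$pedigree
  for (i in sample(nrow(ped), 5)) {
    row <- ped[i, ]
    pc <- panel$parents$calls[row$parent_id, ]
    rc <- panel$parents$calls[row$reference_id, ]
    hc <- panel$hybrids$calls[row$hybrid_id, ]
    hamming <- sum(pc != rc)
    expect_identical(sum(hc == 1L), hamming)
    expect_identical(which(hc == 1L), which(pc != rc))
  }
})

test_that("a parent identical to the reference yields a fully homozygous hybrid", {
  calls <- rbind(p1 = c(0L, 2L, 0L), ref = c(0L, 2L, 0L))
  g <- toy_genotypes(calls)
  hyb <- derive_hybrid_genotypes(g, toy_pedigree())
  expect_true(all(hyb$calls != 1L))
  expect_identical(unname(hyb$calls[1, ]), c(0L, 2L, 0L))
})

test_that("non-inbred or unknown parents are rejected", {
  calls <- rbind(p1 = c(1L, 2L), ref = c(0L, 2L))
  g <- toy_genotypes(calls)
  expect_error(derive_hybrid_genotypes(g, toy_pedigree()), "inbred")
  calls2 <- rbind(p1 = c(0L, 2L), ref = c(0L, 2L))
  expect_error(
    derive_hybrid_genotypes(toy_genotypes(calls2), toy_pedigree(parent = "nope")),
    "unknown|Unknown"
  )
})

test_that("generator rejects invalid configurations", {
  expect_error(sim_config(n_accessions = 2), "n_accessions")
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(maf_range = c(0, 0.6)), "maf_range")
  expect_error(
    sim_config(qtls = qtl_spec(5, 1, 0, "not_a_trait")),
    "absent"
  )
  expect_error(
    sim_config(n_snps = 10, qtls = qtl_spec(11, 1, 0, "HT")),
    "QTL positions"
  )
})

test_that("purely additive architectures produce zero expected MPH_ABS", {
  traits <- tibble::tibble(trait = "HT", baseline = 50, residual_sd = 0)
  cfg <- sim_config(
    n_accessions = 8, n_snps = 40, n_replicates = 2,
    traits = traits,
    qtls = qtl_spec(c(3, 17, 29), a = c(2, 1, 3), d = 0, trait = "HT"),
    seed = 21
  )
  panel <- simulate_panel(cfg)
  het <- heterosis_table(panel$traits, panel$pedigree)
  expect_true(all(abs(het$mph_abs) < 1e-12))
})

test_that("a lone dominance QTL shifts heterozygous hybrids by exactly d", {
  traits <- tibble::tibble(trait = "HT", baseline = 10, residual_sd = 0)
  cfg <- sim_config(
    n_accessions = 8, n_snps = 20, n_replicates = 2,
    traits = traits,
    qtls = qtl_spec(7, a = 0, d = 2, trait = "HT"),
    seed = 31
  )
  panel <- simulate_panel(cfg)
  het <- heterosis_table(panel$traits, panel$pedigree)
  is_het <- panel$hybrids$calls[het$hybrid_id, 7] == 1L
  expect_equal(het$mph_abs[is_het], rep(2, sum(is_het)))
  expect_equal(het$mph_abs[!is_het], rep(0, sum(!is_het)))
})

test_that("noise-free replicates are identical and heritability is one", {
  traits <- tibble::tibble(trait = "HT", baseline = 10, residual_sd = 0)
  cfg <- sim_config(
    n_accessions = 6, n_snps = 20, n_replicates = 3,
    traits = traits, qtls = qtl_spec(3, 1, 0.5, "HT"), seed = 8
  )
  panel <- simulate_panel(cfg)
  spread <- panel$traits |>
    dplyr::group_by(genotype_id, population) |>
    dplyr::summarise(rng = diff(range(value)), .groups = "drop")
  expect_true(all(spread$rng == 0))
  h <- heritability(panel$traits)
  expect_true(all(h$h2 == 1))
})

test_that("growth curves are logistic, monotone, and synchronised without jitter", {
  cfg <- sim_config(
    n_accessions = 4, n_snps = 10, n_replicates = 3, seed = 2,
    curve_params = list(
      onset_jitter_sd = 0, genotype_cv = 0,
      hybrid_onset_advance = 0
    )
  )
  ped <- make_pedigree(simulate_parental_genotypes(cfg), cfg$reference_ids)
  curves <- simulate_growth_curves(cfg, ped, populations = "pop1")
  inc <- curves |>
    dplyr::group_by(plant_id) |>
    dplyr::summarise(mono = !is.unsorted(area_mm2), .groups = "drop")
  expect_true(all(inc$mono))
  t0 <- detect_establishment(curves)
  expect_length(unique(t0$t0), 1L)
})

test_that("a configured hybrid onset advantage is recovered from the curves", {
  cfg <- sim_config(
    n_accessions = 50, n_snps = 10, n_replicates = 2, seed = 13,
    curve_params = list(hybrid_onset_advance = 3, genotype_cv = 0)
  )
  ped <- make_pedigree(simulate_parental_genotypes(cfg), cfg$reference_ids)
  curves <- simulate_growth_curves(cfg, ped, populations = "pop1")
  t0 <- detect_establishment(curves)
  gap <- mean(t0$t0[t0$role != "hybrid"]) - mean(t0$t0[t0$role == "hybrid"])
  expect_lt(abs(gap - 3), 0.6)
})
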