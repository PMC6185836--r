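test_that("genotype summaries match hand arithmetic and a Welford oracle", {
  tt <- toy_trait_table(
    list(g1 = c(2, 4), g2 = 7),
    roles = c(g1 = "parent", g2 = "parent")
  )
  s <- summarize_genotypes(tt)
  expect_equal(s$mean[s$genotype_id == "g1"], 3)
  expect_equal(s$sd[s$genotype_id == "g1"], sqrt(2))
  expect_equal(s$n[s$genotype_id == "g2"], 1L)
  expect_true(is.na(s$sd[s$genotype_id == "g2"]))

  # independent single-pass (Welford) oracle against the two-pass summary
  set.seed(1)
  v <- rnorm(1000, 5, 3)
  welford <- function(x) {
    m <- 0
    m2 <- 0
    for (i in seq_along(x)) {
      d <- x[i] - m
      m <- m + d / i
      m2 <- m2 + d * (x[i] - m)
    }
    list(mean = m, var = m2 / (length(x) - 1))
  }
  w <- welford(v)
  s2 <- summarize_genotypes(toy_trait_table(list(g = v), roles = c(g = "parent")))
  expect_equal(s2$mean, w$mean, tolerance = 1e-12)
  expect_equal(s2$variance, w$var, tolerance = 1e-12)
})

test_that("mid-parent heterosis follows its defining identities", {
  expect_equal(
    mid_parent_heterosis(12, 8, 12),
    tibble::tibble(mpv = 10, mph_abs = 2, mph = 20)
  )
  r <- mid_parent_heterosis(10, 10, 10)
  expect_equal(r$mph, 0)
  expect_equal(r$mph_abs, 0)
  z <- mid_parent_heterosis(3, -2, 2) # mpv = 0
  expect_true(is.na(z$mph))
  expect_equal(z$mph_abs, 3)
})

test_that("better-parent heterosis picks the right parent and direction", {
  expect_equal(better_parent_heterosis(15, 8, 12)$bph, 25)
  r <- better_parent_heterosis(10, 8, 12)
  expect_equal(r$bph, 100 * (10 - 12) / 12)
  expect_equal(mid_parent_heterosis(10, 8, 12)$mph, 0)
  expect_equal(better_parent_heterosis(12, 12, 8)$bph, 0)
  # for flowering time, earlier (lower) is better
  lo <- better_parent_heterosis(7, 8, 12, higher_is_better = FALSE)
  expect_equal(lo$best_parent_mean, 8)
  expect_equal(lo$bph, 100 * (7 - 8) / 8)
})

test_that("best-parent test behaves across modes and degenerate input", {
  same <- best_parent_test(c(3, 3, 3), c(3, 3, 3), mode = "paired")
  expect_equal(same$p, 1)
  expect_false(same$exceeds)

  w <- best_parent_test(c(10, 11, 12), c(5, 6, 7), mode = "welch")
  # closed-form Welch t: diff 5, se sqrt(2/3), df 4
  expect_lt(w$p, 0.01)
  expect_equal(w$p, 2 * pt(-5 / sqrt(2 / 3), df = 4), tolerance = 1e-10)
  expect_true(w$exceeds)

  expect_true(is.na(best_parent_test(5, c(1, 2))$p))
  expect_error(
    best_parent_test(c(1, 2, 3), c(1, 2), mode = "paired"),
    "equal replicate"
  )
})

test_that("MPH and BPH are scale invariant; MPH_ABS scales", {
  panel <- small_panel()
  het <- heterosis_table(panel$traits, panel$pedigree)
  scaled <- panel$traits
  scaled$value <- scaled$value * 3.7
  het2 <- heterosis_table(scaled, panel$pedigree)
  expect_equal(het2$mph, het$mph, tolerance = 1e-10)
  expect_equal(het2$bph, het$bph, tolerance = 1e-10)
  expect_equal(het2$mph_abs, het$mph_abs * 3.7, tolerance = 1e-10)
})

test_that("BPH never exceeds MPH for positive mid-parent values", {
  panel <- small_panel()
  het <- heterosis_table(panel$traits, panel$pedigree)
  dir <- heterosisr::trait_registry()
  up <- dir$trait[dir$higher_is_better]
  ok <- het$trait %in% up & het$mpv > 0
  expect_true(all(het$bph[ok] <= het$mph[ok] + 1e-10))
})

test_that("variance components match the hand-computed two-genotype case", {
  # genotype means 0 and 2, within-genotype sample variance 1 each
  tt <- toy_trait_table(
    list(g1 = c(-1, 0, 1), g2 = c(1, 2, 3)),
    roles = c(g1 = "parent", g2 = "parent")
  )
  h <- heritability(tt)
  expect_equal(h$v_g, 2)
  expect_equal(h$v_e, 1)
  expect_equal(h$h2, 2 / 3)
  expect_equal(h$cvg, 100 * sqrt(2) / 1)

  # ANOVA expected-mean-squares alternative on the same balanced data:
  # V_G = (MS_b - MS_w) / n0 = (6 - 1) / 3
  h2 <- heritability(tt, method = "anova")
  expect_equal(h2$v_g, 5 / 3)
  expect_equal(h2$v_e, 1)
})

test_that("heritability is undefined for pooled single-replicate traits", {
  tt <- toy_trait_table(
    list(g1 = 1, g2 = 2, g3 = 5),
    roles = c(g1 = "parent", g2 = "parent", g3 = "parent")
  )
  h <- heritability(tt)
  expect_true(is.na(h$h2))
  expect_false(is.na(h$cvg))
})

test_that("heritability decreases with configured noise and recovers the target", {
  base <- list(n_accessions = 30, n_snps = 80, n_replicates = 4)
  h_at <- function(sd) {
    cfg <- do.call(sim_config, c(base, list(residual_sd = sd, seed = 17)))
    panel <- simulate_panel(cfg)
    h <- heritability(panel$traits)
    mean(h$h2[h$role == "parents" & h$trait == "HT"])
  }
  hs <- vapply(c(0.5, 3, 10), h_at, numeric(1))
  expect_true(all(diff(hs) < 0))
  expect_true(all(hs >= 0 & hs <= 1))
})

test_that("seed number estimation matches its algebraic definition", {
  expect_equal(estimate_seed_number(0.25, 25), 10000)
  expect_equal(estimate_seed_number(0, 30), 0)
  sy <- c(0.1, 0.27, 0.5)
  sw <- c(18, 25.3, 31)
  ns <- estimate_seed_number(sy, sw)
  expect_equal(ns * sw * 1e-6, sy, tolerance = 1e-12)
  expect_error(estimate_seed_number(0.1, 0), "positive")
})

test_that("derived seed-number rows join yield and seed weight by replicate", {
  tt <- dplyr::bind_rows(
    toy_trait_table(list(g1 = c(0.2, 0.3)), roles = c(g1 = "parent"), trait = "SY"),
    toy_trait_table(list(g1 = c(20, 25)), roles = c(g1 = "parent"), trait = "SW")
  )
  out <- add_seed_number(tt)
  ns <- out[out$trait == "NS", ]
  expect_equal(ns$value, c(1e6 * 0.2 / 20, 1e6 * 0.3 / 25))
})

test_that("population summary reproduces Table-1-style structure", {
  panel <- small_panel()
  ps <- population_summary(panel$traits, panel$pedigree)
  expect_setequal(unique(ps$role), c("parents", "hybrids"))
  expect_true(all(is.na(ps$rs_hybrid_vs_mpv[ps$role == "parents"])))
  expect_true(all(ps$h2 >= 0 & ps$h2 <= 1, na.rm = TRUE))
  expect_true(all(ps$cvg >= 0, na.rm = TRUE))
})

test_that("hybrid-vs-MPV rank correlation is high for additive high-h2 traits", {
  traits <- tibble::tibble(trait = "HT", baseline = 50, residual_sd = 1)
  cfg <- sim_config(
    n_accessions = 40, n_snps = 100, n_replicates = 6,
    traits = traits,
    qtls = qtl_spec(c(5, 30, 70), a = c(4, 3, 5), d = 0, trait = "HT"),
    seed = 23
  )
  panel <- simulate_panel(cfg)
  ps <- population_summary(panel$traits, panel$pedigree)
  expect_true(all(ps$rs_hybrid_vs_mpv[ps$role == "hybrids"] > 0.8))
})

test_that("a role with a single genotype is flagged, not dropped", {
  tt <- dplyr::bind_rows(
    toy_trait_table(
      list(g1 = c(1, 2), ref = c(2, 3)),
      roles = c(g1 = "parent", ref = "reference")
    ),
    toy_trait_table(list(h1 = c(2, 4)), roles = c(h1 = "hybrid"))
  )
  ps <- population_summary(tt, toy_pedigree(parent = "g1"))
  hyb <- ps[ps$role == "hybrids", ]
  expect_equal(hyb$n_genotypes, 1L)
  expect_true(is.na(hyb$sd))
})

test_that("outlier-lineage exclusion removes exactly the matching rows", {
  panel <- small_panel()
  ped <- panel$pedigree
  target <- ped$parent_id[1]
  victims <- c(target, ped$hybrid_id[ped$parent_id == target])
  out <- exclude_outlier_lineage(panel$traits, target,
    traits = c("SW", "SZ"),
    pedigree = ped
  )
  removed <- nrow(panel$traits) - nrow(out)
  expect_equal(
    removed,
    sum(panel$traits$genotype_id %in% victims & panel$traits$trait %in% c("SW", "SZ"))
  )
  # untouched traits intact
  expect_equal(
    sum(out$genotype_id == target & out$trait == "HT"),
    sum(panel$traits$genotype_id == target & panel$traits$trait == "HT")
  )
  expect_equal(exclude_outlier_lineage(panel$traits, character(0)), panel$traits)
  expect_warning(
    exclude_outlier_lineage(panel$traits, "no_such_line"),
    "Unknown"
  )
})

test_that("mean MPH_ABS of an additive-only noisy panel is centred at zero", {
  traits <- tibble::tibble(trait = "HT", baseline = 50, residual_sd = 2)
  cfg <- sim_config(
    n_accessions = 50, n_snps = 100, n_replicates = 6,
    traits = traits,
    qtls = qtl_spec(c(10, 40, 80), a = c(3, 2, 4), d = 0, trait = "HT"),
    seed = 29
  )
  panel <- simulate_panel(cfg)
  het <- heterosis_table(panel$traits, panel$pedigree) |>
    dplyr::filter(population == "pop1")
  z <- mean_mph_abs_z(het, panel$traits)
  expect_lt(abs(z), qnorm(0.995))
})
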