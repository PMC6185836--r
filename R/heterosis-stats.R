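#' Per-genotype replicate summaries
#'
#' Collapses a replicate-level trait table to one row per
#' (genotype, population, trait): replicate count (missing values excluded),
#' mean, standard deviation and variance. Groups with a single replicate get
#' `NA` for sd/variance.
#'
#' @param table Replicate-level trait tibble (columns `genotype_id`, `role`,
#'   `population`, `trait`, `replicate`, `value`).
#' @return A tibble with columns `genotype_id`, `role`, `population`,
#'   `trait`, `n`, `mean`, `sd`, `variance`.
#' @export
summarize_genotypes <- function(table) {
  .assert_cols(
    table, c("genotype_id", "role", "population", "trait", "value"),
    "trait table"
  )
  table |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(
      .data$genotype_id, .data$role, .data$population,
      .data$trait
    ) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      variance = var(.data$value),
      .groups = "drop"
    )
}

#' Mid-parent heterosis
#'
#' Computes the mid-parent value `MPV = (p1 + p2) / 2`, absolute mid-parent
#' heterosis `MPH_ABS = F1 - MPV` (trait units; purely additive gene action
#' cancels in this difference) and relative mid-parent heterosis
#' `MPH = 100 * MPH_ABS / MPV` (percent). When `MPV` is zero the relative
#' value is undefined and returned as `NA`, while `MPH_ABS` is still
#' reported.
#'
#' @param f1_mean,p1_mean,p2_mean Genotype means of the hybrid and its two
#'   parents (vectorised).
#' @return A tibble with columns `mpv`, `mph_abs`, `mph`.
#' @export
#' @examples
#' mid_parent_heterosis(12, 8, 12) # mpv 10, mph_abs 2, mph 20%
mid_parent_heterosis <- function(f1_mean, p1_mean, p2_mean) {
  mpv <- (p1_mean + p2_mean) / 2
  mph_abs <- f1_mean - mpv
  mph <- ifelse(mpv == 0, NA_real_, 100 * mph_abs / mpv)
  tibble::tibble(mpv = mpv, mph_abs = mph_abs, mph = mph)
}

#' Better-parent heterosis
#'
#' Percent deviation of the hybrid mean from the best-performing parent:
#' `BPH = 100 * (F1 - P_best) / P_best`. The best parent is the one with the
#' higher mean when `higher_is_better` is `TRUE` (the default for most
#' traits) and the lower mean otherwise. Undefined (`NA`) when the best
#' parent's mean is zero.
#'
#' @inheritParams mid_parent_heterosis
#' @param higher_is_better Logical (vectorised): does a larger trait value
#'   define the better parent?
#' @param p1_id,p2_id Optional parent identifiers used to label the best
#'   parent.
#' @return A tibble with columns `best_parent`, `best_parent_mean`, `bph`.
#' @export
#' @examples
#' better_parent_heterosis(15, 8, 12) # best = 12, bph = 25%
better_parent_heterosis <- function(f1_mean, p1_mean, p2_mean,
                                    higher_is_better = TRUE,
                                    p1_id = "p1", p2_id = "p2") {
  p1_best <- ifelse(higher_is_better, p1_mean >= p2_mean, p1_mean <= p2_mean)
  best_mean <- ifelse(p1_best, p1_mean, p2_mean)
  best_id <- ifelse(p1_best, p1_id, p2_id)
  bph <- ifelse(best_mean == 0, NA_real_, 100 * (f1_mean - best_mean) / best_mean)
  tibble::tibble(
    best_parent = best_id, best_parent_mean = best_mean,
    bph = bph
  )
}

#' Test whether a hybrid beats its best parent
#'
#' Two-tailed t-test comparing the hybrid's replicate values with the best
#' parent's. The default is a Welch two-sample test (replicates are not
#' naturally paired); `mode = "paired"` pairs replicates by index and
#' requires equal counts. Identical replicate vectors (all paired
#' differences zero, or both samples constant and equal) carry no evidence
#' against the null and return `p = 1` by convention. Fewer than two
#' replicates on either side returns `NA`.
#'
#' @param hybrid,parent Numeric replicate vectors.
#' @param mode `"welch"` or `"paired"`.
#' @param higher_is_better Direction defining "better".
#' @param alpha Significance level for the `exceeds` flag.
#' @return A list with elements `p` and `exceeds` (hybrid mean better than
#'   parent mean AND `p < alpha`).
#' @export
best_parent_test <- function(hybrid, parent, mode = c("welch", "paired"),
                             higher_is_better = TRUE, alpha = 0.05) {
  mode <- match.arg(mode)
  hybrid <- hybrid[is.finite(hybrid)]
  parent <- parent[is.finite(parent)]
  if (length(hybrid) < 2 || length(parent) < 2) {
    return(list(p = NA_real_, exceeds = NA))
  }
  if (mode == "paired" && length(hybrid) != length(parent)) {
    abort("Paired mode requires equal replicate counts.")
  }
  p <- if (mode == "paired") {
    diffs <- hybrid - parent
    if (all(diffs == 0)) {
      1
    } else if (sd(diffs) == 0) {
      0 # constant non-zero difference: noise-free separation
    } else {
      t.test(diffs)$p.value
    }
  } else {
    if (sd(hybrid) == 0 && sd(parent) == 0) {
      if (mean(hybrid) == mean(parent)) 1 else 0
    } else {
      t.test(hybrid, parent, var.equal = FALSE)$p.value
    }
  }
  better <- if (higher_is_better) {
    mean(hybrid) > mean(parent)
  } else {
    mean(hybrid) < mean(parent)
  }
  list(p = p, exceeds = better && !is.na(p) && p < alpha)
}

#' Full per-hybrid heterosis table
#'
#' For every hybrid and trait, computes the mid-parent value, absolute and
#' relative mid-parent heterosis, better-parent heterosis, and the
#' best-parent comparison test (both Welch and paired p-values are reported;
#' the `exceeds_best` flag uses `test_mode`).
#'
#' @param table Replicate-level trait tibble.
#' @param pedigree Pedigree tibble mapping each hybrid to its variable
#'   parent and common-reference parent.
#' @param higher_is_better Optional named logical vector of per-trait
#'   directions, overriding [trait_registry()] defaults (unknown traits
#'   default to higher-is-better).
#' @param test_mode Best-parent test mode driving `best_parent_p` and
#'   `exceeds_best`: `"welch"` (default) or `"paired"`.
#' @param alpha Significance level for `exceeds_best`.
#' @return A tibble with one row per (hybrid, trait): ids, means, `mpv`,
#'   `mph_abs`, `mph`, `bph`, best-parent columns and test results.
#' @export
heterosis_table <- function(table, pedigree, higher_is_better = NULL,
                            test_mode = c("welch", "paired"), alpha = 0.05) {
  test_mode <- match.arg(test_mode)
  .assert_cols(
    pedigree, c("hybrid_id", "parent_id", "reference_id", "population"),
    "`pedigree`"
  )
  sums <- summarize_genotypes(table)
  reps <- table |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(
      .data$genotype_id, .data$population,
      .data$trait
    ) |>
    dplyr::summarise(values = list(.data$value), .groups = "drop")

  dir <- .trait_direction(unique(table$trait), higher_is_better)

  hyb <- sums |>
    dplyr::filter(.data$role == "hybrid") |>
    dplyr::inner_join(pedigree, by = c(
      "genotype_id" = "hybrid_id",
      "population" = "population"
    )) |>
    dplyr::rename(hybrid_id = "genotype_id", hybrid_mean = "mean")

  means <- sums |>
    dplyr::select("genotype_id", "population", "trait", "mean")
  hyb <- hyb |>
    dplyr::left_join(
      dplyr::rename(means, parent_id = "genotype_id", parent_mean = "mean"),
      by = c("parent_id", "population", "trait")
    ) |>
    dplyr::left_join(
      dplyr::rename(means,
        reference_id = "genotype_id",
        reference_mean = "mean"
      ),
      by = c("reference_id", "population", "trait")
    )

  mp <- mid_parent_heterosis(hyb$hybrid_mean, hyb$parent_mean, hyb$reference_mean)
  bp <- better_parent_heterosis(
    hyb$hybrid_mean, hyb$parent_mean, hyb$reference_mean,
    higher_is_better = dir[hyb$trait],
    p1_id = hyb$parent_id, p2_id = hyb$reference_id
  )
  out <- dplyr::bind_cols(
    dplyr::select(
      hyb, "hybrid_id", "population", "trait", "parent_id",
      "reference_id", "n", "hybrid_mean", "parent_mean", "reference_mean"
    ),
    mp,
    dplyr::rename(bp, best_parent_id = "best_parent")
  )

  rep_lookup <- setNames(
    reps$values,
    paste(reps$genotype_id, reps$population, reps$trait, sep = "\r")
  )
  key <- function(id, pop, tr) paste(id, pop, tr, sep = "\r")
  tests <- purrr::pmap(
    list(out$hybrid_id, out$best_parent_id, out$population, out$trait),
    function(hid, bid, pop, tr) {
      hv <- rep_lookup[[key(hid, pop, tr)]]
      bv <- rep_lookup[[key(bid, pop, tr)]]
      if (is.null(hv) || is.null(bv)) {
        return(list(welch = NA_real_, paired = NA_real_, exceeds = NA))
      }
      w <- best_parent_test(hv, bv,
        mode = "welch",
        higher_is_better = dir[[tr]], alpha = alpha
      )
      p <- if (length(hv) == length(bv)) {
        best_parent_test(hv, bv,
          mode = "paired",
          higher_is_better = dir[[tr]], alpha = alpha
        )
      } else {
        list(p = NA_real_, exceeds = NA)
      }
      chosen <- if (test_mode == "welch") w else p
      list(welch = w$p, paired = p$p, exceeds = chosen$exceeds)
    }
  )
  out$best_parent_p_welch <- purrr::map_dbl(tests, "welch")
  out$best_parent_p_paired <- purrr::map_dbl(tests, "paired")
  out$best_parent_p <- if (test_mode == "welch") {
    out$best_parent_p_welch
  } else {
    out$best_parent_p_paired
  }
  out$exceeds_best <- purrr::map_lgl(tests, "exceeds")
  class(out) <- c("heterosis_tbl", class(out))
  out
}

# variance components among replicated genotypes: V_G is the variance of
# genotype means (n-1 divisor), V_E the mean within-genotype sample variance
.h2_components <- function(values, genotype, method = c("means", "anova")) {
  method <- match.arg(method)
  ok <- is.finite(values)
  values <- values[ok]
  genotype <- genotype[ok]
  means <- tapply(values, genotype, mean)
  ns <- tapply(values, genotype, length)
  if (length(means) < 2) {
    return(list(v_g = NA_real_, v_e = NA_real_, h2 = NA_real_, grand = mean(values)))
  }
  within <- tapply(values, genotype, function(v) if (length(v) >= 2) var(v) else NA_real_)
  v_e <- mean(within, na.rm = TRUE)
  if (!is.finite(v_e)) v_e <- NA_real_
  if (method == "means") {
    v_g <- var(means)
  } else {
    # expected-mean-squares estimator from one-way ANOVA with (possibly)
    # unbalanced replicate counts
    n <- length(values)
    k <- length(means)
    grand <- mean(values)
    ss_b <- sum(ns * (means - grand)^2)
    ms_b <- ss_b / (k - 1)
    ms_w <- sum((values - means[as.character(genotype)])^2) / (n - k)
    n0 <- (n - sum(ns^2) / n) / (k - 1)
    v_g <- max((ms_b - ms_w) / n0, 0)
    v_e <- ms_w
  }
  h2 <- if (is.na(v_e) || (v_g + v_e) == 0) NA_real_ else v_g / (v_g + v_e)
  list(v_g = v_g, v_e = v_e, h2 = h2, grand = mean(values))
}

#' Broad-sense heritability and genetic coefficient of variation
#'
#' For each (population, trait, role group), estimates the genotypic
#' variance `V_G` as the variance among genotype means and the environmental
#' variance `V_E` as the mean of within-genotype sample variances, then
#' reports the broad-sense heritability `H2 = V_G / (V_G + V_E)` and the
#' genetic coefficient of variation `CV_G = 100 * sqrt(V_G) / mean`. Roles
#' `parent` and `reference` are pooled as `"parents"`. When no genotype has
#' two or more replicates (pooled measurements) `V_E` and `H2` are `NA`
#' ("not determined"); `CV_G` is `NA` when the grand mean is zero. An
#' ANOVA-based expected-mean-squares estimator of `V_G` is available via
#' `method = "anova"`.
#'
#' @param table Replicate-level trait tibble.
#' @param method `"means"` (default) or `"anova"`.
#' @return A tibble with columns `population`, `trait`, `role`,
#'   `n_genotypes`, `v_g`, `v_e`, `h2`, `cvg`.
#' @export
heritability <- function(table, method = c("means", "anova")) {
  method <- match.arg(method)
  .assert_cols(
    table, c("genotype_id", "role", "population", "trait", "value"),
    "trait table"
  )
  table |>
    dplyr::mutate(role_group = ifelse(.data$role == "hybrid", "hybrids", "parents")) |>
    dplyr::group_by(.data$population, .data$trait, role = .data$role_group) |>
    dplyr::group_modify(function(df, key) {
      cmp <- .h2_components(df$value, df$genotype_id, method = method)
      tibble::tibble(
        n_genotypes = length(unique(df$genotype_id)),
        v_g = cmp$v_g,
        v_e = cmp$v_e,
        h2 = cmp$h2,
        cvg = if (is.na(cmp$v_g) || cmp$grand == 0) {
          NA_real_
        } else {
          100 * sqrt(cmp$v_g) / cmp$grand
        }
      )
    }) |>
    dplyr::ungroup()
}

#' Estimate seeds per plant from yield and seed weight
#'
#' `NS = SY / per-seed weight`, with seed yield `SY` in grams per plant and
#' `SW` the 1000-seed weight in milligrams, i.e. `NS = 1e6 * SY / SW`.
#'
#' @param sy Seed yield, g/plant.
#' @param sw 1000-seed weight, mg per 1000 seeds; must be positive.
#' @return Estimated seed count (vectorised).
#' @export
#' @examples
#' estimate_seed_number(0.25, 25) # 10,000 seeds
estimate_seed_number <- function(sy, sw) {
  if (any(sw <= 0, na.rm = TRUE)) abort("`sw` must be positive.")
  1e6 * sy / sw
}

#' Append an estimated seed-number trait to a trait table
#'
#' Matches SY and SW observations by (genotype, population, replicate) and
#' derives `NS` rows via [estimate_seed_number()].
#'
#' @param table Replicate-level trait tibble containing `SY` and `SW` rows.
#' @param sy_trait,sw_trait,ns_trait Trait labels to read from / write to.
#' @return The input table with `NS` rows appended.
#' @export
add_seed_number <- function(table, sy_trait = "SY", sw_trait = "SW",
                            ns_trait = "NS") {
  sy <- dplyr::filter(table, .data$trait == sy_trait)
  sw <- dplyr::filter(table, .data$trait == sw_trait) |>
    dplyr::select("genotype_id", "population", "replicate", sw = "value")
  ns <- sy |>
    dplyr::inner_join(sw, by = c("genotype_id", "population", "replicate")) |>
    dplyr::mutate(
      value = estimate_seed_number(.data$value, .data$sw),
      trait = ns_trait
    ) |>
    dplyr::select(-"sw")
  dplyr::bind_rows(table, ns)
}

#' Population-level descriptive summary
#'
#' Produces one row per (population, trait, role group) with the population
#' average and SD across genotype means, broad-sense heritability and
#' genetic coefficient of variation, plus — on hybrid rows — the Spearman
#' rank correlation (with two-tailed p) between hybrid genotype means and
#' their expected mid-parent values.
#'
#' @param table Replicate-level trait tibble.
#' @param pedigree Pedigree tibble.
#' @param method Variance-component method passed to [heritability()].
#' @return A tibble with columns `population`, `trait`, `role`,
#'   `n_genotypes`, `avg`, `sd`, `h2`, `cvg`, `rs_hybrid_vs_mpv`, `rs_p`
#'   (correlation columns are `NA` on parent rows).
#' @export
population_summary <- function(table, pedigree, method = c("means", "anova")) {
  sums <- summarize_genotypes(table)
  herit <- heritability(table, method = method)

  desc <- sums |>
    dplyr::mutate(role_group = ifelse(.data$role == "hybrid", "hybrids", "parents")) |>
    dplyr::group_by(.data$population, .data$trait, role = .data$role_group) |>
    dplyr::summarise(
      n_genotypes = dplyr::n(),
      avg = mean(.data$mean),
      sd = if (dplyr::n() >= 2) sd(.data$mean) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::select(herit, "population", "trait", "role", "h2", "cvg"),
      by = c("population", "trait", "role")
    )

  het <- heterosis_table(table, pedigree)
  rs <- het |>
    dplyr::group_by(.data$population, .data$trait) |>
    dplyr::summarise(
      rs_hybrid_vs_mpv = {
        ok <- is.finite(.data$hybrid_mean) & is.finite(.data$mpv)
        if (sum(ok) >= 3) {
          suppressWarnings(cor(.data$hybrid_mean[ok], .data$mpv[ok],
            method = "spearman"
          ))
        } else {
          NA_real_
        }
      },
      rs_p = {
        ok <- is.finite(.data$hybrid_mean) & is.finite(.data$mpv)
        if (sum(ok) >= 3) {
          suppressWarnings(cor.test(.data$hybrid_mean[ok], .data$mpv[ok],
            method = "spearman", exact = FALSE
          )$p.value)
        } else {
          NA_real_
        }
      },
      .groups = "drop"
    )

  desc |>
    dplyr::left_join(rs, by = c("population", "trait")) |>
    dplyr::mutate(
      rs_hybrid_vs_mpv = ifelse(.data$role == "hybrids", .data$rs_hybrid_vs_mpv, NA_real_),
      rs_p = ifelse(.data$role == "hybrids", .data$rs_p, NA_real_)
    ) |>
    dplyr::arrange(.data$trait, .data$population, .data$role)
}

#' Remove an outlier accession and its hybrids for selected traits
#'
#' Drops the named genotypes — and, when a pedigree is supplied, every
#' hybrid derived from them — from the trait table, but only for the named
#' traits. Used for seed traits when one accession's exceptional seed size
#' would confound mapping. Unknown ids produce a warning, not an error.
#'
#' @param table Replicate-level trait tibble.
#' @param genotype_ids Accession ids to exclude.
#' @param traits Traits the exclusion applies to (default: all traits in
#'   the table).
#' @param pedigree Optional pedigree used to resolve derived hybrids.
#' @return The filtered trait tibble.
#' @export
exclude_outlier_lineage <- function(table, genotype_ids,
                                    traits = unique(table$trait),
                                    pedigree = NULL) {
  ids <- genotype_ids
  known <- unique(table$genotype_id)
  if (!is.null(pedigree)) {
    derived <- pedigree$hybrid_id[pedigree$parent_id %in% genotype_ids |
      pedigree$reference_id %in% genotype_ids]
    ids <- unique(c(ids, derived))
    known <- unique(c(known, pedigree$hybrid_id, pedigree$parent_id))
  }
  unknown <- setdiff(genotype_ids, known)
  if (length(unknown) > 0) {
    warn(sprintf(
      "Unknown genotype id(s) in exclusion list: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  dplyr::filter(
    table,
    !(.data$genotype_id %in% ids & .data$trait %in% traits)
  )
}
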