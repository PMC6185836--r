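#' Combine genotype matrices sharing one map
#'
#' @param ... `geno_matrix` objects with identical maps (e.g. parents and
#'   derived hybrids).
#' @return A single `geno_matrix` stacking all accessions.
#' @export
bind_genotypes <- function(...) {
  gs <- list(...)
  stopifnot(length(gs) >= 1, all(purrr::map_lgl(gs, inherits, "geno_matrix")))
  map <- gs[[1]]$map
  for (g in gs[-1]) {
    if (!identical(g$map$snp_id, map$snp_id)) {
      abort("All genotype matrices must share one SNP map.")
    }
  }
  geno_matrix(do.call(rbind, purrr::map(gs, "calls")), map)
}

# genotypic value contribution of one locus: +a / d / -a for
# reference-homozygote / heterozygote / alternate-homozygote
.qtl_value <- function(call, a, d) {
  ifelse(call == 1L, d, a * (call - 1))
}

# genotypic values for every accession x trait under the configured QTLs
.genotypic_values <- function(genotypes, config) {
  ids <- accessions(genotypes)
  out <- matrix(0, nrow = length(ids), ncol = nrow(config$traits),
    dimnames = list(ids, config$traits$trait)
  )
  out <- sweep(out, 2, config$traits$baseline, `+`)
  for (i in seq_len(nrow(config$qtls))) {
    q <- config$qtls[i, ]
    call <- genotypes$calls[, q$snp_index]
    out[, q$trait] <- out[, q$trait] + .qtl_value(call, q$a, q$d)
  }
  out
}

#' Simulate replicate-level trait observations
#'
#' Assigns each genotype a genotypic value per trait — baseline plus the sum
#' of `+a` / `d` / `-a` contributions over the configured QTLs for
#' reference-homozygous / heterozygous / alternate-homozygous calls — and
#' adds independent Gaussian replicate noise with the per-trait residual SD.
#' Each population (one per reference parent) contains its reference line,
#' all variable parents and its hybrids, each with `n_replicates` rows per
#' trait. When `config$target_h2` is set, the residual SD of every trait is
#' rescaled so that the broad-sense heritability among parental lines
#' (genotypic variance over genotypic-plus-replicate variance) equals the
#' target.
#'
#' @param genotypes Combined `geno_matrix` of parents and hybrids (see
#'   [bind_genotypes()]).
#' @param pedigree Pedigree tibble.
#' @param config A [sim_config()].
#' @return A replicate-level trait tibble with columns `genotype_id`,
#'   `role`, `population`, `trait`, `replicate`, `value`.
#' @export
#' @examples
#' cfg <- sim_config(n_accessions = 5, n_snps = 30, n_replicates = 3, seed = 1)
#' par <- simulate_parental_genotypes(cfg)
#' ped <- make_pedigree(par, cfg$reference_ids)
#' hyb <- derive_hybrid_genotypes(par, ped)
#' tt <- simulate_traits(bind_genotypes(par, hyb), ped, cfg)
#' head(tt)
simulate_traits <- function(genotypes, pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  unknown <- setdiff(config$qtls$trait, config$traits$trait)
  if (length(unknown) > 0) {
    abort(sprintf(
      "QTL trait(s) absent from configured trait list: %s",
      paste(unique(unknown), collapse = ", ")
    ))
  }
  need <- unique(c(
    pedigree$parent_id, pedigree$reference_id,
    pedigree$hybrid_id
  ))
  missing <- setdiff(need, accessions(genotypes))
  if (length(missing) > 0) {
    abort(sprintf(
      "Genotypes absent for: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  gv <- .genotypic_values(genotypes, config)

  resid <- setNames(config$traits$residual_sd, config$traits$trait)
  if (!is.null(config$target_h2)) {
    # calibrate noise to the realised parental genotypic variance
    pids <- unique(pedigree$parent_id)
    for (tr in config$traits$trait) {
      vg <- var(gv[pids, tr])
      resid[tr] <- if (vg > 0) {
        sqrt(vg * (1 - config$target_h2) / config$target_h2)
      } else {
        0
      }
    }
  }

  set.seed(config$seed + 1L)
  pops <- split(pedigree, pedigree$population)
  out <- purrr::imap_dfr(pops, function(ped, pop) {
    ref <- unique(ped$reference_id)
    members <- tibble::tibble(
      genotype_id = c(ref, unique(ped$parent_id), ped$hybrid_id),
      role = c(
        rep("reference", length(ref)),
        rep("parent", length(unique(ped$parent_id))),
        rep("hybrid", nrow(ped))
      )
    )
    grid <- tidyr::expand_grid(
      members,
      trait = config$traits$trait,
      replicate = seq_len(config$n_replicates)
    )
    grid$population <- pop
    grid$value <- gv[cbind(grid$genotype_id, grid$trait)] +
      rnorm(nrow(grid), 0, resid[grid$trait])
    grid
  })
  dplyr::select(
    out, "genotype_id", "role", "population",
    "trait", "replicate", "value"
  )
}

#' Simulate per-plant logistic growth curves
#'
#' Emulates daily projected-leaf-area imaging: each plant follows a logistic
#' area-versus-time curve with genotype-specific growth rate and asymptote
#' (log-normal variation around the configured values) and a per-plant
#' establishment onset. Hybrid plants establish `hybrid_onset_advance` days
#' earlier than parental plants, emulating the germination/establishment
#' advantage that motivates t0 normalisation.
#'
#' @param config A [sim_config()]; `config$curve_params` controls the curve
#'   shape.
#' @param pedigree Pedigree tibble.
#' @param populations Populations to simulate (default: all in the
#'   pedigree).
#' @return A long tibble with columns `plant_id`, `genotype_id`, `role`,
#'   `population`, `time` (days after sowing), `area_mm2`.
#' @export
simulate_growth_curves <- function(config, pedigree,
                                   populations = unique(pedigree$population)) {
  stopifnot(inherits(config, "sim_config"))
  cp <- config$curve_params
  if (cp$rate <= 0 || cp$asymptote <= 0) {
    abort("Growth-curve rate and asymptote must be positive.")
  }
  set.seed(config$seed + 2L)
  ped <- pedigree[pedigree$population %in% populations, , drop = FALSE]
  days <- seq_len(cp$n_days)

  out <- purrr::imap_dfr(split(ped, ped$population), function(pd, pop) {
    ref <- unique(pd$reference_id)
    members <- tibble::tibble(
      genotype_id = c(ref, unique(pd$parent_id), pd$hybrid_id),
      role = c(
        rep("reference", length(ref)),
        rep("parent", length(unique(pd$parent_id))),
        rep("hybrid", nrow(pd))
      )
    )
    n_g <- nrow(members)
    rate_g <- cp$rate * exp(rnorm(n_g, 0, cp$genotype_cv))
    asym_g <- cp$asymptote * exp(rnorm(n_g, 0, cp$genotype_cv))
    onset_g <- cp$onset_day - ifelse(members$role == "hybrid",
      cp$hybrid_onset_advance, 0
    )
    purrr::map_dfr(seq_len(n_g), function(i) {
      reps <- seq_len(config$n_replicates)
      onset_p <- onset_g[i] + rnorm(length(reps), 0, cp$onset_jitter_sd)
      purrr::map_dfr(reps, function(r) {
        shift <- (cp$asymptote - cp$initial_area) / cp$initial_area
        area <- asym_g[i] / (1 + shift * exp(-rate_g[i] * (days - onset_p[r])))
        tibble::tibble(
          plant_id = sprintf("%s.%s.r%d", pop, members$genotype_id[i], r),
          genotype_id = members$genotype_id[i],
          role = members$role[i],
          population = pop,
          time = days,
          area_mm2 = area
        )
      })
    })
  })
  out
}

#' Simulate a complete common-reference hybrid panel
#'
#' Convenience wrapper running the whole generator: parental genotypes,
#' pedigrees (one population per reference parent), hybrid genotypes,
#' replicate-level trait data, and (optionally) growth curves.
#'
#' @param config A [sim_config()].
#' @param growth_curves Simulate growth curves too? (default `FALSE`; they
#'   dominate runtime for large panels).
#' @return A list with elements `config`, `parents`, `pedigree`, `hybrids`,
#'   `genotypes` (parents + hybrids), `traits`, and optionally `curves`.
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(
#'   n_accessions = 6, n_snps = 40,
#'   n_replicates = 3, seed = 2
#' ))
#' names(panel)
simulate_panel <- function(config, growth_curves = FALSE) {
  parents <- simulate_parental_genotypes(config)
  pedigree <- make_pedigree(parents, config$reference_ids)
  hybrids <- derive_hybrid_genotypes(parents, pedigree)
  genotypes <- bind_genotypes(parents, hybrids)
  traits <- simulate_traits(genotypes, pedigree, config)
  out <- list(
    config = config, parents = parents, pedigree = pedigree,
    hybrids = hybrids, genotypes = genotypes, traits = traits
  )
  if (growth_curves) {
    out$curves <- simulate_growth_curves(config, pedigree)
  }
  out
}
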