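#' QTL specification for the synthetic panel
#'
#' Describes one biallelic quantitative trait locus by its marker index and
#' its additive and dominance effects. Under the classical single-locus
#' model the three genotype classes (reference homozygote, heterozygote,
#' alternate homozygote) take genotypic values `+a`, `d`, `-a` around the
#' homozygote midpoint; `|d| > |a|` represents overdominance.
#'
#' @param snp_index Integer marker index (1-based, into the simulated SNP
#'   panel).
#' @param a Additive effect in trait units: half the difference between the
#'   two homozygote means.
#' @param d Dominance effect in trait units: the heterozygote deviation from
#'   the homozygote midpoint.
#' @param trait Trait name the locus acts on.
#' @return A tibble with one row per locus.
#' @export
#' @examples
#' qtl_spec(snp_index = c(10, 250), a = c(1, 0), d = c(0, 2), trait = "HT")
qtl_spec <- function(snp_index, a, d, trait) {
  out <- tibble::tibble(
    snp_index = as.integer(snp_index),
    a = as.numeric(a),
    d = as.numeric(d),
    trait = as.character(trait)
  )
  if (any(!is.finite(out$a)) || any(!is.finite(out$d))) {
    abort("QTL effects `a` and `d` must be finite.")
  }
  if (any(out$snp_index < 1)) {
    abort("`snp_index` must be >= 1.")
  }
  out
}

# default per-trait baselines and noise chosen to land in Table-1-like
# coefficient-of-variation ranges (roughly 10-40% CV_G depending on trait)
.default_trait_params <- function() {
  tibble::tibble(
    trait = c("LA", "FT", "HT", "MSB", "RB", "SY", "SW", "SZ"),
    baseline = c(4.5, 29, 50, 5.5, 3.5, 0.27, 25, 82),
    residual_sd = c(0.9, 2.0, 5.0, 0.9, 0.8, 0.05, 1.5, 5.0)
  )
}

.default_qtls <- function(traits, n_snps, seed) {
  # a modest polygenic architecture per trait: five additive loci and two
  # dominance loci, effects scaled to the trait baseline
  set.seed(seed + 7919L)
  purrr::map_dfr(seq_len(nrow(traits)), function(i) {
    tr <- traits$trait[i]
    b <- traits$baseline[i]
    k <- min(7L, n_snps)
    n_dom <- if (k >= 7L) 2L else if (k >= 2L) 1L else 0L
    idx <- sample.int(n_snps, k)
    qtl_spec(
      snp_index = idx,
      a = c(rep(0.06 * b, k - n_dom), rep(0, n_dom)),
      d = c(rep(0, k - n_dom), rep(0.08 * b, n_dom)),
      trait = tr
    )
  })
}

#' Configuration for the synthetic common-reference panel
#'
#' Bundles everything the generator needs to emulate a pair of overlapping
#' common-reference hybrid populations: a set of fully homozygous (inbred)
#' parental accessions genotyped at biallelic SNPs, one or two designated
#' common reference parents, F1 hybrids formed by crossing each accession to
#' each reference, replicated trait measurements driven by a known
#' additive/dominance QTL architecture, and logistic rosette growth curves.
#'
#' Defaults emulate the design the package targets: 100 variable parents
#' crossed to two reference lines (populations of ~100 hybrids sharing the
#' variable-parent set), 10 replicates per genotype, and the nine canonical
#' traits with baselines and noise in realistic ranges.
#'
#' @param n_accessions Number of variable (non-reference) parental
#'   accessions.
#' @param n_snps Number of biallelic SNPs.
#' @param n_chromosomes Number of chromosomes the SNPs are spread over.
#' @param maf_range Length-2 numeric in (0, 0.5]: per-SNP allele frequencies
#'   are drawn uniformly within this range.
#' @param traits Tibble with columns `trait`, `baseline`, `residual_sd`
#'   giving per-trait genotypic baselines and replicate noise (trait units).
#' @param qtls QTL table from [qtl_spec()], or `NULL` for a default
#'   polygenic architecture (5 additive + 2 dominance loci per trait).
#' @param n_replicates Replicates grown per genotype.
#' @param residual_sd Optional scalar overriding `traits$residual_sd` for
#'   every trait.
#' @param target_h2 Optional broad-sense heritability in (0, 1): when set,
#'   replicate noise is rescaled per trait so that the realised
#'   genotypic-variance fraction among parental lines equals this value.
#' @param reference_ids Character vector of one or two reference-parent
#'   identifiers; each defines one population.
#' @param curve_params Logistic growth-curve parameters: `initial_area`
#'   (mm2, area at onset), `rate` (per day), `asymptote` (mm2),
#'   `onset_day` (mean establishment day for parents), `onset_jitter_sd`
#'   (days, per-plant), `hybrid_onset_advance` (days earlier that hybrids
#'   establish), `genotype_cv` (relative SD of per-genotype rate and
#'   asymptote), `n_days` (length of the imaging series).
#' @param seed Integer seed; all generator output is deterministic given the
#'   full configuration.
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_accessions = 10, n_snps = 50, n_replicates = 3, seed = 1)
#' cfg$reference_ids
sim_config <- function(n_accessions = 100,
                       n_snps = 1000,
                       n_chromosomes = 5,
                       maf_range = c(0.05, 0.5),
                       traits = .default_trait_params(),
                       qtls = NULL,
                       n_replicates = 10,
                       residual_sd = NULL,
                       target_h2 = NULL,
                       reference_ids = c("Col", "Ler"),
                       curve_params = list(),
                       seed = 1L) {
  if (n_accessions < 3) abort("`n_accessions` must be >= 3.")
  if (n_snps < 1) abort("`n_snps` must be >= 1.")
  if (n_replicates < 2) abort("`n_replicates` must be >= 2.")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
    maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5].")
  }
  if (!length(reference_ids) %in% c(1L, 2L)) {
    abort("`reference_ids` must name one or two reference parents.")
  }
  .assert_cols(traits, c("trait", "baseline", "residual_sd"), "`traits`")
  if (!is.null(residual_sd)) {
    if (residual_sd < 0) abort("`residual_sd` must be non-negative.")
    traits$residual_sd <- residual_sd
  }
  if (!is.null(target_h2) && (target_h2 <= 0 || target_h2 >= 1)) {
    abort("`target_h2` must lie strictly between 0 and 1.")
  }
  if (is.null(qtls)) {
    qtls <- .default_qtls(traits, n_snps, as.integer(seed))
  }
  .assert_cols(qtls, c("snp_index", "a", "d", "trait"), "`qtls`")
  if (any(qtls$snp_index > n_snps)) {
    abort("All QTL positions must be < n_snps.")
  }
  unknown <- setdiff(qtls$trait, traits$trait)
  if (length(unknown) > 0) {
    abort(sprintf(
      "QTL trait(s) absent from configured trait list: %s",
      paste(unique(unknown), collapse = ", ")
    ))
  }

  cp <- modifyList(list(
    initial_area = 0.5, # mm2 at establishment onset
    rate = 0.45, # per day
    asymptote = 450, # mm2, ~4.5 cm2 at maturity
    onset_day = 5, # mean parental establishment day
    onset_jitter_sd = 1, # per-plant jitter, days
    hybrid_onset_advance = 3, # hybrids establish earlier, days
    genotype_cv = 0.1, # genotype-level rate/asymptote variation
    n_days = 17
  ), curve_params)
  if (cp$asymptote <= cp$initial_area) {
    abort("Growth-curve asymptote must exceed the initial area.")
  }
  if (cp$rate <= 0 || cp$asymptote <= 0) {
    abort("Growth-curve rate and asymptote must be positive.")
  }

  structure(
    list(
      n_accessions = as.integer(n_accessions),
      n_snps = as.integer(n_snps),
      n_chromosomes = as.integer(n_chromosomes),
      maf_range = as.numeric(maf_range),
      traits = traits,
      qtls = qtls,
      n_replicates = as.integer(n_replicates),
      target_h2 = target_h2,
      reference_ids = as.character(reference_ids),
      curve_params = cp,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d accessions x %d SNPs on %d chromosomes; MAF in [%.2f, %.2f]\n",
    x$n_accessions, x$n_snps, x$n_chromosomes, x$maf_range[1], x$maf_range[2]
  ))
  cat(sprintf(
    "  reference parent(s): %s; %d replicates/genotype; seed %d\n",
    paste(x$reference_ids, collapse = ", "), x$n_replicates, x$seed
  ))
  cat(sprintf(
    "  %d traits, %d QTLs\n",
    nrow(x$traits), nrow(x$qtls)
  ))
  invisible(x)
}
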