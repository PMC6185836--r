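#' Kinship-corrected association scan for heterosis
#'
#' High-level wrapper running one population x trait x model scan end to
#' end. The *dominant* model maps per-hybrid absolute mid-parent heterosis
#' (`MPH_ABS`, which cancels additive gene action) on hybrid heterozygosity,
#' estimating dominance effects `d`. The *additive* model maps parental
#' genotype means on the reference-allele encoding of the parental
#' accessions, estimating `2a`. Population structure is corrected with a
#' kinship matrix computed from (or supplied for) the variable parental
#' accessions; in the dominant scan each hybrid inherits its variable
#' parent's kinship row, since relatedness among hybrids sharing one
#' reference parent is driven by the variable parent.
#'
#' @param table Replicate-level trait tibble.
#' @param parents `geno_matrix` of parental accessions (incl. the reference
#'   parents).
#' @param pedigree Pedigree tibble.
#' @param trait Trait to scan.
#' @param model `"dominant"` or `"additive"`.
#' @param population Population label (default: first in the pedigree).
#' @param kinship Optional precomputed parent-level kinship matrix;
#'   computed with [compute_kinship()] otherwise.
#' @param kinship_method Passed to [compute_kinship()] when `kinship` is
#'   `NULL`.
#' @param orientation Additive-encoding orientation (see
#'   [encode_additive()]).
#' @param maf_threshold,raw_threshold,fdr_alpha Passed to [scan_gls()].
#' @param heterosis Optional precomputed [heterosis_table()] (avoids
#'   recomputation when scanning many traits).
#' @param exclude Optional accession ids removed (with their hybrids)
#'   before scanning, e.g. an outlier lineage for seed traits.
#' @return A `gwas_scan` tibble with `trait` and `population` columns
#'   prepended.
#' @export
scan_heterosis <- function(table, parents, pedigree, trait,
                           model = c("dominant", "additive"),
                           population = NULL,
                           kinship = NULL,
                           kinship_method = "standardized",
                           orientation = "reference",
                           maf_threshold = 0.05, raw_threshold = 4,
                           fdr_alpha = 0.05, heterosis = NULL,
                           exclude = NULL) {
  model <- match.arg(model)
  if (is.null(population)) population <- pedigree$population[1]
  ped <- pedigree[pedigree$population == population, , drop = FALSE]
  if (nrow(ped) == 0) abort(sprintf("Unknown population '%s'.", population))
  if (!is.null(exclude)) {
    table <- exclude_outlier_lineage(table, exclude,
      traits = trait,
      pedigree = pedigree
    )
    ped <- ped[!(ped$parent_id %in% exclude), , drop = FALSE]
  }

  if (is.null(kinship)) {
    kin_parents <- subset_accessions(parents, unique(pedigree$parent_id))
    kinship <- compute_kinship(kin_parents, method = kinship_method)
  }

  if (model == "dominant") {
    if (is.null(heterosis)) heterosis <- heterosis_table(table, pedigree)
    het <- heterosis |>
      dplyr::filter(
        .data$population == !!population, .data$trait == !!trait,
        is.finite(.data$mph_abs)
      )
    ped <- ped[match(het$hybrid_id, ped$hybrid_id), , drop = FALSE]
    ped <- ped[!is.na(ped$hybrid_id), , drop = FALSE]
    het <- het[het$hybrid_id %in% ped$hybrid_id, , drop = FALSE]
    design <- encode_dominant(parents, ped)
    y <- setNames(het$mph_abs, het$hybrid_id)[design$samples]
    # hybrids inherit their variable parent's kinship row
    k <- kinship[ped$parent_id, ped$parent_id, drop = FALSE]
    dimnames(k) <- list(ped$hybrid_id, ped$hybrid_id)
  } else {
    sums <- summarize_genotypes(table) |>
      dplyr::filter(
        .data$population == !!population, .data$trait == !!trait,
        .data$genotype_id %in% ped$parent_id, is.finite(.data$mean)
      )
    ped <- ped[ped$parent_id %in% sums$genotype_id, , drop = FALSE]
    design <- encode_additive(parents, ped, orientation = orientation)
    y <- setNames(sums$mean, sums$genotype_id)[design$samples]
    k <- kinship[design$samples, design$samples, drop = FALSE]
  }

  null <- fit_null_model(y, k)
  out <- scan_gls(unname(y), design,
    null = null, maf_threshold = maf_threshold,
    raw_threshold = raw_threshold, fdr_alpha = fdr_alpha
  )
  out <- tibble::add_column(out,
    trait = trait, population = population,
    .before = 1
  )
  class(out) <- c("gwas_scan", setdiff(class(out), "gwas_scan"))
  attr(out, "null") <- null
  out
}
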