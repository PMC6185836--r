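#' Biallelic genotype matrix with map positions
#'
#' A light container pairing an accessions-by-SNPs matrix of
#' reference-allele counts (0, 1, 2 or `NA` for missing) with a marker map
#' (SNP id, chromosome, 1-based bp position). Inbred parental accessions
#' carry only 0/2 calls; F1 hybrids may be heterozygous (1).
#'
#' @param calls Integer matrix, accessions in rows (rownames = accession
#'   ids), SNPs in columns (colnames = SNP ids); values in \{0, 1, 2, NA\}.
#' @param map Tibble with columns `snp_id`, `chromosome`, `position`;
#'   `snp_id` must match `colnames(calls)` in order, positions must be
#'   non-decreasing within chromosome.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, map) {
  if (!is.matrix(calls)) abort("`calls` must be a matrix.")
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    abort("`calls` must carry accession rownames and SNP colnames.")
  }
  bad <- !is.na(calls) & !(calls %in% c(0, 1, 2))
  if (any(bad)) {
    abort(sprintf(
      "Genotype calls must be 0, 1, 2 or missing; found %s.",
      paste(unique(calls[bad]), collapse = ", ")
    ))
  }
  .assert_cols(map, c("snp_id", "chromosome", "position"), "`map`")
  if (nrow(map) != ncol(calls)) {
    abort("Map rows must match genotype matrix columns.")
  }
  if (!identical(as.character(map$snp_id), colnames(calls))) {
    abort("`map$snp_id` must equal colnames(calls), in order.")
  }
  ok <- tapply(map$position, map$chromosome, function(p) !is.unsorted(p))
  if (!all(unlist(ok))) {
    abort("Map positions must be non-decreasing within each chromosome.")
  }
  storage.mode(calls) <- "integer"
  structure(list(calls = calls, map = tibble::as_tibble(map)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d accessions x %d SNPs on %d chromosome(s); %d heterozygous, %d missing calls\n",
    nrow(x$calls), ncol(x$calls), length(unique(x$map$chromosome)),
    sum(x$calls == 1L, na.rm = TRUE), sum(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Accession identifiers of a genotype matrix
#' @param x A `geno_matrix`.
#' @return Character vector of accession ids.
#' @export
accessions <- function(x) rownames(x$calls)

#' Subset a genotype matrix by accession
#' @param x A `geno_matrix`.
#' @param ids Accession ids to keep, in the order given.
#' @return A `geno_matrix` restricted to `ids`.
#' @export
subset_accessions <- function(x, ids) {
  missing <- setdiff(ids, accessions(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "Unknown accession id(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  geno_matrix(x$calls[ids, , drop = FALSE], x$map)
}

#' Simulate inbred parental genotypes
#'
#' Draws fully homozygous biallelic calls for each parental accession. Per
#' SNP, a reference-allele frequency is drawn uniformly within
#' `config$maf_range`; each accession is then homozygous reference (2) with
#' that probability and homozygous alternate (0) otherwise, mimicking a
#' panel of naturally inbred lines with no linkage disequilibrium. SNPs are
#' spread evenly over chromosomes with ascending map positions.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] of the variable accessions plus the configured
#'   reference parents.
#' @export
#' @examples
#' g <- simulate_parental_genotypes(sim_config(
#'   n_accessions = 5, n_snps = 20,
#'   n_replicates = 2, seed = 1
#' ))
#' dim(g)
simulate_parental_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_acc <- config$n_accessions
  n_snp <- config$n_snps
  ids <- c(sprintf("acc%03d", seq_len(n_acc)), config$reference_ids)

  freq <- runif(n_snp, config$maf_range[1], config$maf_range[2])
  calls <- matrix(
    2L * rbinom(length(ids) * n_snp, 1L, rep(freq, each = length(ids))),
    nrow = length(ids), ncol = n_snp,
    dimnames = list(ids, sprintf("m%05d", seq_len(n_snp)))
  )

  chrom <- rep(seq_len(config$n_chromosomes), length.out = n_snp)
  chrom <- sort(chrom)
  pos <- integer(n_snp)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- sort(sample.int(3e7L, k))
  }
  map <- tibble::tibble(
    snp_id = colnames(calls),
    chromosome = chrom,
    position = pos
  )
  geno_matrix(calls, map)
}

#' Build the common-reference pedigrees
#'
#' Crosses every variable accession to each configured reference parent,
#' producing one population per reference line. Both populations share the
#' full variable-parent set, emulating two overlapping common-reference
#' panels.
#'
#' @param parents A `geno_matrix` (or character vector of accession ids)
#'   containing the variable parents and reference parents.
#' @param reference_ids Character vector of reference-parent ids; each
#'   defines one population, labelled `pop1`, `pop2`, ...
#' @return A pedigree tibble with columns `hybrid_id`, `parent_id`,
#'   `reference_id`, `population`.
#' @export
make_pedigree <- function(parents, reference_ids) {
  ids <- if (inherits(parents, "geno_matrix")) accessions(parents) else parents
  missing <- setdiff(reference_ids, ids)
  if (length(missing) > 0) {
    abort(sprintf(
      "Reference id(s) absent from parents: %s",
      paste(missing, collapse = ", ")
    ))
  }
  variable <- setdiff(ids, reference_ids)
  purrr::map_dfr(seq_along(reference_ids), function(k) {
    ref <- reference_ids[k]
    tibble::tibble(
      hybrid_id = paste0(variable, "_x_", ref),
      parent_id = variable,
      reference_id = ref,
      population = paste0("pop", k)
    )
  })
}

#' Derive F1 hybrid genotypes from inbred parents
#'
#' Each hybrid receives one allele from its variable parent and one from the
#' common reference parent, so it is heterozygous exactly at the SNPs where
#' the two parental lines carry different alleles and homozygous for the
#' shared allele elsewhere. Requires fully homozygous parents (F1s of inbred
#' lines carry no within-parent segregation).
#'
#' @param parents A `geno_matrix` of homozygous parental accessions.
#' @param pedigree Pedigree tibble (see [make_pedigree()]).
#' @return A `geno_matrix` of hybrid genotypes (calls in \{0, 1, 2\}).
#' @export
derive_hybrid_genotypes <- function(parents, pedigree) {
  stopifnot(inherits(parents, "geno_matrix"))
  .assert_cols(
    pedigree, c("hybrid_id", "parent_id", "reference_id", "population"),
    "`pedigree`"
  )
  need <- unique(c(pedigree$parent_id, pedigree$reference_id))
  missing <- setdiff(need, accessions(parents))
  if (length(missing) > 0) {
    abort(sprintf(
      "Pedigree names unknown parent id(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  pcalls <- parents$calls[need, , drop = FALSE]
  if (any(pcalls == 1L, na.rm = TRUE)) {
    abort("Heterozygous parental call found: parents must be inbred (0/2 only).")
  }
  hyb <- (pcalls[pedigree$parent_id, , drop = FALSE] +
    pcalls[pedigree$reference_id, , drop = FALSE]) %/% 2L
  rownames(hyb) <- pedigree$hybrid_id
  # keep one row per unique hybrid id (a hybrid can appear in one pedigree only)
  geno_matrix(hyb, parents$map)
}
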