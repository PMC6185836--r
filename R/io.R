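#' Read and write replicate-level trait tables
#'
#' Tab-delimited text with columns `genotype_id`, `role`, `population`,
#' `trait`, `replicate`, `value`. The reader validates roles against
#' `parent` / `hybrid` / `reference`, normalises missing-value tokens
#' (`NA`, `""`, `"n.d."`, `"nd"`) to `NA`, rejects duplicate
#' (genotype, population, trait, replicate) keys, and rejects unparseable
#' numerics. A `dialect` list covers plausible layouts of externally
#' produced tables: `col_map` renames source columns onto the canonical
#' ones, and `missing_tokens` extends the missing-value vocabulary.
#'
#' @param path File path.
#' @param dialect Optional list with elements `col_map` (named character
#'   vector: canonical name = source name) and `missing_tokens`.
#' @return A validated trait tibble.
#' @export
read_trait_table <- function(path, dialect = list()) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  na_tokens <- unique(c(
    "NA", "", "n.d.", "nd", "ND",
    dialect$missing_tokens %||% character()
  ))
  df <- readr::read_tsv(path,
    na = na_tokens, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!is.null(dialect$col_map)) {
    for (canon in names(dialect$col_map)) {
      src <- dialect$col_map[[canon]]
      if (src %in% names(df)) names(df)[names(df) == src] <- canon
    }
  }
  .assert_cols(
    df, c("genotype_id", "role", "population", "trait", "replicate", "value"),
    "trait table file"
  )
  bad_role <- setdiff(unique(df$role), c("parent", "hybrid", "reference"))
  if (length(bad_role) > 0) {
    abort(sprintf(
      "Unknown role label(s): %s",
      paste(bad_role, collapse = ", ")
    ))
  }
  value <- suppressWarnings(as.numeric(df$value))
  bad_num <- !is.na(df$value) & is.na(value)
  if (any(bad_num)) {
    abort(sprintf(
      "Unparseable numeric value(s), e.g. '%s' (row %d).",
      df$value[which(bad_num)[1]], which(bad_num)[1]
    ))
  }
  out <- tibble::tibble(
    genotype_id = df$genotype_id,
    role = df$role,
    population = df$population,
    trait = df$trait,
    replicate = as.integer(df$replicate),
    value = value
  )
  key <- paste(out$genotype_id, out$population, out$trait, out$replicate)
  if (anyDuplicated(key)) {
    abort(sprintf(
      "Duplicate (genotype, population, trait, replicate) key: %s",
      key[which(duplicated(key))[1]]
    ))
  }
  out
}

#' @rdname read_trait_table
#' @param table Trait tibble to write.
#' @export
write_trait_table <- function(table, path) {
  .assert_cols(
    table, c("genotype_id", "role", "population", "trait", "replicate", "value"),
    "trait table"
  )
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read and write genotype matrices
#'
#' The genotype file is a tab-delimited accession-by-SNP table whose first
#' column holds accession ids and whose remaining columns (named by SNP id)
#' hold reference-allele counts in \{0, 1, 2\} or `NA`; the map file has
#' three columns `snp_id`, `chromosome`, `position` (1-based bp). Calls
#' outside the domain are rejected, as are dimension mismatches.
#'
#' @param path Genotype matrix file.
#' @param map_path Marker map file.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, map_path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- as.character(df[[1]])
  calls <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(calls)) {
    abort("Genotype calls must be numeric (0, 1, 2 or NA).")
  }
  rownames(calls) <- ids
  map <- readr::read_tsv(map_path,
    show_col_types = FALSE,
    col_types = readr::cols(
      snp_id = readr::col_character(),
      chromosome = readr::col_character(),
      position = readr::col_integer()
    )
  )
  .assert_cols(map, c("snp_id", "chromosome", "position"), "map file")
  if (nrow(map) != ncol(calls)) {
    abort(sprintf(
      "Map has %d SNPs but genotype matrix has %d columns.",
      nrow(map), ncol(calls)
    ))
  }
  geno_matrix(calls, map)
}

#' @rdname read_genotypes
#' @param genotypes A `geno_matrix` to write.
#' @export
write_genotypes <- function(genotypes, path, map_path) {
  df <- tibble::as_tibble(genotypes$calls, rownames = "accession_id")
  readr::write_tsv(df, path)
  readr::write_tsv(genotypes$map, map_path)
  invisible(path)
}

#' Read genotypes from a PLINK-style .raw file
#'
#' Accepts the whitespace-delimited `.raw` additive-allele-count export
#' (columns FID IID PAT MAT SEX PHENOTYPE followed by one column per
#' variant, typically named `snp_allele`). Counts are taken as
#' reference-allele counts; a map is synthesised (single chromosome,
#' positions by column order) unless `map_path` is supplied.
#'
#' @param path `.raw` file path.
#' @param map_path Optional 3-column map file.
#' @return A [geno_matrix()].
#' @export
read_genotypes_raw <- function(path, map_path = NULL) {
  df <- readr::read_table(path, show_col_types = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  .assert_cols(df, c("FID", "IID"), ".raw file")
  snp_cols <- setdiff(names(df), meta)
  calls <- as.matrix(df[, snp_cols, drop = FALSE])
  rownames(calls) <- as.character(df$IID)
  colnames(calls) <- sub("_[ACGT0-9]+$", "", snp_cols)
  map <- if (is.null(map_path)) {
    tibble::tibble(
      snp_id = colnames(calls),
      chromosome = "1",
      position = seq_len(ncol(calls))
    )
  } else {
    readr::read_tsv(map_path, show_col_types = FALSE)
  }
  geno_matrix(calls, map)
}

#' Read and write pedigrees
#'
#' Tab-delimited with columns `hybrid_id`, `parent_id`, `reference_id`,
#' `population`. The reader enforces a single reference per population and
#' `parent_id != reference_id`.
#'
#' @param path File path.
#' @return A pedigree tibble.
#' @export
read_pedigree <- function(path) {
  df <- readr::read_tsv(path,
    show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  .assert_cols(
    df, c("hybrid_id", "parent_id", "reference_id", "population"),
    "pedigree file"
  )
  refs <- tapply(df$reference_id, df$population, function(x) length(unique(x)))
  if (any(refs > 1)) {
    abort("Each population must have a single common reference parent.")
  }
  if (any(df$parent_id == df$reference_id)) {
    abort("`parent_id` must differ from `reference_id`.")
  }
  tibble::as_tibble(df)
}

#' @rdname read_pedigree
#' @param pedigree Pedigree tibble to write.
#' @export
write_pedigree <- function(pedigree, path) {
  readr::write_tsv(
    dplyr::select(
      pedigree, "hybrid_id", "parent_id",
      "reference_id", "population"
    ),
    path
  )
  invisible(path)
}

#' Write and read association-scan results
#'
#' Tab-delimited per-SNP table with columns `snp_id`, `chromosome`,
#' `position`, `model`, `maf`, `effect`, `neg_log10_p`, `q` (plus `trait`
#' and `population` when present), sorted by chromosome then position.
#'
#' @param result A `gwas_scan` tibble.
#' @param path File path.
#' @return `read_scan_results()` returns the tibble back.
#' @export
write_scan_results <- function(result, path) {
  if (nrow(result) == 0) abort("Refusing to write an empty scan result.")
  cols <- intersect(
    c(
      "trait", "population", "snp_id", "chromosome", "position", "model",
      "maf", "effect", "neg_log10_p", "q"
    ),
    names(result)
  )
  out <- result |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::arrange(.data$chromosome, .data$position)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_scan_results
#' @export
read_scan_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read and write long-format growth curves
#'
#' Tab-delimited with columns `plant_id`, `genotype_id`, `role`,
#' `population`, `time`, `area_mm2`; times must be strictly increasing per
#' plant and areas non-negative.
#'
#' @param path File path.
#' @return A growth-curve tibble.
#' @export
read_growth_curves <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  .assert_cols(
    df, c("plant_id", "genotype_id", "role", "population", "time", "area_mm2"),
    "growth-curve file"
  )
  if (any(df$area_mm2 < 0, na.rm = TRUE)) abort("Areas must be non-negative.")
  bad <- df |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$time, strictly = TRUE))
  if (any(!bad$ok)) {
    abort("Times must be strictly increasing within each plant.")
  }
  df
}

#' @rdname read_growth_curves
#' @param curves Growth-curve tibble to write.
#' @export
write_growth_curves <- function(curves, path) {
  readr::write_tsv(curves, path)
  invisible(path)
}
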