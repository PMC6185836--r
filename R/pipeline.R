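#' Read a pipeline run configuration
#'
#' YAML with either a `simulation` block (passed to [sim_config()]) or a
#' `data` block (file paths: `traits`, and optionally `genotypes`, `map`,
#' `pedigree`, `kinship`), plus optional `scan`, `growth`, `exclude` blocks,
#' an `output_dir` and a `seed`.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Reports every violation at once rather than stopping at the first.
#'
#' @param config A configuration list (see [read_run_config()]).
#' @return A tibble with columns `field` and `message`; zero rows when the
#'   configuration is valid.
#' @export
validate_run_config <- function(config) {
  v <- list()
  add <- function(field, message) {
    v[[length(v) + 1]] <<- tibble::tibble(field = field, message = message)
  }
  has_sim <- !is.null(config$simulation)
  has_data <- !is.null(config$data)
  if (!has_sim && !has_data) {
    add("simulation/data", "either a `simulation` or a `data` block is required")
  }
  if (has_sim && has_data) {
    add("simulation/data", "provide `simulation` or `data`, not both")
  }
  if (has_data) {
    if (is.null(config$data$traits)) {
      add("data.traits", "a phenotype table path is required")
    } else if (!file.exists(config$data$traits)) {
      add("data.traits", sprintf("file not found: %s", config$data$traits))
    }
    for (f in c("genotypes", "map", "pedigree", "kinship")) {
      p <- config$data[[f]]
      if (!is.null(p) && !file.exists(p)) {
        add(paste0("data.", f), sprintf("file not found: %s", p))
      }
    }
  }
  maf <- config$scan$maf_threshold
  if (!is.null(maf) && (maf < 0 || maf > 0.5)) {
    add("scan.maf_threshold", "MAF threshold must lie in [0, 0.5]")
  }
  alpha <- config$scan$fdr_alpha
  if (!is.null(alpha) && (alpha <= 0 || alpha >= 1)) {
    add("scan.fdr_alpha", "FDR alpha must lie in (0, 1)")
  }
  if (!is.null(config$seed) && !is.numeric(config$seed)) {
    add("seed", "seed must be numeric")
  }
  if (length(v) == 0) {
    tibble::tibble(field = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

# per-genotype mean values in the long (genotype_id, trait, value) shape
# the correlation functions consume; hybrids can be re-keyed by parent
.mean_values <- function(sums, roles, key = "genotype_id") {
  sums |>
    dplyr::filter(.data$role %in% roles) |>
    dplyr::select(genotype_id = dplyr::all_of(key), "trait", value = "mean")
}

#' Run the full heterosis analysis pipeline
#'
#' Orchestrates an end-to-end run: obtain data (simulate a synthetic panel
#' or read the configured files), compute the per-hybrid heterosis table
#' and population summaries, trait/cross-population/genetic-distance
#' correlations, the association scans for every population x trait x
#' model, and growth-curve analyses when curves are available. All outputs
#' are written as tab-delimited text under `output_dir` together with a
#' `manifest.yaml` recording the configuration hash, seed and package
#' version, and a `warnings.txt` with every warning raised.
#'
#' @param config A `run_config` list (or path to a YAML file).
#' @param output_dir Output directory (overrides `config$output_dir`).
#' @return Invisibly, a list bundle with elements `heterosis`, `summary`,
#'   `correlations`, `cross_population`, `gd_correlation`, `scans`,
#'   `scan_counts`, `growth`, `manifest` (plus the simulated `panel` when
#'   applicable).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  issues <- validate_run_config(config)
  if (nrow(issues) > 0) {
    abort(paste(
      c(
        "Invalid run configuration:",
        sprintf("- %s: %s", issues$field, issues$message)
      ),
      collapse = "\n"
    ))
  }
  out_dir <- output_dir %||% config$output_dir %||% tempfile("heterosis_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  seed <- as.integer(config$seed %||% 1L)
  panel <- NULL
  curves <- NULL
  kinship <- NULL
  genotypes_parents <- NULL

  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    sim_args$seed <- seed
    scfg <- do.call(sim_config, sim_args)
    grow <- isTRUE(config$growth$enabled %||% FALSE)
    panel <- simulate_panel(scfg, growth_curves = grow)
    traits <- panel$traits
    pedigree <- panel$pedigree
    genotypes_parents <- panel$parents
    curves <- panel$curves
  } else {
    traits <- read_trait_table(config$data$traits)
    pedigree <- if (!is.null(config$data$pedigree)) {
      read_pedigree(config$data$pedigree)
    } else {
      abort("A pedigree file is required with real data.")
    }
    if (!is.null(config$data$genotypes)) {
      genotypes_parents <- read_genotypes(config$data$genotypes, config$data$map)
    }
    if (!is.null(config$data$kinship)) {
      kinship <- read_kinship(config$data$kinship)
    }
    if (!is.null(config$data$curves)) {
      curves <- read_growth_curves(config$data$curves)
    }
  }

  excl <- config$exclude
  if (!is.null(excl$genotype_ids)) {
    traits_for_scan <- collect(exclude_outlier_lineage(
      traits, excl$genotype_ids,
      traits = excl$traits %||% unique(traits$trait), pedigree = pedigree
    ))
  } else {
    traits_for_scan <- traits
  }

  # --- heterosis statistics -------------------------------------------------
  het <- heterosis_table(traits, pedigree)
  summary_tbl <- population_summary(traits, pedigree)
  readr::write_tsv(tidy(het), file.path(out_dir, "heterosis.tsv"))
  readr::write_tsv(summary_tbl, file.path(out_dir, "population_summary.tsv"))

  # --- correlations ---------------------------------------------------------
  sums <- summarize_genotypes(traits)
  pops <- unique(pedigree$population)
  cors <- list()
  for (pop in pops) {
    s <- dplyr::filter(sums, .data$population == pop)
    cors[[paste0("parents_", pop)]] <-
      spearman_matrix(.mean_values(s, c("parent", "reference")),
        group = paste0("parents ", pop)
      )
    cors[[paste0("hybrids_", pop)]] <-
      spearman_matrix(.mean_values(dplyr::filter(s, .data$role == "hybrid"), "hybrid"),
        group = paste0("hybrids ", pop)
      )
    mph_long <- het |>
      dplyr::filter(.data$population == pop) |>
      dplyr::select(genotype_id = "hybrid_id", "trait", value = "mph")
    cors[[paste0("mph_", pop)]] <- spearman_matrix(mph_long,
      group = paste0("MPH ", pop)
    )
  }
  cor_long <- purrr::map_dfr(cors, tidy)
  readr::write_tsv(cor_long, file.path(out_dir, "trait_correlations.tsv"))

  cross <- NULL
  if (length(pops) == 2) {
    s1 <- dplyr::filter(sums, .data$population == pops[1])
    s2 <- dplyr::filter(sums, .data$population == pops[2])
    ped1 <- dplyr::filter(pedigree, .data$population == pops[1])
    ped2 <- dplyr::filter(pedigree, .data$population == pops[2])
    hyb_key <- function(s, ped) {
      s |>
        dplyr::filter(.data$role == "hybrid") |>
        dplyr::inner_join(dplyr::select(ped, "hybrid_id", "parent_id"),
          by = c("genotype_id" = "hybrid_id")
        ) |>
        dplyr::select(genotype_id = "parent_id", "trait", value = "mean")
    }
    mph_key <- function(ped) {
      het |>
        dplyr::inner_join(dplyr::select(ped, "hybrid_id"), by = "hybrid_id") |>
        dplyr::select(genotype_id = "parent_id", "trait", value = "mph")
    }
    cross <- dplyr::bind_rows(
      parents = cross_population_r2(
        .mean_values(dplyr::filter(s1, .data$role == "parent"), "parent"),
        .mean_values(dplyr::filter(s2, .data$role == "parent"), "parent")
      ),
      hybrids = cross_population_r2(hyb_key(s1, ped1), hyb_key(s2, ped2)),
      mph = cross_population_r2(mph_key(ped1), mph_key(ped2)),
      .id = "group"
    )
    readr::write_tsv(cross, file.path(out_dir, "cross_population_r2.tsv"))
  }

  # --- genetic distance vs heterosis & scans --------------------------------
  gd <- NULL
  scans <- NULL
  scan_counts <- NULL
  if (!is.null(genotypes_parents) || !is.null(kinship)) {
    if (is.null(kinship)) {
      kin_parents <- subset_accessions(
        genotypes_parents,
        unique(c(pedigree$parent_id, pedigree$reference_id))
      )
      kinship <- compute_kinship(kin_parents,
        method = config$scan$kinship_method %||% "standardized"
      )
    }
    gd <- collect(gd_heterosis_correlation(kinship, het, pedigree))
    readr::write_tsv(gd, file.path(out_dir, "gd_heterosis_correlation.tsv"))
  }
  if (!is.null(genotypes_parents)) {
    scan_traits <- config$scan$traits %||% unique(traits_for_scan$trait)
    models <- config$scan$models %||% c("dominant", "additive")
    het_scan <- if (identical(traits_for_scan, traits)) {
      het
    } else {
      heterosis_table(traits_for_scan, pedigree)
    }
    grid <- tidyr::expand_grid(
      population = pops, trait = scan_traits,
      model = models
    )
    scans <- purrr::pmap_dfr(grid, function(population, trait, model) {
      collect(tidy(scan_heterosis(
        traits_for_scan, genotypes_parents, pedigree,
        trait = trait, model = model, population = population,
        kinship = kinship,
        maf_threshold = config$scan$maf_threshold %||% 0.05,
        raw_threshold = config$scan$raw_threshold %||% 4,
        fdr_alpha = config$scan$fdr_alpha %||% 0.05,
        orientation = config$scan$orientation %||% "reference",
        heterosis = het_scan
      )))
    })
    write_scan_results(scans, file.path(out_dir, "scan_results.tsv"))
    scan_counts <- scans |>
      dplyr::group_by(.data$population, .data$trait, .data$model) |>
      dplyr::summarise(
        n_snps = dplyr::n(),
        n_sig_raw = sum(.data$sig_raw, na.rm = TRUE),
        n_sig_fdr = sum(.data$sig_fdr, na.rm = TRUE),
        .groups = "drop"
      )
    readr::write_tsv(scan_counts, file.path(out_dir, "scan_counts.tsv"))
  } else {
    message("No genotypes configured: association scan stage skipped.")
  }

  # --- growth curves --------------------------------------------------------
  growth <- NULL
  if (!is.null(curves)) {
    thr <- config$growth$threshold %||% 2
    growth <- list(
      establishment = establishment_fraction(curves, threshold = thr),
      mph_raw = mph_over_time(curves, pedigree, align = "raw"),
      mph_t0 = mph_over_time(curves, pedigree,
        align = "t0",
        threshold = thr
      )
    )
    readr::write_tsv(
      growth$establishment,
      file.path(out_dir, "establishment_fraction.tsv")
    )
    readr::write_tsv(growth$mph_t0, file.path(out_dir, "mph_over_time_t0.tsv"))
  }

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = seed,
    package = "heterosisr",
    version = as.character(utils::packageVersion("heterosisr")),
    outputs = sort(list.files(out_dir))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  writeLines(warnings_seen, file.path(out_dir, "warnings.txt"))

  invisible(list(
    heterosis = het, summary = summary_tbl, correlations = cors,
    cross_population = cross, gd_correlation = gd, scans = scans,
    scan_counts = scan_counts, growth = growth, manifest = manifest,
    panel = panel, output_dir = out_dir
  ))
}
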