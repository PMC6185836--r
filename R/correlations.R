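#' Pairwise Spearman correlation matrix across traits
#'
#' Computes pairwise-complete Spearman rank correlations (average-rank ties)
#' between all traits in a per-genotype value table, with two-tailed
#' p-values from the t approximation. Cells with fewer than three complete
#' pairs are undefined (`NA`).
#'
#' @param data Long tibble of per-genotype values: columns `genotype_id`,
#'   `trait`, `value` (typically genotype means or per-hybrid MPH values).
#' @param group Label attached to the result (e.g. `"parents pop1"` or
#'   `"MPH pop2"`).
#' @return A `cor_matrix` object: list with symmetric matrices `r`, `p`,
#'   `n` and the `group` label. Use [tidy()] for a long tibble or
#'   [autoplot()] for a heatmap.
#' @export
spearman_matrix <- function(data, group = "values") {
  .assert_cols(data, c("genotype_id", "trait", "value"), "`data`")
  wide <- tidyr::pivot_wider(
    dplyr::select(data, "genotype_id", "trait", "value"),
    names_from = "trait", values_from = "value"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  traits <- colnames(m)
  k <- length(traits)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1
  diag(p) <- 0
  diag(n) <- colSums(is.finite(m))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- is.finite(m[, i]) & is.finite(m[, j])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) >= 3) {
        ct <- suppressWarnings(
          cor.test(m[ok, i], m[ok, j], method = "spearman", exact = FALSE)
        )
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  structure(list(r = r, p = p, n = n, group = group), class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<cor_matrix> group: %s\n", x$group))
  print(round(x$r, digits))
  invisible(x)
}

#' @rdname spearman_matrix
#' @param x A `cor_matrix`.
#' @param ... Unused.
#' @export
tidy.cor_matrix <- function(x, ...) {
  traits <- rownames(x$r)
  grid <- tidyr::expand_grid(trait_i = traits, trait_j = traits)
  tibble::tibble(
    trait_i = grid$trait_i,
    trait_j = grid$trait_j,
    group = x$group,
    r = x$r[cbind(grid$trait_i, grid$trait_j)],
    p = x$p[cbind(grid$trait_i, grid$trait_j)],
    n = x$n[cbind(grid$trait_i, grid$trait_j)]
  )
}

#' @rdname spearman_matrix
#' @param object A `cor_matrix`.
#' @export
autoplot.cor_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$trait_i, y = .data$trait_j,
    fill = .data$r
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white",
      high = "red", limits = c(-1, 1)
    ) +
    ggplot2::labs(
      title = sprintf("Spearman trait correlations (%s)", object$group),
      x = NULL, y = NULL, fill = "r_s"
    ) +
    ggplot2::theme_minimal()
}

#' Cross-population trait agreement (squared Pearson correlation)
#'
#' Matches genotypes between two per-genotype value tables (parents by
#' identity; hybrids by their shared variable parent — pass the matching id
#' in `genotype_id`) and reports, per trait, the squared Pearson correlation
#' between the two populations with its two-tailed p-value. `r2` is
#' invariant under affine transforms of either table.
#'
#' @param table_a,table_b Long tibbles with columns `genotype_id`, `trait`,
#'   `value` (one value per genotype per trait, e.g. genotype means or MPH).
#' @return A tibble with columns `trait`, `n`, `r`, `r2`, `p`.
#' @export
cross_population_r2 <- function(table_a, table_b) {
  .assert_cols(table_a, c("genotype_id", "trait", "value"), "`table_a`")
  .assert_cols(table_b, c("genotype_id", "trait", "value"), "`table_b`")
  joined <- dplyr::inner_join(
    dplyr::select(table_a, "genotype_id", "trait", value_a = "value"),
    dplyr::select(table_b, "genotype_id", "trait", value_b = "value"),
    by = c("genotype_id", "trait")
  )
  if (nrow(joined) == 0) abort("No shared genotype ids between the tables.")
  joined |>
    dplyr::filter(is.finite(.data$value_a), is.finite(.data$value_b)) |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = if (dplyr::n() >= 3) cor(.data$value_a, .data$value_b) else NA_real_,
      p = if (dplyr::n() >= 3) {
        cor.test(.data$value_a, .data$value_b)$p.value
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(r2 = .data$r^2, .after = "r")
}

#' Correlation between heterosis and parental genetic distance
#'
#' Uses the kinship between each hybrid's two parental lines as a proxy for
#' their genetic distance (kinship is a similarity: higher = genetically
#' closer, so a positive MPH-vs-kinship correlation means less heterosis for
#' more distant parents would appear as a negative coefficient) and reports,
#' per population and trait, the Spearman correlation between per-hybrid MPH
#' and parental kinship with a two-tailed p-value. Hybrids whose parental
#' kinship entry is missing are dropped with a warning. Constant MPH (or
#' kinship) values make the coefficient undefined: `rs = NA`, `p = 1` by
#' convention.
#'
#' @param kinship Symmetric kinship matrix with accession dimnames.
#' @param heterosis Heterosis table from [heterosis_table()] (needs
#'   `hybrid_id`, `population`, `trait`, `mph`).
#' @param pedigree Pedigree tibble.
#' @param value Heterosis column to correlate (default `"mph"`).
#' @return A tibble with columns `population`, `trait`, `n`, `rs`, `p`.
#' @export
gd_heterosis_correlation <- function(kinship, heterosis, pedigree,
                                     value = "mph") {
  .assert_cols(heterosis, c("hybrid_id", "population", "trait", value), "`heterosis`")
  ped <- dplyr::select(pedigree, "hybrid_id", "parent_id", "reference_id")
  df <- dplyr::inner_join(heterosis, ped, by = "hybrid_id",
    suffix = c("", ".ped")
  )
  have <- df$parent_id %in% rownames(kinship) &
    df$reference_id %in% colnames(kinship)
  if (any(!have)) {
    warn(sprintf(
      "%d hybrid-trait rows dropped: parental pair missing from kinship.",
      sum(!have)
    ))
    df <- df[have, , drop = FALSE]
  }
  df$gd_kinship <- kinship[cbind(df$parent_id, df$reference_id)]
  df$.het <- df[[value]]
  df |>
    dplyr::filter(is.finite(.data$.het), is.finite(.data$gd_kinship)) |>
    dplyr::group_by(.data$population, .data$trait) |>
    dplyr::summarise(
      n = dplyr::n(),
      rs = if (dplyr::n() >= 3 && sd(.data$.het) > 0 && sd(.data$gd_kinship) > 0) {
        suppressWarnings(cor(.data$.het, .data$gd_kinship, method = "spearman"))
      } else {
        NA_real_
      },
      p = if (dplyr::n() >= 3 && sd(.data$.het) > 0 && sd(.data$gd_kinship) > 0) {
        suppressWarnings(cor.test(.data$.het, .data$gd_kinship,
          method = "spearman", exact = FALSE
        )$p.value)
      } else {
        1
      },
      .groups = "drop"
    )
}
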