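# collapse (possibly sub-daily) imaging series to one value per plant per
# day: the daily maximum area, since establishment is defined per day
.daily_curves <- function(curves) {
  .assert_cols(
    curves, c("plant_id", "genotype_id", "role", "population", "time", "area_mm2"),
    "`curves`"
  )
  curves |>
    dplyr::mutate(day = floor(.data$time)) |>
    dplyr::group_by(
      .data$plant_id, .data$genotype_id, .data$role,
      .data$population, .data$day
    ) |>
    dplyr::summarise(area_mm2 = max(.data$area_mm2), .groups = "drop")
}

#' Detect establishment day (t0) per plant
#'
#' Assigns each plant's t0 to the first day its projected leaf area exceeds
#' the threshold (default 2 mm2, the area at which cotyledons emerge and
#' expand). Sub-daily series are collapsed to daily maxima first. The first
#' crossing counts even if a noisy curve later dips back below the
#' threshold; set `confirm > 1` to require that many consecutive days above
#' the threshold instead. Plants that never exceed the threshold get
#' `NA` ("undetected").
#'
#' @param curves Long growth-curve tibble (`plant_id`, `genotype_id`,
#'   `role`, `population`, `time`, `area_mm2`).
#' @param threshold Area threshold in mm2 (default 2).
#' @param confirm Number of consecutive daily points required above the
#'   threshold (default 1 = plain first crossing).
#' @return A tibble with one row per plant and its `t0` day.
#' @export
#' @examples
#' curves <- tibble::tibble(
#'   plant_id = "p1", genotype_id = "g", role = "parent",
#'   population = "pop1", time = 1:4, area_mm2 = c(0, 1, 3, 5)
#' )
#' detect_establishment(curves)$t0 # day 3
detect_establishment <- function(curves, threshold = 2, confirm = 1) {
  daily <- .daily_curves(curves)
  daily |>
    dplyr::group_by(
      .data$plant_id, .data$genotype_id, .data$role,
      .data$population
    ) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      t0 = {
        above <- .data$area_mm2 > threshold
        runs <- which(purrr::map_lgl(
          seq_along(above),
          function(i) {
            i + confirm - 1 <= length(above) && all(above[i:(i + confirm - 1)])
          }
        ))
        if (length(runs) == 0) NA_real_ else .data$day[runs[1]]
      },
      .groups = "drop"
    )
}

#' Fraction of visible plants per day, hybrids versus parents
#'
#' For each requested day, computes the fraction of plants whose projected
#' leaf area exceeds the detection threshold, separately for hybrids and for
#' parental lines (variable parents and reference pooled), and tests the
#' hybrid-vs-parent difference per day with a two-proportion chi-squared
#' test (continuity-corrected; `NA` when a margin is degenerate).
#'
#' @param curves Long growth-curve tibble.
#' @param days Days to evaluate (default: all days present).
#' @param threshold Detection threshold in mm2 (default 2, matching the
#'   establishment threshold).
#' @return A tibble with columns `day`, `n_hybrid`, `n_parent`,
#'   `frac_hybrid`, `frac_parent`, `p`.
#' @export
establishment_fraction <- function(curves, days = NULL, threshold = 2) {
  daily <- .daily_curves(curves)
  if (is.null(days)) days <- sort(unique(daily$day))
  daily |>
    dplyr::filter(.data$day %in% days) |>
    dplyr::mutate(role_group = ifelse(.data$role == "hybrid", "hybrid", "parent")) |>
    dplyr::group_by(.data$day) |>
    dplyr::group_modify(function(df, key) {
      vis <- tapply(df$area_mm2 > threshold, df$role_group, sum)
      tot <- tapply(df$area_mm2 > threshold, df$role_group, length)
      nh <- tot[["hybrid"]] %||% 0L
      np <- tot[["parent"]] %||% 0L
      vh <- vis[["hybrid"]] %||% 0L
      vp <- vis[["parent"]] %||% 0L
      p <- if (nh > 0 && np > 0 &&
        !(vh + vp == 0) && !(vh + vp == nh + np)) {
        suppressWarnings(
          stats::prop.test(c(vh, vp), c(nh, np))$p.value
        )
      } else {
        NA_real_
      }
      tibble::tibble(
        n_hybrid = nh, n_parent = np,
        frac_hybrid = if (nh > 0) vh / nh else NA_real_,
        frac_parent = if (np > 0) vp / np else NA_real_,
        p = p
      )
    }) |>
    dplyr::ungroup()
}

#' Mid-parent heterosis of projected leaf area over time
#'
#' Computes per-hybrid MPH of genotype-mean leaf area at every shared time
#' offset, either on the raw days-after-sowing axis (`align = "raw"`) or
#' after t0 normalisation (`align = "t0"`), where each plant's series is
#' first re-indexed to days since its own establishment day (see
#' [detect_establishment()]) before genotype averaging. t0 normalisation
#' removes pure establishment-timing differences between genotypes, so the
#' remaining MPH reflects growth-rate/size heterosis.
#'
#' @param curves Long growth-curve tibble.
#' @param pedigree Pedigree tibble.
#' @param align `"raw"` or `"t0"`.
#' @param threshold t0 threshold in mm2 (used when `align = "t0"`).
#' @param min_plants Offsets with fewer plants than this per genotype are
#'   dropped (default 2).
#' @return A tibble with one row per (hybrid, time offset): genotype-mean
#'   areas of hybrid and parents plus `mpv`, `mph_abs`, `mph`.
#' @export
mph_over_time <- function(curves, pedigree, align = c("raw", "t0"),
                          threshold = 2, min_plants = 2) {
  align <- match.arg(align)
  daily <- .daily_curves(curves)
  if (align == "t0") {
    t0 <- detect_establishment(curves, threshold = threshold) |>
      dplyr::select("plant_id", "t0") |>
      dplyr::filter(is.finite(.data$t0))
    daily <- daily |>
      dplyr::inner_join(t0, by = "plant_id") |>
      dplyr::mutate(day = .data$day - .data$t0) |>
      dplyr::filter(.data$day >= 0)
  }
  gmeans <- daily |>
    dplyr::group_by(
      .data$genotype_id, .data$population, .data$day
    ) |>
    dplyr::summarise(
      n_plants = dplyr::n(),
      area = mean(.data$area_mm2), .groups = "drop"
    ) |>
    dplyr::filter(.data$n_plants >= min_plants)

  gsel <- dplyr::select(gmeans, "genotype_id", "population", "day", "area")
  out <- pedigree |>
    dplyr::inner_join(
      dplyr::rename(gsel, hybrid_id = "genotype_id", hybrid_area = "area"),
      by = c("hybrid_id", "population")
    ) |>
    dplyr::inner_join(
      dplyr::rename(gsel, parent_id = "genotype_id", parent_area = "area"),
      by = c("parent_id", "population", "day")
    ) |>
    dplyr::inner_join(
      dplyr::rename(gsel, reference_id = "genotype_id", reference_area = "area"),
      by = c("reference_id", "population", "day")
    )
  dplyr::bind_cols(
    dplyr::select(
      out, "hybrid_id", "parent_id", "reference_id", "population",
      time = "day", "hybrid_area", "parent_area", "reference_area"
    ),
    mid_parent_heterosis(out$hybrid_area, out$parent_area, out$reference_area)
  ) |>
    dplyr::arrange(.data$hybrid_id, .data$time)
}

#' Plot growth curves by role
#'
#' @param curves Long growth-curve tibble.
#' @param max_plants Subsample at most this many plants for legibility.
#' @return A ggplot object: area versus time, coloured by role.
#' @export
plot_growth_curves <- function(curves, max_plants = 200) {
  ids <- unique(curves$plant_id)
  if (length(ids) > max_plants) {
    curves <- dplyr::filter(curves, .data$plant_id %in% ids[seq_len(max_plants)])
  }
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$time, y = .data$area_mm2,
    group = .data$plant_id, colour = .data$role
  )) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "days after sowing", y = expression(area ~ (mm^2)),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
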