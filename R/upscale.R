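#' Upscale the branch-level flower model over one QSM
#'
#' Applies the hurdle model to every flower-bearing branch unit of a single
#' cylinder model and sums the predicted flowers. For each unit, the
#' occurrence probability is evaluated at the unit's root diameter (mm), the
#' tree's dbh and the unit's crown position, with random intercepts at zero
#' (marginal prediction); a Bernoulli draw with that probability decides
#' whether the unit flowers. Flowering units contribute the zero-truncated NB
#' expected count by default, or a full ZTNB draw with
#' `sample_counts = TRUE`. With `force_occurrence = TRUE` every unit flowers
#' and the default total is fully deterministic — the analytic sum of ZTNB
#' means used as an oracle in the package's tests.
#'
#' @param qsm Cylinder table for one tree and replicate.
#' @param coefs A [hurdle_coefficients()] object (or the `$coefficients` of a
#'   [fit_flower_hurdle()] fit).
#' @param dbh_cm Tree dbh in cm; derived from the QSM when `NULL`.
#' @param d_max_mm Branch-unit diameter threshold, mm.
#' @param layer_depth,slice_height Crown-classification geometry, m.
#' @param sample_counts Draw counts from the ZTNB instead of using its mean.
#' @param force_occurrence Skip the Bernoulli stage (all units flower).
#' @param seed Optional integer seed making the replicate reproducible.
#' @param detail Return the per-unit table instead of the total.
#' @return The predicted flower total (numeric scalar), or with
#'   `detail = TRUE` a tibble with one row per unit (`root_cyl_id`,
#'   `root_diameter_mm`, `stratum`, `layer`, `p_occurrence`, `flowering`,
#'   `flowers`).
#' @export
upscale_replicate <- function(qsm, coefs, dbh_cm = NULL, d_max_mm = 30,
                              layer_depth = 2, slice_height = 0.5,
                              sample_counts = FALSE, force_occurrence = FALSE,
                              seed = NULL, detail = FALSE) {
  run <- function() {
    units <- extract_branch_units(qsm, d_max_mm)
    if (nrow(units) == 0) {
      out <- tibble::tibble(
        root_cyl_id = integer(0), root_diameter_mm = numeric(0),
        stratum = character(0), layer = character(0),
        p_occurrence = numeric(0), flowering = logical(0), flowers = numeric(0)
      )
      return(if (detail) out else 0)
    }
    if (any(units$root_diameter_mm <= 0 | units$root_diameter_mm > d_max_mm)) {
      abort("branch-unit root diameter outside (0, d_max]",
        class = "bloomscale_error_threshold"
      )
    }
    units <- classify_crown_position(units, qsm, layer_depth, slice_height)
    if (is.null(dbh_cm)) {
      dbh_cm <- derive_tree_metrics(qsm)$dbh_cm
    }
    p <- predict_occurrence_probability(
      units$root_diameter_mm, dbh_cm, units$layer, units$stratum, coefs
    )
    flowering <- if (force_occurrence) {
      rep(TRUE, nrow(units))
    } else {
      runif(nrow(units)) < p
    }
    mu <- exp(.hurdle_lp(
      coefs$abundance, units$root_diameter_mm, dbh_cm,
      units$layer, units$stratum
    ))
    count <- if (sample_counts) {
      .rztnb(nrow(units), mu, coefs$theta)
    } else {
      ztnb_mean(mu, coefs$theta)
    }
    out <- units |>
      dplyr::select(-"member_cyl_ids", -dplyr::starts_with("center_")) |>
      dplyr::mutate(
        p_occurrence = p,
        flowering = flowering,
        flowers = ifelse(flowering, count, 0)
      )
    if (detail) out else sum(out$flowers)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Upscale a cylinder table covering several trees and replicates
#'
#' Splits a combined cylinder table by `tree_id` and `replicate_id`, runs
#' [upscale_replicate()] on each QSM and returns the per-replicate totals.
#' Each replicate gets its own random stream derived from the master `seed`
#' and the replicate's position, so results are reproducible per seed while
#' replicates stay independent.
#'
#' @param cylinders Cylinder table with `tree_id` and `replicate_id` columns.
#' @param coefs A [hurdle_coefficients()] object.
#' @param seed Master seed for the Bernoulli (and optional count) draws.
#' @inheritParams upscale_replicate
#' @return A tibble with `tree_id`, `replicate_id`, `total`.
#' @export
upscale_qsms <- function(cylinders, coefs, seed = 1L, d_max_mm = 30,
                         layer_depth = 2, slice_height = 0.5,
                         sample_counts = FALSE, force_occurrence = FALSE) {
  groups <- cylinders |>
    dplyr::distinct(.data$tree_id, .data$replicate_id) |>
    dplyr::arrange(.data$tree_id, .data$replicate_id)
  purrr::map(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    qsm <- dplyr::filter(
      cylinders,
      .data$tree_id == g$tree_id, .data$replicate_id == g$replicate_id
    )
    tibble::tibble(
      tree_id = g$tree_id,
      replicate_id = g$replicate_id,
      total = upscale_replicate(qsm, coefs,
        d_max_mm = d_max_mm,
        layer_depth = layer_depth, slice_height = slice_height,
        sample_counts = sample_counts, force_occurrence = force_occurrence,
        seed = seed + i
      )
    )
  }) |> dplyr::bind_rows()
}

#' Aggregate per-replicate flower totals to per-tree estimates
#'
#' Because QSM reconstruction is stochastic, several cylinder models exist
#' per tree; the tree's flower estimate is the median total across its
#' replicates (even counts average the central pair), with the SD across
#' replicates as the reconstruction-dispersion measure.
#'
#' @param totals A tibble with `tree_id`, `replicate_id`, `total` (from
#'   [upscale_qsms()]).
#' @return A tibble with `tree_id`, `n_replicates`, `median_total`,
#'   `sd_total`.
#' @export
aggregate_tree_estimates <- function(totals) {
  if (nrow(totals) == 0) {
    abort("no replicate totals to aggregate", class = "bloomscale_error_aggregation")
  }
  totals |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      median_total = median(.data$total),
      sd_total = ifelse(dplyr::n() > 1, sd(.data$total), 0),
      .groups = "drop"
    )
}
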