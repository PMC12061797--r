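#' Pollen and nectar parameter sets
#'
#' Containers for the per-flower resource constants used in the budgets. The
#' defaults describe wild cherry: 16,059 pollen grains per flower (SE 3,327)
#' with a mean grain diameter of 32.63 um (SE 0.73), a nectar production of
#' 3.7 mg/flower/24 h (literature range 1.4-6.0) and a nectar sugar content
#' of 23.5% (range 10%-37%). Means of ranges are the range midpoints; in the
#' Monte Carlo stage the SEs are used directly as SDs and the ranges are
#' treated as 95% intervals, i.e. range width / 4 as SD.
#'
#' @param grains_per_flower_mean,grains_per_flower_se Pollen grains per
#'   flower.
#' @param grain_diameter_mean_um,grain_diameter_se_um Pollen grain diameter,
#'   um.
#' @return A `pollen_params` / `nectar_params` list.
#' @export
pollen_params <- function(grains_per_flower_mean = 16059,
                          grains_per_flower_se = 3327,
                          grain_diameter_mean_um = 32.63,
                          grain_diameter_se_um = 0.73) {
  if (min(grains_per_flower_mean, grains_per_flower_se,
    grain_diameter_mean_um, grain_diameter_se_um) <= 0) {
    abort("pollen parameters must be positive", class = "bloomscale_error_domain")
  }
  structure(
    list(
      grains_per_flower_mean = grains_per_flower_mean,
      grains_per_flower_se = grains_per_flower_se,
      grain_diameter_mean_um = grain_diameter_mean_um,
      grain_diameter_se_um = grain_diameter_se_um
    ),
    class = "pollen_params"
  )
}

#' @rdname pollen_params
#' @param production_mean Nectar production, mg/flower/24 h.
#' @param production_range Literature range of the production, mg/flower/24 h.
#' @param sugar_fraction_mean Sugar mass fraction of nectar, in (0, 1).
#' @param sugar_range Literature range of the sugar fraction.
#' @export
nectar_params <- function(production_mean = 3.7, production_range = c(1.4, 6.0),
                          sugar_fraction_mean = 0.235, sugar_range = c(0.10, 0.37)) {
  if (production_mean < production_range[1] || production_mean > production_range[2] ||
    sugar_fraction_mean < sugar_range[1] || sugar_fraction_mean > sugar_range[2]) {
    abort("range bounds must bracket the mean", class = "bloomscale_error_domain")
  }
  if (sugar_fraction_mean <= 0 || sugar_fraction_mean >= 1) {
    abort("sugar fraction must be in (0, 1)", class = "bloomscale_error_domain")
  }
  structure(
    list(
      production_mean = production_mean, production_range = production_range,
      sugar_fraction_mean = sugar_fraction_mean, sugar_range = sugar_range
    ),
    class = "nectar_params"
  )
}

#' Default bee-species pollen requirements
#'
#' Per-larva pollen requirements (mm^3) for two bee species commonly
#' foraging on cherry. These values are *synthetic defaults back-solved from
#' published per-tree pollen volumes and larvae counts* — they are not
#' measured requirements, and users with species-specific data should supply
#' their own table (columns `species`, `pollen_mm3_per_larva`).
#'
#' @return A tibble with `species` and `pollen_mm3_per_larva`.
#' @export
bee_species_defaults <- function() {
  tibble::tibble(
    species = c("Lasioglossum laticeps", "Bombus terrestris"),
    pollen_mm3_per_larva = c(10.98, 61.6)
  )
}

#' Pollen volume of a single flower
#'
#' Pollen grains are treated as spheres: the volume per flower is
#' `(pi/6) * d^3` (d in mm) times the number of grains.
#'
#' @param pollen A [pollen_params()] object.
#' @return Pollen volume per flower, mm^3.
#' @examples
#' pollen_volume_per_flower(pollen_params()) # about 0.29 mm^3
#' @export
pollen_volume_per_flower <- function(pollen = pollen_params()) {
  d_mm <- pollen$grain_diameter_mean_um / 1000
  (pi / 6) * d_mm^3 * pollen$grains_per_flower_mean
}

#' Point resource budget of a flower total
#'
#' Converts a flower number into the daily foraging resources it represents:
#' pollen volume (per-flower sphere volume times flowers), nectar mass
#' (flowers times per-flower production) and nectar sugar (nectar times sugar
#' fraction).
#'
#' @param flowers Flower count(s), >= 0.
#' @param pollen A [pollen_params()] object.
#' @param nectar A [nectar_params()] object.
#' @return A tibble with `flowers`, `pollen_mm3`, `pollen_cm3`,
#'   `nectar_g_24h`, `sugar_g_24h`.
#' @examples
#' tree_resources(195535)
#' @export
tree_resources <- function(flowers, pollen = pollen_params(), nectar = nectar_params()) {
  if (any(flowers < 0)) {
    abort("flowers must be >= 0", class = "bloomscale_error_domain")
  }
  per_flower <- pollen_volume_per_flower(pollen)
  pollen_mm3 <- flowers * per_flower
  nectar_g <- flowers * nectar$production_mean / 1000
  tibble::tibble(
    flowers = flowers,
    pollen_mm3 = pollen_mm3,
    pollen_cm3 = pollen_mm3 / 1000,
    nectar_g_24h = nectar_g,
    sugar_g_24h = nectar_g * nectar$sugar_fraction_mean
  )
}

#' Bee larvae supported by a pollen volume
#'
#' Divides the available pollen volume by each species' per-larva
#' requirement, rounded to the nearest whole larva.
#'
#' @param pollen_cm3 Available pollen volume, cm^3.
#' @param species A species table as from [bee_species_defaults()].
#' @return A tibble with `species`, `pollen_mm3_per_larva`, `larvae`.
#' @export
larvae_supported <- function(pollen_cm3, species = bee_species_defaults()) {
  if (any(species$pollen_mm3_per_larva <= 0)) {
    abort("pollen requirement must be > 0", class = "bloomscale_error_domain")
  }
  species |>
    dplyr::mutate(larvae = round(pollen_cm3 * 1000 / .data$pollen_mm3_per_larva))
}

# normal draw truncated below at a small positive floor (1% of the mean)
.rnorm_floor <- function(n, mean, sd) {
  pmax(rnorm(n, mean, sd), 0.01 * mean)
}

#' Bootstrap + Monte Carlo confidence intervals for resource budgets
#'
#' Propagates both the sampling uncertainty of the tree-level dbh allometry
#' and the measurement/literature uncertainty of the resource constants into
#' 95% confidence intervals. Each of the `B` repetitions (i) resamples trees
#' with replacement and refits the NB flower-dbh model, (ii) draws the four
#' uncertain per-flower parameters from normal distributions (SEs as SDs for
#' the measured pollen quantities; range/4 as SD for the literature nectar
#' ranges, negative draws floored at 1% of the mean), and (iii) predicts
#' flowers, pollen, nectar sugar and supported larvae on the dbh grid. CIs
#' are the 2.5% and 97.5% percentiles over repetitions; larvae CIs transform
#' the same pollen predictions per species. Repetitions whose refit fails
#' are dropped; more than 10% failures is an error.
#'
#' @param data Per-tree table with flower totals (`median_total` or
#'   `flowers`) and `dbh_cm`.
#' @param dbh_grid dbh values (cm) at which to report budgets.
#' @param pollen,nectar Parameter sets; see [pollen_params()],
#'   [nectar_params()].
#' @param species Bee-species table; see [bee_species_defaults()].
#' @param B Number of bootstrap repetitions (default 1000).
#' @param seed Integer seed.
#' @return A tibble with one row per dbh grid point and quantity
#'   (`flowers`, `pollen_cm3`, `nectar_g_24h`, `sugar_g_24h`, and one
#'   `larvae: <species>` row per species): `dbh_cm`, `quantity`, `estimate`,
#'   `ci_low`, `ci_high`. The number of dropped repetitions is attached as
#'   attribute `"n_failed"`.
#' @export
bootstrap_resource_ci <- function(data, dbh_grid, pollen = pollen_params(),
                                  nectar = nectar_params(),
                                  species = bee_species_defaults(),
                                  B = 1000, seed = 1L) {
  y <- round(data[["median_total"]] %||% data[["flowers"]])
  x <- data$dbh_cm
  if (length(y) < 5) {
    abort("need at least 5 trees", class = "bloomscale_error_size")
  }
  if (B < 2) {
    abort("B must be >= 2", class = "bloomscale_error_domain")
  }

  point_model <- fit_tree_model(
    tibble::tibble(flowers = y, dbh_cm = x), "dbh", loocv = FALSE
  )
  point_flowers <- suppressWarnings(predict_tree_flowers(point_model, dbh_grid))
  point_res <- tree_resources(point_flowers, pollen, nectar)

  sims <- withr::with_seed(seed, {
    purrr::map(seq_len(B), function(b) {
      idx <- sample(length(y), replace = TRUE)
      fit <- tryCatch(
        suppressWarnings(MASS::glm.nb(yy ~ xx, data = data.frame(yy = y[idx], xx = x[idx]))),
        error = function(e) NULL
      )
      draws <- c(
        grains = .rnorm_floor(1, pollen$grains_per_flower_mean, pollen$grains_per_flower_se),
        diam = .rnorm_floor(1, pollen$grain_diameter_mean_um, pollen$grain_diameter_se_um),
        prod = .rnorm_floor(1, nectar$production_mean, diff(nectar$production_range) / 4),
        sugar = .rnorm_floor(1, nectar$sugar_fraction_mean, diff(nectar$sugar_range) / 4)
      )
      if (is.null(fit)) {
        return(NULL)
      }
      fl <- exp(coef(fit)[1] + coef(fit)[2] * dbh_grid)
      per_flower_mm3 <- (pi / 6) * (draws[["diam"]] / 1000)^3 * draws[["grains"]]
      tibble::tibble(
        b = b, dbh_cm = dbh_grid,
        flowers = fl,
        pollen_cm3 = fl * per_flower_mm3 / 1000,
        nectar_g_24h = fl * draws[["prod"]] / 1000,
        sugar_g_24h = fl * draws[["prod"]] * draws[["sugar"]] / 1000
      )
    })
  })
  failed <- sum(vapply(sims, is.null, logical(1)))
  if (failed > 0.1 * B) {
    abort(paste0(failed, " of ", B, " bootstrap refits failed"),
      class = "bloomscale_error_ci"
    )
  }
  if (failed > 0) {
    inform(paste0(failed, " bootstrap repetitions dropped after refit failure"))
  }
  sims <- dplyr::bind_rows(sims)

  base_quants <- c("flowers", "pollen_cm3", "nectar_g_24h", "sugar_g_24h")
  long <- sims |>
    tidyr::pivot_longer(dplyr::all_of(base_quants),
      names_to = "quantity", values_to = "value"
    )
  larvae_long <- purrr::map(seq_len(nrow(species)), function(i) {
    sims |>
      dplyr::transmute(
        .data$b, .data$dbh_cm,
        quantity = paste0("larvae: ", species$species[i]),
        value = .data$pollen_cm3 * 1000 / species$pollen_mm3_per_larva[i]
      )
  }) |> dplyr::bind_rows()

  ci <- dplyr::bind_rows(long, larvae_long) |>
    dplyr::group_by(.data$dbh_cm, .data$quantity) |>
    dplyr::summarise(
      ci_low = quantile(.data$value, 0.025, names = FALSE),
      ci_high = quantile(.data$value, 0.975, names = FALSE),
      .groups = "drop"
    )

  point_larvae <- purrr::map(seq_len(nrow(species)), function(i) {
    tibble::tibble(
      dbh_cm = dbh_grid,
      quantity = paste0("larvae: ", species$species[i]),
      estimate = point_res$pollen_cm3 * 1000 / species$pollen_mm3_per_larva[i]
    )
  }) |> dplyr::bind_rows()
  points <- dplyr::bind_rows(
    tibble::tibble(
      dbh_cm = rep(dbh_grid, length(base_quants)),
      quantity = rep(base_quants, each = length(dbh_grid)),
      estimate = c(
        point_res$flowers, point_res$pollen_cm3,
        point_res$nectar_g_24h, point_res$sugar_g_24h
      )
    ),
    point_larvae
  )

  out <- dplyr::left_join(points, ci, by = c("dbh_cm", "quantity")) |>
    dplyr::arrange(.data$dbh_cm, .data$quantity)
  attr(out, "n_failed") <- failed
  out
}
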