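test_that("predictor screening reports Pearson r and collinearity", {
  d <- tibble::tibble(
    flowers = c(10, 20, 30, 40, 50),
    dbh_cm = c(1, 2, 3, 4, 5),
    height_m = c(5, 3, 8, 1, 9)
  )
  out <- screen_predictors(d)
  expect_equal(out$r[out$predictor == "dbh_cm"], 1)
  expect_gt(out$r[out$predictor == "dbh_cm"], out$r[out$predictor == "height_m"])

  expect_error(
    screen_predictors(dplyr::mutate(d, dbh_cm = 2)),
    class = "bloomscale_error_correlation"
  )
  expect_error(screen_predictors(d[1:2, ]), class = "bloomscale_error_size")
})

test_that("synthetic forests couple dbh and crown volume collinearly", {
  forest <- generate_forest(synthetic_forest_spec(
    n_trees = 10, n_replicates = 1, noise_sd = 0, seed = 2
  ))
  metrics <- forest$cylinders |>
    dplyr::group_by(tree_id) |>
    dplyr::group_modify(~ derive_tree_metrics(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(flowers = exp(8.03 + 0.17 * dbh_cm))
  out <- screen_predictors(metrics)
  coll <- attr(out, "collinearity")
  pair <- coll[coll$predictor_1 == "dbh_cm" & coll$predictor_2 == "crown_volume_m3", ]
  expect_gt(abs(pair$r), 0.7)
  expect_true(pair$collinear)
})

test_that("NB allometry fitting recovers structure and flags degeneracies", {
  withr::with_seed(23, {
    x <- runif(39, 9, 28)
    y <- rnbinom(39, size = 5, mu = exp(8.03 + 0.17 * x))
    fit <- fit_tree_model(tibble::tibble(flowers = y, dbh_cm = x), "dbh")
    expect_lt(abs(fit$coefficients["slope"] - 0.17), 3 * fit$se["slope"])
    expect_gt(fit$metrics$r2, 0.5)
    # no leakage: held-out error at least as large as in-sample
    expect_gte(fit$metrics$rmse_cv, fit$metrics$rmse * 0.99)

    const <- tibble::tibble(flowers = rep(1000, 10) + rep(c(0, 1), 5), dbh_cm = runif(10, 9, 28))
    cfit <- suppressWarnings(fit_tree_model(const, "dbh", loocv = FALSE))
    expect_lt(abs(cfit$coefficients["slope"]), 0.01)

    pois <- tibble::tibble(
      flowers = rpois(30, exp(4 + 0.1 * (1:30 / 3))),
      dbh_cm = 1:30 / 3 + 9
    )
    expect_warning(fit_tree_model(pois, "dbh", loocv = FALSE), "theta|Poisson")
  })
  expect_error(
    fit_tree_model(tibble::tibble(flowers = 1:3, dbh_cm = 1:3), "dbh"),
    class = "bloomscale_error_size"
  )
})

test_that("allometric predictions follow the log link", {
  cv_model <- tree_flower_model(9.80, 0.01, "crown_volume")
  expect_equal(predict_tree_flowers(cv_model, 20), exp(10.0))
  expect_equal(round(predict_tree_flowers(cv_model, 20) / 1000) * 1000, 22000)

  dbh_model <- tree_flower_model(8.03, 0.17, "dbh", calibration_range = c(9, 28))
  expect_warning(p0 <- predict_tree_flowers(dbh_model, 1e-9), "calibration")
  expect_equal(p0, exp(8.03), tolerance = 1e-6)
  expect_error(predict_tree_flowers(dbh_model, -1), class = "bloomscale_error_domain")

  x <- seq(9, 28, by = 1)
  expect_true(all(diff(predict_tree_flowers(dbh_model, x)) > 0))
})

test_that("fold changes and row totals reproduce the nonlinearity arithmetic", {
  expect_equal(round(flower_fold_change(0.1662, 150)), 12)
  expect_equal(round(flower_fold_change(0.1662, 100)), 5)
  expect_equal(flower_fold_change(0.1662, 0), 1)

  expect_equal(row_flower_total(34, 16163), 549542)
  expect_equal(row_flower_total(14, 195535), 2737490)
  expect_equal(round(row_flower_ratio(14, 195535, 34, 16163)), 5)
  expect_equal(row_flower_total(0, 1e5), 0)
  expect_equal(row_flower_ratio(10, 50, 10, 50), 1)
})

test_that("tidiers expose coefficients and metrics", {
  withr::with_seed(3, {
    x <- runif(20, 9, 28)
    y <- rnbinom(20, size = 5, mu = exp(8 + 0.17 * x))
    fit <- fit_tree_model(tibble::tibble(flowers = y, dbh_cm = x), "dbh", loocv = FALSE)
  })
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "dbh"))
  gl <- glance(fit)
  expect_true(all(c("predictor", "theta", "r2", "mae", "rmse") %in% names(gl)))
})
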