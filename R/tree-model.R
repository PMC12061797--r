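#' Screen tree dimensions as predictors of flower totals
#'
#' Computes Pearson correlations (with p-values) between per-tree flower
#' totals and each candidate tree dimension, and flags collinearity between
#' candidate predictors (|r| > 0.7), the criterion used to fit separate
#' single-predictor allometries instead of a joint model.
#'
#' @param data A tibble with `median_total` (or `flowers`) and any of
#'   `dbh_cm`, `height_m`, `crown_diameter_m`, `crown_projection_area_m2`,
#'   `crown_volume_m3`.
#' @param collinearity_threshold Absolute correlation above which two
#'   predictors are flagged as collinear (default 0.7).
#' @return A tibble with `predictor`, `r`, `p_value`; the pairwise
#'   between-predictor correlations with a `collinear` flag are attached as
#'   attribute `"collinearity"`.
#' @export
screen_predictors <- function(data, collinearity_threshold = 0.7) {
  y <- data[["median_total"]] %||% data[["flowers"]]
  if (nrow(data) < 3) {
    abort("need at least 3 trees to screen predictors", class = "bloomscale_error_size")
  }
  candidates <- intersect(
    c("dbh_cm", "height_m", "crown_diameter_m", "crown_projection_area_m2", "crown_volume_m3"),
    names(data)
  )
  out <- purrr::map(candidates, function(v) {
    x <- data[[v]]
    if (sd(x) == 0 || sd(y) == 0) {
      abort(paste0("zero-variance variable: ", v), class = "bloomscale_error_correlation")
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(predictor = v, r = unname(ct$estimate), p_value = ct$p.value)
  }) |> dplyr::bind_rows()

  pairs <- utils::combn(candidates, 2, simplify = FALSE)
  coll <- purrr::map(pairs, function(p) {
    r <- stats::cor(data[[p[1]]], data[[p[2]]])
    tibble::tibble(
      predictor_1 = p[1], predictor_2 = p[2], r = r,
      collinear = abs(r) > collinearity_threshold
    )
  }) |> dplyr::bind_rows()
  attr(out, "collinearity") <- coll
  out
}

#' Tree-level flower allometry
#'
#' `tree_flower_model()` builds the model object directly from known
#' coefficients — the form `log(flowers) = b0 + b1 * x` with a negative
#' binomial response — so published coefficient tables can be used for
#' prediction without refitting. `fit_tree_model()` estimates the
#' coefficients from per-tree flower totals by maximum likelihood
#' (`MASS::glm.nb`, NB2 parameterisation); totals are rounded to the nearest
#' integer for the count likelihood. The intercept is estimated freely (not
#' forced through the origin).
#'
#' @param intercept,slope Coefficients on the log link scale.
#' @param predictor `"dbh"` (cm) or `"crown_volume"` (m^3).
#' @param theta NB dispersion, if known.
#' @param calibration_range Range of the predictor over which the model was
#'   calibrated; predictions outside it warn.
#' @return An object of class `tree_flower_model`.
#' @export
tree_flower_model <- function(intercept, slope, predictor = c("dbh", "crown_volume"),
                              theta = NA_real_, calibration_range = NULL) {
  predictor <- match.arg(predictor)
  structure(
    list(
      predictor = predictor,
      coefficients = c(intercept = intercept, slope = slope),
      theta = theta,
      se = c(intercept = NA_real_, slope = NA_real_),
      calibration_range = calibration_range,
      metrics = NULL,
      fit = NULL
    ),
    class = "tree_flower_model"
  )
}

#' @rdname tree_flower_model
#' @param data A tibble with the flower totals (`median_total` or `flowers`)
#'   and the predictor column (`dbh_cm` or `crown_volume_m3`).
#' @param loocv Also compute leave-one-out cross-validated MAE/RMSE.
#' @export
fit_tree_model <- function(data, predictor = c("dbh", "crown_volume"), loocv = TRUE) {
  predictor <- match.arg(predictor)
  y <- round(data[["median_total"]] %||% data[["flowers"]])
  x <- switch(predictor,
    dbh = data$dbh_cm,
    crown_volume = data$crown_volume_m3
  )
  if (length(y) < 5) {
    abort("need at least 5 trees to fit the tree-level model",
      class = "bloomscale_error_size"
    )
  }
  if (any(y <= 0)) {
    abort("tree flower totals must be positive", class = "bloomscale_error_domain")
  }
  df <- data.frame(y = y, x = x)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ x, data = df)),
    error = function(e) {
      abort(paste0("tree-level NB fit failed: ", conditionMessage(e)),
        class = "bloomscale_error_optimization"
      )
    }
  )
  if (fit$theta > 1e5) {
    warn("dispersion estimate at its large-theta boundary (data look Poisson)")
  }

  pred_in <- exp(predict(fit, newdata = df))
  mae_in <- mean(abs(y - pred_in))
  rmse_in <- sqrt(mean((y - pred_in)^2))
  # pseudo-R2 on the log scale, the scale of the linear predictor
  r2 <- stats::cor(log(y), predict(fit, newdata = df))^2

  metrics <- tibble::tibble(
    r2 = r2, mae = mae_in, rmse = rmse_in,
    mae_cv = NA_real_, rmse_cv = NA_real_
  )
  if (loocv) {
    cv_pred <- vapply(seq_along(y), function(i) {
      refit <- suppressWarnings(MASS::glm.nb(y ~ x, data = df[-i, , drop = FALSE]))
      exp(predict(refit, newdata = df[i, , drop = FALSE]))
    }, numeric(1))
    metrics$mae_cv <- mean(abs(y - cv_pred))
    metrics$rmse_cv <- sqrt(mean((y - cv_pred)^2))
  }

  structure(
    list(
      predictor = predictor,
      coefficients = c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2])),
      theta = fit$theta,
      se = c(
        intercept = unname(sqrt(diag(vcov(fit)))[1]),
        slope = unname(sqrt(diag(vcov(fit)))[2])
      ),
      calibration_range = range(x),
      metrics = metrics,
      fit = fit
    ),
    class = "tree_flower_model"
  )
}

#' @export
print.tree_flower_model <- function(x, ...) {
  cat(
    "Tree flower allometry: log(flowers) =",
    signif(x$coefficients["intercept"], 4), "+",
    signif(x$coefficients["slope"], 4), "*", x$predictor, "\n"
  )
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Predict whole-tree flower numbers
#'
#' Evaluates `exp(b0 + b1 * x)` for a fitted or hand-built
#' [tree_flower_model()]. Predictions outside the calibration range warn but
#' are returned (the allometry extrapolates smoothly; the warning marks where
#' it is unsupported by data).
#'
#' @param model A `tree_flower_model`.
#' @param x Predictor values (dbh in cm or crown volume in m^3), > 0.
#' @return Expected flower numbers.
#' @examples
#' m <- tree_flower_model(9.80, 0.01, "crown_volume")
#' predict_tree_flowers(m, 20)
#' @export
predict_tree_flowers <- function(model, x) {
  if (any(x < 0)) {
    abort("predictor must be non-negative", class = "bloomscale_error_domain")
  }
  rng <- model$calibration_range
  if (!is.null(rng) && any(x < rng[1] | x > rng[2])) {
    warn(paste0(
      "prediction outside the calibration range [",
      signif(rng[1], 3), ", ", signif(rng[2], 3), "] of ", model$predictor
    ))
  }
  unname(exp(model$coefficients["intercept"] + model$coefficients["slope"] * x))
}

#' Multiplicative flower increase for a relative dbh increase
#'
#' For the exponential dbh allometry, increasing the dbh of a tree of
#' diameter `baseline_dbh_cm` by `pct` percent multiplies the predicted
#' flower number by `exp(slope * baseline_dbh_cm * pct / 100)` — the
#' "fold-change" form of the model's nonlinearity.
#'
#' @param slope Slope of the dbh model per cm of dbh.
#' @param pct Percent increase in dbh.
#' @param baseline_dbh_cm Baseline dbh, cm (default 10).
#' @return The fold change (dimensionless).
#' @examples
#' flower_fold_change(0.1662, 100) # doubling a 10 cm tree
#' @export
flower_fold_change <- function(slope, pct, baseline_dbh_cm = 10) {
  exp(slope * baseline_dbh_cm * pct / 100)
}

#' Flower totals of planted tree rows
#'
#' Helpers for comparing planting scenarios: the flower total of a row is
#' trees times flowers per tree, and `row_flower_ratio()` compares two
#' scenarios (e.g. few large trees versus many small ones in a row of fixed
#' length).
#'
#' @param n_trees Number of trees in the row, >= 0.
#' @param flowers_per_tree Predicted flowers per tree.
#' @return Total flowers of the row.
#' @export
row_flower_total <- function(n_trees, flowers_per_tree) {
  if (any(n_trees < 0)) {
    abort("n_trees must be >= 0", class = "bloomscale_error_domain")
  }
  n_trees * flowers_per_tree
}

#' @rdname row_flower_total
#' @param n_trees_a,flowers_a,n_trees_b,flowers_b The two scenarios; the
#'   ratio is scenario A over scenario B.
#' @export
row_flower_ratio <- function(n_trees_a, flowers_a, n_trees_b, flowers_b) {
  row_flower_total(n_trees_a, flowers_a) / row_flower_total(n_trees_b, flowers_b)
}
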