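#' Fit the two-part branch-level flower model
#'
#' Fits the hurdle model to a (typically subsampled) branch table: a binomial
#' mixed model for flower occurrence and a zero-truncated negative binomial
#' (NB2) mixed model for flower abundance on the flowering branches. Both
#' parts use nested random intercepts for the cut-off branch within the tree
#' and are estimated by maximum likelihood (Laplace approximation) through
#' \pkg{glmmTMB}; with `random_effects = FALSE` the parts reduce to ordinary
#' logistic and zero-truncated NB regressions, which is the deterministic
#' route used for recovery tests and for prediction on new trees.
#'
#' The response is `flowers_total` when that column is present (flower counts
#' cumulated over subbranches, see [cumulate_flower_counts()]) and `flowers`
#' otherwise. The grouping variable of the branch random intercept is
#' `cutoff_id` when present, else `branch_id`.
#'
#' @param branches Branch table with the response column as described.
#' @param trees Tree table (`tree_id`, `dbh_cm`).
#' @param random_effects Include the nested random intercepts (default
#'   `TRUE`).
#' @param occurrence_formula,abundance_formula Optional fixed-effect formula
#'   overrides (right-hand side only, e.g. `~ ln_d + dbh`) used for model
#'   selection; the defaults are the selected wild-cherry formulas
#'   (`~ ln_d + dbh + layer * stratum` and `~ ln_d * dbh + layer * stratum`).
#' @return An object of class `flower_hurdle`: a list with `coefficients` (a
#'   [hurdle_coefficients()] object), `se`, the two glmmTMB `fits`, `logLik`,
#'   the prepared model `data` and metadata. Supports [tidy()], [glance()],
#'   `predict()` and [hurdle_fit_metrics()].
#' @export
fit_flower_hurdle <- function(branches, trees, random_effects = TRUE,
                              occurrence_formula = NULL,
                              abundance_formula = NULL) {
  data <- .prepare_hurdle_data(branches, trees)
  single_tree <- dplyr::n_distinct(data$tree_id) < 2
  if (single_tree && random_effects) {
    warn(paste(
      "only one tree in the data: the tree random-intercept SD is at its",
      "boundary (0) and the tree level is dropped from the random term"
    ))
  }
  if (all(data$flowering) || !any(data$flowering)) {
    abort("need both flowering and non-flowering branches to fit a hurdle model",
      class = "bloomscale_error_degenerate"
    )
  }

  occ_rhs <- occurrence_formula %||% ~ ln_d + dbh + layer * stratum
  abd_rhs <- abundance_formula %||% ~ ln_d * dbh + layer * stratum
  re <- if (!random_effects) {
    ""
  } else if (single_tree) {
    " + (1 | cutoff_id)"
  } else {
    " + (1 | tree_id/cutoff_id)"
  }
  occ_f <- stats::as.formula(paste0(
    "flowering ~ ", deparse(occ_rhs[[2]]), re
  ))
  abd_f <- stats::as.formula(paste0(
    "flowers ~ ", deparse(abd_rhs[[2]]), re
  ))

  occ_fit <- glmmTMB::glmmTMB(occ_f, data = data, family = stats::binomial())
  abd_fit <- glmmTMB::glmmTMB(abd_f,
    data = dplyr::filter(data, .data$flowering),
    family = glmmTMB::truncated_nbinom2()
  )
  for (f in list(occ_fit, abd_fit)) {
    beta <- glmmTMB::fixef(f)$cond
    if (anyNA(beta) || any(!is.finite(beta)) || !is.finite(as.numeric(logLik(f)))) {
      abort(paste0("hurdle part did not converge: ", f$fit$message %||% "estimates non-finite"),
        class = "bloomscale_error_optimization"
      )
    }
    if (!is.null(f$fit$convergence) && f$fit$convergence != 0) {
      # boundary fits (random-effect variance collapsing to 0) land here;
      # estimates remain usable, so report instead of failing
      warn(paste0("hurdle part converged at a boundary: ", f$fit$message))
    }
  }

  re_sd <- function(fit) {
    if (!random_effects) {
      return(c(tree = 0, branch = 0))
    }
    vc <- glmmTMB::VarCorr(fit)$cond
    get <- function(nm) {
      if (nm %in% names(vc)) sqrt(unname(vc[[nm]][1, 1])) else 0
    }
    c(
      tree = get("tree_id"),
      branch = max(get("cutoff_id:tree_id"), get("cutoff_id"))
    )
  }
  occ_sd <- re_sd(occ_fit)
  abd_sd <- re_sd(abd_fit)

  coefs <- tryCatch(
    hurdle_coefficients(
      occurrence = .map_glmmtmb_terms(glmmTMB::fixef(occ_fit)$cond),
      abundance = .map_glmmtmb_terms(glmmTMB::fixef(abd_fit)$cond),
      theta = glmmTMB::sigma(abd_fit),
      sd_tree = mean(c(occ_sd["tree"], abd_sd["tree"])),
      sd_branch = mean(c(occ_sd["branch"], abd_sd["branch"]))
    ),
    error = function(e) NULL # reduced formulas do not fill the full term set
  )

  structure(
    list(
      coefficients = coefs,
      se = list(
        occurrence = sqrt(diag(vcov(occ_fit)$cond)),
        abundance = sqrt(diag(vcov(abd_fit)$cond))
      ),
      fits = list(occurrence = occ_fit, abundance = abd_fit),
      random_sd = list(occurrence = occ_sd, abundance = abd_sd),
      logLik = c(
        occurrence = as.numeric(logLik(occ_fit)),
        abundance = as.numeric(logLik(abd_fit))
      ),
      formulas = list(occurrence = occ_f, abundance = abd_f),
      random_effects = random_effects,
      data = data,
      n = nrow(data)
    ),
    class = "flower_hurdle"
  )
}

# model frame shared by both hurdle parts
.prepare_hurdle_data <- function(branches, trees) {
  response <- if ("flowers_total" %in% names(branches)) {
    branches$flowers_total
  } else {
    branches$flowers
  }
  dbh <- trees$dbh_cm[match(branches$tree_id, trees$tree_id)]
  if (anyNA(dbh)) {
    abort("branch refers to a tree absent from the tree table",
      class = "bloomscale_error_reference"
    )
  }
  tibble::tibble(
    tree_id = factor(branches$tree_id),
    branch_id = branches$branch_id,
    cutoff_id = factor(branches[["cutoff_id"]] %||% branches$branch_id),
    ln_d = log(branches$cutoff_diameter_mm),
    dbh = dbh,
    layer = factor(branches$layer, levels = c("out", "in")),
    stratum = factor(branches$stratum, levels = c("bot", "mid", "top")),
    flowers = as.numeric(response),
    flowering = response > 0
  )
}

# glmmTMB coefficient names -> the package's canonical names
.map_glmmtmb_terms <- function(beta) {
  map <- c(
    "(Intercept)" = "intercept", "ln_d" = "ln_d", "dbh" = "dbh",
    "layerin" = "layer_in", "stratummid" = "stratum_mid",
    "stratumtop" = "stratum_top", "ln_d:dbh" = "ln_d:dbh",
    "layerin:stratummid" = "layer_in:stratum_mid",
    "layerin:stratumtop" = "layer_in:stratum_top"
  )
  out <- unname(beta)
  names(out) <- map[names(beta)]
  out
}

#' @export
print.flower_hurdle <- function(x, ...) {
  cat(
    "Two-part flower hurdle model,", x$n, "branches,",
    nlevels(x$data$tree_id), "trees",
    if (x$random_effects) "(nested random intercepts)" else "(fixed effects only)", "\n"
  )
  if (!is.null(x$coefficients)) print(x$coefficients)
  invisible(x)
}

#' Predict from a fitted flower hurdle model
#'
#' @param object A `flower_hurdle` fit.
#' @param newdata Data frame with `cutoff_diameter_mm` (or `D_mm`), `dbh_cm`
#'   (or a `tree_id` resolvable in the training data), `layer`, `stratum`.
#' @param type `"occurrence"` (probability), `"conditional"` (ZTNB mean given
#'   flowering) or `"expected"` (their product).
#' @param ... Unused.
#' @return Numeric vector of marginal predictions (random intercepts at 0).
#' @export
predict.flower_hurdle <- function(object, newdata,
                                  type = c("expected", "occurrence", "conditional"),
                                  ...) {
  type <- match.arg(type)
  D <- newdata[["cutoff_diameter_mm"]] %||% newdata[["D_mm"]]
  dbh <- newdata[["dbh_cm"]] %||% newdata[["dbh"]]
  fn <- switch(type,
    occurrence = predict_occurrence_probability,
    conditional = predict_conditional_count,
    expected = predict_expected_flowers
  )
  fn(D, dbh, newdata$layer, newdata$stratum, object$coefficients)
}

#' Likelihood ratio test between nested model fits
#'
#' Compares two maximum-likelihood fits of nested models: the statistic is
#' twice the log-likelihood difference, referred to a chi-square distribution
#' with the difference in parameter counts as degrees of freedom. Used for
#' stepwise reduction of the hurdle parts (terms are kept when dropping them
#' significantly worsens the fit at p < 0.05).
#'
#' @param full,reduced Fitted models with [logLik()] methods (e.g. the
#'   `$fits$occurrence` component of a [fit_flower_hurdle()] object), the
#'   reduced model nested in the full one.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  ll_f <- logLik(full)
  ll_r <- logLik(reduced)
  df <- attr(ll_f, "df") - attr(ll_r, "df")
  if (df < 0 || as.numeric(ll_f) - as.numeric(ll_r) < -1e-6) {
    abort("models are not nested (reduced must have fewer parameters and lower likelihood)",
      class = "bloomscale_error_nesting"
    )
  }
  stat <- max(0, 2 * (as.numeric(ll_f) - as.numeric(ll_r)))
  tibble::tibble(
    statistic = stat,
    df = df,
    p_value = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Estimated marginal means for the crown factors
#'
#' Computes estimated marginal means of a hurdle part over the crown layer
#' and/or stratum factors on the link scale, averaging over a balanced
#' reference grid of the other factor with continuous covariates at their
#' means, together with Tukey-adjusted pairwise comparisons.
#'
#' @param fit A [fit_flower_hurdle()] object.
#' @param part `"occurrence"` or `"abundance"`.
#' @param specs Factor specification passed to [emmeans::emmeans()], e.g.
#'   `~ layer`, `~ stratum` or `~ layer | stratum`.
#' @return A list with tibbles `means` (level, estimate, SE, df) and
#'   `contrasts` (Tukey-adjusted pairwise tests).
#' @export
estimated_marginal_means <- function(fit, part = c("occurrence", "abundance"),
                                     specs = ~layer) {
  part <- match.arg(part)
  vars <- all.vars(specs)
  present <- all.vars(stats::formula(fit$fits[[part]]))
  if (!all(vars %in% present)) {
    abort(paste0("factor(s) absent from the ", part, " model: ",
      paste(setdiff(vars, present), collapse = ", ")),
      class = "bloomscale_error_specification"
    )
  }
  emm <- emmeans::emmeans(fit$fits[[part]], specs = specs)
  prs <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  list(
    means = tibble::as_tibble(as.data.frame(emm)),
    contrasts = tibble::as_tibble(as.data.frame(prs))
  )
}

#' Fit metrics of the hurdle model
#'
#' Computes marginal (fixed effects only) and conditional (including
#' predicted random intercepts) Nakagawa-style R-squared, MAE and RMSE for
#' both hurdle parts and for the combined prediction `p * E[N | N >= 1]`, and
#' optionally leave-one-out cross-validated MAE/RMSE. The R-squared
#' distribution-specific variance uses the logit-distribution constant
#' pi^2 / 3 for the binomial part and the delta-method approximation
#' `1/lambda + 1/theta` for the log-link NB part. The cross-validation unit
#' is the cut-off branch (the random-effect group); held-out predictions use
#' fixed effects only.
#'
#' @param fit A [fit_flower_hurdle()] object.
#' @param loocv Also compute leave-one-out CV metrics (default `FALSE`).
#' @return A tibble with one row per part (`occurrence`, `abundance`,
#'   `combined`) and columns `r2_marginal`, `r2_conditional`, `mae_marginal`,
#'   `mae_conditional`, `rmse_marginal`, `rmse_conditional` and, with
#'   `loocv = TRUE`, `mae_cv`, `rmse_cv`. R-squared is reported only for the
#'   two model parts.
#' @export
hurdle_fit_metrics <- function(fit, loocv = FALSE) {
  data <- fit$data
  pos <- dplyr::filter(data, .data$flowering)

  lp <- function(part, newdata, conditional) {
    predict(fit$fits[[part]],
      newdata = newdata, type = "link",
      re.form = if (conditional) NULL else NA, allow.new.levels = TRUE
    )
  }
  theta <- glmmTMB::sigma(fit$fits$abundance)

  occ_pred <- function(conditional) plogis(lp("occurrence", data, conditional))
  abd_pred <- function(conditional) ztnb_mean(exp(lp("abundance", pos, conditional)), theta)
  comb_pred <- function(conditional) {
    plogis(lp("occurrence", data, conditional)) *
      ztnb_mean(exp(lp("abundance", data, conditional)), theta)
  }

  err <- function(y, yhat) c(mae = mean(abs(y - yhat)), rmse = sqrt(mean((y - yhat)^2)))
  occ_m <- err(as.numeric(data$flowering), occ_pred(FALSE))
  occ_c <- err(as.numeric(data$flowering), occ_pred(TRUE))
  abd_m <- err(pos$flowers, abd_pred(FALSE))
  abd_c <- err(pos$flowers, abd_pred(TRUE))
  cmb_m <- err(data$flowers, comb_pred(FALSE))
  cmb_c <- err(data$flowers, comb_pred(TRUE))

  r2 <- function(part) {
    f <- fit$fits[[part]]
    lp_fix <- predict(f, type = "link", re.form = NA)
    var_f <- var(lp_fix)
    var_re <- sum(fit$random_sd[[part]]^2)
    var_d <- if (part == "occurrence") {
      pi^2 / 3
    } else {
      lambda <- exp(mean(lp_fix) + 0.5 * (var_f + var_re))
      1 / lambda + 1 / theta
    }
    c(
      marginal = var_f / (var_f + var_re + var_d),
      conditional = (var_f + var_re) / (var_f + var_re + var_d)
    )
  }
  r2_occ <- r2("occurrence")
  r2_abd <- r2("abundance")

  out <- tibble::tibble(
    part = c("occurrence", "abundance", "combined"),
    r2_marginal = c(r2_occ["marginal"], r2_abd["marginal"], NA),
    r2_conditional = c(r2_occ["conditional"], r2_abd["conditional"], NA),
    mae_marginal = c(occ_m["mae"], abd_m["mae"], cmb_m["mae"]),
    mae_conditional = c(occ_c["mae"], abd_c["mae"], cmb_c["mae"]),
    rmse_marginal = c(occ_m["rmse"], abd_m["rmse"], cmb_m["rmse"]),
    rmse_conditional = c(occ_c["rmse"], abd_c["rmse"], cmb_c["rmse"])
  )
  attr(out, "r2_variant") <- "Nakagawa, delta-method distribution variance"

  if (loocv) {
    groups <- unique(as.character(data$cutoff_id))
    if (length(groups) < 3) {
      abort("leave-one-out cross-validation needs at least 3 cut-off branches",
        class = "bloomscale_error_size"
      )
    }
    preds <- purrr::map(groups, function(g) {
      train <- data[data$cutoff_id != g, , drop = FALSE]
      test <- data[data$cutoff_id == g, , drop = FALSE]
      refit <- fit_flower_hurdle(
        .as_branch_like(train), .trees_from_data(train),
        random_effects = fit$random_effects
      )
      tibble::tibble(
        y_occ = as.numeric(test$flowering),
        p = plogis(lp_of(refit, "occurrence", test)),
        y_all = test$flowers,
        mu = ztnb_mean(
          exp(lp_of(refit, "abundance", test)),
          glmmTMB::sigma(refit$fits$abundance)
        ),
        flowering = test$flowering
      )
    }) |> dplyr::bind_rows()
    occ_cv <- err(preds$y_occ, preds$p)
    abd_cv <- err(preds$y_all[preds$flowering], preds$mu[preds$flowering])
    cmb_cv <- err(preds$y_all, preds$p * preds$mu)
    out$mae_cv <- c(occ_cv["mae"], abd_cv["mae"], cmb_cv["mae"])
    out$rmse_cv <- c(occ_cv["rmse"], abd_cv["rmse"], cmb_cv["rmse"])
  }
  out
}

# fixed-effect linear predictor of one part on new rows
lp_of <- function(fit, part, newdata) {
  predict(fit$fits[[part]],
    newdata = newdata, type = "link",
    re.form = NA, allow.new.levels = TRUE
  )
}

# reconstruct branch/tree tables from a prepared model frame (LOOCV refits)
.as_branch_like <- function(data) {
  tibble::tibble(
    tree_id = as.character(data$tree_id),
    branch_id = data$branch_id,
    parent_branch_id = NA_character_,
    cutoff_id = as.character(data$cutoff_id),
    cutoff_diameter_mm = exp(data$ln_d),
    stratum = as.character(data$stratum),
    layer = as.character(data$layer),
    flowers = as.integer(round(data$flowers)),
    detailed = FALSE
  )
}

.trees_from_data <- function(data) {
  dplyr::distinct(tibble::tibble(
    tree_id = as.character(data$tree_id),
    dbh_cm = data$dbh
  ))
}
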