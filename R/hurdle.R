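#' Coefficient set of the two-part branch-level flower model
#'
#' The branch-level model is a hurdle: a binomial part on the logit scale for
#' whether a branch carries any flowers, and a zero-truncated negative
#' binomial (ZTNB) part on the log scale for how many flowers it carries given
#' at least one. Both parts share the covariates branch diameter (log mm),
#' stem diameter dbh (cm), crown layer (reference `out`) and crown stratum
#' (reference `bot`) with a layer x stratum interaction; the abundance part
#' additionally carries a `log(D) x dbh` interaction. The abundance linear
#' predictor is interpreted as `log(mu)` of the *untruncated* negative
#' binomial, the convention of truncated-NB2 fitting software, so published
#' coefficient tables are directly usable.
#'
#' @param occurrence Named numeric vector of the occurrence coefficients:
#'   `intercept`, `ln_d`, `dbh`, `layer_in`, `stratum_mid`, `stratum_top`,
#'   `layer_in:stratum_mid`, `layer_in:stratum_top`.
#' @param abundance Same names plus `ln_d:dbh`, for the abundance part.
#' @param theta ZTNB size (dispersion) parameter, > 0.
#' @param sd_tree,sd_branch Standard deviations of the nested random
#'   intercepts (tree, and cut-off branch within tree), >= 0.
#' @return An object of class `hurdle_coefficients`.
#' @seealso [cherry_hurdle_coefficients()] for a ready-made wild-cherry set.
#' @export
hurdle_coefficients <- function(occurrence, abundance, theta = 1.5,
                                sd_tree = 0, sd_branch = 0) {
  occ_names <- c(
    "intercept", "ln_d", "dbh", "layer_in", "stratum_mid", "stratum_top",
    "layer_in:stratum_mid", "layer_in:stratum_top"
  )
  abd_names <- c(occ_names, "ln_d:dbh")
  if (!setequal(names(occurrence), occ_names)) {
    abort("occurrence coefficients must be named: intercept, ln_d, dbh, layer_in, stratum_mid, stratum_top, layer_in:stratum_mid, layer_in:stratum_top",
      class = "bloomscale_error_domain"
    )
  }
  if (!setequal(names(abundance), abd_names)) {
    abort("abundance coefficients need the occurrence names plus ln_d:dbh",
      class = "bloomscale_error_domain"
    )
  }
  if (theta <= 0) {
    abort("theta must be > 0", class = "bloomscale_error_dispersion")
  }
  if (sd_tree < 0 || sd_branch < 0) {
    abort("random-intercept SDs must be >= 0", class = "bloomscale_error_domain")
  }
  structure(
    list(
      occurrence = occurrence[occ_names],
      abundance = abundance[abd_names],
      theta = theta, sd_tree = sd_tree, sd_branch = sd_branch
    ),
    class = "hurdle_coefficients"
  )
}

#' @export
print.hurdle_coefficients <- function(x, ...) {
  cat("Hurdle coefficients (occurrence: logit; abundance: log of untruncated NB mean)\n")
  cat("theta =", x$theta, " sd_tree =", x$sd_tree, " sd_branch =", x$sd_branch, "\n")
  print(tibble::tibble(
    term = names(x$abundance),
    occurrence = unname(x$occurrence[names(x$abundance)]),
    abundance = unname(x$abundance)
  ), n = Inf)
  invisible(x)
}

#' Wild-cherry hurdle coefficients
#'
#' A ready-made coefficient set for wild cherry (*Prunus avium*), taken from a
#' fitted branch-level flower model on field data from a South-West German
#' plantation. It is the default ground truth of the synthetic-data generator
#' and a convenient plug-in model for upscaling experiments. The dispersion
#' and random-intercept SDs were not published alongside the fixed effects;
#' the defaults here (`theta = 1.5`, SDs 0.3) are the package's own choices
#' and are freely overridable.
#'
#' @inheritParams hurdle_coefficients
#' @return An object of class `hurdle_coefficients`.
#' @export
cherry_hurdle_coefficients <- function(theta = 1.5, sd_tree = 0.3, sd_branch = 0.3) {
  hurdle_coefficients(
    occurrence = c(
      intercept = -2.85, ln_d = 2.16, dbh = 0.13,
      layer_in = -3.38, stratum_mid = -1.54, stratum_top = -0.15,
      "layer_in:stratum_mid" = 3.86, "layer_in:stratum_top" = 0.76
    ),
    abundance = c(
      intercept = 0.42, ln_d = 1.22, dbh = -0.06,
      layer_in = -1.18, stratum_mid = 0.54, stratum_top = 0.89,
      "ln_d:dbh" = 0.04,
      "layer_in:stratum_mid" = 0.35, "layer_in:stratum_top" = 0.62
    ),
    theta = theta, sd_tree = sd_tree, sd_branch = sd_branch
  )
}

# shared linear predictor of both hurdle parts (vectorised)
.hurdle_lp <- function(beta, D_mm, dbh_cm, layer, stratum, random_intercept = 0) {
  if (any(D_mm <= 0) || any(dbh_cm <= 0)) {
    abort("branch diameter and dbh must be > 0", class = "bloomscale_error_domain")
  }
  bad_l <- !layer %in% c("in", "out")
  bad_s <- !stratum %in% c("bot", "mid", "top")
  if (any(bad_l) || any(bad_s)) {
    abort("layer must be in/out and stratum bot/mid/top",
      class = "bloomscale_error_domain"
    )
  }
  l_in <- as.numeric(layer == "in")
  s_mid <- as.numeric(stratum == "mid")
  s_top <- as.numeric(stratum == "top")
  lp <- beta[["intercept"]] +
    beta[["ln_d"]] * log(D_mm) +
    beta[["dbh"]] * dbh_cm +
    beta[["layer_in"]] * l_in +
    beta[["stratum_mid"]] * s_mid +
    beta[["stratum_top"]] * s_top +
    beta[["layer_in:stratum_mid"]] * l_in * s_mid +
    beta[["layer_in:stratum_top"]] * l_in * s_top +
    random_intercept
  if ("ln_d:dbh" %in% names(beta)) {
    lp <- lp + beta[["ln_d:dbh"]] * log(D_mm) * dbh_cm
  }
  lp
}

#' Predict flower occurrence probability for a branch
#'
#' Evaluates the binomial hurdle part: the probability that a branch of
#' diameter `D_mm` on a tree of diameter `dbh_cm`, in the given crown
#' position, carries at least one flower. All arguments are vectorised.
#'
#' @param D_mm Branch diameter at the cut, mm (> 0).
#' @param dbh_cm Stem diameter at breast height, cm (> 0).
#' @param layer Crown layer, `"in"` or `"out"`.
#' @param stratum Crown stratum, `"bot"`, `"mid"` or `"top"`.
#' @param coefs A [hurdle_coefficients()] object.
#' @param random_intercept Optional random-intercept value(s) on the link
#'   scale; 0 gives the marginal (population-level) prediction.
#' @return Probability in (0, 1).
#' @examples
#' predict_occurrence_probability(20, 20, "out", "bot", cherry_hurdle_coefficients())
#' @export
predict_occurrence_probability <- function(D_mm, dbh_cm, layer, stratum, coefs,
                                           random_intercept = 0) {
  plogis(.hurdle_lp(coefs$occurrence, D_mm, dbh_cm, layer, stratum, random_intercept))
}

#' Mean of the zero-truncated negative binomial
#'
#' For an untruncated NB2 with mean `mu` and size `theta`, the probability of
#' zero is `(theta / (theta + mu))^theta` and the mean conditional on a
#' positive outcome is `mu / (1 - P(0))`, always at least `max(mu, 1)`.
#'
#' @param mu Untruncated NB mean, > 0.
#' @param theta NB size parameter, > 0.
#' @return The zero-truncated mean.
#' @export
ztnb_mean <- function(mu, theta) {
  if (any(theta <= 0)) {
    abort("theta must be > 0", class = "bloomscale_error_dispersion")
  }
  p0 <- (theta / (theta + mu))^theta
  mu / (1 - p0)
}

#' Predict the flower count of a flowering branch
#'
#' Evaluates the abundance hurdle part: the expected number of flowers on a
#' branch *given that it flowers*. The linear predictor gives `log(mu)` of the
#' untruncated negative binomial; the returned value is the zero-truncated
#' mean `mu / (1 - (theta/(theta+mu))^theta)`.
#'
#' @inheritParams predict_occurrence_probability
#' @return Expected flower count, >= 1.
#' @examples
#' predict_conditional_count(10, 20, "out", "bot", cherry_hurdle_coefficients())
#' @export
predict_conditional_count <- function(D_mm, dbh_cm, layer, stratum, coefs,
                                      random_intercept = 0) {
  mu <- exp(.hurdle_lp(coefs$abundance, D_mm, dbh_cm, layer, stratum, random_intercept))
  ztnb_mean(mu, coefs$theta)
}

#' Unconditional expected flower count of a branch
#'
#' Combines both hurdle parts: occurrence probability times the
#' zero-truncated conditional mean.
#'
#' @inheritParams predict_occurrence_probability
#' @return Expected flower count, >= 0.
#' @export
predict_expected_flowers <- function(D_mm, dbh_cm, layer, stratum, coefs,
                                     random_intercept = 0) {
  predict_occurrence_probability(D_mm, dbh_cm, layer, stratum, coefs, random_intercept) *
    predict_conditional_count(D_mm, dbh_cm, layer, stratum, coefs, random_intercept)
}

# draw from the zero-truncated NB by inverse-cdf restricted above P(0)
.rztnb <- function(n, mu, theta) {
  p0 <- (theta / (theta + mu))^theta
  u <- runif(n, min = p0, max = 1)
  qnbinom(u, size = theta, mu = mu)
}
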