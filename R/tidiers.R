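#' Tidy a fitted flower hurdle model
#'
#' @param x A [fit_flower_hurdle()] object.
#' @param ... Unused.
#' @return A tibble with `part`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.flower_hurdle <- function(x, ...) {
  one <- function(part) {
    beta <- glmmTMB::fixef(x$fits[[part]])$cond
    se <- x$se[[part]]
    tibble::tibble(
      part = part,
      term = names(beta),
      estimate = unname(beta),
      std.error = unname(se[names(beta)]),
      statistic = unname(beta / se[names(beta)]),
      p.value = 2 * stats::pnorm(abs(unname(beta / se[names(beta)])), lower.tail = FALSE)
    )
  }
  dplyr::bind_rows(one("occurrence"), one("abundance"))
}

#' @rdname tidy.flower_hurdle
#' @export
glance.flower_hurdle <- function(x, ...) {
  tibble::tibble(
    n_branches = x$n,
    n_trees = nlevels(x$data$tree_id),
    random_effects = x$random_effects,
    theta = glmmTMB::sigma(x$fits$abundance),
    sd_tree = if (is.null(x$coefficients)) NA_real_ else x$coefficients$sd_tree,
    sd_branch = if (is.null(x$coefficients)) NA_real_ else x$coefficients$sd_branch,
    logLik_occurrence = x$logLik[["occurrence"]],
    logLik_abundance = x$logLik[["abundance"]]
  )
}

#' Tidy a tree-level flower allometry
#'
#' @param x A [tree_flower_model()] object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.tree_flower_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$predictor),
    estimate = unname(x$coefficients),
    std.error = unname(x$se)
  )
}

#' @rdname tidy.tree_flower_model
#' @export
glance.tree_flower_model <- function(x, ...) {
  base <- tibble::tibble(predictor = x$predictor, theta = x$theta)
  if (is.null(x$metrics)) base else dplyr::bind_cols(base, x$metrics)
}
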