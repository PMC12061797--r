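truth0 <- cherry_hurdle_coefficients(sd_tree = 0, sd_branch = 0)
trees16 <- tibble::tibble(tree_id = sprintf("t%02d", 1:16), dbh_cm = seq(9, 31, length.out = 16))

test_that("intercept-only occurrence part recovers the closed-form MLE", {
  b <- tibble::tibble(
    tree_id = "t1",
    branch_id = sprintf("b%03d", 1:100),
    parent_branch_id = NA_character_,
    cutoff_diameter_mm = 10,
    stratum = "bot", layer = "out", compass = "N",
    flowers = rep(c(0L, 5L), c(40, 60)),
    detailed = FALSE
  )
  fit <- fit_flower_hurdle(b, one_tree(),
    random_effects = FALSE,
    occurrence_formula = ~1, abundance_formula = ~1
  )
  expect_equal(
    unname(glmmTMB::fixef(fit$fits$occurrence)$cond[1]),
    qlogis(0.6),
    tolerance = 1e-5
  )
})

test_that("degenerate outcomes and single trees are flagged", {
  b <- chain_branches(flowers = c(0L, 0L, 0L))
  expect_error(
    fit_flower_hurdle(b, one_tree(), random_effects = FALSE),
    class = "bloomscale_error_degenerate"
  )
  # one tree: dbh is constant, so fit an identifiable reduced formula
  b2 <- flat_branches(80, one_tree(), truth0, seed = 2)
  expect_warning(
    fit_flower_hurdle(b2, one_tree(),
      random_effects = TRUE,
      occurrence_formula = ~ ln_d + layer,
      abundance_formula = ~ ln_d + layer
    ),
    "one tree"
  )
})

test_that("fitted fixed effects track the generating truth", {
  b <- flat_branches(400, trees16, truth0, seed = 31)
  fit <- fit_flower_hurdle(b, trees16, random_effects = FALSE)
  td <- tidy(fit)
  # point checks on the two slope terms that drive upscaling
  ln_d_occ <- td[td$part == "occurrence" & td$term == "ln_d", ]
  expect_lt(abs(ln_d_occ$estimate - 2.16), 3 * ln_d_occ$std.error)
  ln_d_abd <- td[td$part == "abundance" & td$term == "ln_d", ]
  expect_lt(abs(ln_d_abd$estimate - 1.22), 3 * ln_d_abd$std.error)
  expect_equal(fit$coefficients$sd_tree, 0)

  # predictions from the package equations equal the glmmTMB route
  nd <- b[1:20, ]
  expect_equal(
    predict(fit, nd |> dplyr::mutate(dbh_cm = trees16$dbh_cm[match(nd$tree_id, trees16$tree_id)]),
      type = "occurrence"
    ),
    unname(predict(fit$fits$occurrence,
      newdata = fit$data[1:20, ], type = "response", re.form = NA
    )),
    tolerance = 1e-6
  )
})

test_that("likelihood ratio tests do the bookkeeping", {
  b <- flat_branches(250, trees16, truth0, seed = 5)
  full <- fit_flower_hurdle(b, trees16, random_effects = FALSE)
  red <- fit_flower_hurdle(b, trees16,
    random_effects = FALSE,
    occurrence_formula = ~ ln_d + dbh + layer
  )
  same <- likelihood_ratio_test(full$fits$occurrence, full$fits$occurrence)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  lrt <- likelihood_ratio_test(full$fits$occurrence, red$fits$occurrence)
  expect_equal(lrt$df, 4) # stratum (2) + layer:stratum (2)
  expect_gte(lrt$statistic, 0)

  expect_error(
    likelihood_ratio_test(red$fits$occurrence, full$fits$occurrence),
    class = "bloomscale_error_nesting"
  )
})

test_that("the LRT holds its size on null data", {
  withr::with_seed(99, {
    pvals <- replicate(200, {
      df <- data.frame(y = rbinom(150, 1, 0.4), x = rnorm(150))
      f <- stats::glm(y ~ x, family = binomial(), data = df)
      r <- stats::glm(y ~ 1, family = binomial(), data = df)
      likelihood_ratio_test(f, r)$p_value
    })
    expect_gt(mean(pvals < 0.05), 0.02)
    expect_lt(mean(pvals < 0.05), 0.10)
  })
})

test_that("marginal means reduce to coefficients without interactions", {
  b <- flat_branches(300, trees16, truth0, seed = 13)
  fit <- fit_flower_hurdle(b, trees16,
    random_effects = FALSE,
    abundance_formula = ~ ln_d + dbh + layer + stratum
  )
  emm <- estimated_marginal_means(fit, "abundance", ~layer)
  beta_in <- glmmTMB::fixef(fit$fits$abundance)$cond[["layerin"]]
  diff_means <- emm$means$emmean[emm$means$layer == "in"] -
    emm$means$emmean[emm$means$layer == "out"]
  expect_equal(diff_means, beta_in, tolerance = 1e-6)

  # two-level factor: Tukey equals the unadjusted comparison
  unadj <- emmeans::contrast(
    emmeans::emmeans(fit$fits$abundance, ~layer),
    method = "pairwise", adjust = "none"
  )
  expect_equal(
    emm$contrasts$p.value,
    as.data.frame(unadj)$p.value,
    tolerance = 1e-9
  )

  expect_error(
    estimated_marginal_means(fit, "abundance", ~compass),
    class = "bloomscale_error_specification"
  )
})

test_that("the fitted crown-layer ordering out > in is recovered", {
  b <- flat_branches(350, trees16, truth0, seed = 17)
  fit <- fit_flower_hurdle(b, trees16, random_effects = FALSE)
  for (part in c("occurrence", "abundance")) {
    emm <- estimated_marginal_means(fit, part, ~layer)
    m <- setNames(emm$means$emmean, as.character(emm$means$layer))
    expect_gt(m[["out"]], m[["in"]])
    expect_lt(emm$contrasts$p.value, 0.05)
  }
})

test_that("fit metrics behave like proper error measures", {
  bd <- generate_branch_dataset(seed = 8)
  sub <- subsample_branches(bd$branches, bd$trees)
  fit <- suppressWarnings(fit_flower_hurdle(sub, bd$trees, random_effects = TRUE))
  m <- hurdle_fit_metrics(fit)
  expect_true(all(m$rmse_marginal >= m$mae_marginal - 1e-12))
  expect_true(all(m$rmse_conditional >= m$mae_conditional - 1e-12))
  r2 <- m[m$part != "combined", c("r2_marginal", "r2_conditional")]
  expect_true(all(r2 >= 0 & r2 <= 1))
  # conditional R2 includes the random-effect variance share
  expect_true(all(m$r2_conditional[1:2] >= m$r2_marginal[1:2] - 1e-12))
})

test_that("leave-one-out CV refits without the held-out cut-off branch", {
  b <- flat_branches(120, trees16, truth0, seed = 46) |>
    dplyr::mutate(cutoff_id = rep(sprintf("g%d", 1:8), length.out = 120))
  fit <- suppressWarnings(fit_flower_hurdle(b, trees16, random_effects = FALSE))
  m <- suppressWarnings(hurdle_fit_metrics(fit, loocv = TRUE))
  expect_true(all(c("mae_cv", "rmse_cv") %in% names(m)))
  expect_true(all(m$rmse_cv >= m$mae_cv - 1e-12))

  tiny <- b |> dplyr::mutate(cutoff_id = rep(c("g1", "g2"), length.out = 120))
  tiny_fit <- suppressWarnings(fit_flower_hurdle(tiny, trees16, random_effects = FALSE))
  expect_error(hurdle_fit_metrics(tiny_fit, loocv = TRUE),
    class = "bloomscale_error_size"
  )
})
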