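test_that("per-flower pollen volume follows the sphere formula", {
  p <- pollen_params()
  grain_mm3 <- (pi / 6) * (32.63 / 1000)^3
  expect_equal(grain_mm3, 1.819e-5, tolerance = 1e-3)
  expect_equal(pollen_volume_per_flower(p), grain_mm3 * 16059)
  expect_equal(round(pollen_volume_per_flower(p), 2), 0.29)

  doubled <- pollen_params(grain_diameter_mean_um = 2 * 32.63)
  expect_equal(pollen_volume_per_flower(doubled), 8 * pollen_volume_per_flower(p))
})

test_that("tree budgets convert flowers into pollen, nectar and sugar", {
  big <- tree_resources(195535)
  expect_equal(round(big$pollen_cm3), 57)
  expect_equal(round(big$sugar_g_24h), 170)

  small <- tree_resources(16163)
  expect_equal(round(small$pollen_cm3), 5)
  expect_equal(round(small$sugar_g_24h), 14)

  zero <- tree_resources(0)
  expect_true(all(zero[, -1] == 0))

  # unit conservation round trips
  expect_equal(big$pollen_cm3 * 1000, big$pollen_mm3)
  expect_equal(big$sugar_g_24h, big$nectar_g_24h * nectar_params()$sugar_fraction_mean)
})

test_that("parameter containers enforce their invariants", {
  expect_error(pollen_params(grains_per_flower_mean = -1),
    class = "bloomscale_error_domain"
  )
  expect_error(nectar_params(production_mean = 10),
    class = "bloomscale_error_domain"
  )
})

test_that("larvae counts divide pollen by the per-larva requirement", {
  pollen_cm3 <- tree_resources(195535)$pollen_cm3
  out <- larvae_supported(pollen_cm3)
  expect_equal(out$larvae[out$species == "Lasioglossum laticeps"], 5202)
  expect_equal(out$larvae[out$species == "Bombus terrestris"], 927)

  small <- tree_resources(16163)$pollen_cm3
  out2 <- larvae_supported(small)
  expect_equal(out2$larvae[out2$species == "Lasioglossum laticeps"], 430)
  expect_equal(out2$larvae[out2$species == "Bombus terrestris"], 77)

  sp <- tibble::tibble(species = "huge", pollen_mm3_per_larva = 1e9)
  expect_equal(larvae_supported(1, sp)$larvae, 0)

  # monotone in both directions
  reqs <- tibble::tibble(species = c("a", "b"), pollen_mm3_per_larva = c(10, 20))
  l <- larvae_supported(5, reqs)$larvae
  expect_true(l[1] >= l[2])
  expect_true(all(larvae_supported(10, reqs)$larvae >= l))
})

sim_trees <- function(n = 12, seed = 1) {
  withr::with_seed(seed, {
    x <- runif(n, 9, 28)
    tibble::tibble(
      dbh_cm = x,
      flowers = rnbinom(n, size = 5, mu = exp(8.03 + 0.17 * x))
    )
  })
}

test_that("bootstrap CIs are order-valid, reproducible and widen with noise", {
  d <- sim_trees()
  ci <- bootstrap_resource_ci(d, dbh_grid = c(10, 25), B = 80, seed = 7)
  expect_true(all(ci$ci_low <= ci$ci_high))
  expect_true(all(ci$estimate >= 0 & ci$ci_low >= 0))
  expect_equal(nrow(ci), 2 * (4 + 2)) # 2 grid points x (4 quantities + 2 species)

  ci2 <- bootstrap_resource_ci(d, dbh_grid = c(10, 25), B = 80, seed = 7)
  expect_identical(ci, ci2)

  wide_nectar <- nectar_params(production_range = c(0.2, 7.2))
  ci_wide <- bootstrap_resource_ci(d,
    dbh_grid = 25, nectar = wide_nectar,
    B = 80, seed = 7
  )
  w0 <- ci[ci$quantity == "nectar_g_24h" & ci$dbh_cm == 25, ]
  w1 <- ci_wide[ci_wide$quantity == "nectar_g_24h", ]
  expect_gt(w1$ci_high - w1$ci_low, w0$ci_high - w0$ci_low)

  expect_error(
    bootstrap_resource_ci(d[1:3, ], 10, B = 10, seed = 1),
    class = "bloomscale_error_size"
  )
  expect_error(
    bootstrap_resource_ci(d, 10, B = 1, seed = 1),
    class = "bloomscale_error_domain"
  )
})

test_that("point predictions fall inside their own bootstrap CI", {
  hits <- vapply(1:8, function(s) {
    d <- sim_trees(n = 15, seed = 100 + s)
    ci <- bootstrap_resource_ci(d, dbh_grid = 18, B = 60, seed = s)
    fl <- ci[ci$quantity == "flowers", ]
    fl$ci_low <= fl$estimate && fl$estimate <= fl$ci_high
  }, logical(1))
  expect_gte(mean(hits), 7 / 8)
})
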