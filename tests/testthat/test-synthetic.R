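test_that("generators are deterministic per seed", {
  a <- generate_branch_dataset(seed = 5)
  b <- generate_branch_dataset(seed = 5)
  expect_identical(a$branches, b$branches)
  expect_identical(a$measurements, b$measurements)

  q1 <- generate_qsm(20, seed = 9)
  q2 <- generate_qsm(20, seed = 9)
  expect_identical(q1, q2)
  expect_false(identical(q1, generate_qsm(20, seed = 10)))
})

test_that("an impossible occurrence intercept silences every branch", {
  truth <- cherry_hurdle_coefficients()
  truth$occurrence["intercept"] <- -50
  bd <- generate_branch_dataset(n_trees = 4, truth = truth, seed = 2)
  expect_true(all(bd$branches$flowers == 0))
})

test_that("zeroed crown effects give position-independent occurrence", {
  truth <- cherry_hurdle_coefficients(sd_tree = 0, sd_branch = 0)
  crown <- c(
    "layer_in", "stratum_mid", "stratum_top",
    "layer_in:stratum_mid", "layer_in:stratum_top"
  )
  truth$occurrence[crown] <- 0
  truth$abundance[crown] <- 0
  bd <- generate_branch_dataset(
    n_trees = 30, branches_per_tree = 12,
    truth = truth, seed = 6
  )
  expect_gt(nrow(bd$branches), 1500)
  tab <- table(bd$branches$stratum, bd$branches$flowers > 0)
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("synthetic QSMs honour the requested dbh and the 3 mm floor", {
  for (dbh in c(9, 20, 28)) {
    qsm <- generate_qsm(dbh, seed = dbh)
    m <- derive_tree_metrics(qsm)
    expect_lt(abs(m$dbh_cm - dbh) / dbh, 0.05)
    expect_gte(min(2 * qsm$radius_m * 1000), 3)
    expect_equal(sum(is.na(qsm$parent_id)), 1)
  }
})

test_that("replicates jitter geometry multiplicatively", {
  qsm <- generate_qsm(18, seed = 4)
  clean <- generate_replicates(qsm, k = 3, noise_sd = 0, seed = 1)
  for (r in 1:3) {
    rep_r <- clean[clean$replicate_id == r, ] |> dplyr::mutate(replicate_id = 1L)
    expect_equal(rep_r, qsm, tolerance = 1e-12)
  }

  one <- generate_replicates(qsm, k = 1, noise_sd = 0.05, seed = 2)
  expect_equal(unique(one$replicate_id), 1L)

  noisy <- generate_replicates(qsm, k = 200, noise_sd = 0.05, seed = 3)
  dbh_reps <- noisy |>
    dplyr::group_by(replicate_id) |>
    dplyr::group_map(~ derive_tree_metrics(.x)$dbh_cm) |>
    unlist()
  expect_gt(sd(dbh_reps) / mean(dbh_reps), 0.03)
  expect_lt(sd(dbh_reps) / mean(dbh_reps), 0.07)
})

test_that("tables round-trip through the CSV readers and writers", {
  bd <- generate_branch_dataset(n_trees = 3, seed = 12)
  qsm <- generate_qsm(15, seed = 12)
  dir <- withr::local_tempdir()

  write_branch_table(bd$branches, file.path(dir, "branches.csv"))
  back <- read_branch_table(file.path(dir, "branches.csv"))
  shared <- intersect(names(back), names(bd$branches))
  expect_equal(
    as.data.frame(back[shared]),
    as.data.frame(bd$branches[shared]),
    tolerance = 1e-12
  )

  write_measurement_table(bd$measurements, file.path(dir, "meas.csv"))
  expect_equal(
    as.data.frame(read_measurement_table(file.path(dir, "meas.csv"))),
    as.data.frame(bd$measurements),
    tolerance = 1e-12
  )

  write_tree_table(bd$trees, file.path(dir, "trees.csv"))
  expect_equal(
    as.data.frame(read_tree_table(file.path(dir, "trees.csv"))),
    as.data.frame(bd$trees),
    tolerance = 1e-12
  )

  write_cylinder_table(qsm, file.path(dir, "cyl.csv"))
  back_q <- read_cylinder_table(file.path(dir, "cyl.csv"))
  expect_equal(as.data.frame(back_q), as.data.frame(qsm[names(back_q)]),
    tolerance = 1e-12
  )
})
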