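test_that("a bare trunk yields dbh and height by construction", {
  qsm <- trunk_qsm(height = 10, radius = 0.10)
  expect_warning(m <- derive_tree_metrics(qsm), "crown")
  expect_equal(m$dbh_cm, 20)
  expect_equal(m$height_m, 10)
  expect_true(is.na(m$crown_volume_m3))

  short <- trunk_qsm(height = 1, radius = 0.05)
  expect_error(derive_tree_metrics(short), class = "bloomscale_error_metric")
})

test_that("QSM validation rejects malformed cylinder tables", {
  qsm <- trunk_qsm()
  two_roots <- qsm
  two_roots$parent_id[2] <- NA
  expect_error(validate_qsm(two_roots), class = "bloomscale_error_qsm")

  bad_axis <- qsm
  bad_axis$axis_z[3] <- 2
  expect_error(validate_qsm(bad_axis), class = "bloomscale_error_qsm")

  cyc <- qsm
  cyc$parent_id[1] <- qsm$cyl_id[3]
  expect_error(validate_qsm(cyc), class = "bloomscale_error_qsm")
})

test_that("crown area and diameter follow from the hull of a square crown", {
  qsm <- square_crown_qsm(height = 10, side = 4, crown_z = c(6, 7, 8))
  m <- derive_tree_metrics(qsm)
  expect_equal(m$crown_projection_area_m2, 16)
  expect_equal(m$crown_base_height_m, 6)
  mx <- derive_tree_metrics(qsm, diameter_method = "max")
  expect_equal(mx$crown_diameter_m, 4 * sqrt(2))
  expect_gte(m$crown_diameter_m, 4)
  expect_lte(m$crown_diameter_m, 4 * sqrt(2))
})

test_that("sliced-hull crown volume approaches the cuboid volume", {
  # 4 x 4 x 5 m crown: square perimeter every 0.5 m of height
  qsm <- square_crown_qsm(height = 10.01, side = 4, crown_z = seq(5, 10, by = 0.5))
  m <- derive_tree_metrics(qsm)
  expect_equal(m$crown_volume_m3, 80, tolerance = 0.1)
})

test_that("metrics are invariant to translation and eighth-turn rotation", {
  qsm <- generate_qsm(18, seed = 9)
  m0 <- derive_tree_metrics(qsm)

  shifted <- qsm |> dplyr::mutate(
    start_x_m = start_x_m + 13.7, start_y_m = start_y_m - 4.2,
    start_z_m = start_z_m + 2.5
  )
  expect_equal(derive_tree_metrics(shifted), m0, tolerance = 1e-9)

  a <- pi / 4 # multiple of the 8-direction spacing, so spread is preserved
  rot <- qsm |> dplyr::mutate(
    x = start_x_m * cos(a) - start_y_m * sin(a),
    y = start_x_m * sin(a) + start_y_m * cos(a),
    ax = axis_x * cos(a) - axis_y * sin(a),
    ay = axis_x * sin(a) + axis_y * cos(a),
    start_x_m = x, start_y_m = y, axis_x = ax, axis_y = ay
  ) |> dplyr::select(-x, -y, -ax, -ay)
  mr <- derive_tree_metrics(rot)
  expect_equal(mr$dbh_cm, m0$dbh_cm)
  expect_equal(mr$height_m, m0$height_m)
  expect_equal(mr$crown_projection_area_m2, m0$crown_projection_area_m2,
    tolerance = 1e-9
  )
  expect_equal(mr$crown_diameter_m, m0$crown_diameter_m, tolerance = 1e-9)
  expect_equal(mr$crown_volume_m3, m0$crown_volume_m3, tolerance = 1e-9)
})

test_that("branch units start where the diameter first drops to the threshold", {
  # trunk 100 mm with a branch tapering 40 -> 25 -> 10 mm
  qsm <- trunk_qsm(height = 6, radius = 0.05)
  mk <- function(qsm, parent, r) {
    tibble::add_row(qsm,
      tree_id = "t1", replicate_id = 1L,
      cyl_id = max(qsm$cyl_id) + 1L, parent_id = as.integer(parent),
      start_x_m = 0.5 * (max(qsm$cyl_id) - 5), start_y_m = 0, start_z_m = 4,
      axis_x = 1, axis_y = 0, axis_z = 0,
      length_m = 0.5, radius_m = r, branch_order = 1L
    )
  }
  qsm <- mk(qsm, 5, 0.020) # 40 mm
  qsm <- mk(qsm, 7, 0.0125) # 25 mm
  qsm <- mk(qsm, 8, 0.005) # 10 mm
  units <- extract_branch_units(qsm, d_max_mm = 30)
  expect_equal(nrow(units), 1)
  expect_equal(units$root_diameter_mm, 25)
  expect_setequal(units$member_cyl_ids[[1]], c(8, 9))

  # whole tree below the threshold: one unit covering everything
  thin <- trunk_qsm(height = 5, radius = 0.01)
  u <- extract_branch_units(thin)
  expect_equal(nrow(u), 1)
  expect_equal(u$n_cylinders, nrow(thin))

  # nothing at or below the threshold: no units
  fat <- trunk_qsm(height = 5, radius = 0.05)
  expect_equal(nrow(extract_branch_units(fat)), 0)
})

test_that("unit extraction is order-independent and partitions eligible cylinders", {
  qsm <- generate_qsm(22, seed = 14)
  units <- extract_branch_units(qsm)
  perm_units <- extract_branch_units(qsm[sample(nrow(qsm)), ])
  expect_setequal(units$root_cyl_id, perm_units$root_cyl_id)

  members <- unlist(units$member_cyl_ids)
  expect_equal(anyDuplicated(members), 0)
  eligible <- qsm$cyl_id[2 * qsm$radius_m * 1000 <= 30]
  expect_setequal(members, eligible)
  expect_equal(sum(units$n_cylinders), length(eligible))
})

test_that("crown strata partition the crown length into thirds", {
  # crown from z = 4 to z = 10 on a 10 m tree: boundaries at 6 and 8
  qsm <- square_crown_qsm(height = 10.01, side = 10, crown_z = seq(4, 10, by = 0.5))
  centers <- tibble::tibble(
    root_cyl_id = 1:4, root_diameter_mm = 10, n_cylinders = 1,
    center_x_m = 4.7, center_y_m = 0,
    center_z_m = c(4.2, 6.0, 8.0, 9.4),
    member_cyl_ids = list(1L, 1L, 1L, 1L)
  )
  cls <- classify_crown_position(centers, qsm)
  expect_equal(cls$stratum, c("bot", "mid", "top", "top"))
  expect_equal(cls$layer, rep("out", 4)) # 0.3 m from the hull edge

  # centroid of a 10 m slice hull is 5 m from every edge: inner layer
  centroid <- centers[1, ] |> dplyr::mutate(center_x_m = 0, center_z_m = 9.4)
  expect_equal(classify_crown_position(centroid, qsm)$layer, "in")

  # hull narrower than twice the layer depth erodes away entirely
  narrow <- square_crown_qsm(height = 10.01, side = 3, crown_z = seq(4, 10, by = 0.5))
  expect_equal(
    classify_crown_position(centroid, narrow)$layer, "out"
  )
})
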