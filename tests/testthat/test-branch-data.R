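test_that("flower counts cumulate over the hierarchy", {
  b <- chain_branches()
  out <- cumulate_flower_counts(b)
  expect_equal(out$flowers_total, c(6, 5, 3))

  leaf <- chain_branches()[3, ] |> dplyr::mutate(parent_branch_id = NA, flowers = 7L)
  expect_equal(cumulate_flower_counts(leaf)$flowers_total, 7)

  empty <- chain_branches()[0, ]
  expect_equal(nrow(cumulate_flower_counts(empty)), 0)
})

test_that("cumulation is order-independent and monotone over subtrees", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      b <- random_hierarchy(25)
      out <- cumulate_flower_counts(b)
      perm <- sample(nrow(b))
      out_perm <- cumulate_flower_counts(b[perm, ])
      expect_equal(
        out_perm$flowers_total[match(out$branch_id, out_perm$branch_id)],
        out$flowers_total
      )
      # parent total >= own count + child totals is an equality here; check
      # the monotone consequences
      expect_true(all(out$flowers_total >= b$flowers))
      kids <- !is.na(b$parent_branch_id)
      parent_tot <- out$flowers_total[match(b$parent_branch_id[kids], out$branch_id)]
      expect_true(all(parent_tot >= out$flowers_total[kids]))
    }
  })
})

test_that("hierarchy defects are rejected", {
  b <- chain_branches()
  b$parent_branch_id[1] <- "c" # cycle a -> b -> c -> a
  expect_error(cumulate_flower_counts(b), class = "bloomscale_error_hierarchy")

  b2 <- chain_branches()
  b2$parent_branch_id[2] <- "nope"
  expect_error(cumulate_flower_counts(b2), class = "bloomscale_error_reference")

  b3 <- chain_branches()
  b3$tree_id <- c("t1", "t2", "t2") # parent link crosses trees
  expect_error(validate_branch_table(b3), class = "bloomscale_error_reference")
})

test_that("diameter-class segmentation solves the linear taper", {
  out <- segment_diameter_classes(c(0, 100), c(12, 2))
  expect_equal(out$class_lower_mm, c(0, 5, 10))
  expect_equal(out$length_cm, c(30, 50, 20))

  const <- segment_diameter_classes(c(0, 40), c(8, 8))
  expect_equal(const$class_lower_mm, 5)
  expect_equal(const$length_cm, 40)

  expect_error(
    segment_diameter_classes(c(10, 10), c(8, 6)),
    class = "bloomscale_error_ordering"
  )
  expect_error(
    segment_diameter_classes(5, 8),
    class = "bloomscale_error_insufficient_data"
  )
})

test_that("segment lengths conserve the measured shoot length", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- sample(2:8, 1)
      pos <- sort(runif(n, 0, 200))
      while (any(diff(pos) == 0)) pos <- sort(runif(n, 0, 200))
      dia <- runif(n, 1, 40)
      out <- segment_diameter_classes(pos, dia)
      expect_equal(sum(out$length_cm), max(pos) - min(pos), tolerance = 1e-9)
      expect_true(all(out$length_cm >= 0))
    }
  })
})

test_that("flower density summarises per class and crown section", {
  b <- tibble::tibble(
    tree_id = "t1", branch_id = "a", parent_branch_id = NA_character_,
    cutoff_diameter_mm = 4, stratum = "top", layer = "out", compass = "N",
    flowers = 30L, detailed = TRUE
  )
  m <- tibble::tibble(branch_id = "a", position_cm = c(0, 15), diameter_mm = c(4, 3))
  out <- flowers_per_cm_summary(b, m)
  expect_equal(out$flowers_per_cm, 2)
  expect_equal(out$class_lower_mm, 0)
  expect_equal(out$stratum, "top")

  expect_equal(nrow(flowers_per_cm_summary(b[0, ], m)), 0)
})

test_that("generated attachments respect the sub-20 mm rule", {
  bd <- generate_branch_dataset(seed = 21)
  out <- flowers_per_cm_summary(bd$branches, bd$measurements, bd$attachments)
  thick <- dplyr::filter(out, class_lower_mm >= 20)
  expect_true(all(thick$flowers_per_cm == 0))
  expect_true(any(out$flowers_per_cm > 0))
})
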