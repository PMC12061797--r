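#' Specification of a synthetic forest
#'
#' Bundles the study-design constants the generators emulate: 39 trees
#' spanning a dbh range of 9-28 cm, 30 replicate cylinder models per tree
#' with a few percent geometric reconstruction noise, and the wild-cherry
#' hurdle coefficients as the generating truth for flower counts (with the
#' package's invented dispersion `theta = 1.5` and random-intercept SDs 0.3,
#' which no published table provides).
#'
#' @param n_trees Number of trees.
#' @param dbh_range dbh range, cm.
#' @param n_replicates Replicate QSMs per tree.
#' @param noise_sd Multiplicative geometric noise SD of the replicates.
#' @param truth A [hurdle_coefficients()] object used as generating truth.
#' @param seed Master seed.
#' @return A list of class `synthetic_forest_spec`.
#' @export
synthetic_forest_spec <- function(n_trees = 39, dbh_range = c(9, 28),
                                  n_replicates = 30, noise_sd = 0.05,
                                  truth = cherry_hurdle_coefficients(),
                                  seed = 1L) {
  if (dbh_range[1] <= 0 || dbh_range[2] < dbh_range[1] || n_replicates < 1) {
    abort("invalid forest specification", class = "bloomscale_error_domain")
  }
  structure(
    list(
      n_trees = n_trees, dbh_range = dbh_range, n_replicates = n_replicates,
      noise_sd = noise_sd, truth = truth, seed = seed
    ),
    class = "synthetic_forest_spec"
  )
}

# one simulated flower count from the hurdle truth (vectorised)
.sim_counts <- function(truth, D_mm, dbh_cm, layer, stratum, re_occ = 0, re_abd = 0) {
  p <- plogis(.hurdle_lp(truth$occurrence, D_mm, dbh_cm, layer, stratum, re_occ))
  mu <- exp(.hurdle_lp(truth$abundance, D_mm, dbh_cm, layer, stratum, re_abd))
  n <- length(p)
  flowering <- runif(n) < p
  counts <- integer(n)
  if (any(flowering)) {
    counts[flowering] <- .rztnb(sum(flowering), mu[flowering], truth$theta)
  }
  counts
}

#' Generate a branch dataset with known ground truth
#'
#' Simulates the manual branch-measurement campaign: each tree contributes
#' several cut-off branches, each cut-off branch a small hierarchy of
#' subbranches with tapering diameters, and every (sub)branch draws its own
#' flower count from the hurdle truth — a Bernoulli occurrence stage times a
#' zero-truncated NB abundance stage, both with nested normal random
#' intercepts (tree, and cut-off branch within tree). Flower attachment on
#' the detailed branches is restricted to shoot segments thinner than 20 mm,
#' mirroring where cherry flowers actually sit. Smaller cut-off branches
#' (< 20 mm) are "detailed" and carry along-shoot measurement series plus
#' attachment positions; larger ones are simplified records with only the
#' cut-off diameter and the count.
#'
#' @param n_trees Number of trees (default 16).
#' @param branches_per_tree Cut-off branches per tree.
#' @param dbh_range dbh range of the branch-sampled trees, cm.
#' @param truth A [hurdle_coefficients()] generating truth.
#' @param seed Integer seed.
#' @return A list with tibbles `branches` (including `cutoff_id` and the
#'   cumulated `flowers_total`), `measurements`, `attachments`, `trees`, and
#'   the `truth` used.
#' @export
generate_branch_dataset <- function(n_trees = 16, branches_per_tree = 4,
                                    dbh_range = c(9, 31),
                                    truth = cherry_hurdle_coefficients(),
                                    seed = 1L) {
  withr::with_seed(seed, {
    trees <- tibble::tibble(
      tree_id = sprintf("t%02d", seq_len(n_trees)),
      dbh_cm = runif(n_trees, dbh_range[1], dbh_range[2])
    )
    strata <- c("bot", "mid", "top")
    layers <- c("in", "out")
    compasses <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

    rows <- list()
    counter <- 0L
    for (t in seq_len(n_trees)) {
      re_tree_occ <- rnorm(1, 0, truth$sd_tree)
      re_tree_abd <- rnorm(1, 0, truth$sd_tree)
      for (b in seq_len(branches_per_tree)) {
        re_br_occ <- re_tree_occ + rnorm(1, 0, truth$sd_branch)
        re_br_abd <- re_tree_abd + rnorm(1, 0, truth$sd_branch)
        stratum <- sample(strata, 1)
        layer <- sample(layers, 1)
        compass <- sample(compasses, 1)
        d0 <- min(55, max(3, exp(rnorm(1, log(9), 0.7))))
        counter <- counter + 1L
        root_id <- sprintf("%s_b%03d", trees$tree_id[t], counter)
        # recursive subbranch hierarchy with tapering diameters
        grow <- function(parent_id, d, depth) {
          out <- list()
          n_child <- if (depth >= 4 || d < 4) 0 else sample(0:3, 1, prob = c(.2, .3, .3, .2))
          for (k in seq_len(n_child)) {
            dc <- d * runif(1, 0.35, 0.7)
            if (dc < 2) next
            counter <<- counter + 1L
            cid <- sprintf("%s_b%03d", trees$tree_id[t], counter)
            out <- c(out, list(tibble::tibble(
              tree_id = trees$tree_id[t], branch_id = cid,
              parent_branch_id = parent_id, cutoff_id = root_id,
              cutoff_diameter_mm = dc, stratum = stratum, layer = layer,
              compass = compass,
              flowers = .sim_counts(truth, dc, trees$dbh_cm[t], layer, stratum,
                re_br_occ, re_br_abd
              ),
              detailed = FALSE
            )), grow(cid, dc, depth + 1))
          }
          out
        }
        rows <- c(rows, list(tibble::tibble(
          tree_id = trees$tree_id[t], branch_id = root_id,
          parent_branch_id = NA_character_, cutoff_id = root_id,
          cutoff_diameter_mm = d0, stratum = stratum, layer = layer,
          compass = compass,
          flowers = .sim_counts(truth, d0, trees$dbh_cm[t], layer, stratum,
            re_br_occ, re_br_abd
          ),
          detailed = d0 < 20
        )), grow(root_id, d0, 1))
      }
    }
    branches <- dplyr::bind_rows(rows) |>
      dplyr::mutate(flowers = as.integer(.data$flowers))

    # along-shoot measurements and flower attachments for detailed branches
    meas <- list()
    attach <- list()
    for (i in which(branches$detailed)) {
      d0 <- branches$cutoff_diameter_mm[i]
      len <- d0 * 8 # cm; slimmer shoots are shorter
      pos <- seq(0, len, length.out = 6)
      dia <- d0 - (d0 - 2) * pos / len
      meas[[length(meas) + 1]] <- tibble::tibble(
        branch_id = branches$branch_id[i], position_cm = pos, diameter_mm = dia
      )
      nf <- branches$flowers[i]
      if (nf > 0) {
        # attach only where the interpolated diameter is below 20 mm
        x20 <- if (d0 <= 20) 0 else len * (d0 - 20) / (d0 - 2)
        attach[[length(attach) + 1]] <- tibble::tibble(
          branch_id = branches$branch_id[i],
          position_cm = runif(nf, x20, len)
        )
      }
    }

    totals <- cumulate_flower_counts(branches)
    branches <- dplyr::left_join(branches, totals, by = "branch_id")

    list(
      branches = branches,
      measurements = dplyr::bind_rows(meas),
      attachments = dplyr::bind_rows(attach),
      trees = trees,
      truth = truth
    )
  })
}

#' Generate a synthetic cylinder model of one tree
#'
#' Builds a QSM-like cylinder table by simple recursive branching: a vertical
#' trunk whose lower section carries exactly the requested dbh, first-order
#' branches leaving the trunk above the crown base at random azimuths, and
#' tapering subbranches down to a minimum cylinder diameter of 3 mm. The
#' geometry is plumbing for the pipeline, not a biological crown model: it
#' gives every tree a trunk spanning 1.3 m (so the derived dbh is within a
#' few percent of the request), a crown with points in every stratum, and
#' branch units on both sides of the 30 mm threshold.
#'
#' @param dbh_cm Target dbh, cm.
#' @param tree_id,replicate_id Identifier columns of the output.
#' @param seed Integer seed.
#' @return A cylinder tibble (see [read_cylinder_table()] for columns).
#' @export
generate_qsm <- function(dbh_cm, tree_id = "t01", replicate_id = 1L, seed = 1L) {
  if (dbh_cm <= 0) {
    abort("dbh must be > 0", class = "bloomscale_error_domain")
  }
  withr::with_seed(seed, {
    height <- 3 + 0.55 * dbh_cm
    crown_base <- 0.45 * height
    r_base <- dbh_cm / 200
    rows <- list()
    next_id <- 1L
    add <- function(parent, start, axis, len, radius, order) {
      id <- next_id
      next_id <<- next_id + 1L
      rows[[id]] <<- tibble::tibble(
        cyl_id = id, parent_id = parent,
        start_x_m = start[1], start_y_m = start[2], start_z_m = start[3],
        axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
        length_m = len, radius_m = radius, branch_order = order
      )
      id
    }
    unit <- function(v) v / sqrt(sum(v^2))

    # trunk in 1 m segments; constant radius below 2 m, linear taper above
    trunk_z <- seq(0, height - 1, by = 1)
    parent <- NA_integer_
    trunk_ids <- integer(0)
    for (z in trunk_z) {
      len <- min(1, height - z)
      r <- if (z < 2) r_base else max(0.005, r_base * (1 - (z - 2) / (height - 2)) + 0.005)
      parent <- add(parent, c(0, 0, z), c(0, 0, 1), len, r, 0L)
      trunk_ids <- c(trunk_ids, parent)
    }

    # one whorl of first-order branches per trunk segment above the crown base
    grow_branch <- function(parent_id, start, dir, radius, order, depth) {
      n_seg <- sample(3:5, 1)
      seg_len <- 0.5
      r <- radius
      p <- parent_id
      s <- start
      d <- dir
      for (k in seq_len(n_seg)) {
        r <- max(0.0015, r * 0.78)
        d <- unit(d + c(rnorm(2, 0, 0.15), 0.08))
        p <- add(p, s, d, seg_len, r, order)
        s <- s + d * seg_len
        if (depth < 2 && r > 0.004 && runif(1) < 0.5) {
          az <- runif(1, 0, 2 * pi)
          child_dir <- unit(d + c(0.8 * cos(az), 0.8 * sin(az), 0.1))
          grow_branch(p, s, child_dir, r * 0.6, order + 1L, depth + 1)
        }
        if (2 * r <= 0.003) break
      }
    }
    trunk_radius_at <- function(z) {
      if (z < 2) r_base else max(0.005, r_base * (1 - (z - 2) / (height - 2)) + 0.005)
    }
    for (i in seq_along(trunk_z)) {
      z <- trunk_z[i]
      if (z + 0.5 < crown_base || z > height - 1) next
      for (b in seq_len(sample(2:3, 1))) {
        az <- runif(1, 0, 2 * pi)
        dir <- unit(c(cos(az), sin(az), runif(1, 0.2, 0.6)))
        # keep branch bases thinner than the carrying trunk segment so
        # diameters taper monotonically along every root-to-tip path
        r0 <- min(
          0.025, 0.7 * trunk_radius_at(z),
          max(0.006, r_base * runif(1, 0.15, 0.35))
        )
        if (2 * r0 < 0.003) next
        grow_branch(trunk_ids[i], c(0, 0, z + 0.5), dir, r0, 1L, 0)
      }
    }
    dplyr::bind_rows(rows) |>
      dplyr::mutate(
        tree_id = tree_id, replicate_id = as.integer(replicate_id),
        .before = 1
      )
  })
}

#' Replicate a QSM with reconstruction noise
#'
#' Emulates the stochasticity of repeated QSM reconstruction: each replicate
#' applies one global multiplicative scale to all coordinates and lengths
#' (preserving connectivity) and an independent multiplicative jitter to
#' every cylinder radius, both with SD `noise_sd`. With `noise_sd = 0` the
#' replicates are identical copies.
#'
#' @param qsm Cylinder table of the base tree.
#' @param k Number of replicates (default 30).
#' @param noise_sd Multiplicative noise SD.
#' @param seed Integer seed.
#' @return A cylinder tibble with `replicate_id` 1..k.
#' @export
generate_replicates <- function(qsm, k = 30, noise_sd = 0.05, seed = 1L) {
  if (k < 1) {
    abort("k must be >= 1", class = "bloomscale_error_domain")
  }
  withr::with_seed(seed, {
    purrr::map(seq_len(k), function(r) {
      s <- max(0.5, rnorm(1, 1, noise_sd))
      jitter <- pmax(0.2, rnorm(nrow(qsm), 1, noise_sd))
      qsm |>
        dplyr::mutate(
          replicate_id = as.integer(r),
          start_x_m = .data$start_x_m * s,
          start_y_m = .data$start_y_m * s,
          start_z_m = .data$start_z_m * s,
          length_m = .data$length_m * s,
          radius_m = .data$radius_m * jitter
        )
    }) |> dplyr::bind_rows()
  })
}

#' Generate a whole synthetic forest
#'
#' Convenience wrapper running [generate_qsm()] and [generate_replicates()]
#' for every tree of a [synthetic_forest_spec()].
#'
#' @param spec A [synthetic_forest_spec()].
#' @return A list with `trees` (tree_id, dbh_cm) and `cylinders` (all
#'   replicates of all trees).
#' @export
generate_forest <- function(spec = synthetic_forest_spec()) {
  dbh <- withr::with_seed(
    spec$seed,
    runif(spec$n_trees, spec$dbh_range[1], spec$dbh_range[2])
  )
  trees <- tibble::tibble(
    tree_id = sprintf("t%02d", seq_len(spec$n_trees)),
    dbh_cm = dbh
  )
  cylinders <- purrr::map(seq_len(spec$n_trees), function(i) {
    base <- generate_qsm(dbh[i],
      tree_id = trees$tree_id[i],
      seed = spec$seed + 1000 + i
    )
    generate_replicates(base,
      k = spec$n_replicates, noise_sd = spec$noise_sd,
      seed = spec$seed + 2000 + i
    )
  }) |> dplyr::bind_rows()
  list(trees = trees, cylinders = cylinders)
}
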