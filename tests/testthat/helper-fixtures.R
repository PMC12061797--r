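# Shared fixtures and independent oracles, all built in code.

# minimal branch table: chain a <- b <- c plus defaults
chain_branches <- function(flowers = c(1L, 2L, 3L)) {
  tibble::tibble(
    tree_id = "t1",
    branch_id = c("a", "b", "c"),
    parent_branch_id = c(NA, "a", "b"),
    cutoff_diameter_mm = c(20, 10, 5),
    stratum = "bot", layer = "out", compass = "N",
    flowers = flowers, detailed = FALSE
  )
}

one_tree <- function(tree_id = "t1", dbh_cm = 20) {
  tibble::tibble(tree_id = tree_id, dbh_cm = dbh_cm)
}

# branch table with independent rows (no hierarchy), counts drawn from the
# hurdle truth — the covariate design for parameter-recovery simulations
flat_branches <- function(n, trees, truth, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      tree_id = sample(trees$tree_id, n, replace = TRUE),
      branch_id = sprintf("b%04d", seq_len(n)),
      parent_branch_id = NA_character_,
      cutoff_diameter_mm = exp(runif(n, log(2), log(25))),
      stratum = sample(c("bot", "mid", "top"), n, replace = TRUE),
      layer = sample(c("in", "out"), n, replace = TRUE),
      compass = "N", detailed = FALSE
    ) |>
      dplyr::mutate(
        flowers = as.integer(bloomscale:::.sim_counts(
          truth, .data$cutoff_diameter_mm,
          trees$dbh_cm[match(.data$tree_id, trees$tree_id)],
          .data$layer, .data$stratum
        ))
      )
  })
}

# random branch hierarchy: each branch's parent is a uniformly chosen earlier
# branch (or none), all in one tree
random_hierarchy <- function(n, tree_id = "t1") {
  parent <- rep(NA_character_, n)
  ids <- sprintf("b%03d", seq_len(n))
  for (i in seq(2, length.out = max(0, n - 1))) {
    if (runif(1) < 0.8) parent[i] <- ids[sample(i - 1, 1)]
  }
  tibble::tibble(
    tree_id = tree_id, branch_id = ids, parent_branch_id = parent,
    cutoff_diameter_mm = runif(n, 2, 55),
    stratum = sample(c("bot", "mid", "top"), n, replace = TRUE),
    layer = sample(c("in", "out"), n, replace = TRUE),
    compass = sample(c("N", "NE", "E", "SE", "S", "SW", "W", "NW"), n, replace = TRUE),
    flowers = rpois(n, 3),
    detailed = FALSE
  )
}

# is sel[i] an ancestor or descendant of sel[j] in the branch table?
count_related_pairs <- function(branches, selected_ids) {
  parent <- setNames(branches$parent_branch_id, branches$branch_id)
  ancestors_of <- function(id) {
    out <- character(0)
    p <- parent[[id]]
    while (!is.na(p)) {
      out <- c(out, p)
      p <- parent[[p]]
    }
    out
  }
  anc <- lapply(selected_ids, ancestors_of)
  names(anc) <- selected_ids
  sum(vapply(selected_ids, function(id) {
    length(intersect(anc[[id]], selected_ids)) > 0
  }, logical(1)))
}

# brute-force point-in-eroded-polygon oracle: ray casting + exact
# point-to-segment distances (independent of the half-plane implementation)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
      px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

dist_point_segment <- function(px, py, ax, ay, bx, by) {
  abx <- bx - ax; aby <- by - ay
  t <- ((px - ax) * abx + (py - ay) * aby) / (abx^2 + aby^2)
  t <- min(1, max(0, t))
  sqrt((px - (ax + t * abx))^2 + (py - (ay + t * aby))^2)
}

oracle_in_eroded <- function(px, py, poly, depth) {
  if (!point_in_polygon(px, py, poly)) {
    return(FALSE)
  }
  n <- nrow(poly)
  j <- c(2:n, 1)
  dmin <- min(vapply(seq_len(n), function(i) {
    dist_point_segment(px, py, poly[i, 1], poly[i, 2], poly[j[i], 1], poly[j[i], 2])
  }, numeric(1)))
  dmin >= depth
}

# independent ZTNB mean by direct summation of the truncated pmf
ztnb_mean_oracle <- function(mu, theta, kmax = NULL) {
  if (is.null(kmax)) {
    kmax <- max(4000, 2 * stats::qnbinom(1e-12, size = theta, mu = mu, lower.tail = FALSE))
  }
  k <- seq_len(kmax)
  p <- stats::dnbinom(k, size = theta, mu = mu)
  sum(k * p) / sum(p)
}

# hand-built QSM: vertical trunk of `height` m (1 m segments, constant
# radius), plus arbitrary branch cylinders appended by the caller
trunk_qsm <- function(height = 10, radius = 0.1, tree_id = "t1") {
  z <- seq(0, height - 1, by = 1)
  tibble::tibble(
    tree_id = tree_id, replicate_id = 1L,
    cyl_id = seq_along(z),
    parent_id = c(NA, head(seq_along(z), -1)),
    start_x_m = 0, start_y_m = 0, start_z_m = z,
    axis_x = 0, axis_y = 0, axis_z = 1,
    length_m = 1, radius_m = radius, branch_order = 0L
  )
}

# append horizontal branch cylinders from (x0,y0,z) to (x1,y1,z)
add_branch_cyl <- function(qsm, x0, y0, x1, y1, z, radius = 0.005, order = 1L,
                           parent = 1L) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  dplyr::bind_rows(qsm, tibble::tibble(
    tree_id = qsm$tree_id[1], replicate_id = 1L,
    cyl_id = max(qsm$cyl_id) + 1L, parent_id = as.integer(parent),
    start_x_m = x0, start_y_m = y0, start_z_m = z,
    axis_x = (x1 - x0) / len, axis_y = (y1 - y0) / len, axis_z = 0,
    length_m = len, radius_m = radius, branch_order = as.integer(order)
  ))
}

# square crown perimeter (side `side` centred on the trunk) at given heights
square_crown_qsm <- function(height = 10, side = 10, crown_z, radius = 0.005,
                             trunk_radius = 0.1) {
  qsm <- trunk_qsm(height = height, radius = trunk_radius)
  h <- side / 2
  for (z in crown_z) {
    qsm <- add_branch_cyl(qsm, -h, -h, h, -h, z, radius)
    qsm <- add_branch_cyl(qsm, h, -h, h, h, z, radius)
    qsm <- add_branch_cyl(qsm, h, h, -h, h, z, radius)
    qsm <- add_branch_cyl(qsm, -h, h, -h, -h, z, radius)
  }
  qsm
}
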