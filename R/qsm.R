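#' Validate a cylinder table
#'
#' A quantitative structure model (QSM) is a table of cylinders forming a
#' rooted tree: columns `cyl_id`, `parent_id` (`NA` for the single root),
#' `start_x_m`, `start_y_m`, `start_z_m`, unit `axis_x/y/z`, `length_m`,
#' `radius_m` and `branch_order` (0 for the trunk). Coordinates are metres in
#' a right-handed frame with +z up; a cylinder runs from its start point along
#' its axis for its length.
#'
#' @param qsm Cylinder table for one tree and replicate.
#' @param tol Tolerance for the unit-axis check.
#' @return `qsm`, invisibly.
#' @export
validate_qsm <- function(qsm, tol = 1e-6) {
  if (nrow(qsm) == 0) {
    abort("empty cylinder table", class = "bloomscale_error_qsm")
  }
  roots <- which(is.na(qsm$parent_id))
  if (length(roots) != 1) {
    abort("a QSM must have exactly one root cylinder", class = "bloomscale_error_qsm")
  }
  if (anyDuplicated(qsm$cyl_id)) {
    abort("duplicated cyl_id", class = "bloomscale_error_qsm")
  }
  parent_idx <- match(qsm$parent_id, qsm$cyl_id)
  if (any(!is.na(qsm$parent_id) & is.na(parent_idx))) {
    abort("parent_id refers to an unknown cylinder", class = "bloomscale_error_qsm")
  }
  norms <- sqrt(qsm$axis_x^2 + qsm$axis_y^2 + qsm$axis_z^2)
  if (any(abs(norms - 1) > tol)) {
    abort("cylinder axes must be unit vectors", class = "bloomscale_error_qsm")
  }
  if (any(qsm$length_m <= 0) || any(qsm$radius_m <= 0)) {
    abort("cylinder length and radius must be > 0", class = "bloomscale_error_qsm")
  }
  # acyclicity: walking up parents must terminate
  n <- nrow(qsm)
  for (i in seq_len(n)) {
    j <- i
    steps <- 0L
    while (!is.na(parent_idx[j])) {
      j <- parent_idx[j]
      steps <- steps + 1L
      if (steps > n) {
        abort("cycle in cylinder parent graph", class = "bloomscale_error_qsm")
      }
    }
  }
  invisible(qsm)
}

# cylinder end points
.cyl_ends <- function(qsm) {
  tibble::tibble(
    end_x = qsm$start_x_m + qsm$axis_x * qsm$length_m,
    end_y = qsm$start_y_m + qsm$axis_y * qsm$length_m,
    end_z = qsm$start_z_m + qsm$axis_z * qsm$length_m
  )
}

# start and end points of the crown cylinders (branch order >= 1), as a
# matrix with columns x, y, z
.crown_points <- function(qsm) {
  crown <- qsm[qsm$branch_order >= 1, , drop = FALSE]
  if (nrow(crown) == 0) {
    return(NULL)
  }
  ends <- .cyl_ends(crown)
  cbind(
    x = c(crown$start_x_m, ends$end_x),
    y = c(crown$start_y_m, ends$end_y),
    z = c(crown$start_z_m, ends$end_z)
  )
}

#' Derive whole-tree metrics from a QSM
#'
#' Computes the standard tree dimensions used as candidate predictors of
#' flower abundance:
#'
#' * `dbh_cm` — twice the radius of the trunk cylinder whose axial span
#'   contains 1.3 m above the stem base;
#' * `height_m` — vertical extent of the model;
#' * `crown_base_height_m` — height of the lowest branch cylinder above the
#'   base;
#' * `crown_projection_area_m2` — area of the 2D convex hull of the crown
#'   cylinder endpoints projected onto the ground;
#' * `crown_diameter_m` — mean horizontal extent of that hull over eight
#'   azimuthal directions (or the maximum extent with
#'   `diameter_method = "max"`);
#' * `crown_volume_m3` — the crown volume obtained by slicing the crown into
#'   horizontal sections of `slice_height` metres, taking the 2D convex hull
#'   of each slice's points, and summing hull area times slice height. For
#'   convex crowns this converges to the convex-hull volume while still
#'   tracking vertical concavity of the crown profile.
#'
#' Trees without branch cylinders get `NA` crown metrics with a warning.
#'
#' @param qsm Cylinder table for one tree and replicate.
#' @param slice_height Slice height for the crown volume, m.
#' @param diameter_method `"spread"` (default) or `"max"`.
#' @return A one-row tibble of metrics.
#' @export
derive_tree_metrics <- function(qsm, slice_height = 0.5,
                                diameter_method = c("spread", "max")) {
  diameter_method <- match.arg(diameter_method)
  validate_qsm(qsm)
  ends <- .cyl_ends(qsm)
  base_z <- qsm$start_z_m[is.na(qsm$parent_id)]
  top_z <- max(qsm$start_z_m, ends$end_z)
  height <- top_z - base_z
  if (height <= 1.3) {
    abort("tree shorter than 1.3 m: dbh undefined", class = "bloomscale_error_metric")
  }

  trunk <- qsm$branch_order == 0
  z_lo <- pmin(qsm$start_z_m, ends$end_z)
  z_hi <- pmax(qsm$start_z_m, ends$end_z)
  target <- base_z + 1.3
  spanning <- which(trunk & z_lo <= target & z_hi > target)
  if (length(spanning) == 0) {
    spanning <- which(trunk & z_lo <= target)
    spanning <- spanning[which.max(z_lo[spanning])]
  } else {
    spanning <- spanning[which.min(z_lo[spanning])]
  }
  dbh_cm <- 2 * qsm$radius_m[spanning] * 100

  crown <- .crown_points(qsm)
  if (is.null(crown)) {
    warn("QSM has no branch cylinders: crown metrics are NA")
    return(tibble::tibble(
      dbh_cm = dbh_cm, height_m = height, crown_base_height_m = NA_real_,
      crown_diameter_m = NA_real_, crown_projection_area_m2 = NA_real_,
      crown_volume_m3 = NA_real_
    ))
  }
  crown_base_z <- min(qsm$start_z_m[qsm$branch_order >= 1])
  hull <- .hull_xy(crown[, "x"], crown[, "y"])
  cpa <- if (is.null(hull)) 0 else .polygon_area(hull)
  cd <- if (is.null(hull)) 0 else .hull_diameter(hull, diameter_method)

  # sliced convex-hull crown volume
  n_slices <- max(1L, ceiling((top_z - crown_base_z) / slice_height))
  vol <- 0
  for (k in seq_len(n_slices)) {
    z0 <- crown_base_z + (k - 1) * slice_height
    z1 <- min(z0 + slice_height, top_z)
    in_slice <- crown[, "z"] >= z0 & crown[, "z"] < z1 + (k == n_slices) * 1e-9
    h <- .hull_xy(crown[in_slice, "x"], crown[in_slice, "y"])
    if (!is.null(h)) vol <- vol + .polygon_area(h) * (z1 - z0)
  }

  tibble::tibble(
    dbh_cm = dbh_cm,
    height_m = height,
    crown_base_height_m = crown_base_z - base_z,
    crown_diameter_m = cd,
    crown_projection_area_m2 = cpa,
    crown_volume_m3 = vol
  )
}

#' Extract flower-bearing branch units from a QSM
#'
#' Branch units are the pieces of a tree to which the branch-level flower
#' model is applied during upscaling. Walking the cylinder tree from the
#' root, the first cylinder along any path whose diameter drops to at most
#' `d_max_mm` opens a unit consisting of that cylinder and its entire
#' subtree; cylinders already claimed by a unit are never claimed again, so
#' units are disjoint and each eligible cylinder belongs to exactly one unit.
#'
#' @param qsm Cylinder table for one tree and replicate.
#' @param d_max_mm Diameter threshold, mm (default 30).
#' @return A tibble with one row per unit: `root_cyl_id`,
#'   `root_diameter_mm`, `n_cylinders`, bounding-box center
#'   `center_x/y/z_m`, and a list-column `member_cyl_ids`.
#' @export
extract_branch_units <- function(qsm, d_max_mm = 30) {
  validate_qsm(qsm)
  diam_mm <- 2 * qsm$radius_m * 1000
  parent_idx <- match(qsm$parent_id, qsm$cyl_id)
  n <- nrow(qsm)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent_idx[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  subtree <- function(i) {
    out <- integer(0)
    stack <- i
    while (length(stack) > 0) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      out <- c(out, j)
      stack <- c(stack, children[[j]])
    }
    out
  }

  roots <- integer(0)
  stack <- which(is.na(qsm$parent_id))
  while (length(stack) > 0) {
    j <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (diam_mm[j] <= d_max_mm) {
      roots <- c(roots, j) # whole subtree becomes a unit; stop descending
    } else {
      stack <- c(stack, children[[j]])
    }
  }
  if (length(roots) == 0) {
    return(tibble::tibble(
      root_cyl_id = integer(0), root_diameter_mm = numeric(0),
      n_cylinders = integer(0), center_x_m = numeric(0),
      center_y_m = numeric(0), center_z_m = numeric(0),
      member_cyl_ids = list()
    ))
  }

  ends <- .cyl_ends(qsm)
  purrr::map(roots, function(r) {
    members <- subtree(r)
    xs <- c(qsm$start_x_m[members], ends$end_x[members])
    ys <- c(qsm$start_y_m[members], ends$end_y[members])
    zs <- c(qsm$start_z_m[members], ends$end_z[members])
    tibble::tibble(
      root_cyl_id = qsm$cyl_id[r],
      root_diameter_mm = diam_mm[r],
      n_cylinders = length(members),
      center_x_m = (min(xs) + max(xs)) / 2,
      center_y_m = (min(ys) + max(ys)) / 2,
      center_z_m = (min(zs) + max(zs)) / 2,
      member_cyl_ids = list(qsm$cyl_id[members])
    )
  }) |> dplyr::bind_rows()
}

#' Classify branch units into crown strata and layers
#'
#' Assigns each branch unit a vertical stratum and a horizontal layer from
#' its bounding-box center. The crown length (crown base to tree top) is
#' split into three equal thirds — `bot`, `mid`, `top` — with half-open
#' boundaries; centers below the crown base fall into `bot`. For the layer,
#' the crown is sliced into horizontal cross sections of `slice_height`
#' metres; the convex hull of the crown points in the center's slice is
#' eroded inward by `layer_depth` metres, and centers inside the eroded hull
#' are `in`, all others `out`. Degenerate slices (fewer than three distinct
#' points, or hulls narrower than twice the depth) classify as `out`.
#'
#' @param units Tibble from [extract_branch_units()].
#' @param qsm The cylinder table the units came from.
#' @param layer_depth Depth of the outer layer, m (default 2).
#' @param slice_height Height of the cross-section slices, m (default 0.5).
#' @return `units` with `stratum` and `layer` columns added.
#' @export
classify_crown_position <- function(units, qsm, layer_depth = 2, slice_height = 0.5) {
  validate_qsm(qsm)
  if (nrow(units) == 0) {
    return(dplyr::mutate(units, stratum = character(0), layer = character(0)))
  }
  ends <- .cyl_ends(qsm)
  base_z <- qsm$start_z_m[is.na(qsm$parent_id)]
  top_z <- max(qsm$start_z_m, ends$end_z)
  crown <- .crown_points(qsm)
  if (is.null(crown)) {
    abort("QSM has no branch cylinders: crown position undefined",
      class = "bloomscale_error_metric"
    )
  }
  crown_base_z <- min(qsm$start_z_m[qsm$branch_order >= 1])
  crown_len <- top_z - crown_base_z

  rel <- (units$center_z_m - crown_base_z) / crown_len
  stratum <- dplyr::case_when(
    rel < 1 / 3 ~ "bot",
    rel < 2 / 3 ~ "mid",
    .default = "top"
  )

  slice_idx <- floor((crown[, "z"] - crown_base_z) / slice_height)
  layer <- vapply(seq_len(nrow(units)), function(i) {
    k <- floor((units$center_z_m[i] - crown_base_z) / slice_height)
    pts <- crown[slice_idx == k, , drop = FALSE]
    hull <- if (nrow(pts) >= 3) .hull_xy(pts[, "x"], pts[, "y"]) else NULL
    if (is.null(hull)) {
      return("out")
    }
    d <- .signed_depth(units$center_x_m[i], units$center_y_m[i], hull)
    if (d >= layer_depth) "in" else "out"
  }, character(1))

  dplyr::mutate(units, stratum = stratum, layer = layer)
}
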