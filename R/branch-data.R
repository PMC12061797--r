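#' Branch measurement tables
#'
#' The branch-level data model is a pair of plain tables. The *branch table*
#' holds one row per (sub)branch of a cut-off branch:
#'
#' * `tree_id` — tree identifier,
#' * `branch_id` — branch identifier, unique within the table,
#' * `parent_branch_id` — identifier of the parent branch, `NA` for a cut-off
#'   branch itself,
#' * `cutoff_diameter_mm` — branch diameter at the cut (mm),
#' * `stratum` — vertical crown stratum, one of `"bot"`, `"mid"`, `"top"`,
#' * `layer` — horizontal crown layer, `"in"` or `"out"`,
#' * `compass` — one of the eight compass directions, or `NA`,
#' * `flowers` — flowers counted on this branch alone (not its subbranches),
#' * `detailed` — whether the branch carries along-shoot measurements.
#'
#' The companion *measurement table* is long-format with one row per
#' along-shoot calliper reading: `branch_id`, `position_cm` (distance from the
#' cut), `diameter_mm`. Positions must be strictly increasing within a branch.
#'
#' `validate_branch_table()` checks identifiers, the parent graph (acyclic,
#' same-tree links) and value ranges, and returns its input invisibly.
#'
#' @param branches A branch table as described above.
#' @param measurements Optional measurement table to validate against
#'   `branches`.
#' @return `branches`, invisibly.
#' @export
validate_branch_table <- function(branches, measurements = NULL) {
  required <- c(
    "tree_id", "branch_id", "parent_branch_id", "cutoff_diameter_mm",
    "stratum", "layer", "flowers"
  )
  missing_cols <- setdiff(required, names(branches))
  if (length(missing_cols) > 0) {
    abort(
      paste0("branch table lacks columns: ", paste(missing_cols, collapse = ", ")),
      class = "bloomscale_error_columns"
    )
  }
  if (anyDuplicated(branches$branch_id)) {
    abort("duplicated branch_id", class = "bloomscale_error_reference")
  }
  if (any(branches$cutoff_diameter_mm <= 0)) {
    abort("cutoff_diameter_mm must be > 0", class = "bloomscale_error_domain")
  }
  if (any(branches$flowers < 0) || any(branches$flowers != round(branches$flowers))) {
    abort("flowers must be non-negative integers", class = "bloomscale_error_domain")
  }
  bad_stratum <- !branches$stratum %in% c("bot", "mid", "top")
  bad_layer <- !branches$layer %in% c("in", "out")
  if (any(bad_stratum) || any(bad_layer)) {
    abort("stratum must be bot/mid/top and layer in/out",
      class = "bloomscale_error_domain"
    )
  }
  has_parent <- !is.na(branches$parent_branch_id)
  idx <- match(branches$parent_branch_id[has_parent], branches$branch_id)
  if (anyNA(idx)) {
    abort("parent_branch_id refers to an unknown branch",
      class = "bloomscale_error_reference"
    )
  }
  if (any(branches$tree_id[has_parent] != branches$tree_id[idx])) {
    abort("parent links must stay within one tree",
      class = "bloomscale_error_reference"
    )
  }
  # acyclicity is checked by the same parent walk used for cumulation
  .branch_depths(branches)
  if (!is.null(measurements)) {
    unknown <- setdiff(measurements$branch_id, branches$branch_id)
    if (length(unknown) > 0) {
      abort("measurement rows for unknown branch ids",
        class = "bloomscale_error_reference"
      )
    }
    by_branch <- split(measurements$position_cm, measurements$branch_id)
    ok <- vapply(by_branch, function(p) all(diff(p) > 0), logical(1))
    if (!all(ok)) {
      abort("positions must be strictly increasing within a branch",
        class = "bloomscale_error_ordering"
      )
    }
  }
  invisible(branches)
}

# depth of each branch in the parent graph; errors on cycles / dangling links
.branch_depths <- function(branches) {
  parent_idx <- match(branches$parent_branch_id, branches$branch_id)
  if (any(!is.na(branches$parent_branch_id) & is.na(parent_idx))) {
    abort("parent_branch_id refers to an unknown branch",
      class = "bloomscale_error_reference"
    )
  }
  n <- nrow(branches)
  depth <- integer(n)
  for (i in seq_len(n)) {
    j <- i
    steps <- 0L
    while (!is.na(parent_idx[j])) {
      j <- parent_idx[j]
      steps <- steps + 1L
      if (steps > n) {
        abort("cycle detected in branch hierarchy",
          class = "bloomscale_error_hierarchy"
        )
      }
    }
    depth[i] <- steps
  }
  depth
}

#' Cumulate flower counts over the branch hierarchy
#'
#' Each branch's total is its own flower count plus the totals of all its
#' subbranches, recursively — the quantity the branch-level models are fitted
#' to. The result does not depend on row order.
#'
#' @param branches A branch table (see [validate_branch_table()]).
#' @return A tibble with `branch_id` and `flowers_total`, one row per input
#'   branch, in input order.
#' @examples
#' b <- tibble::tibble(
#'   tree_id = 1, branch_id = c("a", "b", "c"),
#'   parent_branch_id = c(NA, "a", "b"),
#'   cutoff_diameter_mm = c(20, 10, 5),
#'   stratum = "bot", layer = "out", flowers = c(1L, 2L, 3L)
#' )
#' cumulate_flower_counts(b)
#' @export
cumulate_flower_counts <- function(branches) {
  if (nrow(branches) == 0) {
    return(tibble::tibble(branch_id = branches$branch_id, flowers_total = numeric(0)))
  }
  validate_branch_table(branches)
  parent_idx <- match(branches$parent_branch_id, branches$branch_id)
  total <- as.numeric(branches$flowers)
  n <- nrow(branches)
  # push each branch's own count up its full ancestor chain
  for (i in seq_len(n)) {
    j <- parent_idx[i]
    while (!is.na(j)) {
      total[j] <- total[j] + branches$flowers[i]
      j <- parent_idx[j]
    }
  }
  tibble::tibble(branch_id = branches$branch_id, flowers_total = total)
}

#' Split a measured shoot into diameter classes
#'
#' Along-shoot calliper series are interpolated linearly between consecutive
#' readings and the shoot length falling into each diameter class is
#' accumulated. Classes are half-open `[lower, upper)` with boundaries at
#' multiples of `class_width`, so a reading exactly on a boundary belongs to
#' the upper class. Class lengths sum to the measured shoot length.
#'
#' @param position_cm Strictly increasing positions along the shoot (cm from
#'   the cut).
#' @param diameter_mm Diameters at those positions (mm, > 0).
#' @param class_width Diameter class width in mm (default 5).
#' @return A tibble with `class_lower_mm`, `class_upper_mm`, `length_cm`,
#'   classes with zero length omitted, ordered by class.
#' @examples
#' segment_diameter_classes(c(0, 100), c(12, 2))
#' @export
segment_diameter_classes <- function(position_cm, diameter_mm, class_width = 5) {
  if (length(position_cm) < 2) {
    abort("need at least two measurements", class = "bloomscale_error_insufficient_data")
  }
  if (length(position_cm) != length(diameter_mm)) {
    abort("position and diameter lengths differ", class = "bloomscale_error_domain")
  }
  if (any(diff(position_cm) <= 0)) {
    abort("positions must be strictly increasing", class = "bloomscale_error_ordering")
  }
  if (any(diameter_mm <= 0)) {
    abort("diameters must be > 0", class = "bloomscale_error_domain")
  }
  lengths <- new.env()
  add_len <- function(cls, len) {
    key <- as.character(cls)
    lengths[[key]] <- (lengths[[key]] %||% 0) + len
  }
  for (i in seq_len(length(position_cm) - 1)) {
    x1 <- position_cm[i]
    x2 <- position_cm[i + 1]
    d1 <- diameter_mm[i]
    d2 <- diameter_mm[i + 1]
    lo <- min(d1, d2)
    hi <- max(d1, d2)
    bounds <- class_width * seq(ceiling(lo / class_width), floor(hi / class_width))
    bounds <- bounds[bounds > lo & bounds < hi]
    if (length(bounds) > 0 && d1 != d2) {
      x_cross <- x1 + (bounds - d1) / (d2 - d1) * (x2 - x1)
    } else {
      x_cross <- numeric(0)
    }
    cuts <- sort(c(x1, x_cross, x2))
    for (k in seq_len(length(cuts) - 1)) {
      xm <- (cuts[k] + cuts[k + 1]) / 2
      dm <- d1 + (xm - x1) / (x2 - x1) * (d2 - d1)
      add_len(floor(dm / class_width), cuts[k + 1] - cuts[k])
    }
  }
  keys <- sort(as.integer(ls(lengths)))
  tibble::tibble(
    class_lower_mm = keys * class_width,
    class_upper_mm = (keys + 1) * class_width,
    length_cm = vapply(as.character(keys), function(k) lengths[[k]], numeric(1),
      USE.NAMES = FALSE
    )
  )
}

# interpolated diameter (mm) at arbitrary positions of one measured shoot
.diameter_at <- function(position_cm, diameter_mm, at_cm) {
  stats::approx(position_cm, diameter_mm, xout = at_cm, rule = 2)$y
}

#' Flower density per diameter class and crown section
#'
#' Summarises, for the detailed branches only, how many flowers sit on a
#' centimetre of shoot in each diameter class, split by crown stratum and
#' layer. When an attachment table (`branch_id`, `position_cm` of each flower)
#' is supplied, flowers are assigned to the class of the interpolated shoot
#' diameter at their position; without one, each branch's own flowers are
#' assigned to the class of its cut-off diameter and its whole measured length
#' is used.
#'
#' @param branches Branch table; only rows with `detailed = TRUE` contribute.
#' @param measurements Long-format measurement table.
#' @param attachments Optional table of flower attachment positions.
#' @param class_width Diameter class width in mm.
#' @return A tibble with one row per diameter class x stratum x layer:
#'   `class_lower_mm`, `class_upper_mm`, `stratum`, `layer`, `length_cm`,
#'   `flowers`, `flowers_per_cm`.
#' @export
flowers_per_cm_summary <- function(branches, measurements, attachments = NULL,
                                   class_width = 5) {
  if (nrow(branches) == 0) {
    return(tibble::tibble(
      class_lower_mm = numeric(0), class_upper_mm = numeric(0),
      stratum = character(0), layer = character(0),
      length_cm = numeric(0), flowers = numeric(0), flowers_per_cm = numeric(0)
    ))
  }
  validate_branch_table(branches, measurements)
  detailed <- dplyr::filter(branches, .data$detailed)
  pieces <- purrr::map(seq_len(nrow(detailed)), function(i) {
    row <- detailed[i, ]
    m <- dplyr::filter(measurements, .data$branch_id == row$branch_id)
    if (nrow(m) < 2) {
      return(NULL)
    }
    cls <- segment_diameter_classes(m$position_cm, m$diameter_mm, class_width)
    if (is.null(attachments)) {
      fl_class <- floor(row$cutoff_diameter_mm / class_width)
      fl <- tibble::tibble(class_idx = fl_class, flowers = as.numeric(row$flowers))
    } else {
      a <- dplyr::filter(attachments, .data$branch_id == row$branch_id)
      d_at <- .diameter_at(m$position_cm, m$diameter_mm, a$position_cm)
      fl <- tibble::tibble(class_idx = floor(d_at / class_width)) |>
        dplyr::count(.data$class_idx, name = "flowers") |>
        dplyr::mutate(flowers = as.numeric(.data$flowers))
    }
    cls |>
      dplyr::mutate(class_idx = .data$class_lower_mm / class_width) |>
      dplyr::full_join(fl, by = "class_idx") |>
      dplyr::mutate(
        class_lower_mm = .data$class_idx * class_width,
        class_upper_mm = (.data$class_idx + 1) * class_width,
        length_cm = dplyr::coalesce(.data$length_cm, 0),
        flowers = dplyr::coalesce(.data$flowers, 0),
        stratum = row$stratum, layer = row$layer
      )
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    return(flowers_per_cm_summary(branches[0, ], measurements))
  }
  out <- out |>
    dplyr::group_by(.data$class_lower_mm, .data$class_upper_mm, .data$stratum, .data$layer) |>
    dplyr::summarise(
      length_cm = sum(.data$length_cm),
      flowers = sum(.data$flowers),
      .groups = "drop"
    )
  if (any(out$length_cm == 0 & out$flowers > 0)) {
    abort("flowers recorded in a diameter class with zero shoot length",
      class = "bloomscale_error_inconsistency"
    )
  }
  out |>
    dplyr::mutate(flowers_per_cm = ifelse(.data$length_cm > 0,
      .data$flowers / .data$length_cm, 0
    )) |>
    dplyr::arrange(.data$class_lower_mm, .data$stratum, .data$layer)
}
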