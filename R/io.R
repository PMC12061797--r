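#' Read and write the package's CSV tables
#'
#' Thin readr wrappers that pin the column types of the four table formats the
#' pipeline exchanges:
#'
#' * branch tables (`tree_id`, `branch_id`, `parent_branch_id`,
#'   `cutoff_diameter_mm`, `stratum`, `layer`, `compass`, `flowers`,
#'   `detailed`),
#' * along-shoot measurement tables (`branch_id`, `position_cm`,
#'   `diameter_mm`),
#' * tree tables (`tree_id`, `dbh_cm`),
#' * cylinder tables (`tree_id`, `replicate_id`, `cyl_id`, `parent_id`,
#'   `start_x_m`, `start_y_m`, `start_z_m`, `axis_x`, `axis_y`, `axis_z`,
#'   `length_m`, `radius_m`, `branch_order`).
#'
#' Readers validate what they read; writers are plain `readr::write_csv()`.
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return a tibble; writers return `x` invisibly.
#' @name bloomscale_io
NULL

#' @rdname bloomscale_io
#' @export
read_branch_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    tree_id = readr::col_character(),
    branch_id = readr::col_character(),
    parent_branch_id = readr::col_character(),
    cutoff_diameter_mm = readr::col_double(),
    stratum = readr::col_character(),
    layer = readr::col_character(),
    compass = readr::col_character(),
    flowers = readr::col_integer(),
    detailed = readr::col_logical()
  ))
  validate_branch_table(out)
  out
}

#' @rdname bloomscale_io
#' @export
read_measurement_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    branch_id = readr::col_character(),
    position_cm = readr::col_double(),
    diameter_mm = readr::col_double()
  ))
}

#' @rdname bloomscale_io
#' @export
read_tree_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    tree_id = readr::col_character(),
    dbh_cm = readr::col_double()
  ))
  if (any(out$dbh_cm <= 0)) {
    abort("dbh_cm must be > 0", class = "bloomscale_error_domain")
  }
  out
}

#' @rdname bloomscale_io
#' @export
read_cylinder_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    tree_id = readr::col_character(),
    replicate_id = readr::col_integer(),
    cyl_id = readr::col_integer(),
    parent_id = readr::col_integer(),
    start_x_m = readr::col_double(),
    start_y_m = readr::col_double(),
    start_z_m = readr::col_double(),
    axis_x = readr::col_double(),
    axis_y = readr::col_double(),
    axis_z = readr::col_double(),
    length_m = readr::col_double(),
    radius_m = readr::col_double(),
    branch_order = readr::col_integer()
  ))
  out
}

#' @rdname bloomscale_io
#' @export
write_branch_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname bloomscale_io
#' @export
write_measurement_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname bloomscale_io
#' @export
write_tree_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname bloomscale_io
#' @export
write_cylinder_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}
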