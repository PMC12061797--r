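#' Numeric coordinates for branches in the sampling space
#'
#' Each branch becomes a point in a six-dimensional space spanned by branch
#' diameter, crown layer, crown stratum, compass direction, tree identity and
#' stem diameter (dbh). Categorical variables are coded along their only
#' natural orderings (stratum bot/mid/top as 0/1/2, layer in/out as 0/1,
#' compass N through NW as 0..7, tree id as a dense index); branch diameter
#' enters on the log scale by default, matching its use in the branch models.
#' Every dimension is then z-standardised (mean 0, SD 1) over the input set so
#' no variable dominates the Euclidean distance; a dimension with zero spread
#' collapses to the constant 0. Missing compass directions also code to 0
#' after scaling.
#'
#' @param branches Branch table (see [validate_branch_table()]).
#' @param trees Tree table with `tree_id` and `dbh_cm`.
#' @param log_diameter Use `log(cutoff_diameter_mm)` as the diameter
#'   coordinate (default `TRUE`).
#' @return A tibble with `branch_id` and the six scaled coordinates
#'   (`diameter`, `layer`, `stratum`, `compass`, `tree`, `dbh`); the encoding
#'   and the centring/scaling constants are attached as attributes
#'   `"encoding"` and `"scaling"`.
#' @export
scale_branch_coordinates <- function(branches, trees, log_diameter = TRUE) {
  stratum_levels <- c(bot = 0, mid = 1, top = 2)
  layer_levels <- c("in" = 0, out = 1)
  compass_levels <- setNames(0:7, c("N", "NE", "E", "SE", "S", "SW", "W", "NW"))

  code <- function(x, levels, what) {
    known <- is.na(x) | x %in% names(levels)
    if (!all(known)) {
      abort(
        paste0("unknown ", what, " level: ", paste(unique(x[!known]), collapse = ", ")),
        class = "bloomscale_error_encoding"
      )
    }
    unname(levels[x])
  }

  dbh <- trees$dbh_cm[match(branches$tree_id, trees$tree_id)]
  if (anyNA(dbh)) {
    abort("branch refers to a tree absent from the tree table",
      class = "bloomscale_error_reference"
    )
  }
  tree_codes <- as.numeric(factor(branches$tree_id, levels = sort(unique(trees$tree_id))))

  raw <- cbind(
    diameter = if (log_diameter) log(branches$cutoff_diameter_mm) else branches$cutoff_diameter_mm,
    layer = code(branches$layer, layer_levels, "layer"),
    stratum = code(branches$stratum, stratum_levels, "stratum"),
    compass = if ("compass" %in% names(branches)) {
      code(branches$compass, compass_levels, "compass")
    } else {
      rep(NA_real_, nrow(branches))
    },
    tree = tree_codes,
    dbh = dbh
  )
  center <- colMeans(raw, na.rm = TRUE)
  center[is.nan(center)] <- 0
  spread <- apply(raw, 2, sd, na.rm = TRUE)
  spread[is.na(spread)] <- 0
  scaled <- sweep(raw, 2, center, "-")
  scaled <- sweep(scaled, 2, ifelse(spread > 0, spread, 1), "/")
  scaled[, spread == 0] <- 0
  scaled[is.na(scaled)] <- 0

  out <- tibble::tibble(branch_id = branches$branch_id) |>
    dplyr::bind_cols(tibble::as_tibble(scaled))
  attr(out, "encoding") <- list(
    stratum = stratum_levels, layer = layer_levels,
    compass = compass_levels, log_diameter = log_diameter
  )
  attr(out, "scaling") <- list(center = center, spread = spread)
  out
}

# indices of all ancestors (resp. descendants) of each branch
.relatives <- function(branches) {
  n <- nrow(branches)
  parent_idx <- match(branches$parent_branch_id, branches$branch_id)
  ancestors <- vector("list", n)
  for (i in seq_len(n)) {
    anc <- integer(0)
    j <- parent_idx[i]
    while (!is.na(j)) {
      anc <- c(anc, j)
      j <- parent_idx[j]
    }
    ancestors[[i]] <- anc
  }
  descendants <- vector("list", n)
  for (i in seq_len(n)) {
    for (a in ancestors[[i]]) descendants[[a]] <- c(descendants[[a]], i)
  }
  list(ancestors = ancestors, descendants = descendants)
}

#' Farthest-distance subsampling of a branch hierarchy
#'
#' Selects a balanced subset of branches for model fitting while breaking the
#' statistical dependence between a branch and its own subbranches. Branches
#' are points in the scaled six-dimensional sampling space of
#' [scale_branch_coordinates()]. Selection starts with the branch of largest
#' cut-off diameter; each further pick is the candidate farthest from the
#' already-selected set (maximum over candidates of the minimum Euclidean
#' distance to any selected point). Whenever a branch is selected, all of its
#' ancestors and descendants leave the candidate pool, so the final set never
#' contains an ancestor-descendant pair. Selection stops when the pool is
#' empty. Ties in diameter or distance are broken by the lexicographically
#' smallest `branch_id`, which makes the procedure deterministic and
#' independent of row order.
#'
#' @inheritParams scale_branch_coordinates
#' @return A tibble with one row per selected branch: `branch_id`,
#'   `selection_order` and `min_dist`, the distance to the selected set at the
#'   moment of selection (`NA` for the seed).
#' @export
farthest_distance_sample <- function(branches, trees, log_diameter = TRUE) {
  if (nrow(branches) == 0) {
    abort("cannot subsample an empty branch table",
      class = "bloomscale_error_empty_selection"
    )
  }
  validate_branch_table(branches)
  coords <- scale_branch_coordinates(branches, trees, log_diameter)
  xm <- as.matrix(coords[, -1])
  rel <- .relatives(branches)
  ids <- branches$branch_id

  in_pool <- rep(TRUE, nrow(branches))
  min_dist <- rep(Inf, nrow(branches))
  selected <- integer(0)
  dist_at_selection <- numeric(0)

  pick_seed <- function() {
    cand <- which(in_pool & branches$cutoff_diameter_mm == max(branches$cutoff_diameter_mm[in_pool]))
    cand[order(ids[cand])][1]
  }

  s <- pick_seed()
  first <- TRUE
  repeat {
    selected <- c(selected, s)
    dist_at_selection <- c(dist_at_selection, if (first) NA_real_ else min_dist[s])
    in_pool[c(s, rel$ancestors[[s]], rel$descendants[[s]])] <- FALSE
    if (!any(in_pool)) break
    d_new <- sqrt(colSums((t(xm) - xm[s, ])^2))
    min_dist <- pmin(min_dist, d_new)
    pool <- which(in_pool)
    best <- pool[min_dist[pool] == max(min_dist[pool])]
    s <- best[order(ids[best])][1]
    first <- FALSE
  }

  out <- tibble::tibble(
    branch_id = ids[selected],
    selection_order = seq_along(selected),
    min_dist = dist_at_selection
  )
  attr(out, "encoding") <- attr(coords, "encoding")
  attr(out, "scaling") <- attr(coords, "scaling")
  out
}

#' @rdname farthest_distance_sample
#' @details `subsample_branches()` is a convenience wrapper returning the
#'   branch table filtered to the selected rows.
#' @export
subsample_branches <- function(branches, trees, log_diameter = TRUE) {
  sel <- farthest_distance_sample(branches, trees, log_diameter)
  dplyr::semi_join(branches, sel, by = "branch_id")
}
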