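# 2D convex-polygon helpers for crown cross sections.
# Hulls are stored as (n x 2) matrices of vertices in counter-clockwise order.

.hull_xy <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) {
    return(NULL)
  }
  idx <- grDevices::chull(pts[, 1], pts[, 2]) # clockwise
  hull <- pts[rev(idx), , drop = FALSE] # counter-clockwise
  if (nrow(hull) < 3 || .polygon_area(hull) <= 0) {
    return(NULL) # collinear
  }
  hull
}

# shoelace; positive for counter-clockwise vertex order
.polygon_area <- function(xy) {
  x <- xy[, 1]
  y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

# signed distance of a point to a convex CCW polygon boundary:
# positive inside, negative outside, equal to the inradius-style minimum
# over the supporting lines of all edges (valid because the polygon is convex)
.signed_depth <- function(px, py, hull) {
  n <- nrow(hull)
  j <- c(2:n, 1)
  ex <- hull[j, 1] - hull[, 1]
  ey <- hull[j, 2] - hull[, 2]
  len <- sqrt(ex^2 + ey^2)
  # inward normal of a CCW edge is (-ey, ex) / len
  d <- (-ey * (px - hull[, 1]) + ex * (py - hull[, 2])) / len
  min(d)
}

# extent of hull points along 8 azimuthal directions, averaged ("spread")
# or the maximum pairwise distance ("max")
.hull_diameter <- function(pts, method = c("spread", "max")) {
  method <- match.arg(method)
  if (method == "max") {
    return(max(stats::dist(pts)))
  }
  angles <- (0:7) * pi / 8
  mean(vapply(angles, function(a) {
    proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(proj) - min(proj)
  }, numeric(1)))
}
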