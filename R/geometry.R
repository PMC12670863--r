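# Low-level planar geometry on contour polygons.
#
# Contours are n x 2 matrices of continuous pixel coordinates, columns
# (col, row), 0-based, implicitly closed.  A "region" is a list of such
# polygons interpreted with even-odd filling, which represents fragmented
# segmentations as well as rings with holes (output of region_minus()).
# Physical areas follow from area_pixels * spacing_row * spacing_col; all
# boolean operations are performed in pixel coordinates since area ratios
# (Dice) are invariant under the anisotropic scaling.

#' Signed shoelace area of a single polygon
#'
#' @param poly An n x 2 numeric matrix of (col, row) vertices, implicitly
#'   closed. Positive for counterclockwise orientation in the (col, row)
#'   plane.
#' @return Signed area in squared pixel units.
#' @keywords internal
shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (n < 3) return(0)
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  0.5 * sum(x * ys - xs * y)
}

#' Test whether a polygon is self-intersecting
#'
#' Checks all non-adjacent edge pairs of the implicitly closed polygon for
#' proper crossings. Shared endpoints between adjacent edges are allowed.
#'
#' @inheritParams shoelace_area
#' @return `TRUE` if any two non-adjacent edges cross.
#' @keywords internal
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  p1 <- poly
  p2 <- poly[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    j <- seq(i + 2, n)
    # edge i and the closing edge n are adjacent when i == 1
    if (i == 1) j <- j[j != n]
    if (!length(j)) next
    d1 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p1[j, 1], p1[j, 2])
    d2 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p2[j, 1], p2[j, 2])
    d3 <- cross(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], rep(p1[i, 1], length(j)), rep(p1[i, 2], length(j)))
    d4 <- cross(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], rep(p2[i, 1], length(j)), rep(p2[i, 2], length(j)))
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(TRUE)
  }
  FALSE
}

# -- region representation ----------------------------------------------------

as_region <- function(contours) {
  if (is.null(contours)) return(list())
  if (is.matrix(contours)) contours <- list(contours)
  contours[vapply(contours, function(p) nrow(p) >= 3, logical(1))]
}

region_to_paths <- function(region) {
  lapply(region, function(p) list(x = p[, 1], y = p[, 2]))
}

paths_to_region <- function(paths) {
  lapply(paths, function(p) cbind(col = p$x, row = p$y))
}

#' Area of a region in squared pixel units
#'
#' Even-odd area of a polygon list: the paths are first normalized by a
#' self-union through the clipper (making hole/outer orientations
#' consistent regardless of how the input was wound), then signed
#' shoelace areas are summed. Correct for ring regions returned by
#' [region_minus()] and for disjoint fragment lists alike.
#'
#' @param region List of polygon matrices (even-odd region).
#' @return Non-negative area in pixel^2.
#' @keywords internal
region_area_px <- function(region) {
  region <- as_region(region)
  if (!length(region)) return(0)
  norm <- polyclip::polyclip(region_to_paths(region), region_to_paths(region),
                             op = "union", fillA = "evenodd", fillB = "evenodd")
  abs(sum(vapply(norm, function(p) {
    shoelace_area(cbind(p$x, p$y))
  }, numeric(1))))
}

# even-odd region area in mm^2
region_area_mm2 <- function(region, geom) {
  region_area_px(region) * geom$spacing_row * geom$spacing_col
}

region_op <- function(a, b, op) {
  a <- as_region(a); b <- as_region(b)
  if (op == "intersection" && (!length(a) || !length(b))) return(list())
  if (op == "minus" && !length(a)) return(list())
  if (op == "minus" && !length(b)) return(a)
  if (op == "union" && !length(a)) return(b)
  if (op == "union" && !length(b)) return(a)
  out <- polyclip::polyclip(region_to_paths(a), region_to_paths(b), op = op,
                            fillA = "evenodd", fillB = "evenodd")
  paths_to_region(out)
}

region_intersect <- function(a, b) region_op(a, b, "intersection")
region_minus <- function(a, b) region_op(a, b, "minus")
region_union <- function(a, b) region_op(a, b, "union")

#' Even-odd point-in-region membership test
#'
#' Vectorised ray casting: a point is inside when a horizontal ray crosses
#' the union of polygon edges an odd number of times. Points exactly on an
#' edge are resolved by the strict/non-strict comparison and are not
#' guaranteed either way (voxel centers on contour lines are measure-zero
#' for the phantoms used here).
#'
#' @param pts m x 2 matrix of (col, row) query points.
#' @param region List of polygon matrices.
#' @return Logical vector of length m.
#' @keywords internal
point_in_region <- function(pts, region) {
  region <- as_region(region)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  inside <- rep(FALSE, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  for (poly in region) {
    x <- poly[, 1]; y <- poly[, 2]
    n <- length(x)
    xj <- c(x[n], x[-n]); yj <- c(y[n], y[-n])
    for (k in seq_len(n)) {
      sel <- ((y[k] > py) != (yj[k] > py))
      if (any(sel)) {
        xint <- x[k] + (py[sel] - y[k]) * (xj[k] - x[k]) / (yj[k] - y[k])
        flip <- rep(FALSE, length(py))
        flip[sel] <- px[sel] < xint
        inside <- xor(inside, flip)
      }
    }
  }
  inside
}

# -- polyline machinery for Hausdorff distances -------------------------------

# Resample the closed polyline so no segment exceeds max_len (same units as
# the coordinates). Returns the augmented vertex matrix.
densify_closed <- function(poly, max_len = 0.1) {
  p2 <- rbind(poly, poly[1, , drop = FALSE])
  seg <- diff(p2)
  len <- sqrt(rowSums(seg^2))
  out <- vector("list", nrow(poly))
  for (i in seq_len(nrow(poly))) {
    k <- max(1L, ceiling(len[i] / max_len))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    out[[i]] <- cbind(p2[i, 1] + t * seg[i, 1], p2[i, 2] + t * seg[i, 2])
  }
  do.call(rbind, out)
}

# Minimum distance from each point in pts (m x 2) to a set of closed
# polylines given as a list of vertex matrices. Exact point-to-segment;
# loops over segments (few) keeping a running minimum over points (many).
dist_points_to_polylines <- function(pts, polys) {
  px <- pts[, 1]; py <- pts[, 2]
  best <- rep(Inf, length(px))
  for (poly in polys) {
    n <- nrow(poly)
    ax <- poly[, 1]; ay <- poly[, 2]
    bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
    dx <- bx - ax; dy <- by - ay
    L2 <- pmax(dx^2 + dy^2, 1e-300)
    for (k in seq_len(n)) {
      tt <- ((px - ax[k]) * dx[k] + (py - ay[k]) * dy[k]) / L2[k]
      tt[tt < 0] <- 0; tt[tt > 1] <- 1
      ex <- px - (ax[k] + tt * dx[k]); ey <- py - (ay[k] + tt * dy[k])
      best <- pmin(best, ex * ex + ey * ey)
    }
  }
  sqrt(best)
}

#' Symmetric Hausdorff distance between two contour boundary sets
#'
#' Works on boundaries (polylines), not filled regions. Coordinates are
#' first scaled to millimetres with the anisotropic pixel spacing; the
#' supremum over each boundary is approximated by densifying it to
#' segments no longer than `max_len` mm (the distance function is
#' 1-Lipschitz, bounding the error by `max_len`/2).
#'
#' @param ca,cb Lists of polygon matrices (pixel coordinates).
#' @param spacing Numeric length-2: (spacing_col, spacing_row) mm/pixel.
#' @param max_len Densification step in mm.
#' @return Hausdorff distance in mm.
#' @keywords internal
hausdorff_mm_regions <- function(ca, cb, spacing, max_len = 0.1) {
  scale_poly <- function(p) cbind(p[, 1] * spacing[1], p[, 2] * spacing[2])
  a <- lapply(as_region(ca), scale_poly)
  b <- lapply(as_region(cb), scale_poly)
  if (!length(a) || !length(b)) return(NA_real_)
  pa <- do.call(rbind, lapply(a, densify_closed, max_len = max_len))
  pb <- do.call(rbind, lapply(b, densify_closed, max_len = max_len))
  max(max(dist_points_to_polylines(pa, b)), max(dist_points_to_polylines(pb, a)))
}

# Maximum caliper diameter (max pairwise vertex distance) of a region, in
# the units of the scaled coordinates. The maximum over a polygon is always
# attained at vertices.
max_caliper <- function(region, spacing = c(1, 1)) {
  region <- as_region(region)
  if (!length(region)) return(NA_real_)
  pts <- do.call(rbind, region)
  pts <- cbind(pts[, 1] * spacing[1], pts[, 2] * spacing[2])
  # convex hull first keeps the O(n^2) pass small
  h <- grDevices::chull(pts)
  pts <- pts[h, , drop = FALSE]
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2))
}

# Area centroid of a polygon (pixel coordinates).
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xs) * cr) / (6 * a), sum((y + ys) * cr) / (6 * a))
}

# Regular k-gon approximation of a circle, counterclockwise.
circle_polygon <- function(center, radius, n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(col = center[1] + radius * cos(th), row = center[2] + radius * sin(th))
}
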