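# Fixture builders and independent oracles used across the suite.

# unit geometry: 1 mm isotropic pixels, 8 mm slices + 2 mm gap (D = 10)
geom_unit <- function(thickness = 8, gap = 2, sr = 1, sc = 1) {
  cmr_geometry(sr, sc, thickness, gap)
}

square_poly <- function(x0 = 0, y0 = 0, side = 10) {
  cbind(col = c(x0, x0 + side, x0 + side, x0),
        row = c(y0, y0, y0 + side, y0 + side))
}

circle_poly <- function(cx, cy, r, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(col = cx + r * cos(th), row = cy + r * sin(th))
}

# a single-ctype short-axis case: one contour type, given per-slice radii
radii_case <- function(radii, phase = "ED", ctype = "lv_endo",
                       geom = geom_unit(), case_id = "c1", reader = "R1",
                       sequence = "sax_cine", n = 180) {
  slices <- lapply(seq_along(radii), function(i) {
    cont <- list()
    cont[[ctype]] <- list(circle_poly(60, 60, radii[i], n))
    cmr_slice(i - 1L, phase, cont)
  })
  cmr_case(case_id, reader, sequence, geom, slices)
}

# independent point-in-polygon oracle: winding number via complex
# arguments (a different formulation and code path than the package's
# crossing-count implementation)
pip_winding <- function(pts, poly) {
  z <- complex(real = poly[, 1], imaginary = poly[, 2])
  p <- complex(real = pts[, 1], imaginary = pts[, 2])
  n <- length(z)
  w <- numeric(length(p))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    w <- w + Arg((z[k2] - p) / (z[k] - p))
  }
  abs(w) > pi
}

# rasterized-mask Dice oracle on a grid of the given resolution
raster_dice <- function(polys1, polys2, res = 0.1) {
  pts <- rbind(do.call(rbind, polys1), do.call(rbind, polys2))
  xr <- range(pts[, 1]) + c(-1, 1); yr <- range(pts[, 2]) + c(-1, 1)
  # offset by res/3 so no grid node sits exactly on a vertex or edge
  gx <- seq(xr[1] + res / 3, xr[2], by = res)
  gy <- seq(yr[1] + res / 3, yr[2], by = res)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  member <- function(polys) {
    m <- rep(FALSE, nrow(grid))
    for (p in polys) m <- xor(m, pip_winding(grid, p))
    m
  }
  m1 <- member(polys1); m2 <- member(polys2)
  2 * sum(m1 & m2) / (sum(m1) + sum(m2))
}

# small phantom configurations used to keep simulation-based tests quick;
# the vignette documents the full-size defaults
small_params <- function(...) {
  phantom_params(n_slices = 5, n_vertices = 180, map_size = 96, ...)
}
tiny_params <- function(...) {
  phantom_params(n_slices = 4, n_vertices = 96, papmu_radius = 4, ...)
}
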