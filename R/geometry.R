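# Planar polygon utilities shared by the morphology and planform code.
# Polygons are n x 2 matrices (or data frames) of vertices in order, open
# (first vertex not repeated); orientation may be either sense.

as_polygon_matrix <- function(boundary) {
  xy <- as.matrix(boundary)
  if (!is.numeric(xy) || ncol(xy) != 2) {
    stop("polygon boundary must be an n x 2 numeric matrix or data frame", call. = FALSE)
  }
  # drop a repeated closing vertex
  n <- nrow(xy)
  if (n >= 2 && all(abs(xy[1, ] - xy[n, ]) < 1e-12)) xy <- xy[-n, , drop = FALSE]
  if (nrow(xy) < 3) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  unname(xy)
}

polygon_area <- function(boundary) {
  xy <- as_polygon_matrix(boundary)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Exact area moments of a simple polygon about the origin via Green's
# theorem: area, centroid, and the second moments Ixx = int y^2 dA,
# Iyy = int x^2 dA, Ixy = int xy dA.
polygon_moments <- function(boundary) {
  xy <- as_polygon_matrix(boundary)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a_signed <- sum(cr) / 2
  if (abs(a_signed) < .Machine$double.eps) {
    stop("degenerate polygon: area is zero", call. = FALSE)
  }
  s <- sign(a_signed)
  cx <- sum((x + xn) * cr) / (6 * a_signed)
  cy <- sum((y + yn) * cr) / (6 * a_signed)
  iyy <- s * sum((x^2 + x * xn + xn^2) * cr) / 12
  ixx <- s * sum((y^2 + y * yn + yn^2) * cr) / 12
  ixy <- s * sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(area = abs(a_signed), cx = cx, cy = cy, ixx = ixx, iyy = iyy, ixy = ixy)
}

points_in_polygon <- function(px, py, boundary) {
  xy <- as_polygon_matrix(boundary)
  pracma::inpolygon(px, py, xy[, 1], xy[, 2], boundary = TRUE)
}

# Proper-crossing test for two closed segments p1-p2 and p3-p4.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# Returns NULL when simple, else the indices (i, j) of the first pair of
# non-adjacent edges that intersect.
polygon_self_intersection <- function(boundary) {
  xy <- as_polygon_matrix(boundary)
  n <- nrow(xy)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    if (i + 2 > jmax) next
    for (j in seq.int(i + 2, jmax)) {
      if (segments_cross(xy[i, ], xy[nxt[i], ], xy[j, ], xy[nxt[j], ])) {
        return(c(i, j))
      }
    }
  }
  NULL
}
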