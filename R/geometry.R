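# Planar polygon primitives used by the zoning engine.
#
# A polygon is a list with an `outer` ring (n x 2 matrix, open: the last
# vertex is not repeated) and an optional list of `holes` rings. Rings are
# in micrometers. Zone construction works on the *signed distance* to the
# union of the (hole-filled) outer rings: negative inside, positive
# outside. Offset contours (outward buffer / inward erosion) are traced by
# radial bisection of that signed distance, one contour per tumor-field
# component; areas come from the shoelace formula on the traced contours.

#' Construct a polygon (outer ring plus optional holes)
#'
#' @param outer numeric matrix (n x 2) of vertices in um; the closing edge
#'   is implicit (do not repeat the first vertex).
#' @param holes list of hole rings in the same format.
#' @return an object of class `tt_polygon`.
#' @export
tt_polygon <- function(outer, holes = list()) {
  outer <- as_ring(outer)
  holes <- lapply(holes, as_ring)
  structure(list(outer = outer, holes = holes), class = "tt_polygon")
}

# normalise a ring matrix: drop a repeated closing vertex, check shape
as_ring <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("ring must be an n x 2 matrix")
  n <- nrow(m)
  if (n >= 2L && all(m[1L, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3L) stop("ring needs at least 3 distinct vertices")
  if (!all(is.finite(m))) stop("ring coordinates must be finite")
  dimnames(m) <- NULL
  m
}

# signed shoelace area of a ring (positive for counter-clockwise)
ring_area_signed <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Area of a polygon ring (shoelace formula)
#' @param ring n x 2 vertex matrix (open ring).
#' @return area in um^2.
#' @export
ring_area <- function(ring) abs(ring_area_signed(ring))

ring_centroid <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' @export
print.tt_polygon <- function(x, ...) {
  a <- ring_area(x$outer) - sum(vapply(x$holes, ring_area, 0))
  cat(sprintf("<tt_polygon> %d outer vertices, %d hole(s), area %.4f mm^2\n",
              nrow(x$outer), length(x$holes), a / 1e6))
  invisible(x)
}

#' Area of a polygon with holes
#' @param poly a [tt_polygon()].
#' @return area in um^2 (outer ring minus holes).
#' @export
polygon_area <- function(poly) {
  ring_area(poly$outer) - sum(vapply(poly$holes, ring_area, 0))
}

# even-odd point-in-ring test, vectorised over points
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# min distance from points to the boundary of a ring, vectorised over points
dist_to_ring <- function(px, py, ring) {
  n <- nrow(ring)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- ring[j, 1L]; ay <- ring[j, 2L]
    bx <- ring[i, 1L]; by <- ring[i, 2L]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    if (L2 == 0) {
      dx <- px - ax; dy <- py - ay
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
      dx <- px - (ax + t * vx)
      dy <- py - (ay + t * vy)
    }
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

# Signed distance from points to the union of hole-filled field polygons:
# negative inside any outer ring, positive outside all of them.
signed_distance <- function(px, py, fields) {
  d <- rep(Inf, length(px))
  inside <- logical(length(px))
  for (f in fields) {
    d <- pmin(d, dist_to_ring(px, py, f$outer))
    inside <- inside | point_in_ring(px, py, f$outer)
  }
  ifelse(inside, -d, d)
}

# membership in the (unfilled) tumor fields: inside an outer ring and not
# inside one of its holes; boundary-inclusive within `eps` (eps = 0 skips
# the boundary-distance checks, fine for measure-zero sampling use)
point_in_fields <- function(px, py, fields, eps = 1e-9) {
  res <- logical(length(px))
  for (f in fields) {
    inn <- point_in_ring(px, py, f$outer)
    if (eps > 0) inn <- inn | (dist_to_ring(px, py, f$outer) <= eps)
    if (length(f$holes)) {
      for (h in f$holes) {
        in_h <- point_in_ring(px, py, h)
        if (eps > 0) in_h <- in_h & (dist_to_ring(px, py, h) > eps)
        inn <- inn & !in_h
      }
    }
    res <- res | inn
  }
  res
}

# O(n^2) simplicity test: no two non-adjacent edges intersect
ring_is_simple <- function(ring) {
  n <- nrow(ring)
  a <- ring
  b <- ring[c(2:n, 1L), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1x <- p2[1L] - p1[1L]; d1y <- p2[2L] - p1[2L]
    d2x <- p4[1L] - p3[1L]; d2y <- p4[2L] - p3[2L]
    den <- d1x * d2y - d1y * d2x
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((p3[1L] - p1[1L]) * d2y - (p3[2L] - p1[2L]) * d2x) / den
    u <- ((p3[1L] - p1[1L]) * d1y - (p3[2L] - p1[2L]) * d1x) / den
    t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) break
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Trace the contour {signed_distance = level} around one field component by
# radial bisection from the component centroid. Returns NULL when the level
# set does not contain the centroid (e.g. erosion swallows the component).
trace_level_ring <- function(fields, center, level, n_angles = 192L,
                             n_scan = 72L, tol = 1e-6) {
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  ux <- cos(theta); uy <- sin(theta)
  # generous radial extent: farthest field vertex from center + offset
  tmax <- 0
  for (f in fields) {
    tmax <- max(tmax, sqrt(max((f$outer[, 1L] - center[1L])^2 +
                               (f$outer[, 2L] - center[2L])^2)))
  }
  tmax <- tmax + max(level, 0) + 10
  g0 <- signed_distance(center[1L], center[2L], fields) - level
  if (g0 > 0) return(NULL)
  ts <- seq(0, tmax, length.out = n_scan)
  G <- matrix(NA_real_, n_angles, n_scan)
  for (k in seq_len(n_scan)) {
    G[, k] <- signed_distance(center[1L] + ts[k] * ux,
                              center[2L] + ts[k] * uy, fields) - level
  }
  # outermost crossing from <=0 to >0 along each ray
  lo <- hi <- numeric(n_angles)
  for (i in seq_len(n_angles)) {
    neg <- which(G[i, ] <= 0)
    k <- max(neg)
    if (k == n_scan) stop("level contour escapes scan window")
    lo[i] <- ts[k]; hi[i] <- ts[k + 1L]
  }
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    gm <- signed_distance(center[1L] + mid * ux,
                          center[2L] + mid * uy, fields) - level
    neg <- gm <= 0
    lo[neg] <- mid[neg]
    hi[!neg] <- mid[!neg]
  }
  r <- (lo + hi) / 2
  cbind(center[1L] + r * ux, center[2L] + r * uy)
}

# do bounding boxes of two rings overlap (with margin)?
bbox_overlap <- function(r1, r2, margin = 0) {
  !(max(r1[, 1L]) + margin < min(r2[, 1L]) ||
    max(r2[, 1L]) + margin < min(r1[, 1L]) ||
    max(r1[, 2L]) + margin < min(r2[, 2L]) ||
    max(r2[, 2L]) + margin < min(r1[, 2L]))
}

# grid quadrature of the area where `member(px, py)` is TRUE over a bbox
grid_area <- function(member, xlim, ylim, n = 300L) {
  hx <- diff(xlim) / n; hy <- diff(ylim) / n
  if (hx <= 0 || hy <= 0) return(0)
  gx <- xlim[1L] + (seq_len(n) - 0.5) * hx
  gy <- ylim[1L] + (seq_len(n) - 0.5) * hy
  px <- rep(gx, times = n)
  py <- rep(gy, each = n)
  sum(member(px, py)) * hx * hy
}

# area of the intersection of two traced component regions (both defined as
# signed_distance(fields_i) <= level); used when dilations of two field
# components overlap
component_overlap_area <- function(ring1, ring2) {
  xlim <- c(max(min(ring1[, 1L]), min(ring2[, 1L])),
            min(max(ring1[, 1L]), max(ring2[, 1L])))
  ylim <- c(max(min(ring1[, 2L]), min(ring2[, 2L])),
            min(max(ring1[, 2L]), max(ring2[, 2L])))
  if (diff(xlim) <= 0 || diff(ylim) <= 0) return(0)
  grid_area(function(px, py) {
    point_in_ring(px, py, ring1) & point_in_ring(px, py, ring2)
  }, xlim, ylim, n = 250L)
}
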