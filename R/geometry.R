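# Convex-polygon primitives used for genet footprints and patch outlines.
# Polygons are n x 2 matrices of vertices, not closed (first vertex not
# repeated), oriented counter-clockwise.  All genet footprints (convex
# hulls, discs, stadiums) are convex, so intersections of any number of
# them remain convex and Sutherland-Hodgman clipping is exact.

# Signed area (positive for counter-clockwise orientation).
shoelace_signed <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Area of a simple polygon
#'
#' Planar (shoelace) area of a polygon given as an `n x 2` vertex matrix
#' (not closed).
#'
#' @param p Numeric matrix of vertices.
#' @return Non-negative area.
#' @export
polygon_area <- function(p) abs(shoelace_signed(p))

ensure_ccw <- function(p) {
  if (shoelace_signed(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

# Convex hull as a CCW polygon matrix (NULL if fewer than 3 distinct,
# non-collinear points).
convex_hull_poly <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3L) return(NULL)
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  poly <- pts[h, , drop = FALSE]
  if (nrow(poly) < 3L || polygon_area(poly) == 0) return(NULL)
  ensure_ccw(unname(poly))
}

# Sutherland-Hodgman: clip polygon `subject` by convex CCW polygon `clip`.
# Returns the (convex) intersection, or NULL when empty.
convex_clip <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    a <- clip[e, ]
    b <- clip[if (e == nc) 1L else e + 1L, ]
    ex <- b[1L] - a[1L]; ey <- b[2L] - a[2L]
    # signed distance-like quantity: > 0 means inside (left of a->b)
    s <- ex * (out[, 2L] - a[2L]) - ey * (out[, 1L] - a[1L])
    n <- nrow(out)
    keep_in <- s >= 0
    res <- matrix(numeric(0), ncol = 2L)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      p1 <- out[k, ]; p2 <- out[k2, ]
      in1 <- keep_in[k]; in2 <- keep_in[k2]
      if (in1) res <- rbind(res, p1)
      if (xor(in1, in2)) {
        t <- s[k] / (s[k] - s[k2])
        res <- rbind(res, p1 + t * (p2 - p1))
      }
    }
    out <- res
  }
  if (is.null(out) || nrow(out) < 3L || polygon_area(out) < 1e-12) return(NULL)
  out
}

# Regular polygon approximating a disc; `r` is the vertex radius.
disc_poly <- function(cx, cy, r, n_segments = 64L) {
  th <- seq(0, 2 * pi, length.out = n_segments + 1L)[-(n_segments + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Area factor of the discretized disc: polygon area = disc_factor * r^2.
disc_factor <- function(n_segments) 0.5 * n_segments * sin(2 * pi / n_segments)

# Disc polygon whose *polygon* area equals `target` exactly.
disc_with_area <- function(cx, cy, target, n_segments = 64L) {
  r <- sqrt(target / disc_factor(n_segments))
  disc_poly(cx, cy, r, n_segments)
}

# Stadium (segment buffer) polygon around p1--p2 with half-width w:
# rectangle of length d plus two polygonal semicircles of k segments each.
stadium_poly <- function(p1, p2, w, n_segments = 64L) {
  k <- max(4L, n_segments %/% 2L)
  d <- sqrt(sum((p2 - p1)^2))
  th0 <- atan2(p2[2L] - p1[2L], p2[1L] - p1[1L])
  arc <- function(center, from, to) {
    th <- seq(from, to, length.out = k + 1L)
    cbind(center[1L] + w * cos(th), center[2L] + w * sin(th))
  }
  a1 <- arc(p2, th0 - pi / 2, th0 + pi / 2)   # cap around p2
  a2 <- arc(p1, th0 + pi / 2, th0 + 3 * pi / 2) # cap around p1
  ensure_ccw(rbind(a1, a2))
}

# Half-width such that the *discretized* stadium area equals `target`:
# c w^2 + 2 d w = target with c = k sin(pi/k), k caps segments.
stadium_halfwidth <- function(d, target, n_segments = 64L) {
  k <- max(4L, n_segments %/% 2L)
  cc <- k * sin(pi / k)
  (-d + sqrt(d^2 + cc * target)) / cc
}

# Minkowski-style outward buffer of a convex polygon by `margin`:
# convex hull of discs placed on every vertex.
convex_buffer <- function(poly, margin, n_segments = 32L) {
  pts <- do.call(rbind, lapply(seq_len(nrow(poly)), function(i) {
    disc_poly(poly[i, 1L], poly[i, 2L], margin, n_segments)
  }))
  convex_hull_poly(pts[, 1L], pts[, 2L])
}

# Does a simple-polygon check: no two non-adjacent edges intersect.
is_simple_polygon <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  seg <- function(i) rbind(p[i, ], p[if (i == n) 1L else i + 1L, ])
  inter <- function(s1, s2) {
    d1 <- s1[2, ] - s1[1, ]; d2 <- s2[2, ] - s2[1, ]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((s2[1, 1] - s1[1, 1]) * d2[2] - (s2[1, 2] - s1[1, 2]) * d2[1]) / den
    u <- ((s2[1, 1] - s1[1, 1]) * d1[2] - (s2[1, 2] - s1[1, 2]) * d1[1]) / den
    t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      adjacent <- j == i + 1L || (i == 1L && j == n)
      if (!adjacent && inter(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

bbox <- function(p) c(min(p[, 1L]), min(p[, 2L]), max(p[, 1L]), max(p[, 2L]))

bbox_disjoint <- function(b1, b2) {
  b1[3L] < b2[1L] || b2[3L] < b1[1L] || b1[4L] < b2[2L] || b2[4L] < b1[2L]
}

# Inclusion-exclusion overlay of convex polygons: sums of k-wise
# intersection areas S_k until intersections vanish.  Returns the union
# area, the area covered by >= 2 polygons, the maximum multiplicity, and
# the positive pairwise intersection areas.
convex_overlay <- function(polys) {
  m <- length(polys)
  areas <- vapply(polys, polygon_area, numeric(1))
  boxes <- lapply(polys, bbox)
  s <- sum(areas)
  s_k <- c(s)
  pair_i <- integer(0); pair_j <- integer(0); pair_a <- numeric(0)
  # frontier entries: list(last = max index, poly, box)
  frontier <- lapply(seq_len(m), function(i) list(last = i, poly = polys[[i]], box = boxes[[i]]))
  depth <- 1L
  while (length(frontier) > 0 && depth < m) {
    nxt <- list()
    total <- 0
    for (entry in frontier) {
      i0 <- entry$last
      if (i0 >= m) next
      for (jj in seq(i0 + 1L, m)) {
        if (bbox_disjoint(entry$box, boxes[[jj]])) next
        q <- convex_clip(entry$poly, polys[[jj]])
        if (is.null(q)) next
        a <- polygon_area(q)
        total <- total + a
        nxt[[length(nxt) + 1L]] <- list(last = jj, poly = q, box = bbox(q))
        if (depth == 1L) {
          pair_i <- c(pair_i, i0); pair_j <- c(pair_j, jj); pair_a <- c(pair_a, a)
        }
      }
    }
    frontier <- nxt
    depth <- depth + 1L
    if (length(nxt) > 0) s_k <- c(s_k, total)
  }
  k <- seq_along(s_k)
  union_area <- sum((-1)^(k - 1) * s_k)
  area_ge2 <- if (length(s_k) >= 2L) sum((-1)^(k) * (k - 1) * s_k) else 0
  list(
    s_k = s_k,
    union_area = union_area,
    area_ge2 = max(0, area_ge2),
    max_multiplicity = length(s_k),
    pairs = tibble::tibble(i = pair_i, j = pair_j, area = pair_a)
  )
}
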