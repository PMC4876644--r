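# Plane-geometry helpers shared by the point-pattern and laminar modules.
# Polygons are k x 2 matrices (x, y), vertices in order, not necessarily
# closed; all routines close them implicitly.

.polyArea <- function(v) {
  v <- as.matrix(v)
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

.polyClose <- function(v) {
  if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v else rbind(v, v[1, ])
}

.pointsInPolygon <- function(pts, poly, boundaryTolUm = 0) {
  pts <- as.matrix(pts)
  if (nrow(pts) == 0L) return(logical(0))
  inside <- mgcv::in.out(.polyClose(as.matrix(poly)), pts)
  if (boundaryTolUm > 0 && !all(inside)) {
    # accept points within tolerance of the boundary (generator edge hits)
    idx <- which(!inside)
    d <- vapply(idx, function(i) .distToPolygon(pts[i, ], poly), numeric(1))
    inside[idx[d <= boundaryTolUm]] <- TRUE
  }
  inside
}

.distToPolygon <- function(p, poly) {
  poly <- .polyClose(as.matrix(poly))
  dmin <- Inf
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), .Machine$double.eps)
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    dmin <- min(dmin, sqrt(sum((p - q)^2)))
  }
  dmin
}

.segIntersects <- function(a, b, c, d) {
  # proper intersection of open segments ab and cd
  orient <- function(p, q, r) {
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  }
  o1 <- orient(a, b, c); o2 <- orient(a, b, d)
  o3 <- orient(c, d, a); o4 <- orient(c, d, b)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}

.polyIsSimple <- function(v) {
  v <- as.matrix(v)
  k <- nrow(v)
  if (k < 3L) return(FALSE)
  idx <- function(i) ((i - 1L) %% k) + 1L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i + 1L || (i == 1L && j == k)) next
      if (.segIntersects(v[i, ], v[idx(i + 1L), ], v[j, ], v[idx(j + 1L), ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Sutherland-Hodgman clip of a simple polygon against the half-plane
# (v - p0) . nrm <= 0; returns a (possibly empty) vertex matrix.
.clipHalfplane <- function(poly, p0, nrm) {
  poly <- as.matrix(poly)
  k <- nrow(poly)
  d <- as.numeric((poly - matrix(p0, k, 2, byrow = TRUE)) %*% nrm)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    if (d[i] <= 0) out <- rbind(out, poly[i, ])
    if ((d[i] < 0) != (d[j] < 0) && d[i] != d[j]) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Clip polygon to the slab a <= (v . axis) <= b.
.clipSlab <- function(poly, axis, a, b) {
  axis <- as.numeric(axis)
  p <- .clipHalfplane(poly, a * axis, -axis)   # keep v.axis >= a
  if (nrow(p) < 3L) return(p)
  .clipHalfplane(p, b * axis, axis)            # keep v.axis <= b
}

.projectOnAxis <- function(pts, axis) {
  as.numeric(as.matrix(pts) %*% as.numeric(axis))
}

# First intersection of ray P + u*D (u > tol) with a polyline; NA if none.
.rayPolylineU <- function(P, D, polyline, tol = 1e-9) {
  best <- NA_real_
  for (i in seq_len(nrow(polyline) - 1L)) {
    A <- polyline[i, ]; B <- polyline[i + 1L, ]
    M <- cbind(D, A - B)
    det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    if (abs(det) < 1e-12) next
    rhs <- A - P
    u <- (rhs[1] * M[2, 2] - rhs[2] * M[1, 2]) / det
    s <- (M[1, 1] * rhs[2] - M[2, 1] * rhs[1]) / det
    if (u > tol && s >= -1e-9 && s <= 1 + 1e-9) {
      if (is.na(best) || u < best) best <- u
    }
  }
  best
}

# Point and unit tangent at arc-length fraction f along a polyline.
.polylinePointTangent <- function(polyline, f) {
  seg <- diff(polyline)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  target <- f * cum[length(cum)]
  i <- max(1L, min(findInterval(target, cum, all.inside = TRUE),
                   nrow(polyline) - 1L))
  t <- (target - cum[i]) / max(len[i], .Machine$double.eps)
  list(point = polyline[i, ] + t * seg[i, ],
       tangent = seg[i, ] / max(len[i], .Machine$double.eps))
}
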