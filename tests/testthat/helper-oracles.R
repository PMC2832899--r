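# Independent oracles and small fixture builders used across the suite.
# Every oracle here is deliberately naive (winding numbers, half-space
# checks, direct kernel sums) and shares no code with the implementation
# paths it checks.

# Winding-number point-in-polygon oracle (one point at a time).
winding_inside <- function(pt, ring) {
  n <- nrow(ring) - 1
  ang <- 0
  for (i in seq_len(n)) {
    a <- ring[i, ] - pt
    b <- ring[i + 1, ] - pt
    ang <- ang + atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
  }
  abs(ang) > pi
}

# Half-space oracle for convex meshes: inside iff on the inner side of every
# face plane (outward normals).
halfspace_inside <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ok <- rep(TRUE, nrow(points))
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; cc <- v[f[k, 3], ]
    nrm <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
             (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
             (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    ok <- ok & (sweep(points, 2, a) %*% nrm <= 1e-9 * sqrt(sum(nrm^2)))
  }
  as.vector(ok)
}

# Exact direct-sum Gaussian KDE at arbitrary evaluation points.
direct_kde <- function(eval_pts, data, h) {
  d <- ncol(data)
  h <- rep_len(h, d)
  out <- numeric(nrow(eval_pts))
  for (i in seq_len(nrow(data))) {
    k <- rep(1, nrow(eval_pts))
    for (j in seq_len(d)) k <- k * dnorm(eval_pts[, j], data[i, j], h[j])
    out <- out + k
  }
  out / nrow(data)
}

# Random convex polygon / mesh generators.
random_convex_polygon <- function(k = 9, scale = 1, shift = c(0, 0)) {
  repeat {
    pts <- matrix(rnorm(2 * max(k, 5), sd = scale), ncol = 2)
    p <- tryCatch(convex_hull(pts), error = function(e) NULL)
    if (!is.null(p)) break
  }
  p$vertices <- sweep(p$vertices, 2, shift, "+")
  p
}

random_convex_mesh <- function(k = 30, scale = 1) {
  convex_hull(matrix(rnorm(3 * k, sd = scale), ncol = 3))
}

# Canonical unit-cube mesh (12 triangles).
unit_cube_mesh <- function() {
  convex_hull(as.matrix(expand.grid(0:1, 0:1, 0:1)))
}

regular_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  convex_hull(v)
}

# Membership of points in a list of components (union), via package code.
components_contain <- function(comps, points) {
  out <- rep(FALSE, nrow(points))
  for (cmp in comps) out <- out | curvgate:::component_contains(cmp, points)
  out
}
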