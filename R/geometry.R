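#' Construct a gate region
#'
#' A `gate_region` is a union of components in channel space: closed
#' intervals for `d = 1`, simple closed polygons (clockwise rings with first
#' vertex repeated last) for `d = 2`, and closed triangle meshes with
#' outward-consistent face orientation for `d = 3`. Components are kept
#' unmerged even when they touch, so each retains its provenance.
#'
#' @param d dimension (1, 2 or 3).
#' @param components list of components; each is a list with `type`
#'   (`"interval"`, `"polygon"` or `"trimesh"`) and the matching data fields
#'   (`lo`/`hi`; `vertices`; `vertices` + `faces`).
#' @param space_tag coordinate space the vertices live in.
#' @return An object of class `gate_region`.
#' @export
gate_region <- function(d, components = list(),
                        space_tag = c("standardized", "original", "transformed")) {
  space_tag <- match.arg(space_tag)
  cg_assert(d %in% 1:3, "dimension must be 1, 2 or 3")
  expected <- c("interval", "polygon", "trimesh")[d]
  for (cmp in components) {
    cg_assert(identical(cmp$type, expected),
              sprintf("component type '%s' does not match dimension %d", cmp$type, d))
  }
  structure(list(d = d, components = components, space_tag = space_tag),
            class = "gate_region")
}

#' @export
print.gate_region <- function(x, ...) {
  cat(sprintf("<gate_region> d=%d, %d component(s) [%s space]\n",
              x$d, length(x$components), x$space_tag))
  for (i in seq_along(x$components)) {
    cmp <- x$components[[i]]
    desc <- switch(cmp$type,
      interval = sprintf("interval [%.4g, %.4g]", cmp$lo, cmp$hi),
      polygon = sprintf("polygon, %d vertices, area %.4g",
                        nrow(cmp$vertices) - 1, polygon_area(cmp)),
      trimesh = sprintf("trimesh, %d vertices / %d faces, volume %.4g",
                        nrow(cmp$vertices), nrow(cmp$faces), trimesh_volume(cmp)))
    cat(sprintf("  [%d] %s\n", i, desc))
  }
  invisible(x)
}

# Close a ring (first row repeated last) and orient it clockwise.
normalize_ring <- function(v) {
  v <- as_event_matrix(v)
  if (any(v[1, ] != v[nrow(v), ])) v <- rbind(v, v[1, ])
  if (signed_ring_area(v) > 0) v <- v[nrow(v):1, , drop = FALSE]
  v
}

make_polygon <- function(vertices) {
  list(type = "polygon", vertices = normalize_ring(vertices))
}

# Shoelace signed area of a closed ring; positive for counter-clockwise.
signed_ring_area <- function(v) {
  n <- nrow(v)
  sum(v[-n, 1] * v[-1, 2] - v[-1, 1] * v[-n, 2]) / 2
}

#' Polygon area (shoelace formula)
#'
#' @param p a polygon component (closed clockwise ring), or a vertex matrix.
#' @return Positive area.
#' @examples
#' sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 0))
#' polygon_area(sq)
#' @export
polygon_area <- function(p) {
  v <- if (is.list(p)) p$vertices else normalize_ring(p)
  a <- abs(signed_ring_area(v))
  scale2 <- max(apply(v, 2, function(u) diff(range(u))))^2
  if (a <= 1e-12 * max(scale2, 1e-300)) {
    cg_abort("degenerate polygon: zero area (collinear ring)",
             class = "curvgate_degenerate_error")
  }
  a
}

# Closedness / orientation check: every undirected edge must be used exactly
# twice, once in each direction.
validate_closed_mesh <- function(m) {
  f <- m$faces
  a <- c(f[, 1], f[, 2], f[, 3]); b <- c(f[, 2], f[, 3], f[, 1])
  nv <- nrow(m$vertices)
  fwd <- (a - 1) * nv + b
  rev <- (b - 1) * nv + a
  if (anyDuplicated(fwd) || !setequal(fwd, rev)) {
    cg_abort("mesh is not a closed, consistently oriented triangle surface",
             class = "curvgate_open_mesh_error")
  }
  invisible(TRUE)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Sum of signed tetrahedron volumes spanned by each face and the origin;
#' the absolute value is returned so translation of the mesh does not matter.
#'
#' @param m a trimesh component: list with `vertices` (V x 3) and `faces`
#'   (F x 3 vertex indices, outward-consistent orientation).
#' @param check validate closedness first (default `TRUE`).
#' @return Positive enclosed volume.
#' @export
trimesh_volume <- function(m, check = TRUE) {
  if (check) validate_closed_mesh(m)
  abs(signed_mesh_volume(m))
}

signed_mesh_volume <- function(m) {
  v <- m$vertices; f <- m$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

#' Convex hull of points or of a region component
#'
#' For `d = 1` the hull is the spanning interval; for `d = 2` the clockwise
#' hull polygon; for `d = 3` a closed triangle mesh built by an incremental
#' (visible-face / horizon) algorithm with outward-oriented faces.
#'
#' @param x an m x d matrix of points, or a component (interval / polygon /
#'   trimesh) whose vertices are hulled.
#' @return An interval, polygon or trimesh component.
#' @export
convex_hull <- function(x) {
  if (is.list(x) && !is.null(x$type)) {
    x <- switch(x$type,
      interval = matrix(c(x$lo, x$hi), ncol = 1),
      polygon = x$vertices,
      trimesh = x$vertices,
      cg_abort("unknown component type"))
  }
  pts <- as_event_matrix(x)
  d <- ncol(pts)
  cg_assert(d %in% 1:3, "convex_hull supports dimensions 1-3")
  cg_assert(nrow(pts) >= d + 1,
            "convex hull needs at least d + 1 points",
            class = "curvgate_degenerate_error")
  if (d == 1) {
    r <- range(pts[, 1])
    if (r[1] >= r[2]) cg_abort("degenerate hull: all points equal",
                               class = "curvgate_degenerate_error")
    return(list(type = "interval", lo = r[1], hi = r[2]))
  }
  if (d == 2) {
    idx <- grDevices::chull(pts[, 1], pts[, 2])
    if (length(idx) < 3) cg_abort("degenerate hull: points are collinear",
                                  class = "curvgate_degenerate_error")
    return(make_polygon(pts[idx, , drop = FALSE]))
  }
  convex_hull_3d(pts)
}

# Incremental 3D convex hull. Faces are vertex-index triples oriented so
# outward normals give positive enclosed volume.
convex_hull_3d <- function(pts) {
  pts <- unique(round(pts, 12))
  n <- nrow(pts)
  scale <- max(apply(pts, 2, function(u) diff(range(u))), 1e-12)
  eps <- 1e-9 * scale
  if (n < 4) cg_abort("degenerate hull: fewer than 4 distinct points",
                      class = "curvgate_degenerate_error")
  # Initial non-degenerate tetrahedron: spread point, farthest point, then
  # farthest from the line, then farthest from the plane.
  i1 <- which.max(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  e <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  tproj <- rel %*% e / sum(e^2)
  perp <- rel - tproj %*% t(e)
  i3 <- which.max(rowSums(perp^2))
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  if (sqrt(sum(nrm^2)) <= eps^2) {
    cg_abort("degenerate hull: points are collinear", class = "curvgate_degenerate_error")
  }
  hgt <- rel %*% nrm
  i4 <- which.max(abs(hgt))
  if (abs(hgt[i4]) <= eps * sqrt(sum(nrm^2))) {
    cg_abort("degenerate hull: points are coplanar", class = "curvgate_degenerate_error")
  }
  faces <- rbind(c(i1, i2, i3), c(i1, i3, i4), c(i1, i4, i2), c(i2, i4, i3))
  ctr <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient_out <- function(f) {
    nn <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nn * (pts[f[1], ] - ctr)) < 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient_out))
  face_geo <- function(faces) {
    v1 <- pts[faces[, 1], , drop = FALSE]
    v2 <- pts[faces[, 2], , drop = FALSE]
    v3 <- pts[faces[, 3], , drop = FALSE]
    nx <- (v2[, 2] - v1[, 2]) * (v3[, 3] - v1[, 3]) - (v2[, 3] - v1[, 3]) * (v3[, 2] - v1[, 2])
    ny <- (v2[, 3] - v1[, 3]) * (v3[, 1] - v1[, 1]) - (v2[, 1] - v1[, 1]) * (v3[, 3] - v1[, 3])
    nz <- (v2[, 1] - v1[, 1]) * (v3[, 2] - v1[, 2]) - (v2[, 2] - v1[, 2]) * (v3[, 1] - v1[, 1])
    nl <- sqrt(nx^2 + ny^2 + nz^2)
    list(n = cbind(nx, ny, nz) / pmax(nl, 1e-300), p0 = v1)
  }
  geo <- face_geo(faces)
  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in remaining) {
    sgn <- rowSums(geo$n * matrix(pts[p, ], nrow(faces), 3, byrow = TRUE)) -
      rowSums(geo$n * geo$p0)
    vis <- sgn > eps
    if (!any(vis)) next
    visf <- faces[vis, , drop = FALSE]
    keep <- faces[!vis, , drop = FALSE]
    ea <- c(visf[, 1], visf[, 2], visf[, 3])
    eb <- c(visf[, 2], visf[, 3], visf[, 1])
    fwd <- paste(ea, eb)
    rev <- paste(eb, ea)
    horizon <- !(fwd %in% rev)  # edges not shared between two visible faces
    ha <- ea[horizon]; hb <- eb[horizon]
    newf <- cbind(ha, hb, p)
    faces <- rbind(keep, newf)
    geo <- face_geo(faces)
  }
  used <- sort(unique(as.vector(faces)))
  remap <- match(faces, used)
  mesh <- list(type = "trimesh",
               vertices = pts[used, , drop = FALSE],
               faces = matrix(remap, ncol = 3))
  if (signed_mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  validate_closed_mesh(mesh)
  mesh
}

#' Grow a convex region to a target volume factor
#'
#' Implements circle/sphere rolling: a disc (sphere) of radius `r` rolled
#' around the region boundary is approximated by offsetting each edge
#' midpoint (face centroid) a distance `2r` along the outward normal and
#' joining (hulling) the offset points. The rolling radius is found by root
#' search so that the grown area (volume) is `G` times the original, to 0.5
#' percent relative tolerance. Intervals are simply widened symmetrically to
#' `G` times their length.
#'
#' @param r an interval, convex polygon, or convex trimesh component.
#' @param G growth factor, `> 1`.
#' @param tol relative tolerance on the achieved area/volume ratio.
#' @return A grown component of the same type, containing the input.
#' @export
grow_region <- function(r, G, tol = 0.005) {
  cg_assert(is.numeric(G) && length(G) == 1 && G > 1, "growth factor G must be > 1")
  if (r$type == "interval") {
    len <- r$hi - r$lo
    mid <- (r$lo + r$hi) / 2
    return(list(type = "interval", lo = mid - G * len / 2, hi = mid + G * len / 2))
  }
  if (r$type == "polygon") {
    v <- r$vertices
    base_area <- polygon_area(r)
    nseg <- nrow(v) - 1
    mids <- (v[-nrow(v), , drop = FALSE] + v[-1, , drop = FALSE]) / 2
    dxy <- v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE]
    len <- sqrt(rowSums(dxy^2))
    ok <- len > 1e-14 * max(len)
    # clockwise ring: outward normal of edge (dx, dy) is (-dy, dx) / len
    nrm <- cbind(-dxy[, 2], dxy[, 1]) / len
    mids <- mids[ok, , drop = FALSE]; nrm <- nrm[ok, , drop = FALSE]
    offset_poly <- function(rr) {
      # original vertices are kept in the hull so the grown region always
      # contains the input, even at small rolling radii
      pts <- rbind(mids + 2 * rr * nrm, v[-nrow(v), , drop = FALSE])
      idx <- grDevices::chull(pts[, 1], pts[, 2])
      make_polygon(pts[idx, , drop = FALSE])
    }
    ratio <- function(rr) polygon_area(offset_poly(rr)) / base_area
    rr <- solve_growth_radius(ratio, G, diam = sqrt(base_area), tol = tol)
    return(offset_poly(rr))
  }
  if (r$type == "trimesh") {
    validate_closed_mesh(r)
    base_vol <- trimesh_volume(r, check = FALSE)
    v <- r$vertices; f <- r$faces
    cents <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
                v[f[, 3], , drop = FALSE]) / 3
    e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    nl <- sqrt(nx^2 + ny^2 + nz^2)
    nrm <- cbind(nx, ny, nz) / pmax(nl, 1e-300)
    offset_mesh <- function(rr) convex_hull_3d(rbind(cents + 2 * rr * nrm, v))
    ratio <- function(rr) trimesh_volume(offset_mesh(rr), check = FALSE) / base_vol
    rr <- solve_growth_radius(ratio, G, diam = base_vol^(1 / 3), tol = tol)
    return(offset_mesh(rr))
  }
  cg_abort(sprintf("cannot grow component of type '%s'", r$type))
}

# Root search for the rolling radius: ratio(0) < 1 < G and ratio is
# continuous and increasing, so the bracket always exists after expansion.
solve_growth_radius <- function(ratio, G, diam, tol) {
  upper <- diam
  it <- 0
  while (ratio(upper) < G) {
    upper <- upper * 2
    it <- it + 1
    if (it > 60) cg_abort("growth bisection failed to bracket the target ratio",
                          class = "curvgate_internal_error")
  }
  root <- stats::uniroot(function(rr) ratio(rr) - G, lower = 0, upper = upper,
                         tol = min(tol, 1e-3) * diam * 1e-3)$root
  achieved <- ratio(root)
  if (abs(achieved / G - 1) > tol) {
    cg_abort(sprintf("growth ratio %.4f misses target %.4f", achieved, G),
             class = "curvgate_internal_error")
  }
  root
}

#' Batch point-in-polygon test
#'
#' Even-odd (crossing number) containment of `m` points in a simple closed
#' polygon, vectorized over points. Points on the boundary (within a tiny
#' relative tolerance) count as inside: gates are closed sets, so events
#' exactly on a printed gate bound have deterministic membership.
#'
#' @param points m x 2 matrix.
#' @param p polygon component or vertex ring.
#' @return Logical vector of length `m`.
#' @export
points_in_polygon <- function(points, p) {
  v <- if (is.list(p)) p$vertices else normalize_ring(p)
  points <- as_event_matrix(points)
  px <- points[, 1]; py <- points[, 2]
  m <- length(px)
  scale <- max(abs(v), 1)
  eps <- 1e-9 * scale
  inside <- rep(FALSE, m)
  onb <- rep(FALSE, m)
  nseg <- nrow(v) - 1
  for (i in seq_len(nseg)) {
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[i + 1, 1]; y2 <- v[i + 1, 2]
    dx <- x2 - x1; dy <- y2 - y1
    seg2 <- dx^2 + dy^2
    if (seg2 > 0) {
      crossp <- (px - x1) * dy - (py - y1) * dx
      tpar <- ((px - x1) * dx + (py - y1) * dy) / seg2
      onb <- onb | (abs(crossp) <= eps * sqrt(seg2) & tpar >= -1e-12 & tpar <= 1 + 1e-12)
    }
    if (dy != 0) {
      cand <- (y1 > py) != (y2 > py)
      if (any(cand)) {
        xint <- x1 + (py - y1) * dx / dy
        hit <- cand & px < xint
        inside <- xor(inside, hit)
      }
    }
  }
  inside | onb
}

#' Batch point-in-polyhedron test
#'
#' Ray-casting parity test against a closed triangle mesh, vectorized over
#' points with a bounding-box prefilter. The ray direction is a fixed
#' irrational-slope vector; any point whose ray grazes a vertex, edge, or a
#' near-parallel face is deterministically retried with the next direction in
#' a fixed sequence, so the result needs no random number generator. Points
#' on the surface count as inside.
#'
#' @param points m x 3 matrix.
#' @param mesh closed trimesh component.
#' @return Logical vector of length `m`.
#' @export
points_in_polyhedron <- function(points, mesh) {
  validate_closed_mesh(mesh)
  points <- as_event_matrix(points)
  m <- nrow(points)
  v <- mesh$vertices; f <- mesh$faces
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  scale <- max(hi - lo, 1e-12)
  eps <- 1e-9 * scale
  cand <- points[, 1] >= lo[1] - eps & points[, 1] <= hi[1] + eps &
    points[, 2] >= lo[2] - eps & points[, 2] <= hi[2] + eps &
    points[, 3] >= lo[3] - eps & points[, 3] <= hi[3] + eps
  out <- rep(FALSE, m)
  if (!any(cand)) return(out)
  P <- points[cand, , drop = FALSE]
  res <- rep(NA, nrow(P))
  todo <- seq_len(nrow(P))
  v1 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v1
  e2 <- v[f[, 3], , drop = FALSE] - v1
  for (attempt in 1:12) {
    dir <- ray_directions(attempt)
    Pt <- P[todo, , drop = FALSE]
    np <- nrow(Pt)
    count <- integer(np)
    bad <- rep(FALSE, np)
    onb <- rep(FALSE, np)
    # Moeller-Trumbore, constant pieces per face
    pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
                dir[3] * e2[, 1] - dir[1] * e2[, 3],
                dir[1] * e2[, 2] - dir[2] * e2[, 1])
    det <- rowSums(e1 * pv)
    for (k in seq_len(nrow(f))) {
      tv1 <- Pt[, 1] - v1[k, 1]; tv2 <- Pt[, 2] - v1[k, 2]; tv3 <- Pt[, 3] - v1[k, 3]
      if (abs(det[k]) < 1e-12) {
        # ray parallel to face: only a problem for points near its plane
        nrmk <- cross3(e1[k, ], e2[k, ])
        nl <- sqrt(sum(nrmk^2))
        if (nl > 0) {
          dist <- abs(tv1 * nrmk[1] + tv2 * nrmk[2] + tv3 * nrmk[3]) / nl
          bad <- bad | dist < eps
        }
        next
      }
      u <- (tv1 * pv[k, 1] + tv2 * pv[k, 2] + tv3 * pv[k, 3]) / det[k]
      q1 <- tv2 * e1[k, 3] - tv3 * e1[k, 2]
      q2 <- tv3 * e1[k, 1] - tv1 * e1[k, 3]
      q3 <- tv1 * e1[k, 2] - tv2 * e1[k, 1]
      vv <- (dir[1] * q1 + dir[2] * q2 + dir[3] * q3) / det[k]
      tt <- (e2[k, 1] * q1 + e2[k, 2] * q2 + e2[k, 3] * q3) / det[k]
      inface <- u >= 0 & vv >= 0 & u + vv <= 1
      near <- u >= -1e-7 & vv >= -1e-7 & u + vv <= 1 + 1e-7
      onb <- onb | (near & abs(tt) <= eps)
      hit <- inface & tt > eps
      graze <- hit & (u < 1e-10 | vv < 1e-10 | u + vv > 1 - 1e-10)
      bad <- bad | graze
      count <- count + hit
    }
    got <- !bad
    res[todo[got]] <- (count[got] %% 2L == 1L) | onb[got]
    todo <- todo[bad]
    if (length(todo) == 0) break
  }
  if (length(todo) > 0) res[todo] <- FALSE  # unresolved grazing: treat as outside
  out[cand] <- res
  out
}

# Containment dispatch over a single component.
component_contains <- function(cmp, points) {
  points <- as_event_matrix(points)
  switch(cmp$type,
    interval = points[, 1] >= cmp$lo & points[, 1] <= cmp$hi,
    polygon = points_in_polygon(points, cmp),
    trimesh = points_in_polyhedron(points, cmp),
    cg_abort("unknown component type"))
}

# Sutherland-Hodgman clip of a convex-or-not polygon to an axis-aligned box.
# Returns a polygon component or NULL when the intersection is empty.
clip_polygon_box <- function(p, lo, hi) {
  ring <- p$vertices
  ring <- ring[-nrow(ring), , drop = FALSE]
  clip_half <- function(ring, axis, bound, keep_leq) {
    n <- nrow(ring)
    if (n == 0) return(ring)
    out <- NULL
    for (i in seq_len(n)) {
      a <- ring[i, ]; b <- ring[if (i == n) 1 else i + 1, ]
      ain <- if (keep_leq) a[axis] <= bound else a[axis] >= bound
      bin <- if (keep_leq) b[axis] <= bound else b[axis] >= bound
      if (ain) out <- rbind(out, a)
      if (xor(ain, bin)) {
        t <- (bound - a[axis]) / (b[axis] - a[axis])
        out <- rbind(out, a + t * (b - a))
      }
    }
    if (is.null(out)) matrix(numeric(0), 0, 2) else out
  }
  for (axis in 1:2) {
    ring <- clip_half(ring, axis, lo[axis], keep_leq = FALSE)
    ring <- clip_half(ring, axis, hi[axis], keep_leq = TRUE)
  }
  if (nrow(ring) < 3) return(NULL)
  ring <- ring[c(TRUE, rowSums(abs(diff(ring))) > 1e-12), , drop = FALSE]
  if (nrow(ring) < 3) return(NULL)
  cmp <- make_polygon(ring)
  if (abs(signed_ring_area(cmp$vertices)) < 1e-14) return(NULL)
  cmp
}
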