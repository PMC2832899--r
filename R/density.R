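#' Default bandwidth for the curvature-significance phase
#'
#' Evaluates the recommended curvature-phase bandwidth
#' `h_curv = [4 / ((d + 6) n)]^(1 / (d + 8))`, the asymptotically optimal
#' scalar bandwidth for estimating the Hessian of a d-variate standard normal
#' density. Because a Gaussian target needs close to the most smoothing of any
#' density, this is approximately the largest bandwidth worth considering for
#' curvature estimation, and it presumes the data have unit standard
#' deviation per channel (i.e. are standardized).
#'
#' @param d dimension, 1 to 3.
#' @param n number of events.
#' @return A positive scalar bandwidth.
#' @examples
#' default_curvature_bandwidth(2, 10000)
#' @export
default_curvature_bandwidth <- function(d, n) {
  cg_assert(d %in% 1:3, "dimension must be 1, 2 or 3")
  cg_assert(is.numeric(n) && length(n) == 1 && n >= 2, "n must be >= 2")
  (4 / ((d + 6) * n))^(1 / (d + 8))
}

#' Define a regular evaluation grid
#'
#' Builds the `grid_spec` used by the binned estimators: per-axis bounds
#' covering the data range plus `pad * h` on each side (so Gaussian kernels
#' of bandwidth `h` have negligible mass outside the grid), with `nodes`
#' equally spaced nodes per axis. Node `i` (0-based) of axis `k` sits at
#' `lo[k] + i * spacing[k]`.
#'
#' @param points n x d matrix whose range the grid must cover, or a 2 x d
#'   matrix of explicit (lo, hi) bounds when `from_range = TRUE`.
#' @param h scalar or per-axis bandwidth(s) used for padding.
#' @param nodes integer nodes per axis (scalar or length d), each >= 8.
#' @param pad padding in bandwidth units (default 3.7).
#' @param from_range interpret `points` as explicit bounds.
#' @return A `grid_spec`: list with `lo`, `hi`, `nodes`, `spacing`.
#' @export
make_grid_spec <- function(points, h, nodes, pad = 3.7, from_range = FALSE) {
  points <- as_event_matrix(points)
  d <- ncol(points)
  nodes <- as.integer(rep_len(nodes, d))
  cg_assert(all(nodes >= 8), "grid needs at least 8 nodes per axis")
  h <- rep_len(h, d)
  cg_assert(all(h > 0), "bandwidth must be positive")
  if (from_range) {
    lo <- points[1, ]; hi <- points[2, ]
  } else {
    lo <- apply(points, 2, min); hi <- apply(points, 2, max)
  }
  lo <- lo - pad * h
  hi <- hi + pad * h
  structure(
    list(lo = lo, hi = hi, nodes = nodes, spacing = (hi - lo) / (nodes - 1)),
    class = "grid_spec"
  )
}

#' Grid node coordinates along one axis
#' @param grid a `grid_spec`.
#' @param k axis index.
#' @return Numeric vector of node positions.
#' @export
grid_axis <- function(grid, k) {
  seq(grid$lo[k], grid$hi[k], length.out = grid$nodes[k])
}

# All node coordinates as an N x d matrix (column-major node order, matching
# R array linearization).
grid_coords <- function(grid) {
  axes <- lapply(seq_along(grid$nodes), function(k) grid_axis(grid, k))
  as.matrix(do.call(expand.grid, axes))
}

#' Linear binning of events onto a grid
#'
#' Distributes each event's unit mass multilinearly over the `2^d` grid nodes
#' surrounding it, the standard fast preprocessing step for kernel smoothing:
#' total grid mass equals the number of in-bounds events exactly. Events
#' outside the grid bounds contribute nothing; their count is returned so
#' callers can track effective sample size.
#'
#' @param points n x d matrix of (standardized) coordinates.
#' @param grid a `grid_spec` from [make_grid_spec()].
#' @return list with `counts` (d-dimensional array of node masses), `n_eff`
#'   (total binned mass), `n_lost` (events outside the grid).
#' @export
linear_bin <- function(points, grid) {
  points <- as_event_matrix(points)
  d <- length(grid$nodes)
  cg_assert(ncol(points) == d, "point dimension does not match grid")
  pos <- sweep(sweep(points, 2, grid$lo, "-"), 2, grid$spacing, "/")
  inb <- rep(TRUE, nrow(points))
  for (k in seq_len(d)) {
    inb <- inb & pos[, k] >= -1e-9 & pos[, k] <= grid$nodes[k] - 1 + 1e-9
  }
  n_lost <- sum(!inb)
  pos <- pos[inb, , drop = FALSE]
  m <- nrow(pos)
  counts <- array(0, dim = grid$nodes)
  if (m > 0) {
    i0 <- matrix(0L, m, d); fr <- matrix(0, m, d)
    for (k in seq_len(d)) {
      i <- pmin.int(pmax.int(floor(pos[, k]), 0), grid$nodes[k] - 2L)
      i0[, k] <- as.integer(i)
      fr[, k] <- pos[, k] - i
    }
    stride <- cumprod(c(1, grid$nodes[-d]))
    for (corner in 0:(2^d - 1)) {
      bits <- as.integer(intToBits(corner))[seq_len(d)]
      w <- rep(1, m); lin <- rep(1, m)
      for (k in seq_len(d)) {
        w <- w * if (bits[k] == 1L) fr[, k] else 1 - fr[, k]
        lin <- lin + (i0[, k] + bits[k]) * stride[k]
      }
      agg <- rowsum(w, lin)
      idx <- as.integer(rownames(agg))
      counts[idx] <- counts[idx] + agg[, 1]
    }
  }
  list(counts = counts, n_eff = sum(counts), n_lost = n_lost)
}

#' Binned kernel density estimate on a grid
#'
#' Evaluates the Gaussian-product kernel density estimator at every grid node
#' by separable convolution of the linear-binned counts with the kernel
#' sampled at node offsets. With grid spacing a small fraction of the
#' bandwidth this matches the exact event-sum estimator closely at a cost
#' independent of `n`.
#'
#' @param counts binned count array from [linear_bin()].
#' @param grid the matching `grid_spec`.
#' @param h bandwidth: scalar, or one value per axis (diagonal bandwidth).
#' @param n sample size used for normalization; defaults to `sum(counts)`.
#' @return Array of nonnegative density values, same shape as `counts`.
#' @export
kde_on_grid <- function(counts, grid, h, n = sum(counts)) {
  d <- length(grid$nodes)
  h <- rep_len(h, d)
  cg_assert(all(is.finite(h) & h > 0), "bandwidth must be positive")
  mats <- lapply(seq_len(d), function(k) kernel_matrix(grid_axis(grid, k), h[k], 0))
  fhat <- sep_apply(counts, mats) / n
  fhat[fhat < 0] <- 0
  fhat
}

#' Kernel Hessian estimate on a grid
#'
#' Estimates every second partial derivative of the density by convolving the
#' binned counts with the analytically differentiated Gaussian kernel (never
#' by finite differences of the density estimate). The product-kernel
#' structure makes each entry separable: axis `i` carries the second
#' derivative factor for diagonal entries, axes `i` and `j` each carry a
#' first derivative factor for off-diagonal entries.
#'
#' @inheritParams kde_on_grid
#' @return List of `d(d+1)/2` arrays, the lower-triangular Hessian entries in
#'   column-major `vech` order, with attribute `pairs` giving the (i, j)
#'   index of each slot. Symmetric entries share the same array.
#' @export
hessian_on_grid <- function(counts, grid, h, n = sum(counts)) {
  d <- length(grid$nodes)
  h <- rep_len(h, d)
  cg_assert(all(is.finite(h) & h > 0), "bandwidth must be positive")
  pairs <- vech_pairs(d)
  axes <- lapply(seq_len(d), function(k) grid_axis(grid, k))
  base <- lapply(seq_len(d), function(k) kernel_matrix(axes[[k]], h[k], 0))
  out <- vector("list", nrow(pairs))
  for (s in seq_len(nrow(pairs))) {
    i <- pairs[s, 1]; j <- pairs[s, 2]
    mats <- base
    if (i == j) {
      mats[[i]] <- kernel_matrix(axes[[i]], h[i], 2)
    } else {
      mats[[i]] <- kernel_matrix(axes[[i]], h[i], 1)
      mats[[j]] <- kernel_matrix(axes[[j]], h[j], 1)
    }
    out[[s]] <- sep_apply(counts, mats) / n
  }
  attr(out, "pairs") <- pairs
  out
}

# Closed-form R-functional matrix for the Wald test: R[a, b] =
# integral over R^d of the a-th and b-th second partials of the standard
# d-variate Gaussian kernel. Separable across axes into 1-D moments of
# phi(t)^2 against the Hermite factors {1, t, t^2 - 1}.
curvature_R_matrix <- function(d) {
  m1d <- matrix(0, 3, 3)  # codes 0,1,2 -> rows/cols 1..3
  m1d[1, 1] <- 1 / (2 * sqrt(pi))
  m1d[2, 2] <- 1 / (4 * sqrt(pi))
  m1d[3, 3] <- 3 / (8 * sqrt(pi))
  m1d[1, 3] <- m1d[3, 1] <- -1 / (4 * sqrt(pi))
  pairs <- vech_pairs(d)
  q <- nrow(pairs)
  codes <- matrix(0L, q, d)
  for (s in seq_len(q)) {
    i <- pairs[s, 1]; j <- pairs[s, 2]
    if (i == j) codes[s, i] <- 2L else codes[s, c(i, j)] <- 1L
  }
  R <- matrix(0, q, q)
  for (a in seq_len(q)) for (b in seq_len(q)) {
    R[a, b] <- prod(m1d[cbind(codes[a, ] + 1L, codes[b, ] + 1L)])
  }
  R
}

# Vectorized negative-definiteness of symmetric matrices given as an N x q
# matrix of vech entries (column-major lower triangle).
negdef_mask <- function(V, d) {
  if (d == 1) return(V[, 1] < 0)
  if (d == 2) {
    h11 <- V[, 1]; h21 <- V[, 2]; h22 <- V[, 3]
    return(h11 < 0 & h11 * h22 - h21^2 > 0)
  }
  h11 <- V[, 1]; h21 <- V[, 2]; h31 <- V[, 3]
  h22 <- V[, 4]; h32 <- V[, 5]; h33 <- V[, 6]
  det2 <- h11 * h22 - h21^2
  det3 <- h11 * (h22 * h33 - h32^2) - h21 * (h21 * h33 - h32 * h31) +
    h31 * (h21 * h32 - h22 * h31)
  h11 < 0 & det2 > 0 & det3 < 0
}

#' Test for significant high negative curvature
#'
#' Flags grid nodes where the estimated density Hessian is both negative
#' definite (a genuine local-maximum shape) and statistically distinguishable
#' from zero. At each node a Wald statistic
#' `W(x) = vech(H)' Sigma^{-1} vech(H)` is compared with a chi-squared
#' critical value on `d(d+1)/2` degrees of freedom, where the covariance of
#' the vectorized kernel Hessian estimator has the plug-in form
#' `Sigma(x) = fhat(x) R / (n h^(d+4))` with `R` the (closed-form) matrix of
#' integrated products of second partials of the Gaussian kernel. Nodes with
#' density below `floor * max(fhat)` are never flagged: the variance estimate
#' is unreliable there and such regions cannot hold a meaningful gate.
#'
#' @param fhat density array from [kde_on_grid()].
#' @param hessian Hessian entry list from [hessian_on_grid()].
#' @param n effective sample size.
#' @param h scalar curvature bandwidth the estimates were built with.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param adjustment multiplicity handling over in-support nodes:
#'   `"hochberg"` (step-up, default) or `"pointwise"` (no adjustment).
#' @param floor relative density floor; default `1e-3`.
#' @return Logical array, `TRUE` where curvature is significantly negative.
#' @export
significant_negative_curvature <- function(fhat, hessian, n, h,
                                           alpha = 0.05,
                                           adjustment = c("hochberg", "pointwise"),
                                           floor = 1e-3) {
  adjustment <- match.arg(adjustment)
  cg_assert(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  pairs <- attr(hessian, "pairs")
  d <- max(pairs)
  q <- nrow(pairs)
  h <- h[1]
  V <- do.call(cbind, lapply(hessian, as.vector))
  f <- as.vector(fhat)
  support <- f >= floor * max(f) & f > 0
  Rinv <- solve(curvature_R_matrix(d))
  W <- rep(NA_real_, length(f))
  idx <- which(support)
  Vi <- V[idx, , drop = FALSE]
  quad <- rowSums((Vi %*% Rinv) * Vi)
  W[idx] <- (n * h^(d + 4) / f[idx]) * quad
  pval <- stats::pchisq(W[idx], df = q, lower.tail = FALSE)
  if (adjustment == "hochberg") pval <- stats::p.adjust(pval, method = "hochberg")
  flag <- rep(FALSE, length(f))
  flag[idx] <- pval <= alpha & negdef_mask(Vi, d)
  flag[!is.finite(W) & seq_along(flag) %in% idx] <- FALSE
  array(flag, dim = if (is.null(dim(fhat))) length(fhat) else dim(fhat))
}

#' Full curvature field for a standardized sample
#'
#' Convenience wrapper running linear binning, the binned density and Hessian
#' estimates, and the negative-curvature significance test on one grid.
#'
#' @param points n x d standardized event matrix.
#' @param h_curv curvature bandwidth (scalar); see
#'   [default_curvature_bandwidth()].
#' @param nodes grid nodes per axis; defaults to 151 for d <= 2, 51 for d = 3.
#' @param alpha,adjustment,floor passed to [significant_negative_curvature()].
#' @param pad grid padding in bandwidths.
#' @return A `density_field`: list with `grid`, `counts`, `fhat`, `hessian`,
#'   `sig_neg_curv`, `h_curv`, `n_eff`.
#' @export
curvature_field <- function(points, h_curv, nodes = NULL, alpha = 0.05,
                            adjustment = "hochberg", floor = 1e-3, pad = 3.7) {
  points <- as_event_matrix(points)
  d <- ncol(points)
  if (is.null(nodes)) nodes <- if (d <= 2) 151L else 51L
  grid <- make_grid_spec(points, h_curv, nodes, pad = pad)
  b <- linear_bin(points, grid)
  fhat <- kde_on_grid(b$counts, grid, h_curv, n = b$n_eff)
  hess <- hessian_on_grid(b$counts, grid, h_curv, n = b$n_eff)
  flags <- significant_negative_curvature(fhat, hess, b$n_eff, h_curv,
                                          alpha = alpha, adjustment = adjustment,
                                          floor = floor)
  structure(
    list(grid = grid, counts = b$counts, fhat = fhat, hessian = hess,
         sig_neg_curv = flags, h_curv = h_curv, n_eff = b$n_eff,
         n_lost = b$n_lost),
    class = "density_field"
  )
}
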