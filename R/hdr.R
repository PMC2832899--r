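# HDR phase: per-subset plug-in bandwidths, order-statistic HDR levels, and
# level-tau gate components.

# Binned estimate of the integrated density-derivative functional
# psi_r = E[f^{(r)}(X)] on pre-scaled data: (1/m^2) c' A c with A the
# separable derivative-kernel matrix at pilot bandwidth g. `codes` gives the
# derivative order per axis.
binned_psi <- function(z, g, codes, nodes) {
  d <- ncol(z)
  grid <- make_grid_spec(z, g, nodes, pad = 4)
  b <- linear_bin(z, grid)
  mats <- lapply(seq_len(d), function(k) {
    kernel_matrix(grid_axis(grid, k), g, codes[k])
  })
  s <- sep_apply(b$counts, mats)
  sum(b$counts * s) / b$n_eff^2
}

#' Two-stage diagonal plug-in bandwidth
#'
#' Per-axis kernel density bandwidths for the HDR phase, chosen by a
#' two-stage direct plug-in. Each axis is first scaled to unit standard
#' deviation; a single bandwidth `h` is then selected for the scaled data
#' and mapped back as `h * sd` per axis (so the selector is equivariant
#' under axis scaling and the bandwidths scale as `m^(-1/(d+4))`).
#'
#' For `d = 1` this is the classical two-stage selector: the 8th-order
#' functional is taken at its normal reference value, a pilot bandwidth
#' estimates the 6th-order functional, a second pilot estimates the 4th-order
#' functional `psi_4`, and the final bandwidth solves the AMISE expression
#' `h = [R(K) / (m psi_4)]^(1/5)`. For `d = 2, 3` the stage-1 pilot is the
#' normal-reference curvature bandwidth; the stage-2 functionals
#' `psi_{iijj}` (all fourth-order integrated products of second derivatives)
#' are re-estimated with it and the final bandwidth solves the diagonal
#' AMISE expression `h = [d R(K)^d / (m sum_ij psi_iijj)]^(1/(d+4))`. All
#' functional estimates use linear binning. If an estimated functional has
#' the wrong sign the normal-scale bandwidth is used instead.
#'
#' @param subset m x d matrix of (standardized-space) points, `m >= 10`.
#' @return Vector of `d` positive bandwidths.
#' @export
plugin_bandwidth <- function(subset) {
  subset <- as_event_matrix(subset)
  m <- nrow(subset); d <- ncol(subset)
  if (m < 10) cg_abort("plug-in bandwidth needs at least 10 points",
                       class = "curvgate_too_few_points_error")
  sds <- apply(subset, 2, stats::sd)
  cg_assert(all(sds > 0), "plug-in bandwidth: constant coordinate",
            class = "curvgate_degenerate_channel_error")
  z <- sweep(sweep(subset, 2, colMeans(subset), "-"), 2, sds, "/")
  RK <- 1 / (2 * sqrt(pi))
  h <- if (d == 1) {
    nodes <- 401L
    psi8 <- 105 / (32 * sqrt(pi))              # normal reference, sigma = 1
    g6 <- (-2 * (-15 / sqrt(2 * pi)) / (psi8 * m))^(1 / 9)
    psi6 <- binned_psi(z, g6, codes = 6, nodes = nodes)
    if (psi6 >= 0) {
      (4 / 3)^(1 / 5) * m^(-1 / 5)             # normal-scale fallback
    } else {
      g4 <- (-2 * (3 / sqrt(2 * pi)) / (psi6 * m))^(1 / 7)
      psi4 <- binned_psi(z, g4, codes = 4, nodes = nodes)
      if (psi4 <= 0) (4 / 3)^(1 / 5) * m^(-1 / 5)
      else (RK / (psi4 * m))^(1 / 5)
    }
  } else {
    nodes <- if (d == 2) 101L else 31L
    g <- (4 / ((d + 6) * m))^(1 / (d + 8))     # stage-1 normal-reference pilot
    psis <- 0
    for (i in seq_len(d)) for (j in seq_len(d)) {
      codes <- rep(0L, d)
      if (i == j) codes[i] <- 4L else codes[c(i, j)] <- 2L
      psis <- psis + binned_psi(z, g, codes, nodes)
    }
    if (psis <= 0) {
      (4 / ((d + 2) * m))^(1 / (d + 4))        # normal-scale fallback
    } else {
      (d * RK^d / (psis * m))^(1 / (d + 4))
    }
  }
  h * sds
}

#' Highest-density-region level from density values
#'
#' The level of the tau HDR estimated from the density values at the sample
#' points: the `ceiling(tau * m)`-th smallest value, so at least a fraction
#' `1 - tau` of the points have density at or above the level. With
#' `tau = 0.1` the region above the level carries about 90 percent of the
#' probability mass; with `tau = 0.9`, about 10 percent.
#'
#' @param density_at_points density estimate evaluated at the m points.
#' @param tau HDR level parameter in (0, 1).
#' @return The positive density threshold.
#' @examples
#' hdr_level(1:10, 0.2)  # 2nd order statistic
#' @export
hdr_level <- function(density_at_points, tau) {
  cg_assert(is.numeric(tau) && length(tau) == 1 && tau > 0 && tau < 1,
            "tau must lie in (0, 1)")
  m <- length(density_at_points)
  cg_assert(m >= 1, "need at least one density value")
  sort(density_at_points)[ceiling(tau * m)]
}

#' Fit a level-tau highest density region gate to a point subset
#'
#' The HDR refinement applied to the events captured by one grown curvature
#' region: a binned kernel density estimate with [plugin_bandwidth()] is
#' built on a local grid over the subset's bounding box (padded by 3.7
#' bandwidths), the gate level is the order-statistic HDR threshold of the
#' density values at the subset points, and the gate geometry is the
#' super-level set of the estimate. A single subset can yield several
#' components (for instance when `tau` sits above a saddle between two
#' modes).
#'
#' @param subset m x d matrix of points in standardized space, `m >= 10`.
#' @param tau HDR level parameter in (0, 1).
#' @param nodes grid nodes per axis; defaults to 101 for d <= 2, 21 for d = 3.
#' @return An object of class `hdr_gate`: list with `components`, `tau`,
#'   `level`, `bandwidths`, `subset_size`, `grid`, `fhat`.
#' @export
hdr_gate <- function(subset, tau, nodes = NULL) {
  subset <- as_event_matrix(subset)
  d <- ncol(subset)
  if (nrow(subset) < 10) {
    cg_abort("HDR gate needs at least 10 points", class = "curvgate_too_few_points_error")
  }
  if (is.null(nodes)) nodes <- if (d <= 2) 101L else 21L
  bw <- plugin_bandwidth(subset)
  grid <- make_grid_spec(subset, bw, nodes, pad = 3.7)
  b <- linear_bin(subset, grid)
  fhat <- kde_on_grid(b$counts, grid, bw, n = b$n_eff)
  f_at <- grid_interp(fhat, grid, subset)
  level <- hdr_level(f_at, tau)
  comps <- density_level_regions(fhat, level, grid)
  structure(
    list(components = comps, tau = tau, level = level, bandwidths = bw,
         subset_size = nrow(subset), grid = grid, fhat = fhat),
    class = "hdr_gate"
  )
}

#' @export
print.hdr_gate <- function(x, ...) {
  cat(sprintf("<hdr_gate> tau=%.3g, level=%.4g, %d component(s), m=%d\n",
              x$tau, x$level, length(x$components), x$subset_size))
  cat("  bandwidths:", paste(signif(x$bandwidths, 4), collapse = ", "), "\n")
  invisible(x)
}
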