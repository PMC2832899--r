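#' Gating parameters
#'
#' Collects the tunable parameters of the gating pipeline. Parameters left
#' `NULL` are resolved from the recommended defaults once the data dimension
#' and size are known: curvature bandwidth `h_curv = [4/((d+6)n)]^(1/(d+8))`,
#' growth factor `G = 2^d`, curvature grid of 151 nodes per axis for
#' `d <= 2` (51 for `d = 3`). The HDR level `tau` is the main tuning
#' parameter; 0.1 is a reasonable general-purpose choice, with lower values
#' giving wider, more inclusive gates.
#'
#' @param tau HDR level in (0, 1); default 0.1.
#' @param growth_factor hull growth factor `G > 1`, or `NULL` for `2^d`.
#' @param alpha significance level of the curvature test; default 0.05.
#' @param h_curv curvature-phase bandwidth, or `NULL` for the default formula.
#' @param transform variance-stabilizing transform: `"asinh"` or `"identity"`.
#' @param grid_nodes curvature grid nodes per axis, or `NULL` for defaults.
#' @param hdr_grid_nodes HDR-phase local grid nodes, or `NULL` for defaults.
#' @param debris_threshold boundary pile-up frequency threshold in (0, 1].
#' @param adjustment multiplicity adjustment of the curvature test:
#'   `"hochberg"` or `"pointwise"`.
#' @param min_region_nodes minimum flagged nodes per curvature region.
#' @param density_floor relative density floor for the curvature test.
#' @param seed integer recorded with results; the pipeline itself is
#'   deterministic (no random tie-breaking is currently needed).
#' @return An object of class `curvhdr_params`.
#' @export
curvhdr_params <- function(tau = 0.1, growth_factor = NULL, alpha = 0.05,
                           h_curv = NULL, transform = c("asinh", "identity"),
                           grid_nodes = NULL, hdr_grid_nodes = NULL,
                           debris_threshold = 0.01,
                           adjustment = c("hochberg", "pointwise"),
                           min_region_nodes = 3, density_floor = 1e-3,
                           seed = 1L) {
  transform <- match.arg(transform)
  adjustment <- match.arg(adjustment)
  cg_assert(tau > 0 && tau < 1, "tau must lie in (0, 1)")
  cg_assert(is.null(growth_factor) || growth_factor > 1, "growth factor G must be > 1")
  cg_assert(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  cg_assert(is.null(h_curv) || h_curv > 0, "h_curv must be positive")
  cg_assert(debris_threshold > 0 && debris_threshold <= 1,
            "debris threshold must lie in (0, 1]")
  structure(
    list(tau = tau, growth_factor = growth_factor, alpha = alpha,
         h_curv = h_curv, transform = transform, grid_nodes = grid_nodes,
         hdr_grid_nodes = hdr_grid_nodes, debris_threshold = debris_threshold,
         adjustment = adjustment, min_region_nodes = min_region_nodes,
         density_floor = density_floor, seed = as.integer(seed)),
    class = "curvhdr_params"
  )
}

# Fill in data-dependent defaults; the returned list is the full parameter
# record logged with every run.
resolve_params <- function(params, d, n) {
  p <- unclass(params)
  p$h_curv <- p$h_curv %||% default_curvature_bandwidth(d, n)
  p$growth_factor <- p$growth_factor %||% 2^d
  p$grid_nodes <- p$grid_nodes %||% (if (d <= 2) 151L else 51L)
  p$hdr_grid_nodes <- p$hdr_grid_nodes %||% (if (d <= 2) 101L else 21L)
  p$d <- d
  p$n <- n
  p
}

#' Run the curvature-guided HDR gating pipeline
#'
#' The full automatic gating procedure on 1-3 selected channels:
#' boundary-debris removal, skew-reducing transform, standardization,
#' detection of statistically significant high-negative-curvature regions of
#' the binned kernel density estimate, replacement of each region by its
#' convex hull, hull growth to `G` times the original area/volume, HDR
#' refinement of each grown region on the events it contains (level-`tau`
#' highest density region of a plug-in-bandwidth density estimate), union of
#' the HDR components, per-event membership, and back-transformation of the
#' gate to original measurement units.
#'
#' @param t an [event_table()] in original units.
#' @param channels character or integer vector selecting 1-3 channels;
#'   default all.
#' @param params a [curvhdr_params()] object.
#' @return An object of class `gate_result` with fields `gate` (original
#'   units), `gate_std` (standardized space), `membership` and `indices`
#'   (over the input rows), `curvature_regions` (per-region raw / hull /
#'   grown geometry), `hdr_gates`, `scale`, `params` (fully resolved), and
#'   `log`.
#' @examples
#' \donttest{
#' fx <- fixture_three_cluster_2d(n = 5000, seed = 1)
#' res <- curvhdr_filter(fx$events, params = curvhdr_params(transform = "identity"))
#' res
#' }
#' @export
curvhdr_filter <- function(t, channels = NULL, params = curvhdr_params()) {
  cg_assert(inherits(t, "event_table"), "expected an event_table")
  cg_assert(inherits(params, "curvhdr_params"), "expected curvhdr_params")
  if (!is.null(channels)) {
    if (is.character(channels)) {
      missing <- setdiff(channels, t$channel_names)
      if (length(missing) > 0) {
        cg_abort(sprintf("channel(s) not found: %s (available: %s)",
                         paste(missing, collapse = ", "),
                         paste(t$channel_names, collapse = ", ")))
      }
      channels <- match(channels, t$channel_names)
    }
    t <- event_table(t$values[, channels, drop = FALSE],
                     t$channel_names[channels], space_tag = t$space_tag)
  }
  d <- t$d
  warn <- character(0)

  # Step 1: debris removal, then the skew-reducing transform
  deb <- remove_boundary_debris(t, threshold = params$debris_threshold)
  kept <- deb$events
  if (kept$n < 100) {
    cg_abort(sprintf("only %d events remain after debris removal (need >= 100)",
                     kept$n), class = "curvgate_insufficient_data_error")
  }
  vals <- kept$values
  if (params$transform == "asinh") vals <- asinh_transform(vals)
  tt <- event_table(vals, kept$channel_names, space_tag = "transformed")

  # Step 2: standardize
  std <- standardize_events(tt, transform = params$transform,
                            debris_mask = deb$debris_mask)
  z <- std$events$values
  p <- resolve_params(params, d, nrow(z))

  # Step 3: significant high negative curvature over a mesh
  field <- curvature_field(z, p$h_curv, nodes = p$grid_nodes, alpha = p$alpha,
                           adjustment = p$adjustment, floor = p$density_floor)
  raw_regions <- indicator_to_regions(field$sig_neg_curv, field$grid,
                                      min_region_nodes = p$min_region_nodes)
  raw_regions <- sort_components(raw_regions)

  # Steps 4-8: hull, grow, subset, HDR per region
  curvature_regions <- list()
  hdr_gates <- list()
  components <- list()
  for (i in seq_along(raw_regions)) {
    reg <- raw_regions[[i]]
    hull <- tryCatch(convex_hull(reg), curvgate_degenerate_error = function(e) NULL)
    if (is.null(hull)) {
      warn <- c(warn, sprintf("region %d dropped: degenerate convex hull", i))
      next
    }
    grown <- grow_region(hull, p$growth_factor)
    inside <- component_contains(grown, z)
    m <- sum(inside)
    rec <- list(raw = reg, hull = hull, grown = grown, subset_size = m)
    if (m < 10) {
      warn <- c(warn, sprintf("region %d dropped: only %d events inside grown hull", i, m))
      curvature_regions[[length(curvature_regions) + 1]] <- rec
      next
    }
    hg <- hdr_gate(z[inside, , drop = FALSE], p$tau, nodes = p$hdr_grid_nodes)
    curvature_regions[[length(curvature_regions) + 1]] <- rec
    hdr_gates[[length(hdr_gates) + 1]] <- hg
    components <- c(components, hg$components)
  }
  if (length(raw_regions) == 0) {
    warning("no significant curvature regions found; gate is empty")
  }
  gate_std <- gate_region(d, sort_components(components), space_tag = "standardized")

  # Step 9: membership of the retained events, mapped to input rows
  memb_kept <- gate_membership(gate_std, std$events)
  membership <- rep(FALSE, t$n)
  membership[deb$debris_mask] <- memb_kept

  # Step 10: gate back to original units
  gate <- to_original_units(gate_std, std$scale)

  res <- structure(
    list(gate = gate, gate_std = gate_std, membership = membership,
         indices = which(membership),
         curvature_regions = curvature_regions, hdr_gates = hdr_gates,
         scale = std$scale, params = p,
         log = list(
           n_input = t$n, n_debris = sum(!deb$debris_mask),
           n_retained = kept$n, n_eff = field$n_eff,
           S = length(raw_regions), n_gated = sum(membership),
           channels = t$channel_names, params = p, warnings = warn
         )),
    class = "gate_result"
  )
  res
}

# Deterministic component order: sort by centroid, lexicographic by axis.
sort_components <- function(comps) {
  if (length(comps) <= 1) return(comps)
  cents <- t(vapply(comps, function(cmp) {
    switch(cmp$type,
      interval = c((cmp$lo + cmp$hi) / 2, 0, 0),
      polygon = c(colMeans(cmp$vertices[-nrow(cmp$vertices), , drop = FALSE]), 0),
      trimesh = colMeans(cmp$vertices))
  }, numeric(3)))
  comps[order(cents[, 1], cents[, 2], cents[, 3])]
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("<gate_result> d=%d: %d curvature region(s) -> %d gate component(s)\n",
              x$gate$d, x$log$S, length(x$gate$components)))
  cat(sprintf("  events: %d in, %d boundary debris, %d gated (%.1f%%)\n",
              x$log$n_input, x$log$n_debris, x$log$n_gated,
              100 * x$log$n_gated / x$log$n_input))
  cat(sprintf("  tau=%.3g, G=%.3g, alpha=%.3g, h_curv=%.4g, transform=%s\n",
              x$params$tau, x$params$growth_factor, x$params$alpha,
              x$params$h_curv, x$params$transform))
  for (w in x$log$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Event membership of a gate region
#'
#' Tests every event against every component of a gate region and returns
#' the union (an event inside two components counts once).
#'
#' @param region a [gate_region()].
#' @param t an [event_table()] in the same coordinate space as the region.
#' @return Logical vector over the events.
#' @export
gate_membership <- function(region, t) {
  cg_assert(inherits(region, "gate_region"), "expected a gate_region")
  cg_assert(inherits(t, "event_table"), "expected an event_table")
  cg_assert(identical(region$space_tag, t$space_tag),
            sprintf("space mismatch: region is '%s', events are '%s'",
                    region$space_tag, t$space_tag))
  cg_assert(region$d == t$d, "dimension mismatch between region and events")
  out <- rep(FALSE, t$n)
  for (cmp in region$components) out <- out | component_contains(cmp, t$values)
  out
}

#' Intersect a gate with an axis-aligned rectangle
#'
#' Rectangle gates are the standard way to exclude debris regions from an
#' automatic gate. Intervals are intersected directly; polygons are clipped
#' to the box (Sutherland-Hodgman); for meshes the intersection is applied
#' at the membership level (member iff inside the mesh and inside the box)
#' with the mesh reported alongside its clip box. Empty intersections are
#' dropped.
#'
#' @param g a [curvhdr_filter()] result or a [gate_region()].
#' @param rect 2 x d matrix (rows lo, hi) or length-2d vector
#'   `(lo1, hi1, lo2, hi2, ...)`, in the same units as the gate geometry
#'   (original units for a `gate_result`).
#' @param t the [event_table()] the membership refers to (required for a
#'   `gate_result`, in original units).
#' @return list with `region` (the clipped [gate_region()]) and `membership`
#'   (when events are available).
#' @export
intersect_rectangle <- function(g, rect, t = NULL) {
  region <- if (inherits(g, "gate_result")) g$gate else g
  cg_assert(inherits(region, "gate_region"), "expected a gate_region or gate_result")
  d <- region$d
  rect <- as.numeric(rect)
  cg_assert(length(rect) == 2 * d && all(is.finite(rect)),
            sprintf("rectangle must supply finite lo/hi for each of %d axes", d))
  rm_ <- matrix(rect, nrow = 2)
  lo <- rm_[1, ]; hi <- rm_[2, ]
  cg_assert(all(lo < hi), "rectangle must have lo < hi on every axis")
  comps <- list()
  for (cmp in region$components) {
    clipped <- switch(cmp$type,
      interval = {
        a <- max(cmp$lo, lo[1]); b <- min(cmp$hi, hi[1])
        if (a < b) list(type = "interval", lo = a, hi = b) else NULL
      },
      polygon = clip_polygon_box(cmp, lo, hi),
      trimesh = {
        vlo <- apply(cmp$vertices, 2, min); vhi <- apply(cmp$vertices, 2, max)
        if (any(vlo > hi) || any(vhi < lo)) NULL
        else { cmp$clip_box <- rbind(lo, hi); cmp }
      })
    if (!is.null(clipped)) comps[[length(comps) + 1]] <- clipped
  }
  out_region <- gate_region(d, comps, space_tag = region$space_tag)
  membership <- NULL
  if (inherits(g, "gate_result")) {
    cg_assert(!is.null(t), "pass the event_table to recompute membership")
    cg_assert(t$n == length(g$membership), "event table does not match the gate result")
    inbox <- rep(TRUE, t$n)
    for (k in seq_len(d)) {
      inbox <- inbox & t$values[, k] >= lo[k] & t$values[, k] <= hi[k]
    }
    membership <- g$membership & inbox
  } else if (!is.null(t)) {
    membership <- gate_membership(out_region, t)
    if (any(vapply(comps, function(x) x$type == "trimesh" && !is.null(x$clip_box),
                   logical(1)))) {
      inbox <- rep(TRUE, t$n)
      for (k in seq_len(d)) {
        inbox <- inbox & t$values[, k] >= lo[k] & t$values[, k] <= hi[k]
      }
      membership <- membership & inbox
    }
  }
  list(region = out_region, membership = membership)
}
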