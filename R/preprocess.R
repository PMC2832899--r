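#' Construct an event table
#'
#' An `event_table` is the package's container for flow cytometry events: an
#' `n x d` numeric matrix (one row per event, one column per channel) together
#' with channel names and a tag recording which coordinate space the values
#' live in (`"original"` machine units, `"transformed"` after the
#' variance-stabilizing transform, or `"standardized"` after centring and
#' scaling).
#'
#' @param values numeric matrix, data frame, or vector (one channel) of
#'   per-event measurements; no `NA`/`NaN`/`Inf` allowed.
#' @param channel_names character vector of unique channel labels; defaults to
#'   the column names of `values` or `ch1..chd`.
#' @param space_tag coordinate-space tag, one of `"original"`,
#'   `"transformed"`, `"standardized"`.
#' @return An object of class `event_table` with fields `values`,
#'   `channel_names`, `space_tag`, `n`, `d`.
#' @examples
#' et <- event_table(cbind(FSC = rnorm(50, 500, 50), SSC = rnorm(50, 200, 30)))
#' et
#' @export
event_table <- function(values, channel_names = NULL,
                        space_tag = c("original", "transformed", "standardized")) {
  space_tag <- match.arg(space_tag)
  values <- as_event_matrix(values)
  cg_assert(nrow(values) >= 1, "event table needs at least one event")
  cg_assert(ncol(values) %in% 1:3,
            sprintf("dimension must be 1, 2 or 3 (got %d)", ncol(values)))
  cg_assert(all(is.finite(values)),
            "event values must be finite (no NA/NaN/Inf)")
  if (is.null(channel_names)) {
    channel_names <- colnames(values)
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(values)))
  }
  cg_assert(length(channel_names) == ncol(values) && !anyDuplicated(channel_names),
            "channel names must be unique and match the number of columns")
  colnames(values) <- channel_names
  structure(
    list(values = values, channel_names = channel_names, space_tag = space_tag,
         n = nrow(values), d = ncol(values)),
    class = "event_table"
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events x %d channels [%s space]\n",
              x$n, x$d, x$space_tag))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  rng <- apply(x$values, 2, range)
  for (k in seq_len(x$d)) {
    cat(sprintf("  %s: [%.4g, %.4g]\n", x$channel_names[k], rng[1, k], rng[2, k]))
  }
  invisible(x)
}

#' Inverse hyperbolic sine transform
#'
#' The all-purpose skew-reducing transform used on raw cytometry intensities
#' before gating: `asinh(x) = log(x + sqrt(x^2 + 1))`. It is strictly
#' monotone, odd, behaves like `log(2x)` for large positive `x`, and is
#' defined for negative (compensated) values where `log` is not.
#'
#' @param x numeric vector/matrix of finite values.
#' @return The transformed values, same shape as `x`.
#' @examples
#' asinh_transform(c(0, 1, 1000))
#' @export
asinh_transform <- function(x) {
  cg_assert(is.numeric(x) && all(is.finite(x)),
            "asinh_transform: input must be finite numeric")
  asinh(x)
}

#' Remove boundary saturation pile-ups
#'
#' Cytometers clip events at the instrument range, producing large stacks of
#' events at a channel's exact minimum or maximum value. Such pile-ups are
#' debris for gating purposes: they create artificial density spikes at the
#' boundary. An event is removed when, for some channel, its value equals
#' that channel's observed minimum or maximum *and* that exact value occurs in
#' more than `threshold` of all events. Isolated extremes are kept.
#'
#' @param t an [event_table()] in original units.
#' @param threshold frequency in `(0, 1]` above which an exact extreme value
#'   counts as a pile-up; default 0.01 (1 percent of events).
#' @return list with `events` (the retained [event_table()]) and
#'   `debris_mask` (logical, `TRUE` = retained), aligned with the input rows.
#' @examples
#' x <- c(rnorm(900, 500, 50), rep(1023, 100))
#' out <- remove_boundary_debris(event_table(x))
#' sum(!out$debris_mask)  # 100 saturated events removed
#' @export
remove_boundary_debris <- function(t, threshold = 0.01) {
  cg_assert(inherits(t, "event_table"), "expected an event_table")
  cg_assert(is.numeric(threshold) && length(threshold) == 1 &&
              threshold > 0 && threshold <= 1,
            "debris threshold must lie in (0, 1]")
  keep <- rep(TRUE, t$n)
  for (k in seq_len(t$d)) {
    v <- t$values[, k]
    for (extreme in range(v)) {
      at <- v == extreme
      if (sum(at) > threshold * t$n) keep <- keep & !at
    }
  }
  if (!any(keep)) {
    cg_abort("boundary debris removal would discard every event (degenerate sample)")
  }
  list(
    events = event_table(t$values[keep, , drop = FALSE], t$channel_names,
                         space_tag = t$space_tag),
    debris_mask = keep
  )
}

#' Standardize channels to zero mean and unit standard deviation
#'
#' Gating operates in standardized coordinates so that a single scalar
#' bandwidth is meaningful across channels. The returned `scale_state`
#' records the per-channel affine maps (and the transform already applied)
#' so gates can be mapped back to original units exactly.
#'
#' @param t an [event_table()] with `n >= 2`.
#' @param transform the variance-stabilizing transform that was applied
#'   upstream (recorded for inversion): `"asinh"` or `"identity"`.
#' @param debris_mask optional logical mask over the pre-debris sample,
#'   carried in the state for provenance.
#' @return list with `events` (standardized [event_table()]) and `scale`
#'   (a `scale_state`: `center`, `scale`, `transform`, `debris_mask`).
#' @export
standardize_events <- function(t, transform = c("asinh", "identity"),
                               debris_mask = NULL) {
  transform <- match.arg(transform)
  cg_assert(inherits(t, "event_table"), "expected an event_table")
  cg_assert(t$n >= 2, "standardization needs at least 2 events")
  ctr <- colMeans(t$values)
  scl <- apply(t$values, 2, stats::sd)
  bad <- !is.finite(scl) | scl <= 0
  if (any(bad)) {
    cg_abort(sprintf("degenerate (constant) channel: %s",
                     paste(t$channel_names[bad], collapse = ", ")),
             class = "curvgate_degenerate_channel_error")
  }
  z <- sweep(sweep(t$values, 2, ctr, "-"), 2, scl, "/")
  state <- structure(
    list(center = ctr, scale = scl, transform = transform,
         debris_mask = debris_mask %||% rep(TRUE, t$n)),
    class = "scale_state"
  )
  list(events = event_table(z, t$channel_names, space_tag = "standardized"),
       scale = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map standardized coordinates back to original units: affine un-scaling then
# the inverse transform (sinh undoes asinh). Columns of `z` follow the
# channel order of the scale state.
unstandardize_coords <- function(z, s) {
  z <- as_event_matrix(z)
  x <- sweep(sweep(z, 2, s$scale, "*"), 2, s$center, "+")
  if (s$transform == "asinh") x <- sinh(x)
  x
}

# Forward map: original units -> standardized coordinates.
standardize_coords <- function(x, s) {
  x <- as_event_matrix(x)
  if (s$transform == "asinh") x <- asinh(x)
  sweep(sweep(x, 2, s$center, "-"), 2, s$scale, "/")
}

#' Map a gate region back to original measurement units
#'
#' Every vertex (or interval endpoint) of the region is pushed through the
#' inverse of the standardization pipeline: multiply by the channel standard
#' deviation, add the mean, then invert the variance-stabilizing transform
#' (`sinh` when `asinh` was used). Because `asinh` is nonlinear, straight
#' polygon edges and flat mesh faces map to curves; edges are therefore
#' densified (subdivided) before mapping so the original-units geometry tracks
#' the true curved image closely and event membership is preserved.
#'
#' @param region a [gate_region()] tagged `standardized`.
#' @param s a `scale_state` from [standardize_events()].
#' @param densify number of subdivisions per polygon edge (and rounds of
#'   midpoint triangle subdivision for meshes) applied before a nonlinear
#'   inverse map; ignored for the identity transform, where the map is affine
#'   and exact.
#' @return The region with all coordinates in original units and
#'   `space_tag = "original"`.
#' @export
to_original_units <- function(region, s, densify = 8) {
  cg_assert(inherits(region, "gate_region"), "expected a gate_region")
  cg_assert(inherits(s, "scale_state"), "expected a scale_state")
  cg_assert(identical(region$space_tag, "standardized"),
            sprintf("region is tagged '%s'; to_original_units expects 'standardized'",
                    region$space_tag))
  nonlinear <- s$transform != "identity"
  comps <- lapply(region$components, function(cmp) {
    switch(cmp$type,
      interval = {
        ends <- unstandardize_coords(matrix(c(cmp$lo, cmp$hi), ncol = 1), s)
        list(type = "interval", lo = ends[1], hi = ends[2])
      },
      polygon = {
        v <- cmp$vertices
        if (nonlinear && densify > 1) v <- densify_ring(v, densify)
        list(type = "polygon", vertices = unstandardize_coords(v, s))
      },
      trimesh = {
        m <- cmp
        if (nonlinear && densify > 1) {
          rounds <- max(1, ceiling(log2(densify) / 2))
          for (i in seq_len(rounds)) m <- subdivide_mesh(m)
        }
        list(type = "trimesh", vertices = unstandardize_coords(m$vertices, s),
             faces = m$faces)
      },
      cg_abort(sprintf("unknown component type '%s'", cmp$type))
    )
  })
  gate_region(region$d, comps, space_tag = "original")
}

# Insert `k - 1` intermediate points along each edge of a closed ring.
densify_ring <- function(v, k) {
  nseg <- nrow(v) - 1
  out <- matrix(0, nseg * k + 1, 2)
  row <- 1
  for (i in seq_len(nseg)) {
    a <- v[i, ]; b <- v[i + 1, ]
    for (j in 0:(k - 1)) {
      out[row, ] <- a + (j / k) * (b - a)
      row <- row + 1
    }
  }
  out[row, ] <- v[nrow(v), ]
  out
}

# One round of 1:4 midpoint subdivision of a triangle mesh (shared midpoints
# welded via edge keys, so the result stays closed).
subdivide_mesh <- function(m) {
  v <- m$vertices; f <- m$faces
  nv <- nrow(v)
  ekey <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
  e1 <- ekey(f[, 1], f[, 2]); e2 <- ekey(f[, 2], f[, 3]); e3 <- ekey(f[, 3], f[, 1])
  keys <- c(e1, e2, e3)
  uk <- unique(keys)
  mid_id <- nv + match(keys, uk)
  a <- c(f[, 1], f[, 2], f[, 3]); b <- c(f[, 2], f[, 3], f[, 1])
  mids <- matrix(0, length(uk), 3)
  first <- match(uk, keys)
  mids[] <- (v[a[first], ] + v[b[first], ]) / 2
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2 * nf + seq_len(nf)]
  faces <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(m12, f[, 2], m23),
    cbind(m31, m23, f[, 3]),
    cbind(m12, m23, m31)
  )
  list(type = "trimesh", vertices = rbind(v, mids), faces = faces)
}
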