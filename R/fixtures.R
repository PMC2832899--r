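# Synthetic flow-like samples with known ground truth. Populations are
# specified on the asinh (design) scale, where fluorescence populations are
# approximately Gaussian, and mapped to instrument units by sinh; uniform
# "debris" background and exact-value saturation pile-ups emulate the
# non-cell structure real samples carry.

#' Specify a synthetic sample
#'
#' @param d dimension (1-3).
#' @param n total number of events.
#' @param clusters list of cluster specs, each a list with `weight`, `mean`
#'   (length d) and `cov` (d x d positive definite), on the design scale.
#' @param debris_fraction expected fraction of uniform background events.
#' @param saturation_fraction expected fraction of events clamped to the
#'   saturation value on one channel.
#' @param saturation_value instrument saturation value in original units.
#' @param box 2 x d matrix (lo, hi) bounding the debris background on the
#'   design scale; default: cluster means padded by 2 units.
#' @param scale `"asinh"`: design coordinates are on the asinh scale and
#'   events are stored as `sinh(design)` in original units; `"identity"`:
#'   design coordinates are the original units.
#' @param seed integer seed; the sample is a pure function of the spec.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(d, n, clusters, debris_fraction = 0,
                        saturation_fraction = 0, saturation_value = 262143,
                        box = NULL, scale = c("asinh", "identity"), seed = 1L) {
  scale <- match.arg(scale)
  cg_assert(d %in% 1:3, "dimension must be 1, 2 or 3")
  cg_assert(n >= 1, "n must be >= 1")
  w <- vapply(clusters, function(cl) cl$weight, 0)
  cg_assert(all(w > 0), "cluster weights must be positive")
  cg_assert(debris_fraction >= 0 && debris_fraction < 1 &&
              saturation_fraction >= 0 && saturation_fraction < 1,
            "debris and saturation fractions must lie in [0, 1)")
  cg_assert(sum(w) + debris_fraction + saturation_fraction <= 1 + 1e-9,
            "cluster weights + debris + saturation must sum to at most 1")
  for (cl in clusters) {
    cg_assert(length(cl$mean) == d, "cluster mean has wrong dimension")
    cv <- matrix(as.numeric(cl$cov), d, d)
    ok <- tryCatch({ chol(cv); TRUE }, error = function(e) FALSE)
    cg_assert(ok, "cluster covariance must be positive definite")
  }
  if (is.null(box)) {
    mu <- do.call(rbind, lapply(clusters, function(cl) matrix(cl$mean, nrow = 1)))
    box <- rbind(apply(mu, 2, min) - 2, apply(mu, 2, max) + 2)
  }
  structure(
    list(d = d, n = as.integer(n), clusters = clusters,
         debris_fraction = debris_fraction,
         saturation_fraction = saturation_fraction,
         saturation_value = saturation_value, box = box, scale = scale,
         seed = as.integer(seed)),
    class = "sample_spec"
  )
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Draw a synthetic sample with ground-truth labels
#'
#' @param spec a [sample_spec()].
#' @return list with `events` (an [event_table()] in original units),
#'   `labels` (integer per event: cluster index, `-1` debris, `-2`
#'   saturation), `design` (the design-scale coordinates), and `spec`.
#' @export
simulate_sample <- function(spec) {
  cg_assert(inherits(spec, "sample_spec"), "expected a sample_spec")
  d <- spec$d
  with_seed(spec$seed, {
    w <- vapply(spec$clusters, function(cl) cl$weight, 0)
    probs <- c(w, spec$debris_fraction, spec$saturation_fraction)
    probs <- probs / sum(probs)
    src <- sample.int(length(probs), spec$n, replace = TRUE, prob = probs)
    k <- length(w)
    labels <- ifelse(src <= k, src, ifelse(src == k + 1, -1L, -2L))
    design <- matrix(0, spec$n, d)
    for (ci in seq_len(k)) {
      idx <- which(src == ci)
      if (length(idx) == 0) next
      cl <- spec$clusters[[ci]]
      L <- chol(matrix(as.numeric(cl$cov), d, d))
      design[idx, ] <- matrix(stats::rnorm(length(idx) * d), ncol = d) %*% L +
        matrix(cl$mean, length(idx), d, byrow = TRUE)
    }
    ndeb <- sum(src == k + 1)
    if (ndeb > 0) {
      u <- matrix(stats::runif(ndeb * d), ncol = d)
      design[src == k + 1, ] <- sweep(
        sweep(u, 2, spec$box[2, ] - spec$box[1, ], "*"), 2, spec$box[1, ], "+")
    }
    values <- if (spec$scale == "asinh") sinh(design) else design
    nsat <- sum(src == k + 2)
    if (nsat > 0) {
      idx <- which(src == k + 2)
      mix <- design[sample(which(src <= k + 1), nsat, replace = TRUE), , drop = FALSE]
      base <- if (spec$scale == "asinh") sinh(mix) else mix
      ch <- (seq_len(nsat) - 1L) %% d + 1L
      base[cbind(seq_len(nsat), ch)] <- spec$saturation_value
      values[idx, ] <- base
      design[idx, ] <- if (spec$scale == "asinh") asinh(base) else base
    }
    list(events = event_table(values, paste0("ch", seq_len(d))),
         labels = as.integer(labels), design = design, spec = spec)
  })
}

#' Capture and contamination of a gate result against known labels
#'
#' Each gate component is assigned to the cluster contributing the majority
#' of its member events; per cluster, `capture` is the fraction of the
#' cluster's events inside the union of its assigned components and
#' `contamination` is the fraction of those components' members coming from
#' other clusters, debris, or saturation.
#'
#' @param result a [curvhdr_filter()] result.
#' @param t the [event_table()] the result was computed on (original units).
#' @param labels integer labels from [simulate_sample()].
#' @return data.frame with one row per cluster: `cluster`, `capture`,
#'   `contamination`, `n_components`.
#' @export
gate_recovery_score <- function(result, t, labels) {
  cg_assert(length(labels) == t$n, "labels must align with the events")
  comps <- result$gate$components
  clusters <- sort(unique(labels[labels > 0]))
  masks <- lapply(comps, function(cmp) component_contains(cmp, t$values))
  assign <- vapply(masks, function(m) {
    lab <- labels[m & labels > 0]
    if (length(lab) == 0) return(NA_integer_)
    as.integer(names(which.max(table(lab))))
  }, integer(1))
  out <- data.frame(cluster = clusters, capture = 0, contamination = NA_real_,
                    n_components = 0L)
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    mine <- which(!is.na(assign) & assign == cl)
    out$n_components[i] <- length(mine)
    if (length(mine) == 0) next
    u <- Reduce(`|`, masks[mine])
    out$capture[i] <- sum(u & labels == cl) / sum(labels == cl)
    out$contamination[i] <- sum(u & labels != cl) / sum(u)
  }
  out
}

#' Canonical 1-D bimodal fixture
#'
#' Two fluorescence-like populations of unequal size on the asinh scale,
#' plus diffuse background and saturation pile-up.
#'
#' @param n events; @param seed seed.
#' @return As [simulate_sample()].
#' @export
fixture_bimodal_1d <- function(n = 10000, seed = 1L) {
  simulate_sample(sample_spec(
    d = 1, n = n,
    clusters = list(
      list(weight = 0.60, mean = 4.5, cov = matrix(0.35^2)),
      list(weight = 0.32, mean = 6.2, cov = matrix(0.25^2))
    ),
    debris_fraction = 0.05, saturation_fraction = 0.03, seed = seed
  ))
}

#' Canonical 2-D three-cluster fixture with a non-convex cluster
#'
#' Two roughly Gaussian populations plus a banana-shaped population built as
#' a 6-component Gaussian arc (weights peaked at the arc's middle so the
#' population has a single dominant mode), exercising the nonparametric
#' gate shapes the method is designed for. Cluster labels 1-8 with 3-8
#' forming the banana; use `banana_labels = TRUE` (default) to collapse the
#' arc components to a single cluster label 3.
#'
#' @param n events; @param seed seed.
#' @param banana_labels collapse the arc components to one label.
#' @return As [simulate_sample()].
#' @export
fixture_three_cluster_2d <- function(n = 20000, seed = 1L, banana_labels = TRUE) {
  ang <- seq(200, 340, length.out = 6) * pi / 180
  ctr <- c(6, 7.4); rad <- 1.2
  wts <- c(1, 2, 3, 3, 2, 1); wts <- 0.35 * wts / sum(wts)
  arc <- lapply(seq_along(ang), function(i) {
    list(weight = wts[i],
         mean = ctr + rad * c(cos(ang[i]), sin(ang[i])),
         cov = diag(0.18^2, 2))
  })
  fx <- simulate_sample(sample_spec(
    d = 2, n = n,
    clusters = c(
      list(list(weight = 0.30, mean = c(4.5, 4.5), cov = diag(0.4^2, 2)),
           list(weight = 0.25, mean = c(7.5, 4.3), cov = diag(c(0.35^2, 0.45^2)))),
      arc
    ),
    debris_fraction = 0.07, saturation_fraction = 0.03, seed = seed
  ))
  if (banana_labels) fx$labels[fx$labels >= 3] <- 3L
  fx
}

#' Canonical 3-D two-cluster fixture with debris
#'
#' @param n events; @param seed seed.
#' @return As [simulate_sample()].
#' @export
fixture_two_cluster_3d <- function(n = 8000, seed = 1L) {
  simulate_sample(sample_spec(
    d = 3, n = n,
    clusters = list(
      list(weight = 0.45, mean = c(4.5, 4.5, 4.5), cov = diag(0.40^2, 3)),
      list(weight = 0.40, mean = c(6.5, 6.0, 5.0), cov = diag(0.35^2, 3))
    ),
    debris_fraction = 0.10, saturation_fraction = 0.05, seed = seed
  ))
}
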