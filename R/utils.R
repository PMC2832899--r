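# Internal helpers shared across modules.

# Classed conditions so callers (and the CLI) can distinguish user input
# problems (exit code 2) from internal failures.
cg_abort <- function(msg, class = "curvgate_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "curvgate_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

cg_assert <- function(cond, msg, class = "curvgate_validation_error") {
  if (!isTRUE(cond)) cg_abort(msg, class = class)
  invisible(TRUE)
}

is_finite_matrix <- function(x) is.numeric(x) && all(is.finite(x))

# Coerce event input (vector / data.frame / matrix) to a numeric matrix.
as_event_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

## ---- half-vectorization bookkeeping -------------------------------------

# Index pairs (i, j), i >= j, column-major lower triangle: the order in which
# Hessian entries are stacked into vech().
vech_pairs <- function(d) {
  out <- NULL
  for (j in seq_len(d)) for (i in j:d) out <- rbind(out, c(i, j))
  out
}

## ---- separable Gaussian kernel machinery --------------------------------

# phi^(r)(u) for the standard normal density, r in 0,1,2,4,6 (Hermite form).
gauss_deriv <- function(u, r) {
  p <- switch(as.character(r),
    "0" = 1,
    "1" = -u,
    "2" = u^2 - 1,
    "4" = u^4 - 6 * u^2 + 3,
    "6" = u^6 - 15 * u^4 + 45 * u^2 - 15,
    cg_abort(sprintf("unsupported derivative order %s", r),
             class = "curvgate_internal_error")
  )
  p * stats::dnorm(u)
}

# Dense kernel matrix A[i, j] = phi_h^{(r)}(g_i - g_j) for grid coordinates g.
# Scaled derivative: phi_h^{(r)}(x) = h^{-(r+1)} phi^{(r)}(x / h).
kernel_matrix <- function(g, h, r = 0) {
  u <- outer(g, g, "-") / h
  gauss_deriv(u, r) / h^(r + 1)
}

# Apply one matrix per axis to a d-dimensional array (separable convolution).
sep_apply <- function(arr, mats) {
  d <- length(mats)
  if (d == 1) {
    out <- as.vector(mats[[1]] %*% as.vector(arr))
    return(array(out, dim = length(out)))
  }
  x <- arr
  for (k in seq_len(d)) {
    perm <- c(k, setdiff(seq_len(d), k))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- mats[[k]] %*% matrix(xp, nrow = dp[1])
    x <- aperm(array(m, dp), order(perm))
  }
  x
}

## ---- grid <-> point transfer --------------------------------------------

# Multilinear interpolation of a grid field at points (m x d), the gather
# counterpart of linear binning. Points outside the grid get `outside`.
grid_interp <- function(field, grid, points, outside = 0) {
  points <- as_event_matrix(points)
  d <- length(grid$nodes)
  m <- nrow(points)
  pos <- sweep(sweep(points, 2, grid$lo, "-"), 2, grid$spacing, "/")
  inb <- rep(TRUE, m)
  for (k in seq_len(d)) {
    inb <- inb & pos[, k] >= -1e-9 & pos[, k] <= grid$nodes[k] - 1 + 1e-9
  }
  i0 <- matrix(0L, m, d)
  fr <- matrix(0, m, d)
  for (k in seq_len(d)) {
    i <- pmin.int(pmax.int(floor(pos[, k]), 0), grid$nodes[k] - 2L)
    i0[, k] <- as.integer(i)
    fr[, k] <- pos[, k] - i
  }
  stride <- cumprod(c(1, grid$nodes[-d]))
  vals <- numeric(m)
  for (corner in 0:(2^d - 1)) {
    bits <- as.integer(intToBits(corner))[seq_len(d)]
    w <- rep(1, m)
    lin <- rep(1, m)
    for (k in seq_len(d)) {
      w <- w * if (bits[k] == 1L) fr[, k] else 1 - fr[, k]
      lin <- lin + (i0[, k] + bits[k]) * stride[k]
    }
    vals <- vals + w * field[lin]
  }
  vals[!inb] <- outside
  vals
}

# Deterministic, irrational-slope directions for ray casting (no RNG use).
ray_directions <- function(k) {
  base <- c(0.57735026918962573, 0.62017367294604225, 0.53148794521398767)
  ang <- (k - 1) * 2.399963229728653  # golden angle: successive retries differ
  rot <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  v <- as.vector(rot %*% base) + (k - 1) * 1e-3 * c(0.1234, -0.4321, 0.3141)
  v / sqrt(sum(v^2))
}
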