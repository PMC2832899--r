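test_that("default curvature bandwidth evaluates the recommended formula", {
  expect_equal(default_curvature_bandwidth(1, 1000), (4 / 7000)^(1 / 9),
               tolerance = 1e-12)
  expect_equal(default_curvature_bandwidth(1, 1000), 0.4362, tolerance = 1e-4)
  expect_equal(default_curvature_bandwidth(2, 10000), (5e-5)^(1 / 10),
               tolerance = 1e-12)
  expect_equal(default_curvature_bandwidth(2, 10000), 0.3715, tolerance = 2e-4)
  for (d in 1:3) {
    h <- sapply(c(100, 1000, 10000, 1e5), function(n) default_curvature_bandwidth(d, n))
    expect_true(all(diff(h) < 0))
  }
})

test_that("linear binning distributes mass multilinearly and conserves it", {
  g <- make_grid_spec(rbind(0, 10), 1, 11, pad = 0, from_range = TRUE)
  # point exactly on a node
  b <- linear_bin(matrix(3), g)
  expect_equal(b$counts[4], 1)
  expect_equal(sum(b$counts), 1)
  # point midway between nodes
  b2 <- linear_bin(matrix(3.5), g)
  expect_equal(b2$counts[4], 0.5)
  expect_equal(b2$counts[5], 0.5)
  # conservation on a random cloud, d = 2
  set.seed(1)
  x <- matrix(rnorm(1000), ncol = 2)
  g2 <- make_grid_spec(x, 0.3, 41)
  b3 <- linear_bin(x, g2)
  expect_equal(b3$n_eff, 500, tolerance = 1e-9)
  expect_equal(b3$n_lost, 0)
  # out-of-bounds points are lost, not an error
  g3 <- make_grid_spec(rbind(c(-1, -1), c(1, 1)), 0.1, 11, pad = 0, from_range = TRUE)
  b4 <- linear_bin(rbind(c(0, 0), c(5, 5)), g3)
  expect_equal(b4$n_lost, 1)
  expect_equal(b4$n_eff, 1)
})

test_that("binned KDE matches single-kernel peaks and the direct sum", {
  for (d in 1:2) {
    g <- make_grid_spec(matrix(0, 1, d), 1, 101, pad = 5)
    b <- linear_bin(matrix(0, 1, d), g)
    f <- kde_on_grid(b$counts, g, 1)
    expect_equal(curvgate:::grid_interp(f, g, matrix(0, 1, d)),
                 (2 * pi)^(-d / 2), tolerance = 1e-6)
  }
  # direct-sum oracle at fine spacing, in-support nodes
  set.seed(2)
  x <- matrix(rnorm(400), ncol = 2)
  h <- 0.5
  g <- make_grid_spec(x, h, 401)
  b <- linear_bin(x, g)
  fh <- as.vector(kde_on_grid(b$counts, g, h, n = 200))
  co <- curvgate:::grid_coords(g)
  keep <- fh > 0.01 * max(fh)
  direct <- direct_kde(co[keep, , drop = FALSE], x, h)
  expect_lt(max(abs(fh[keep] - direct) / direct), 1e-3)
  expect_error(kde_on_grid(b$counts, g, -1), class = "curvgate_validation_error")
})

test_that("binned KDE integrates to one with adequate padding", {
  set.seed(3)
  x <- matrix(rnorm(10000), ncol = 1)
  h <- default_curvature_bandwidth(1, 10000)
  g <- make_grid_spec(x, h, 151)
  b <- linear_bin(x, g)
  f <- kde_on_grid(b$counts, g, h)
  expect_gt(sum(f) * prod(g$spacing), 0.98)
  expect_lt(sum(f) * prod(g$spacing), 1.02)
})

test_that("kernel Hessian matches closed forms and is symmetric by construction", {
  # single point at the origin, d = 1: f''(0) = -(2*pi)^(-1/2)
  g <- make_grid_spec(matrix(0), 1, 101, pad = 5)
  b <- linear_bin(matrix(0), g)
  hh <- hessian_on_grid(b$counts, g, 1)
  expect_equal(curvgate:::grid_interp(hh[[1]], g, matrix(0)),
               -(2 * pi)^(-1 / 2), tolerance = 1e-6)

  # large-n standard normal, d = 2: H(0) ~ -(2*pi)^(-1) I after smoothing bias
  set.seed(4)
  n <- 40000
  x <- matrix(rnorm(2 * n), ncol = 2)
  h <- default_curvature_bandwidth(2, n)
  g2 <- make_grid_spec(x, h, 151)
  b2 <- linear_bin(x, g2)
  hh2 <- hessian_on_grid(b2$counts, g2, h)
  at0 <- sapply(hh2, function(a) curvgate:::grid_interp(a, g2, matrix(0, 1, 2)))
  expect_equal(at0[1], -(2 * pi)^(-1), tolerance = 0.25)
  expect_equal(at0[3], -(2 * pi)^(-1), tolerance = 0.25)
  expect_lt(abs(at0[2]), 0.25 * (2 * pi)^(-1))
  # shared storage of the symmetric entries
  pairs <- attr(hh2, "pairs")
  expect_equal(pairs, rbind(c(1, 1), c(2, 1), c(2, 2)))

  # direct-sum oracle for a second derivative entry (d = 1, small n)
  set.seed(5)
  x1 <- matrix(rnorm(100), ncol = 1)
  g3 <- make_grid_spec(x1, 0.6, 401)
  b3 <- linear_bin(x1, g3)
  h3 <- as.vector(hessian_on_grid(b3$counts, g3, 0.6)[[1]])
  co <- curvgate:::grid_coords(g3)
  direct <- sapply(co[, 1], function(u) {
    mean(((u - x1[, 1])^2 / 0.6^4 - 1 / 0.6^2) * dnorm(u, x1[, 1], 0.6))
  })
  expect_lt(max(abs(h3 - direct)), 1e-3 * max(abs(direct)))
})

test_that("curvature test flags modes, skips saddles, and ignores event order", {
  set.seed(6)
  z <- matrix(rnorm(20000), ncol = 2)
  fld <- curvature_field(z, default_curvature_bandwidth(2, 10000))
  expect_gt(sum(fld$sig_neg_curv), 0)
  co <- curvgate:::grid_coords(fld$grid)
  expect_true(as.vector(fld$sig_neg_curv)[which.min(rowSums(co^2))])

  # permutation invariance of the flagged set
  fld2 <- curvature_field(z[sample(nrow(z)), ], default_curvature_bandwidth(2, 10000))
  expect_identical(fld$sig_neg_curv, fld2$sig_neg_curv)

  # two equal clusters 6 sd apart: the saddle midpoint is not flagged
  set.seed(7)
  zz <- rbind(sweep(matrix(rnorm(10000), ncol = 2), 2, c(-3, 0), "+"),
              sweep(matrix(rnorm(10000), ncol = 2), 2, c(3, 0), "+"))
  zz <- scale(zz)
  flds <- curvature_field(zz, 0.35)
  cos <- curvgate:::grid_coords(flds$grid)
  expect_false(as.vector(flds$sig_neg_curv)[which.min(rowSums(cos^2))])
  expect_equal(length(indicator_to_regions(flds$sig_neg_curv, flds$grid)), 2)
})

test_that("pointwise flag rate is controlled in genuinely flat regions", {
  # uniform data with a bandwidth small enough that the deep interior is
  # many bandwidths from the support edge: there H = 0 truly holds
  set.seed(8)
  rates <- sapply(1:3, function(r) {
    u <- matrix(runif(2 * 50000), ncol = 2)
    z <- scale(u)
    fld <- curvature_field(z, 0.12, nodes = 151, adjustment = "pointwise")
    co <- curvgate:::grid_coords(fld$grid)
    interior <- abs(co[, 1]) < sqrt(3) - 0.6 & abs(co[, 2]) < sqrt(3) - 0.6
    mean(as.vector(fld$sig_neg_curv)[interior])
  })
  expect_lt(mean(rates), 0.05 + 2 * sqrt(0.05 * 0.95 / (3 * 1225)))
})
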