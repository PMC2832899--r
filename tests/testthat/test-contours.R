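test_that("indicator grids convert to intervals, polygons and meshes", {
  # d = 1: maximal runs of flagged nodes
  g1 <- make_grid_spec(rbind(0, 10), 1, 11, pad = 0, from_range = TRUE)
  flags <- array(c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                   TRUE, FALSE), 11)
  regs <- indicator_to_regions(flags, g1, min_region_nodes = 3)
  expect_length(regs, 2)
  expect_equal(regs[[1]], list(type = "interval", lo = 2, hi = 4))
  expect_equal(regs[[2]], list(type = "interval", lo = 6, hi = 9))
  # short runs are dropped by the support filter
  expect_length(indicator_to_regions(flags, g1, min_region_nodes = 5), 0)
  expect_length(indicator_to_regions(array(FALSE, 11), g1), 0)

  # d = 2: a centered disk indicator gives one polygon of the disk's area
  g2 <- make_grid_spec(rbind(c(-2, -2), c(2, 2)), 0.1, 101, pad = 0,
                       from_range = TRUE)
  co <- curvgate:::grid_coords(g2)
  disk <- array(sqrt(rowSums(co^2)) <= 1, g2$nodes)
  r2 <- indicator_to_regions(disk, g2)
  expect_length(r2, 1)
  expect_equal(polygon_area(r2[[1]]), pi, tolerance = 0.05)

  # two disjoint blobs give two components
  two <- array(sqrt(rowSums(sweep(co, 2, c(-1, 0))^2)) <= 0.5 |
                 sqrt(rowSums(sweep(co, 2, c(1, 0))^2)) <= 0.5, g2$nodes)
  expect_length(indicator_to_regions(two, g2), 2)

  # d = 3: a ball indicator gives one closed mesh of the ball's volume
  g3 <- make_grid_spec(rbind(c(-1.5, -1.5, -1.5), c(1.5, 1.5, 1.5)), 0.1, 41,
                       pad = 0, from_range = TRUE)
  co3 <- curvgate:::grid_coords(g3)
  ball <- array(sqrt(rowSums(co3^2)) <= 1, g3$nodes)
  r3 <- indicator_to_regions(ball, g3)
  expect_length(r3, 1)
  expect_equal(trimesh_volume(r3[[1]]), 4 * pi / 3, tolerance = 0.05)
})

test_that("flagged nodes are recovered inside their extracted components", {
  set.seed(11)
  for (d in 2:3) {
    nn <- if (d == 2) 61 else 31
    g <- make_grid_spec(matrix(rep(c(-2, 2), d), 2, d, byrow = FALSE), 0.1, nn,
                        pad = 0, from_range = TRUE)
    co <- curvgate:::grid_coords(g)
    ctr <- rnorm(d, sd = 0.3)
    flags <- array(sqrt(rowSums(sweep(co, 2, ctr)^2)) <= 1, g$nodes)
    comps <- indicator_to_regions(flags, g, min_region_nodes = 1)
    nodes <- co[as.vector(flags), , drop = FALSE]
    inside <- components_contain(comps, nodes)
    # one-cell tolerance: nodes not strictly inside must be within one
    # spacing of a node that is
    if (!all(inside)) {
      off <- nodes[!inside, , drop = FALSE]
      on <- nodes[inside, , drop = FALSE]
      mind <- apply(off, 1, function(p) {
        min(sqrt(rowSums(sweep(on, 2, p)^2)))
      })
      expect_lt(max(mind), max(g$spacing) * sqrt(d) + 1e-12)
    } else {
      expect_true(all(inside))
    }
  }
})

test_that("density super-level sets match closed-form normal regions", {
  # d = 1 standard normal density on a grid, level f(1.6449)
  g <- make_grid_spec(rbind(-5, 5), 1, 501, pad = 0, from_range = TRUE)
  f <- array(dnorm(curvgate:::grid_coords(g)[, 1]), g$nodes)
  regs <- density_level_regions(f, dnorm(1.6449), g)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$lo, -1.6449, tolerance = 0.02)
  expect_equal(regs[[1]]$hi, 1.6449, tolerance = 0.02)

  # level just below the maximum: one tiny component at the mode
  regs2 <- density_level_regions(f, dnorm(0) * 0.999, g)
  expect_length(regs2, 1)
  expect_lt(regs2[[1]]$hi - regs2[[1]]$lo, 0.2)
  # level at/above the maximum: empty
  expect_length(density_level_regions(f, dnorm(0), g), 0)
  expect_error(density_level_regions(f, -1, g), class = "curvgate_validation_error")

  # bimodal equal mixture, level above the saddle density: two components
  gb <- make_grid_spec(rbind(-6, 6), 1, 601, pad = 0, from_range = TRUE)
  xb <- curvgate:::grid_coords(gb)[, 1]
  fb <- array(0.5 * dnorm(xb, -2) + 0.5 * dnorm(xb, 2), gb$nodes)
  saddle <- 0.5 * dnorm(0, -2) + 0.5 * dnorm(0, 2)
  expect_length(density_level_regions(fb, saddle * 1.5, gb), 2)
  expect_length(density_level_regions(fb, saddle * 0.5, gb), 1)
})

test_that("marching tetrahedra meshes are watertight with exact volume sums", {
  # iso-surface of a trivariate normal at a known level: volume of the
  # enclosed ball of radius r is recovered
  g <- make_grid_spec(rbind(c(-4, -4, -4), c(4, 4, 4)), 0.1, 51, pad = 0,
                      from_range = TRUE)
  co <- curvgate:::grid_coords(g)
  f <- array((2 * pi)^(-3 / 2) * exp(-rowSums(co^2) / 2), g$nodes)
  r <- 1.8
  lev <- (2 * pi)^(-3 / 2) * exp(-r^2 / 2)
  comps <- density_level_regions(f, lev, g)
  expect_length(comps, 1)
  expect_silent(curvgate:::validate_closed_mesh(comps[[1]]))
  expect_equal(trimesh_volume(comps[[1]]), 4 / 3 * pi * r^3, tolerance = 0.02)
})
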