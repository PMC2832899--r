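test_that("shoelace area matches known shapes and a Monte-Carlo oracle", {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 0))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "curvgate_degenerate_error")

  set.seed(1)
  p <- random_convex_polygon(9)
  a <- polygon_area(p)
  lo <- apply(p$vertices, 2, min); hi <- apply(p$vertices, 2, max)
  ndraw <- 1e5
  q <- cbind(runif(ndraw, lo[1], hi[1]), runif(ndraw, lo[2], hi[2]))
  phit <- mean(points_in_polygon(q, p))
  box <- prod(hi - lo)
  mc_err <- sqrt(phit * (1 - phit) / ndraw) * box
  expect_lt(abs(a - phit * box), 3 * mc_err)
})

test_that("mesh volume matches known solids and a Monte-Carlo oracle", {
  cube <- unit_cube_mesh()
  expect_equal(trimesh_volume(cube), 1, tolerance = 1e-12)
  expect_equal(nrow(cube$faces), 12)
  tet <- convex_hull(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(trimesh_volume(tet), 1 / 6, tolerance = 1e-12)

  open_mesh <- list(type = "trimesh", vertices = cube$vertices,
                    faces = cube$faces[-1, ])
  expect_error(trimesh_volume(open_mesh), class = "curvgate_open_mesh_error")

  set.seed(2)
  m <- random_convex_mesh(50)
  v <- trimesh_volume(m)
  lo <- apply(m$vertices, 2, min); hi <- apply(m$vertices, 2, max)
  ndraw <- 2e5
  q <- cbind(runif(ndraw, lo[1], hi[1]), runif(ndraw, lo[2], hi[2]),
             runif(ndraw, lo[3], hi[3]))
  phit <- mean(points_in_polyhedron(q, m))
  box <- prod(hi - lo)
  mc_err <- sqrt(phit * (1 - phit) / ndraw) * box
  expect_lt(abs(v - phit * box), 3 * mc_err)
})

test_that("convex hulls contain their inputs and are idempotent", {
  set.seed(3)
  # square corners plus interior points hull to the square
  pts <- rbind(as.matrix(expand.grid(0:1, 0:1)), matrix(runif(40), ncol = 2))
  p <- convex_hull(pts)
  expect_equal(polygon_area(p), 1, tolerance = 1e-12)
  expect_equal(nrow(p$vertices) - 1, 4)
  p2 <- convex_hull(p)
  expect_equal(polygon_area(p2), polygon_area(p), tolerance = 1e-12)

  # d = 1 and degenerate cases
  expect_equal(convex_hull(matrix(c(3, 1, 2), ncol = 1)),
               list(type = "interval", lo = 1, hi = 3))
  expect_error(convex_hull(cbind(1:5, 1:5)), class = "curvgate_degenerate_error")
  expect_error(convex_hull(cbind(1:5, 1:5, 0)), class = "curvgate_degenerate_error")

  for (i in 1:5) {
    pts3 <- matrix(rnorm(3 * 40), ncol = 3)
    m <- convex_hull(pts3)
    expect_true(all(points_in_polyhedron(pts3, m)))
    m2 <- convex_hull(m)
    expect_equal(trimesh_volume(m2), trimesh_volume(m), tolerance = 1e-9)
  }
})

test_that("region growth hits the target ratio and contains the input", {
  expect_equal(grow_region(list(type = "interval", lo = 0, hi = 1), 2),
               list(type = "interval", lo = -0.5, hi = 1.5))
  expect_error(grow_region(list(type = "interval", lo = 0, hi = 1), 1),
               class = "curvgate_validation_error")

  sq <- convex_hull(as.matrix(expand.grid(0:1, 0:1)))
  gp <- grow_region(sq, 4)
  expect_equal(polygon_area(gp) / polygon_area(sq), 4, tolerance = 0.005)
  expect_true(all(points_in_polygon(sq$vertices, gp)))

  ico <- regular_icosahedron()
  gm <- grow_region(ico, 8)
  expect_equal(trimesh_volume(gm) / trimesh_volume(ico), 8, tolerance = 0.005)
  expect_true(all(points_in_polyhedron(ico$vertices, gm)))
})

test_that("polygon containment agrees with a winding-number oracle", {
  set.seed(4)
  for (rep in 1:4) {
    p <- random_convex_polygon(sample(5:11, 1), scale = runif(1, 0.5, 2),
                               shift = rnorm(2, sd = 2))
    q <- cbind(runif(2500, -6, 6), runif(2500, -6, 6))
    got <- points_in_polygon(q, p)
    want <- vapply(seq_len(nrow(q)), function(i) winding_inside(q[i, ], p$vertices),
                   logical(1))
    expect_identical(got, want)
  }
  # centroid inside, far point outside, boundary point inside
  p <- random_convex_polygon(8)
  ctr <- colMeans(p$vertices[-nrow(p$vertices), ])
  expect_true(points_in_polygon(matrix(ctr, 1), p))
  expect_false(points_in_polygon(matrix(c(100, 100), 1), p))
  expect_true(all(points_in_polygon(p$vertices, p)))
})

test_that("polyhedron containment agrees with a half-space oracle", {
  cube <- unit_cube_mesh()
  expect_true(points_in_polyhedron(matrix(c(0.5, 0.5, 0.5), 1), cube))
  expect_false(points_in_polyhedron(matrix(c(2, 2, 2), 1), cube))
  expect_true(all(points_in_polyhedron(cube$vertices, cube)))

  set.seed(5)
  for (rep in 1:4) {
    m <- random_convex_mesh(sample(15:40, 1), scale = runif(1, 0.5, 1.5))
    q <- matrix(runif(3 * 2500, -3, 3), ncol = 3)
    expect_identical(points_in_polyhedron(q, m), halfspace_inside(q, m))
  }
})

test_that("geometry is invariant under rigid translation", {
  set.seed(6)
  p <- random_convex_polygon(9)
  sh <- c(13.7, -4.2)
  p2 <- list(type = "polygon", vertices = sweep(p$vertices, 2, sh, "+"))
  expect_equal(polygon_area(p2), polygon_area(p), tolerance = 1e-9)
  q <- matrix(runif(500 * 2, -3, 3), ncol = 2)
  expect_identical(points_in_polygon(sweep(q, 2, sh, "+"), p2),
                   points_in_polygon(q, p))

  m <- random_convex_mesh(25)
  sh3 <- c(-7, 3, 11)
  m2 <- list(type = "trimesh", vertices = sweep(m$vertices, 2, sh3, "+"),
             faces = m$faces)
  expect_equal(trimesh_volume(m2), trimesh_volume(m), tolerance = 1e-9)
})
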