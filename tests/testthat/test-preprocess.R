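test_that("asinh transform matches its closed form and inverts exactly", {
  expect_identical(asinh_transform(0), 0)
  expect_equal(asinh_transform(1), log(1 + sqrt(2)), tolerance = 1e-12)
  x <- c(-1e4, -1, 0.5, 1e4)
  expect_equal(sinh(asinh_transform(x)), x, tolerance = 1e-10)
  expect_true(all(diff(asinh_transform(seq(-5, 5, by = 0.1))) > 0))
  expect_error(asinh_transform(c(1, NA)), class = "curvgate_validation_error")
  expect_error(asinh_transform(Inf), class = "curvgate_validation_error")
})

test_that("event tables validate their invariants", {
  expect_error(event_table(matrix(c(1, NaN), 1)), class = "curvgate_validation_error")
  expect_error(event_table(matrix(1, 2, 4)), class = "curvgate_validation_error")
  expect_error(event_table(matrix(1:4, 2), channel_names = c("a", "a")),
               class = "curvgate_validation_error")
  et <- event_table(1:5)
  expect_equal(et$d, 1)
  expect_equal(et$channel_names, "ch1")
})

test_that("boundary debris removal strips exact saturation pile-ups only", {
  x <- c(rnorm(850, 500, 40), rep(1023, 150))
  out <- remove_boundary_debris(event_table(x))
  expect_equal(sum(!out$debris_mask), 150)
  expect_equal(out$events$n, 850)
  expect_false(any(out$events$values == 1023))

  # no repeated extremes: identity
  y <- seq_len(1000) + 0.5
  out2 <- remove_boundary_debris(event_table(y))
  expect_true(all(out2$debris_mask))

  # degenerate: everything would be removed
  expect_error(remove_boundary_debris(event_table(rep(7, 50))),
               class = "curvgate_validation_error")
  expect_error(remove_boundary_debris(event_table(x), threshold = 0),
               class = "curvgate_validation_error")
  expect_error(remove_boundary_debris(event_table(x), threshold = 1.5),
               class = "curvgate_validation_error")
})

test_that("debris removal commutes with row permutation", {
  set.seed(7)
  x <- cbind(c(rnorm(300), rep(1023, 60)), c(rnorm(340), rep(0, 20)))
  perm <- sample(nrow(x))
  m1 <- remove_boundary_debris(event_table(x))$debris_mask
  m2 <- remove_boundary_debris(event_table(x[perm, ]))$debris_mask
  expect_identical(m1[perm], m2)
})

test_that("standardization yields exact zero mean and unit sd per channel", {
  set.seed(1)
  t <- event_table(cbind(rnorm(500, 10, 3), rexp(500, 0.2)))
  out <- standardize_events(t, transform = "identity")
  z <- out$events$values
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_identical(out$events$space_tag, "standardized")

  # idempotence (already standardized input maps to ~identity scale state)
  out2 <- standardize_events(out$events, transform = "identity")
  expect_lt(max(abs(out2$scale$center)), 1e-12)
  expect_equal(unname(out2$scale$scale), c(1, 1), tolerance = 1e-12)

  # symmetric three-point channel
  s3 <- standardize_events(event_table(c(1, 2, 3)), transform = "identity")
  expect_equal(as.vector(s3$events$values), c(-1, 0, 1))

  expect_error(standardize_events(event_table(cbind(1:5, rep(2, 5))),
                                  transform = "identity"),
               class = "curvgate_degenerate_channel_error")
})

test_that("forward pipeline composed with the inverse reproduces raw values", {
  set.seed(2)
  for (d in 1:3) {
    raw <- matrix(rexp(300 * d, rate = 0.01), ncol = d)
    t <- event_table(raw)
    tr <- event_table(asinh_transform(raw), t$channel_names,
                      space_tag = "transformed")
    std <- standardize_events(tr, transform = "asinh")
    back <- curvgate:::unstandardize_coords(std$events$values, std$scale)
    expect_equal(back, raw, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("gate regions map back to original units exactly for affine scales", {
  s <- structure(list(center = c(5, 0), scale = c(2, 1), transform = "identity",
                      debris_mask = TRUE), class = "scale_state")
  reg <- gate_region(1, list(list(type = "interval", lo = -1, hi = 1)))
  s1 <- structure(list(center = 5, scale = 2, transform = "identity",
                       debris_mask = TRUE), class = "scale_state")
  out <- to_original_units(reg, s1)
  expect_equal(out$components[[1]]$lo, 3)
  expect_equal(out$components[[1]]$hi, 7)
  expect_identical(out$space_tag, "original")

  # square round trip: standardize the vertices, map back
  sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 0))
  z <- curvgate:::standardize_coords(sq, s)
  reg2 <- gate_region(2, list(curvgate:::make_polygon(z)))
  back <- to_original_units(reg2, s)
  v <- back$components[[1]]$vertices
  expect_equal(sort(unique(round(v[, 1], 9))), c(0, 1))
  expect_equal(sort(unique(round(v[, 2], 9))), c(0, 1))

  expect_error(to_original_units(out, s1), class = "curvgate_validation_error")
})

test_that("unit mapping preserves event membership", {
  set.seed(3)
  raw <- matrix(rexp(1000 * 2, rate = 0.01), ncol = 2)
  tr <- event_table(asinh_transform(raw), space_tag = "transformed")
  std <- standardize_events(tr, transform = "asinh")
  z <- std$events$values
  p <- convex_hull(z[sample(nrow(z), 40), ])
  reg_std <- gate_region(2, list(p))
  memb_std <- gate_membership(reg_std, std$events)
  reg_orig <- to_original_units(reg_std, std$scale)
  memb_orig <- gate_membership(reg_orig, event_table(raw))
  expect_identical(memb_std, memb_orig)
})
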