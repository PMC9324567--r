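test_that("to_world applies rigid transforms", {
  expect_equal(to_world(pose(), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(to_world(pose(c(1, 0, 0)), c(0, 0, 0)), c(1, 0, 0))
  q <- quat_axis_angle(c(0, 0, 1), pi / 2)
  expect_equal(to_world(pose(c(0, 0, 0), q), c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-9)
})

test_that("rigid transforms preserve pairwise distances", {
  set.seed(1)
  for (i in 1:20) {
    ax <- stats::rnorm(3)
    p <- pose(stats::rnorm(3), quat_axis_angle(ax, stats::runif(1, 0, 2 * pi)))
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    d0 <- sqrt(sum((a - b)^2))
    d1 <- sqrt(sum((to_world(p, a) - to_world(p, b))^2))
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("pose validation rejects non-unit quaternions", {
  expect_error(pose(c(0, 0, 0), c(1, 1, 0, 0)), "unit quaternion")
})

test_that("overlap detects obstruction symmetrically", {
  sq <- tile_shape("polygon2D",
                   rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  same <- pose()
  far <- pose(c(10, 0, 0))
  near <- pose(c(0, 0, 0.005))
  expect_true(overlap(sq, same, sq, same, clearance = 0.01))
  expect_false(overlap(sq, same, sq, far, clearance = 0.01))
  # parallel unit squares 0.005 apart: analytic plane distance 0.005
  expect_true(overlap(sq, same, sq, near, clearance = 0.01))
  expect_identical(overlap(sq, same, sq, far, 0.01),
                   overlap(sq, far, sq, same, 0.01))
})

test_that("brownian_step moves by exactly the step length", {
  expect_equal(brownian_step(c(1, 2, 3), 0), c(1, 2, 3))
  set.seed(2)
  p <- brownian_step(c(0, 0, 0), 1)
  expect_equal(sqrt(sum(p^2)), 1, tolerance = 1e-9)
  n <- 1e4
  pts <- brownian_step(matrix(0, n, 3), 1)
  expect_equal(sqrt(rowSums(pts^2)), rep(1, n), tolerance = 1e-9)
  # isotropy: mean displacement vanishes like 1/sqrt(n)
  expect_lt(max(abs(colMeans(pts))), 0.05)
})

test_that("brownian_step reflects into the bounding box", {
  set.seed(3)
  b <- rbind(c(-1, -1, -1), c(1, 1, 1))
  pts <- brownian_step(matrix(0.95, 50, 3), 0.5, bounds = b)
  expect_true(all(pts >= -1 & pts <= 1))
})

test_that("tile shapes validate their geometry", {
  expect_error(tile_shape("polygon2D", rbind(c(0, 0, 0), c(1, 0, 0))),
               ">= 3 vertices")
  expect_error(tile_shape("polygon2D",
                          rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0.1))),
               "coplanar")
  expect_error(tile_shape("rod1D", rbind(c(0, 0, 0), c(0, 0, 0))),
               "length")
  oct <- tile_shape_regular_polygon(8)
  edge <- sqrt(sum((oct$vertices[1, ] - oct$vertices[2, ])^2))
  expect_equal(edge, 1, tolerance = 1e-9)
})
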