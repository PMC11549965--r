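make_ring_cavity <- function(radius = 10, zs = -2:2, n = 36, el = "C") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  xyz <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(th), radius * sin(th), z)))
  list(xyz = xyz, elements = el)
}

zaxis <- list(point = c(0, 0, 0), dir = c(0, 0, 1))

test_that("a cylindrical ring cavity has the closed-form profile", {
  ring <- make_ring_cavity(10)
  pr <- profile_pore(ring, step = 1, z_range = c(-2, 2), axis = zaxis)
  expect_equal(pr$radius, rep(10 - 1.7, 5), tolerance = 1e-3 / 8.3)
  s <- summary(pr)
  expect_equal(s$average_diameter, 2 * 8.3, tolerance = 1e-3)
  expect_equal(s$min_diameter, s$average_diameter, tolerance = 1e-3)
  expect_lt(s$sd_diameter, 1e-3)
})

test_that("slice optimization matches the exhaustive grid oracle", {
  set.seed(11)
  for (rep in 1:3) {
    # an irregular cavity: atoms on a noisy ellipse wall
    th <- runif(60, 0, 2 * pi)
    wall <- cbind((4.5 + runif(60, 0, 1.5)) * cos(th) * runif(60, 0.9, 1.1),
                  (3.5 + runif(60, 0, 1.5)) * sin(th),
                  runif(60, -3, 3))
    at <- list(xyz = wall, elements = "C")
    pr <- profile_pore(at, step = 1.5, z_range = c(-1.5, 1.5), axis = zaxis)
    rmax <- max(sqrt(wall[, 1]^2 + wall[, 2]^2))
    for (si in seq_len(nrow(pr))) {
      g <- tmbarrel:::slice_grid_search(wall, rep(1.7, 60), pr$z[si],
                                        rmax, 0.05)
      expect_lt(abs(pr$radius[si] - g$radius), 0.05)
    }
  }
})

test_that("profiles are invariant under rigid-body transforms", {
  ring <- make_ring_cavity(8, zs = c(-1, 0, 1))
  pr0 <- profile_pore(ring, step = 1, z_range = c(-1, 1), axis = zaxis)
  R <- tmbarrel:::rotation_matrix(c(1, 2, 0.5), 0.8)
  shift <- c(5, -3, 2)
  moved <- list(xyz = sweep(ring$xyz %*% t(R), 2, shift, "+"),
                elements = "C")
  ax <- list(point = as.numeric(colMeans(moved$xyz)), dir = R %*% c(0, 0, 1))
  pr1 <- profile_pore(moved, step = 1, z_range = c(-1, 1), axis = ax)
  expect_equal(pr1$radius, pr0$radius, tolerance = 1e-3)
})

test_that("removing atoms never shrinks the pore", {
  set.seed(5)
  ring <- make_ring_cavity(6, zs = 0, n = 24)
  extra <- rbind(ring$xyz, c(3, 0, 0), c(-2, 2, 0.5))
  pr_full <- profile_pore(list(xyz = extra, elements = "C"),
                          step = 1, z_range = c(0, 0), axis = zaxis)
  pr_less <- profile_pore(ring, step = 1, z_range = c(0, 0), axis = zaxis)
  expect_gte(pr_less$radius + 1e-9, pr_full$radius)
})

test_that("the axis finder recovers the construction axis", {
  m <- get_model(10)
  ax <- find_axis(m)
  expect_gt(abs(sum(ax$dir * c(0, 0, 1))), cos(2 * pi / 180))
  # equivariance under rotation, invariance under translation
  ca <- ca_coords(m, tm_only = TRUE)
  R <- tmbarrel:::rotation_matrix(c(1, 0, 1), 0.6)
  axr <- find_axis(ca %*% t(R))
  expect_gt(abs(sum(axr$dir * (R %*% ax$dir))), cos(2 * pi / 180))
  axt <- find_axis(sweep(ca, 2, c(10, 5, -3), "+"))
  expect_equal(abs(sum(axt$dir * ax$dir)), 1, tolerance = 1e-9)
  # planar degenerate input
  flat <- cbind(rnorm(20), rnorm(20), 0)
  expect_error(find_axis(flat), "degenerate")
})

test_that("occluded slices record zero radius", {
  blob <- list(xyz = as.matrix(expand.grid(x = -2:2, y = -2:2, z = 0)) * 1.0,
               elements = "C")
  pr <- profile_pore(blob, step = 1, z_range = c(0, 0), axis = zaxis)
  expect_identical(pr$radius, 0)
})

test_that("missing van der Waals radii raise a parameter error", {
  at <- list(xyz = rbind(c(0, 0, 0)), elements = "XX")
  expect_error(profile_pore(at, z_range = c(0, 0), axis = zaxis), "XX")
})

test_that("profile summaries follow the definitions", {
  pr <- structure(data.frame(z = c(0, 1), x = 0, y = 0, radius = c(2, 4)),
                  class = c("pore_profile", "data.frame"))
  s <- summary(pr)
  expect_equal(s$average_diameter, 6)
  expect_equal(s$min_diameter, 4)
  # oracle: independent summation
  expect_equal(s$average_diameter, sum(2 * c(2, 4)) / 2)
  empty <- structure(data.frame(z = numeric(), x = numeric(),
                                y = numeric(), radius = numeric()),
                     class = c("pore_profile", "data.frame"))
  expect_error(summary(empty), "empty")
})
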