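test_that("shape constructors enforce positive extents", {
  expect_error(shape_box(0, 1, 1))
  expect_error(shape_elliptical_tube(0.7, 0.6, 0))
  expect_error(shape_cylinder(1, 10, r_inner = 1.5), "inner radius")
})

test_that("locate resolves the default scene's landmark points", {
  sc <- default_scene()
  expect_equal(locate(sc, c(0, 0, 0)), "syringe_interior")
  # 12 mm off-axis at mid-length: inside the tungsten wall (5..14.5 mm)
  expect_equal(locate(sc, c(1.2, 0, 0)), "shield")
  expect_equal(locate(sc, c(0, 0, -3.5)), "plunger")
  expect_equal(locate(sc, c(0, 0, -5.45)), "roller")
  expect_equal(locate(sc, c(3.2, 0, 0)), "pastern")
  expect_equal(locate(sc, c(0, 0, 40)), "world")
  expect_error(locate(sc, c(0, 0, 60)), "outside the world")
})

test_that("locate agrees with the brute-force per-shape oracle", {
  sc <- default_scene()
  set.seed(5)
  pts <- cbind(runif(4000, -6, 6), runif(4000, -6, 6), runif(4000, -12, 8))
  got <- handdose:::locate_points(sc, pts)
  want <- apply(pts, 1, function(p) r_locate(sc, p))
  expect_identical(got, want)
})

test_that("boundary distances reproduce the syringe radii and world half-side", {
  empty <- scene_geometry(list(), world_side = 100)
  d <- distance_to_boundary(empty, c(0, 0, 0), c(1, 0, 0))
  expect_equal(d$distance, 50)
  expect_true(d$exit)

  sc <- default_scene()
  d1 <- distance_to_boundary(sc, c(0, 0, 0), c(1, 0, 0))
  expect_equal(d1$distance, 0.5, tolerance = 1e-9)   # bore wall
  expect_equal(d1$next_region, "shield")
  d2 <- distance_to_boundary(sc, c(0.6, 0, 0), c(1, 0, 0))
  expect_equal(0.6 + d2$distance, 1.45, tolerance = 1e-6) # outer wall
  expect_error(distance_to_boundary(sc, c(0, 0, 0), c(1, 1, 0)),
               "normalized")
})

test_that("analytic distances agree with a fixed-step ray-marching oracle", {
  # spec-scale: 1e4 rays at step 1e-3 cm; desk-scaled to 150 rays, same
  # step and 2e-3 cm agreement tolerance
  sc <- default_scene()
  set.seed(6)
  n_rays <- 150
  for (i in seq_len(n_rays)) {
    o <- c(runif(1, -5, 5), runif(1, -5, 5), runif(1, -11, 6))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    start <- handdose:::locate_points(sc, matrix(o, 1))
    d <- distance_to_boundary(sc, o, u)
    s <- seq(1e-3, d$distance + 5e-3, by = 1e-3)
    regs <- handdose:::locate_points(sc, cbind(o[1] + s * u[1],
                                               o[2] + s * u[2],
                                               o[3] + s * u[3]))
    change <- which(regs != start)
    expect_gt(length(change), 0)
    expect_lt(abs(s[change[1]] - d$distance), 2e-3)
  }
})

test_that("walking a ray visits regions consistent with locate at midpoints", {
  sc <- default_scene()
  set.seed(7)
  for (i in 1:40) {
    p <- c(runif(1, -4, 4), runif(1, -4, 4), runif(1, -10, 5))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    crossings <- 0
    repeat {
      cur <- handdose:::locate_points(sc, matrix(p, 1))
      if (cur == "<outside>") break
      d <- distance_to_boundary(sc, p, u)
      mids <- sweep(outer(d$distance * c(0.25, 0.5, 0.75), u), 2, p, "+")
      expect_true(all(handdose:::locate_points(sc, mids) == cur))
      if (d$exit) break
      p <- p + (d$distance + 1e-7) * u
      crossings <- crossings + 1
      expect_lt(crossings, 100) # geometry is closed
    }
  }
})

test_that("translation of scene and ray leaves boundary distances unchanged", {
  mk <- function(shift) scene_geometry(list(
    region("cyl", shape_cylinder(1.45, 10, r_inner = 0.5), "tungsten",
           c(0, 0, 0) + shift),
    region("tip", shape_elliptical_tube(0.7, 0.6, 2.3), "soft_tissue",
           c(-2.2, 0, 0.4) + shift, scoring = TRUE)))
  v <- c(3.1, -2.7, 5.3)
  s0 <- mk(c(0, 0, 0)); s1 <- mk(v)
  set.seed(8)
  for (i in 1:25) {
    o <- c(runif(1, -4, 4), runif(1, -4, 4), runif(1, -6, 6))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    d0 <- distance_to_boundary(s0, o, u)
    d1 <- distance_to_boundary(s1, o + v, u)
    if (!d0$exit || !d1$exit) { # world box itself is not translated
      expect_equal(d0$distance, d1$distance, tolerance = 1e-9)
      expect_identical(d0$next_region, d1$next_region)
    }
  }
})

test_that("region masses match analytic volumes and a hit-or-miss oracle", {
  sc <- default_scene()
  # pastern: printed hand envelope times tissue density
  expect_equal(region_mass(sc, "pastern"),
               3.2 * 8.8 * 11.7 * 1.09 / 1000, tolerance = 1e-12)
  expect_equal(region_mass(sc, "index_distal"),
               pi * 0.7 * 0.6 * 2.3 * 1.09 / 1000, tolerance = 1e-12)
  expect_error(region_mass(sc, "shield"), "not a scoring region")
  expect_error(region_mass(sc, "nope"), "unknown region")

  # Monte Carlo rejection-sampling volume within 1%
  set.seed(9)
  reg <- sc$regions[[which(sc$names == "index_distal")]]
  n <- 1e5
  pts <- cbind(runif(n, reg$center[1] - 0.7, reg$center[1] + 0.7),
               runif(n, reg$center[2] - 1.15, reg$center[2] + 1.15),
               runif(n, reg$center[3] - 0.6, reg$center[3] + 0.6))
  frac <- mean(apply(pts, 1, function(p) r_inside(reg, p)))
  vol_mc <- frac * 1.4 * 2.3 * 1.2
  expect_equal(vol_mc, shape_volume(reg$shape), tolerance = 0.01)
})

test_that("scene validation rejects bad assemblies", {
  expect_error(scene_geometry(list(
    region("a", shape_box(1, 1, 1), "unobtainium"))), "unknown material")
  expect_error(scene_geometry(list(
    region("a", shape_box(1, 1, 1), "water", c(60, 0, 0)))), "enclosed")
  expect_error(scene_geometry(list(
    region("a", shape_box(1, 1, 1), "water"),
    region("a", shape_box(1, 1, 1), "water"))), "unique")
})

test_that("geometry dump round-trips through JSON with masses", {
  sc <- default_scene()
  js <- jsonlite::fromJSON(dump_geometry(sc))
  expect_equal(nrow(js), length(sc$names))
  expect_true(all(c("name", "kind", "material", "mass_kg") %in% names(js)))
  expect_equal(js$mass_kg[js$name == "pastern"],
               region_mass(sc, "pastern"))
})
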