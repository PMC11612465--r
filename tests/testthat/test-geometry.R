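test_that("included angle reproduces the study tube angles", {
  expect_equal(included_angle(make_tube_fixture(29.05)), 29.05,
               tolerance = 1e-9)
  expect_equal(included_angle(make_tube_fixture(51.00)), 51.00,
               tolerance = 1e-9)
  # parallel walls: a rectangular channel has zero included angle
  expect_equal(included_angle(make_tube_fixture(0)), 0)
  for (tube in names(tube_angles))
    expect_equal(included_angle(tube_fixture(tube)), tube_angles[[tube]],
                 tolerance = 1e-9)
})

test_that("cosine of the included angle matches the 2-dp reporting convention", {
  expect_equal(cosine_included_angle(make_tube_fixture(29.05), digits = 2), 0.87)
  expect_equal(cosine_included_angle(make_tube_fixture(0), digits = 2), 1.00)
  expect_equal(cosine_included_angle(make_tube_fixture(51.00), digits = 2), 0.63)
})

test_that("geometry construction rejects degenerate inputs", {
  # walls crossing before the exit (zero-width opening)
  expect_error(tube_geometry(rbind(c(0, 100), c(400, -10)),
                             rbind(c(0, -100), c(400, 10))),
               "degenerate|cross")
  # wall parallel to the entrance line
  expect_error(tube_geometry(rbind(c(0, 100), c(0, 200)),
                             rbind(c(0, -100), c(400, -50))))
  # included angle of 90 or more
  expect_error(make_tube_fixture(95), "90")
  # zero-length segment
  expect_error(tube_geometry(rbind(c(0, 100), c(0, 100)),
                             rbind(c(0, -100), c(400, -50))),
               "degenerate")
})

test_that("region polygons tile the trapezoid", {
  for (angle in c(0, 5.52, 29.05, 51.00, 80)) {
    geom <- make_tube_fixture(angle)
    p <- region_polygons(geom)
    total <- polygon_area(p$middle) + polygon_area(p$left_edge) +
      polygon_area(p$right_edge)
    expect_equal(total, polygon_area(p$trapezoid), tolerance = 1e-9)
    # mirror symmetry of the fixture
    expect_equal(polygon_area(p$left_edge), polygon_area(p$right_edge),
                 tolerance = 1e-9)
  }
  # no taper, no edge triangles
  p0 <- region_polygons(make_tube_fixture(0))
  expect_equal(polygon_area(p0$left_edge), 0)
  expect_equal(polygon_area(p0$right_edge), 0)
})

test_that("region areas agree with a Monte-Carlo point-count oracle", {
  set.seed(42)
  geom <- make_tube_fixture(34.12)
  p <- region_polygons(geom)
  bb <- p$trapezoid
  n <- 1e5
  px <- runif(n, min(bb[, 1]), max(bb[, 1]))
  py <- runif(n, min(bb[, 2]), max(bb[, 2]))
  lab <- classify_points(px, py, geom)
  inside <- lab != "outside"
  frac_mc <- sum(lab == "middle") / sum(inside)
  frac_area <- polygon_area(p$middle) / polygon_area(p$trapezoid)
  expect_equal(frac_mc, frac_area, tolerance = 0.01)
})

test_that("classification agrees with an independent winding-number oracle", {
  set.seed(7)
  geom <- make_tube_fixture(23.84)
  p <- region_polygons(geom)
  n <- 1e4
  px <- runif(n, -50, 450)
  py <- runif(n, -350, 350)
  lab <- as.character(classify_points(px, py, geom))
  in_trap <- pip_winding(px, py, p$trapezoid)
  in_mid <- pip_winding(px, py, p$middle)
  in_left <- pip_winding(px, py, p$left_edge)
  oracle <- ifelse(!in_trap, "outside",
            ifelse(in_mid, "middle",        # boundary ties go to middle
            ifelse(in_left, "left_edge", "right_edge")))
  expect_identical(lab, oracle)
})

test_that("boundary points and region interiors classify deterministically", {
  geom <- make_tube_fixture(29.05, opening_width = 200, length = 400)
  # centroid of the middle rectangle
  expect_equal(as.character(classify_points(200, 0, geom)), "middle")
  # beyond the walls
  expect_equal(as.character(classify_points(200, 300, geom)), "outside")
  expect_equal(as.character(classify_points(-1, 0, geom)), "outside")
  # exactly on the middle/edge boundary -> middle
  expect_equal(as.character(classify_points(200, 100, geom)), "middle")
  expect_equal(as.character(classify_points(200, -100, geom)), "middle")
  # just above it -> left edge
  expect_equal(as.character(classify_points(200, 100.001, geom)), "left_edge")
})

test_that("included angle is invariant under rigid rotation and translation", {
  set.seed(11)
  geom <- make_tube_fixture(36.32)
  base <- included_angle_from_walls(geom$wall_left, geom$wall_right)
  expect_equal(base, 36.32, tolerance = 1e-9)
  for (k in 1:20) {
    phi <- runif(1, -pi, pi)
    shift <- runif(2, -1000, 1000)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    rot <- function(w) sweep(w %*% t(R), 2, -shift)
    expect_equal(included_angle_from_walls(rot(geom$wall_left),
                                           rot(geom$wall_right)),
                 base, tolerance = 1e-9)
  }
})

test_that("geometry configs round-trip through the YAML loader", {
  path <- system.file("extdata", "tubeA_geometry.yaml", package = "tubeswarm")
  geom <- read_tube_config(path)
  expect_s3_class(geom, "tube_geometry")
  expect_equal(geom$tube_id, "A")
  expect_equal(included_angle(geom), 29.05, tolerance = 1e-3)
  expect_error(read_tube_config("no/such/file.yaml"), "not found")
})
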