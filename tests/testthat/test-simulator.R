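make_state <- function(x, y, vx = 1, vy = 0) {
  n <- length(x)
  out <- data.frame(id = seq_len(n), x = x, y = y,
                    vx = rep_len(vx, n), vy = rep_len(vy, n), passed = FALSE)
  class(out) <- c("swarm_state", "data.frame")
  out
}

test_that("model parameters are validated", {
  p <- model_params()
  expect_equal(p$b, 0.8)
  expect_equal(p$d3, 18)
  expect_equal(p$n_fish, 30L)
  expect_error(model_params(d1 = 30, d2 = 10), "d1 < d2")
  expect_error(model_params(v0 = -1), "positive")
  expect_error(model_params(k = 0), "positive")
})

test_that("field-of-view sector includes ahead, excludes behind", {
  p <- model_params(fov_half_angle = 90, fov_range = 200)
  # fish j slightly behind the 180-degree sector of i (heading +x)
  st <- make_state(x = c(0, -1), y = c(0, -0.01))
  nb <- neighbors_in_fov(1, st, p)
  expect_equal(nb$m, 0)
  # single fish ahead within range
  st2 <- make_state(x = c(0, 50), y = c(0, 10))
  nb2 <- neighbors_in_fov(1, st2, p)
  expect_equal(nb2$ids, 2L)
  expect_equal(nb2$nearest_id, 2L)
  expect_equal(nb2$centroid_front, c(50, 10))
  expect_equal(nb2$d_nearest, sqrt(50^2 + 10^2))
  # beyond visual range
  st3 <- make_state(x = c(0, 300), y = c(0, 0))
  expect_equal(neighbors_in_fov(1, st3, p)$m, 0)
  # nearest-fish ties break to the lowest id
  st4 <- make_state(x = c(0, 10, 10), y = c(0, 5, -5))
  expect_equal(neighbors_in_fov(1, st4, p)$nearest_id, 2L)
})

test_that("field-of-view membership matches the brute-force oracle", {
  set.seed(17)
  geom <- make_tube_fixture(29.05)
  p <- model_params(fov_half_angle = 90, fov_range = 120)
  for (rep in 1:200) {
    st <- random_swarm(8, geom)
    i <- sample(8, 1)
    nb <- neighbors_in_fov(i, st, p)
    expect_equal(sort(nb$ids), sort(fov_oracle(i, st, p)))
  }
})

test_that("swarm-following velocity points at the front centroid", {
  p <- model_params(k = 1)
  st <- make_state(x = c(0, 2), y = c(0, 0))
  nb <- neighbors_in_fov(1, st, p)
  expect_equal(swarm_following_velocity(1, st, nb, p), c(1, 0))
  # no front fish (neighbour visible but behind in x, wide sector)
  p2 <- model_params(k = 1, fov_half_angle = 180)
  st2 <- make_state(x = c(0, -2), y = c(0, 0.5))
  nb2 <- neighbors_in_fov(1, st2, p2)
  expect_equal(nb2$m, 1)
  expect_equal(swarm_following_velocity(1, st2, nb2, p2), c(0, 0))
  # three front fish: 0.5 k (mean position - p_i)
  p3 <- model_params(k = 0.4)
  st3 <- make_state(x = c(1, 2, 3, 4), y = c(1, 0, 2, 4))
  nb3 <- neighbors_in_fov(1, st3, p3)
  centroid <- c(mean(c(2, 3, 4)), mean(c(0, 2, 4)))
  expect_equal(swarm_following_velocity(1, st3, nb3, p3),
               0.5 * 0.4 * (centroid - c(1, 1)))
})

test_that("nearest-neighbour term applies the three zone cases", {
  # repulsion below d1
  p <- model_params(k = 1, d1 = 2, d2 = 3)
  st <- make_state(x = c(0, 1), y = c(0, 0))
  nb <- neighbors_in_fov(1, st, p)
  expect_equal(nearest_neighbor_velocity(1, st, nb, p), c(-1, 0))
  # parallel band between d1 and d2
  p2 <- model_params(k = 1, d1 = 2, d2 = 10)
  st2 <- make_state(x = c(0, 5), y = c(0, 0))
  nb2 <- neighbors_in_fov(1, st2, p2)
  expect_equal(nearest_neighbor_velocity(1, st2, nb2, p2), c(0, 0))
  # attraction beyond d2 (neighbour straight up; heading +y to see it)
  p3 <- model_params(k = 0.5, d1 = 1, d2 = 3)
  st3 <- make_state(x = c(0, 0), y = c(0, 5), vx = 0, vy = 1)
  nb3 <- neighbors_in_fov(1, st3, p3)
  expect_equal(nearest_neighbor_velocity(1, st3, nb3, p3), c(0, 2.5))
  # empty neighbourhood
  st4 <- make_state(x = 0, y = 0)
  expect_equal(nearest_neighbor_velocity(1, st4, neighbors_in_fov(1, st4, p), p),
               c(0, 0))
})

test_that("wall avoidance pushes inward with magnitude b * wall distance", {
  geom <- make_tube_fixture(0, opening_width = 200, length = 400)
  p <- model_params(b = 0.8, d3 = 18)
  # far from both walls (rectangle: walls at y = +-100)
  st <- make_state(x = 200, y = 0)
  expect_equal(wall_avoidance_velocity(1, st, geom, p), c(0, 0))
  # 10 px from the left (upper) wall: length 8 straight down
  st2 <- make_state(x = 200, y = 90)
  v <- wall_avoidance_velocity(1, st2, geom, p)
  expect_equal(sqrt(sum(v^2)), 8)
  expect_equal(v, c(0, -8))
  # beyond threshold: 25 px > d3
  st3 <- make_state(x = 200, y = 75)
  expect_equal(wall_avoidance_velocity(1, st3, geom, p), c(0, 0))
  # outside the tube is an error
  st4 <- make_state(x = -5, y = 0)
  expect_error(wall_avoidance_velocity(1, st4, geom, p), "outside")
})

test_that("wall avoidance never points toward the wall", {
  # independent oracle: a small move along the returned vector must increase
  # the point-to-line distance to the nearer wall
  line_dist <- function(p, w) {
    d <- w[2, ] - w[1, ]
    abs(d[1] * (p[2] - w[1, 2]) - d[2] * (p[1] - w[1, 1])) / sqrt(sum(d^2))
  }
  set.seed(23)
  geom <- make_tube_fixture(34.12)
  p <- model_params(d3 = 1e6)  # always active: direction check everywhere
  st <- random_swarm(1000, geom)
  for (i in st$id) {
    v <- wall_avoidance_velocity(i, st, geom, p)
    me <- c(st$x[st$id == i], st$y[st$id == i])
    dl <- line_dist(me, geom$wall_left)
    dr <- line_dist(me, geom$wall_right)
    wall <- if (dl <= dr) geom$wall_left else geom$wall_right
    d0 <- min(dl, dr)
    expect_equal(sqrt(sum(v^2)), p$b * d0, tolerance = 1e-9)
    stepped <- me + 1e-3 * v / max(sqrt(sum(v^2)), 1e-12)
    expect_gt(line_dist(stepped, wall), d0 - 1e-12)
  }
})

test_that("a lone fish mid-tube drifts at the forward drive", {
  geom <- make_tube_fixture(29.05, opening_width = 300, length = 600)
  p <- model_params(v0 = 2)
  st <- make_state(x = 300, y = 0, vx = 1, vy = 0)
  nxt <- step_swarm(st, p, geom)
  expect_equal(c(nxt$vx, nxt$vy), c(2, 0))
  expect_equal(c(nxt$x, nxt$y), c(302, 0))
})

test_that("the update is the sum of the four velocity components", {
  set.seed(29)
  geom <- make_tube_fixture(23.84)
  p <- model_params()
  st <- random_swarm(12, geom)
  nxt <- step_swarm(st, p, geom)
  for (i in st$id) {
    nb <- neighbors_in_fov(i, st, p)
    v <- c(p$v0, 0) +
      swarm_following_velocity(i, st, nb, p) +
      nearest_neighbor_velocity(i, st, nb, p) +
      wall_avoidance_velocity(i, st, geom, p)
    row <- which(nxt$id == i)
    expect_equal(c(nxt$vx[row], nxt$vy[row]), v, tolerance = 1e-12)
  }
})

test_that("simulations are deterministic and conserve fish", {
  geom <- make_tube_fixture(29.05)
  p <- model_params(n_fish = 20)
  s1 <- simulate_swarm(p, geom, n_steps = 40, seed = 3)
  s2 <- simulate_swarm(p, geom, n_steps = 40, seed = 3)
  expect_identical(s1$frames, s2$frames)
  s3 <- simulate_swarm(p, geom, n_steps = 40, seed = 4)
  expect_false(identical(s1$frames, s3$frames))
  # inside + passed = n_fish at every recorded frame
  counts <- table(factor(s1$frames$frame, levels = seq_along(s1$n_passed) - 1))
  expect_true(all(as.integer(counts) + s1$n_passed == 20))
})

test_that("a zero-step simulation is the initial frame alone", {
  geom <- make_tube_fixture(25)
  p <- model_params()
  sim <- simulate_swarm(p, geom, n_steps = 0, seed = 1)
  expect_equal(unique(sim$frames$frame), 0L)
  expect_equal(nrow(sim$frames), 30)
  expect_true(all(classify_points(sim$frames$x, sim$frames$y, geom) != "outside"))
})

test_that("no fish leaves the tube through a wall", {
  geom <- make_tube_fixture(29.05)
  p <- model_params(v0 = 3)
  for (seed in 1:5) {
    sim <- simulate_swarm(p, geom, n_steps = 1000, seed = seed)
    expect_true(all(classify_points(sim$frames$x, sim$frames$y, geom)
                    != "outside"))
  }
})

test_that("the swarm over-occupies the middle region at moderate angles", {
  for (angle in c(20, 25, 30, 35)) {
    geom <- make_tube_fixture(angle)
    pl <- region_polygons(geom)
    frac_area <- polygon_area(pl$middle) / polygon_area(pl$trapezoid)
    sim <- simulate_swarm(model_params(), geom, n_steps = 300, seed = 41)
    expect_gt(occupancy_fraction(sim$frames, geom), frac_area)
  }
  # time-averaged count ratio above 1 at 25 degrees, several seeds
  geom <- make_tube_fixture(25)
  for (seed in 1:5) {
    sim <- simulate_swarm(model_params(), geom, n_steps = 300, seed = seed)
    st <- region_stats(sim$frames, geom)
    expect_gt(mean(st$n_middle) / mean(st$n_edge), 1)
  }
})

test_that("the y-axis occupancy density peaks in the middle band", {
  geom <- make_tube_fixture(29.05)
  sim <- simulate_swarm(model_params(), geom, n_steps = 300, seed = 13)
  curve <- kde_1d(sim$frames$y, axis = "y")
  peak <- curve$grid[which.max(curve$density)]
  half_opening <- (geom$exit_line[2, 2] - geom$exit_line[1, 2]) / 2
  expect_lt(abs(peak), half_opening)
  # x-axis density peaks inside the tube
  cx <- kde_1d(sim$frames$x, axis = "x")
  peak_x <- cx$grid[which.max(cx$density)]
  expect_gte(peak_x, geom$entrance_line[1, 1])
  expect_lte(peak_x, geom$exit_line[1, 1])
})
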