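# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# winding-number point-in-polygon (boundary counts as inside)
pip_winding <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    wn <- 0
    on_edge <- FALSE
    for (i in seq_len(n)) {
      x1 <- poly[i, 1]; y1 <- poly[i, 2]
      j <- if (i == n) 1 else i + 1
      x2 <- poly[j, 1]; y2 <- poly[j, 2]
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-9 &&
          x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
          y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9)
        on_edge <- TRUE
      if (y1 <= y) {
        if (y2 > y && cross > 0) wn <- wn + 1
      } else {
        if (y2 <= y && cross < 0) wn <- wn - 1
      }
    }
    on_edge || wn != 0
  }, logical(1))
}

# brute-force field-of-view membership: loop over every other active fish,
# recompute distance and sector inclusion from first principles
fov_oracle <- function(i, swarm, params) {
  me <- swarm[swarm$id == i, ]
  h_ang <- atan2(me$vy, me$vx)
  if (me$vx == 0 && me$vy == 0) h_ang <- 0
  ids <- integer(0)
  for (j in swarm$id[!swarm$passed]) {
    if (j == i) next
    other <- swarm[swarm$id == j, ]
    dx <- other$x - me$x; dy <- other$y - me$y
    d <- sqrt(dx^2 + dy^2)
    if (d > params$fov_range) next
    if (d == 0) { ids <- c(ids, j); next }
    rel <- atan2(dy, dx) - h_ang
    rel <- atan2(sin(rel), cos(rel))  # wrap to (-pi, pi]
    if (abs(rel) <= params$fov_half_angle * pi / 180 + 1e-12)
      ids <- c(ids, j)
  }
  ids
}

# trapezoidal integral, written out independently of the package's internals
trapz_test <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

# closed-form ordinary least squares from the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# random swarm state inside a tube, for simulator property tests
random_swarm <- function(n, geometry, speed = 3) {
  polys <- region_polygons(geometry)
  bb <- polys$trapezoid
  xs <- ys <- numeric(0)
  while (length(xs) < n) {
    cx <- stats::runif(2 * n, min(bb[, 1]), max(bb[, 1]))
    cy <- stats::runif(2 * n, min(bb[, 2]), max(bb[, 2]))
    ok <- classify_points(cx, cy, geometry) != "outside"
    xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
  }
  az <- stats::runif(n, -pi, pi)
  s <- stats::runif(n, 0, speed)
  out <- data.frame(id = seq_len(n), x = xs[1:n], y = ys[1:n],
                    vx = s * cos(az), vy = s * sin(az), passed = FALSE)
  class(out) <- c("swarm_state", "data.frame")
  out
}
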