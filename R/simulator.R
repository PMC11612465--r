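#' Movement-model parameters
#'
#' Parameters of the discrete-time swarm movement model. Each fish's next
#' velocity is the sum of a constant forward drive `v0` along the exit
#' direction, a swarm-following term toward the centroid of fish ahead of it
#' in its field of view (gain `0.5 * k`), a nearest-neighbour zonal term
#' (repulsion below `d1`, none between `d1` and `d2`, attraction beyond
#' `d2`, gain `k`), and a wall-avoidance term of magnitude `b * d_w` along
#' the inward wall normal whenever the wall distance `d_w` is at most `d3`.
#'
#' @param v0 forward drive, px/frame (> 0).
#' @param k neighbour interaction gain, 1/frame (> 0).
#' @param b wall-avoidance gain, 1/frame (> 0); study value 0.8.
#' @param d1,d2 nearest-neighbour zone thresholds, px, `d1 < d2`.
#' @param d3 wall-avoidance activation distance, px; study value 18.
#' @param fov_half_angle half-angle of the visual sector, degrees
#'   (90 gives the 180-degree field of view assumed for fish).
#' @param fov_range visual range, px.
#' @param dt time step, frames.
#' @param n_fish number of fish; study simulation uses 30.
#' @return A validated list of class `model_params`.
#' @export
model_params <- function(v0 = 3, k = 0.1, b = 0.8, d1 = 10, d2 = 30,
                         d3 = 18, fov_half_angle = 90, fov_range = 200,
                         dt = 1, n_fish = 30) {
  p <- list(v0 = v0, k = k, b = b, d1 = d1, d2 = d2, d3 = d3,
            fov_half_angle = fov_half_angle, fov_range = fov_range,
            dt = dt, n_fish = as.integer(n_fish))
  with(p, {
    if (!all(vapply(p, function(v) is.numeric(v) && is.finite(v) && v > 0,
                    logical(1))))
      stop("all movement-model parameters must be positive and finite")
    if (d1 >= d2) stop("zone thresholds must satisfy d1 < d2")
    if (fov_half_angle > 180) stop("fov_half_angle cannot exceed 180 degrees")
  })
  structure(p, class = "model_params")
}

#' Initialise a swarm state
#'
#' Places `n_fish` uniformly at random inside the tube with region quotas
#' from the count-ratio law and region speed scaling from the speed-ratio
#' law: the middle region receives `round(n * r / (1 + r))` fish where `r`
#' is the predicted middle/edge count ratio, the rest split evenly between
#' the two edge triangles; initial speeds are set so the middle/edge mean
#' ratio equals the predicted speed ratio with overall mean `v0`, headings
#' jittered within 15 degrees of the exit direction.
#'
#' @param params a `model_params`.
#' @param geometry a `tube_geometry`.
#' @return data.frame of class `swarm_state`: `id`, `x`, `y`, `vx`, `vy`,
#'   `passed`.
#' @export
init_swarm <- function(params, geometry) {
  stopifnot(inherits(params, "model_params"),
            inherits(geometry, "tube_geometry"))
  n <- params$n_fish
  theta <- included_angle(geometry)
  polys <- region_polygons(geometry)
  a_left <- polygon_area(polys$left_edge)
  a_right <- polygon_area(polys$right_edge)

  if (a_left + a_right < 1e-9) {
    n_mid <- n; n_left <- 0; n_right <- 0
  } else {
    r <- predict_number_ratio(theta)
    n_mid <- round(n * r / (1 + r))
    n_left <- floor((n - n_mid) / 2)
    n_right <- n - n_mid - n_left
  }
  pos <- rbind(
    sample_region(n_mid, polys$middle, geometry, "middle"),
    sample_region(n_left, polys$left_edge, geometry, "left_edge"),
    sample_region(n_right, polys$right_edge, geometry, "right_edge")
  )
  region <- rep(c("middle", "edge"), c(n_mid, n_left + n_right))

  rs <- predict_speed_ratio(theta)
  s_edge <- 2 * params$v0 / (1 + rs)
  speed <- ifelse(region == "middle", rs * s_edge, s_edge)
  az <- stats::runif(n, -15, 15) * pi / 180
  out <- data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2],
                    vx = speed * cos(az), vy = speed * sin(az),
                    passed = FALSE)
  class(out) <- c("swarm_state", "data.frame")
  out
}

# rejection-sample n uniform points whose classify_points label is `label`
sample_region <- function(n, poly, geometry, label) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  if (is.null(poly) || nrow(poly) < 3 || polygon_area(poly) < 1e-9)
    stop("cannot place ", n, " fish in region '", label, "': region too small")
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(NA_real_, n, 2)
  got <- 0
  while (got < n) {
    m <- max(4 * (n - got), 16)
    px <- stats::runif(m, xr[1], xr[2]); py <- stats::runif(m, yr[1], yr[2])
    ok <- classify_points(px, py, geometry) == label
    take <- min(sum(ok), n - got)
    if (take > 0) {
      idx <- which(ok)[seq_len(take)]
      out[got + seq_len(take), ] <- cbind(px[idx], py[idx])
      got <- got + take
    }
  }
  out
}

#' Neighbours within a fish's field of view
#'
#' The field of view is the circular sector of radius `fov_range` centred on
#' the fish's heading with half-angle `fov_half_angle`. The heading is the
#' normalised velocity (the exit direction when the fish is at rest). Front
#' members are neighbours whose x-coordinate is at least the fish's own.
#'
#' @param i fish id.
#' @param swarm a `swarm_state`.
#' @param params a `model_params`.
#' @return list: `ids` (neighbour ids), `m` (count), `front_ids`, `n_front`,
#'   `centroid_front` (mean position of front members, or NULL), `nearest_id`
#'   (lowest id on ties, or NA), `d_nearest`.
#' @export
neighbors_in_fov <- function(i, swarm, params) {
  active <- swarm[!swarm$passed, , drop = FALSE]
  me <- swarm[swarm$id == i, , drop = FALSE]
  if (nrow(me) != 1) stop("unknown fish id ", i)
  others <- active[active$id != i, , drop = FALSE]
  empty <- list(ids = integer(0), m = 0L, front_ids = integer(0),
                n_front = 0L, centroid_front = NULL, nearest_id = NA_integer_,
                d_nearest = NA_real_)
  if (nrow(others) == 0) return(empty)

  h <- heading_of(me$vx, me$vy)
  rx <- others$x - me$x; ry <- others$y - me$y
  d <- sqrt(rx^2 + ry^2)
  cos_half <- cos(params$fov_half_angle * pi / 180)
  in_sector <- d <= params$fov_range &
    (h[1] * rx + h[2] * ry) >= d * cos_half - 1e-12
  nb <- others[in_sector, , drop = FALSE]
  if (nrow(nb) == 0) return(empty)
  d_nb <- d[in_sector]
  front <- nb$x >= me$x
  nearest <- nb$id[order(d_nb, nb$id)][1]
  list(
    ids = nb$id, m = nrow(nb),
    front_ids = nb$id[front], n_front = sum(front),
    centroid_front = if (any(front)) c(mean(nb$x[front]), mean(nb$y[front]))
                     else NULL,
    nearest_id = nearest,
    d_nearest = min(d_nb)
  )
}

heading_of <- function(vx, vy) {
  s <- sqrt(vx^2 + vy^2)
  if (s > 0) c(vx, vy) / s else c(1, 0)
}

#' Swarm-following velocity component
#'
#' `0.5 * k * (p_c - p_i)` toward the centroid `p_c` of fish ahead of fish
#' `i` within its field of view; zero when none are ahead.
#'
#' @inheritParams neighbors_in_fov
#' @param neighbors a [neighbors_in_fov()] result.
#' @export
swarm_following_velocity <- function(i, swarm, neighbors, params) {
  if (neighbors$n_front == 0) return(c(0, 0))
  me <- swarm[swarm$id == i, ]
  0.5 * params$k * (neighbors$centroid_front - c(me$x, me$y))
}

#' Nearest-neighbour zonal velocity component
#'
#' Repulsion `-k (p_n - p_i)` when the nearest visible fish is closer than
#' `d1`, attraction `+k (p_n - p_i)` when farther than `d2`, zero in the
#' parallel band between, and zero when no fish is visible.
#'
#' @inheritParams swarm_following_velocity
#' @export
nearest_neighbor_velocity <- function(i, swarm, neighbors, params) {
  if (neighbors$m == 0) return(c(0, 0))
  me <- swarm[swarm$id == i, ]
  nn <- swarm[swarm$id == neighbors$nearest_id, ]
  rel <- c(nn$x - me$x, nn$y - me$y)
  if (neighbors$d_nearest < params$d1) -params$k * rel
  else if (neighbors$d_nearest > params$d2) params$k * rel
  else c(0, 0)
}

#' Wall-avoidance velocity component
#'
#' For the nearer of the two walls, if the perpendicular wall distance
#' `d_w` is at most `d3`, returns a vector of length `b * d_w` along that
#' wall's inward normal (away from the wall); otherwise zero.
#'
#' @param i fish id.
#' @param swarm a `swarm_state`.
#' @param geometry a `tube_geometry`.
#' @param params a `model_params`.
#' @export
wall_avoidance_velocity <- function(i, swarm, geometry, params) {
  me <- swarm[swarm$id == i, ]
  if (classify_points(me$x, me$y, geometry) == "outside")
    stop("fish ", i, " is outside the tube: wall distance undefined")
  wd <- wall_distances(me$x, me$y, geometry)
  if (wd$left$dist <= wd$right$dist) {
    d_w <- wd$left$dist; n <- wd$left$normal
  } else {
    d_w <- wd$right$dist; n <- wd$right$normal
  }
  if (d_w <= params$d3) params$b * d_w * n else c(0, 0)
}

#' Advance the swarm one time step
#'
#' Synchronous update: every fish's next velocity
#' `v(t+1) = v0 + v_s + v_n + v_w` is computed from the state at time `t`,
#' then positions advance by `v(t+1) * dt`. Fish whose new position crosses
#' the exit line are marked `passed` and leave the dynamics; fish that would
#' penetrate a wall or back out of the entrance are projected back to the
#' interior (collision resolution).
#'
#' @param swarm a `swarm_state`.
#' @param params a `model_params`.
#' @param geometry a `tube_geometry`.
#' @return The next `swarm_state`.
#' @export
step_swarm <- function(swarm, params, geometry) {
  stopifnot(inherits(swarm, "swarm_state"))
  active_ids <- swarm$id[!swarm$passed]
  nxt <- swarm
  exit_x <- geometry$exit_line[1, 1]
  for (i in active_ids) {
    nb <- neighbors_in_fov(i, swarm, params)
    v <- c(params$v0, 0) +
      swarm_following_velocity(i, swarm, nb, params) +
      nearest_neighbor_velocity(i, swarm, nb, params) +
      wall_avoidance_velocity(i, swarm, geometry, params)
    row <- which(nxt$id == i)
    me <- swarm[row, ]
    p_new <- c(me$x, me$y) + v * params$dt
    nxt$vx[row] <- v[1]; nxt$vy[row] <- v[2]
    if (p_new[1] >= exit_x) {
      nxt$passed[row] <- TRUE
      nxt$x[row] <- p_new[1]; nxt$y[row] <- p_new[2]
    } else {
      p_new <- resolve_collisions(p_new, geometry)
      nxt$x[row] <- p_new[1]; nxt$y[row] <- p_new[2]
    }
  }
  nxt
}

# project a position that left through a wall or the entrance back inside
resolve_collisions <- function(p, geometry, margin = 1e-6) {
  x0 <- geometry$entrance_line[1, 1]
  if (p[1] < x0) p[1] <- x0
  for (pass in 1:2) {
    wd <- wall_distances(p[1], p[2], geometry)
    for (side in c("left", "right")) {
      if (wd[[side]]$dist < margin)
        p <- p + (margin - wd[[side]]$dist) * wd[[side]]$normal
    }
  }
  p
}

#' Simulate fish swarm traffic through a tube
#'
#' Runs the movement model from a law-informed random initialisation and
#' records one frame table per time step in the tracked-table schema.
#'
#' @param params a `model_params`.
#' @param geometry a `tube_geometry`.
#' @param n_steps number of steps to simulate (frame 0 is the initial state).
#' @param seed RNG seed controlling the initial placement.
#' @return List of class `swarm_simulation`: `frames` (a `frame_table`
#'   data frame of active fish, frames 0..n_steps), `n_passed` (cumulative
#'   passed count per frame), `params`, `geometry`, `seed`.
#' @export
simulate_swarm <- function(params, geometry, n_steps = 500, seed = 1) {
  stopifnot(inherits(params, "model_params"),
            inherits(geometry, "tube_geometry"), n_steps >= 0)
  set.seed(seed)
  state <- init_swarm(params, geometry)
  frames <- vector("list", n_steps + 1)
  n_passed <- integer(n_steps + 1)
  frames[[1]] <- state_to_frame(state, 0)
  for (t in seq_len(n_steps)) {
    state <- step_swarm(state, params, geometry)
    frames[[t + 1]] <- state_to_frame(state, t)
    n_passed[t + 1] <- sum(state$passed)
    if (all(state$passed)) {
      frames <- frames[seq_len(t + 1)]
      n_passed <- n_passed[seq_len(t + 1)]
      break
    }
  }
  out <- list(frames = validate_frame_table(do.call(rbind, frames)),
              n_passed = n_passed, params = params, geometry = geometry,
              seed = seed)
  class(out) <- "swarm_simulation"
  out
}

state_to_frame <- function(state, frame) {
  act <- state[!state$passed, , drop = FALSE]
  if (nrow(act) == 0)
    return(stats::setNames(
      as.data.frame(c(replicate(6, numeric(0), simplify = FALSE),
                      list(integer(0)))),
      frame_table_cols))
  data.frame(number = act$id, x = act$x, y = act$y,
             speed_x = abs(act$vx), speed_y = act$vy,
             speed = combined_speed(act$vx, act$vy),
             frame = as.integer(frame))
}

#' @export
print.swarm_simulation <- function(x, ...) {
  n_frames <- length(unique(x$frames$frame))
  cat(sprintf("<swarm_simulation> %d fish, %d frames, %d passed the exit (seed %s)\n",
              x$params$n_fish, n_frames, utils::tail(x$n_passed, 1),
              format(x$seed)))
  invisible(x)
}
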