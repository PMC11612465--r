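#' Construct a trapezoidal tube geometry
#'
#' A tube is a trapezoid in pixel coordinates whose parallel sides (the wide
#' entrance and the narrow exit opening) are perpendicular to the x-axis, the
#' x-axis being the direction in which fish exit the tube. The two
#' non-parallel sides are the left wall (larger y) and right wall (smaller y).
#'
#' @param wall_left,wall_right 2x2 numeric matrices; rows are the entrance-end
#'   and exit-end endpoints of each wall, columns are x and y in pixels.
#' @param tube_id optional label for the tube.
#' @return An object of class `tube_geometry` with wall segments, the signed
#'   wall angles `theta_l`/`theta_r` (degrees from the x-axis), entrance and
#'   exit closing segments, and the exit-direction unit vector.
#' @examples
#' geom <- make_tube_fixture(29.05)
#' included_angle(geom)
#' @export
tube_geometry <- function(wall_left, wall_right, tube_id = "tube") {
  wall_left <- as_wall(wall_left, "wall_left")
  wall_right <- as_wall(wall_right, "wall_right")

  x0l <- wall_left[1, 1]; x1l <- wall_left[2, 1]
  x0r <- wall_right[1, 1]; x1r <- wall_right[2, 1]
  if (abs(x0l - x0r) > 1e-9 || abs(x1l - x1r) > 1e-9)
    stop("entrance and exit lines must be perpendicular to the x-axis ",
         "(wall endpoints must share x at each end)")
  if (x1l <= x0l)
    stop("exit must lie at larger x than entrance (x-axis is the exit direction)")

  if (wall_left[1, 2] <= wall_right[1, 2])
    stop("left wall must lie at larger y than right wall at the entrance")
  if (wall_left[2, 2] <= wall_right[2, 2])
    stop("walls cross before the exit: degenerate (zero or negative) exit opening")
  # the middle rectangle construction needs the exit opening nested inside the
  # entrance opening
  if (wall_left[2, 2] > wall_left[1, 2] + 1e-9 ||
      wall_right[2, 2] < wall_right[1, 2] - 1e-9)
    stop("walls must not diverge: exit opening must be within the entrance opening")

  theta_l <- wall_angle_deg(wall_left)
  theta_r <- wall_angle_deg(wall_right)
  inc <- abs(theta_r - theta_l)
  if (inc >= 90)
    stop("included angle |theta_r - theta_l| must be below 90 degrees, got ",
         format(inc))

  geom <- structure(
    list(
      tube_id = as.character(tube_id)[1],
      wall_left = wall_left,
      wall_right = wall_right,
      theta_l = theta_l,
      theta_r = theta_r,
      entrance_line = rbind(wall_right[1, ], wall_left[1, ]),
      exit_line = rbind(wall_right[2, ], wall_left[2, ]),
      x_axis_direction = c(1, 0)
    ),
    class = "tube_geometry"
  )
  geom
}

as_wall <- function(w, name) {
  w <- as.matrix(w)
  if (!is.numeric(w) || !all(dim(w) == c(2, 2)) || !all(is.finite(w)))
    stop(name, " must be a finite numeric 2x2 matrix of endpoints")
  dimnames(w) <- list(c("entrance", "exit"), c("x", "y"))
  if (sqrt(sum((w[2, ] - w[1, ])^2)) < 1e-9)
    stop(name, " is a degenerate (zero-length) segment")
  w
}

# signed angle of the wall direction (entrance -> exit) against the x-axis
wall_angle_deg <- function(wall) {
  d <- wall[2, ] - wall[1, ]
  if (abs(d[1]) < 1e-12)
    stop("wall is parallel to the entrance line: angle undefined")
  unname(atan2(d[2], d[1]) * 180 / pi)
}

#' Included angle of a tube
#'
#' The tube's opening angle between the two walls, `|theta_r - theta_l|`,
#' in degrees.
#'
#' @param geometry a `tube_geometry`.
#' @return Angle in degrees, in [0, 90).
#' @export
included_angle <- function(geometry) {
  stopifnot(inherits(geometry, "tube_geometry"))
  angle_diff_deg(geometry$theta_r, geometry$theta_l)
}

# |a - b| wrapped into [0, 180]; the angle between two wall directions is
# unaffected by a rigid rotation of both
angle_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  min(d, 360 - d)
}

#' Included angle from raw wall segments
#'
#' Angle between two wall direction vectors (entrance endpoint to exit
#' endpoint), in degrees. Unlike [tube_geometry()], the segments need not be
#' axis-aligned, so the value is invariant under rigid rotation and
#' translation of all coordinates.
#'
#' @param wall_left,wall_right 2x2 matrices of endpoints (rows: entrance,
#'   exit; columns: x, y).
#' @export
included_angle_from_walls <- function(wall_left, wall_right) {
  wl <- as_wall(wall_left, "wall_left")
  wr <- as_wall(wall_right, "wall_right")
  ang <- function(w) atan2(w[2, 2] - w[1, 2], w[2, 1] - w[1, 1]) * 180 / pi
  angle_diff_deg(ang(wr), ang(wl))
}

#' Cosine of a tube's included angle
#'
#' @inheritParams included_angle
#' @param digits round to this many decimals; `NULL` for full precision.
#'   The study tables report 2 decimals.
#' @export
cosine_included_angle <- function(geometry, digits = NULL) {
  v <- cos(included_angle(geometry) * pi / 180)
  if (!is.null(digits)) v <- round(v, digits)
  v
}

#' Region polygons of a tube
#'
#' Partitions the trapezoid into the middle region (the rectangle spanned by
#' the narrow exit opening swept back along the tube's length) and the two
#' residual edge triangles. The three polygons tile the trapezoid exactly.
#'
#' @inheritParams included_angle
#' @return A list with components `middle`, `left_edge`, `right_edge`, each a
#'   matrix of vertices (counter-clockwise, not closed), plus `trapezoid`.
#' @export
region_polygons <- function(geometry) {
  stopifnot(inherits(geometry, "tube_geometry"))
  wl <- geometry$wall_left; wr <- geometry$wall_right
  x0 <- wl[1, 1]; x1 <- wl[2, 1]
  yl0 <- wl[1, 2]; yl1 <- wl[2, 2]   # left wall y at entrance / exit
  yr0 <- wr[1, 2]; yr1 <- wr[2, 2]

  middle <- rbind(c(x0, yr1), c(x1, yr1), c(x1, yl1), c(x0, yl1))
  left_edge <- rbind(c(x0, yl1), c(x1, yl1), c(x0, yl0))
  right_edge <- rbind(c(x0, yr0), c(x1, yr1), c(x0, yr1))
  trapezoid <- rbind(c(x0, yr0), c(x1, yr1), c(x1, yl1), c(x0, yl0))
  list(middle = middle, left_edge = dedupe_poly(left_edge),
       right_edge = dedupe_poly(right_edge), trapezoid = trapezoid)
}

# drop repeated vertices from degenerate (zero-area) triangles
dedupe_poly <- function(p) {
  keep <- c(TRUE, rowSums(abs(diff(p))) > 1e-12)
  p[keep, , drop = FALSE]
}

#' Shoelace area of a polygon
#'
#' @param poly matrix of vertices (x, y), not closed.
#' @return Absolute area.
#' @export
polygon_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Classify points into tube regions
#'
#' Assigns each point the label `middle`, `left_edge`, `right_edge` or
#' `outside`. Points on the middle/edge boundary are labelled `middle`;
#' points on the tube boundary count as inside.
#'
#' @param x,y numeric vectors of pixel coordinates (or `x` a 2-column matrix).
#' @inheritParams included_angle
#' @return A factor with levels `middle`, `left_edge`, `right_edge`, `outside`.
#' @export
classify_points <- function(x, y = NULL, geometry) {
  stopifnot(inherits(geometry, "tube_geometry"))
  if (is.null(y)) {
    x <- as.matrix(x); y <- x[, 2]; x <- x[, 1]
  }
  stopifnot(length(x) == length(y))
  wl <- geometry$wall_left; wr <- geometry$wall_right
  x0 <- wl[1, 1]; x1 <- wl[2, 1]
  tol <- 1e-9
  # wall y at given x by linear interpolation
  fr <- (x - x0) / (x1 - x0)
  y_left <- wl[1, 2] + fr * (wl[2, 2] - wl[1, 2])
  y_right <- wr[1, 2] + fr * (wr[2, 2] - wr[1, 2])
  inside <- x >= x0 - tol & x <= x1 + tol & y <= y_left + tol & y >= y_right - tol
  lab <- rep("outside", length(x))
  in_mid <- inside & y <= wl[2, 2] + tol & y >= wr[2, 2] - tol
  lab[inside] <- ifelse(in_mid[inside], "middle",
                        ifelse(y[inside] > wl[2, 2], "left_edge", "right_edge"))
  factor(lab, levels = c("middle", "left_edge", "right_edge", "outside"))
}

# perpendicular distance from points to an (infinite) wall line, plus the
# inward unit normal (pointing into the tube interior)
wall_distance <- function(x, y, wall, inward) {
  d <- unname(wall[2, ] - wall[1, ])
  u <- d / sqrt(sum(d^2))
  n <- c(-u[2], u[1])
  if (sum(n * unname(inward)) < 0) n <- -n
  list(dist = unname((x - wall[1, 1]) * n[1] + (y - wall[1, 2]) * n[2]),
       normal = n)
}

# signed distances of points to both walls; positive = inside side
wall_distances <- function(x, y, geometry) {
  cl <- centroid(region_polygons(geometry)$trapezoid)
  left <- wall_distance(x, y, geometry$wall_left,
                        inward = cl - geometry$wall_left[1, ])
  right <- wall_distance(x, y, geometry$wall_right,
                         inward = cl - geometry$wall_right[1, ])
  list(left = left, right = right)
}

centroid <- function(poly) colMeans(poly)

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("<tube_geometry> %s\n", x$tube_id))
  cat(sprintf("  walls: theta_l = %.3f deg, theta_r = %.3f deg\n",
              x$theta_l, x$theta_r))
  cat(sprintf("  included angle: %.2f deg (cosine %.2f)\n",
              included_angle(x), cosine_included_angle(x)))
  cat(sprintf("  length: %.1f px, entrance width %.1f px, exit width %.1f px\n",
              x$wall_left[2, 1] - x$wall_left[1, 1],
              x$entrance_line[2, 2] - x$entrance_line[1, 2],
              x$exit_line[2, 2] - x$exit_line[1, 2]))
  invisible(x)
}

#' Read a tube geometry from a YAML or JSON config
#'
#' The config holds `tube_id` and the wall endpoint pairs, e.g.
#' \preformatted{
#' tube_id: A
#' wall_left:  [[0, 244.35], [400, 100]]
#' wall_right: [[0, -244.35], [400, -100]]
#' }
#'
#' @param path file path; format chosen by extension (.yaml/.yml or .json).
#' @return A validated `tube_geometry`.
#' @export
read_tube_config <- function(path) {
  if (!file.exists(path)) stop("geometry config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  for (f in c("wall_left", "wall_right"))
    if (is.null(cfg[[f]])) stop("geometry config missing field: ", f)
  to_mat <- function(w) {
    m <- do.call(rbind, lapply(w, as.numeric))
    if (is.null(dim(m))) m <- matrix(as.numeric(unlist(w)), 2, 2, byrow = TRUE)
    m
  }
  wl <- if (is.matrix(cfg$wall_left)) cfg$wall_left else to_mat(cfg$wall_left)
  wr <- if (is.matrix(cfg$wall_right)) cfg$wall_right else to_mat(cfg$wall_right)
  tube_geometry(wl, wr, tube_id = cfg$tube_id %||% "tube")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
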