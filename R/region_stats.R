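#' Per-frame region statistics
#'
#' For one frame, assigns each fish to the middle or (pooled) edge region,
#' then records the mean combined speed and the count in each, plus their
#' middle-over-edge ratios. A ratio is defined as 0 when its denominator
#' (edge mean speed, or edge count) is 0, matching the convention of the
#' study tables. Fish outside the tube are ignored.
#'
#' @param table a frame-table data frame holding exactly one frame (or the
#'   frame to use via `frame`).
#' @param geometry a `tube_geometry`.
#' @param frame optional frame number to select when `table` spans several.
#' @return One-row data.frame: `frame`, `v_middle`, `v_edge`, `ratio_s`,
#'   `n_middle`, `n_edge`, `ratio_n`.
#' @export
frame_region_stats <- function(table, geometry, frame = NULL) {
  table <- validate_frame_table(table)
  if (!is.null(frame)) table <- table[table$frame == frame, , drop = FALSE]
  if (nrow(table) == 0) stop("no observations in the requested frame")
  fr <- unique(table$frame)
  if (length(fr) != 1)
    stop("frame_region_stats expects a single frame; got ", length(fr),
         " (use region_stats() for a whole recording)")
  region <- classify_points(table$x, table$y, geometry)
  mid <- region == "middle"
  edge <- region %in% c("left_edge", "right_edge")
  v_middle <- if (any(mid)) mean(table$speed[mid]) else 0
  v_edge <- if (any(edge)) mean(table$speed[edge]) else 0
  n_middle <- sum(mid)
  n_edge <- sum(edge)
  data.frame(
    frame = fr,
    v_middle = v_middle,
    v_edge = v_edge,
    ratio_s = if (v_edge > 0) v_middle / v_edge else 0,
    n_middle = n_middle,
    n_edge = n_edge,
    ratio_n = if (n_edge > 0) n_middle / n_edge else 0
  )
}

#' Region statistics for every frame of a recording
#'
#' @inheritParams frame_region_stats
#' @return data.frame with one [frame_region_stats()] row per frame, ordered
#'   by frame.
#' @export
region_stats <- function(table, geometry) {
  table <- validate_frame_table(table)
  out <- do.call(rbind, lapply(split_frames(table), frame_region_stats,
                               geometry = geometry))
  rownames(out) <- NULL
  out[order(out$frame), , drop = FALSE]
}

#' Summarize a tube over a frame window
#'
#' Averages the per-frame ratios over the selected window (mean of per-frame
#' ratios, not ratio of means) and attaches the tube's included angle and its
#' cosine. The window is the analyst's choice of frames during which the
#' swarm met the schooling criterion; by default all frames in `stats` are
#' used.
#'
#' @param stats data.frame of per-frame statistics ([region_stats()] output
#'   or equivalent with columns `frame`, `ratio_s`, `ratio_n`).
#' @param geometry a `tube_geometry`.
#' @param frames frame window (vector of frame numbers); `NULL` for all.
#' @return One-row data.frame: `tube_id`, `mean_ratio_s`, `mean_ratio_n`,
#'   `angle_deg`, `cosine`, `n_frames`.
#' @export
summarize_tube <- function(stats, geometry, frames = NULL) {
  stopifnot(is.data.frame(stats),
            all(c("frame", "ratio_s", "ratio_n") %in% names(stats)))
  if (!is.null(frames)) {
    missing <- setdiff(frames, stats$frame)
    if (length(missing))
      stop("frames not present in stats: ", paste(missing, collapse = ", "))
    stats <- stats[stats$frame %in% frames, , drop = FALSE]
  }
  if (nrow(stats) == 0) stop("empty frame window")
  data.frame(
    tube_id = geometry$tube_id,
    mean_ratio_s = mean(stats$ratio_s),
    mean_ratio_n = mean(stats$ratio_n),
    angle_deg = included_angle(geometry),
    cosine = cosine_included_angle(geometry),
    n_frames = nrow(stats)
  )
}

#' One-dimensional kernel density of fish positions
#'
#' Gaussian-kernel density estimate of positions along one axis, evaluated on
#' a regular grid spanning the data plus three bandwidths on each side, then
#' normalised so its trapezoidal integral over the grid is exactly 1. The
#' default bandwidth is Silverman's rule of thumb. This is the occupancy-
#' density index used to show where along the tube the swarm concentrates.
#'
#' @param positions numeric vector of coordinates, px (length >= 2).
#' @param axis which axis the positions came from (metadata only).
#' @param bandwidth kernel bandwidth in px, or `"auto"` for Silverman's rule.
#' @param n_grid grid resolution.
#' @return data.frame of class `density_curve`: `grid` (px), `density`
#'   (1/px), with attributes `axis` and `bandwidth`.
#' @export
kde_1d <- function(positions, axis = c("x", "y"), bandwidth = "auto",
                   n_grid = 512) {
  axis <- match.arg(axis)
  positions <- as.numeric(positions)
  if (length(positions) < 2) stop("need at least 2 positions")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (identical(bandwidth, "auto")) {
    bw <- if (stats::sd(positions) > 0) stats::bw.nrd0(positions) else 1
  } else {
    bw <- as.numeric(bandwidth)
    if (!is.finite(bw) || bw <= 0) stop("bandwidth must be positive")
  }
  grid <- seq(min(positions) - 3 * bw, max(positions) + 3 * bw,
              length.out = n_grid)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, positions, bw)),
                 numeric(1))
  # renormalise: the finite grid truncates the Gaussian tails (~0.3% mass)
  dens <- dens / trapz(grid, dens)
  out <- data.frame(grid = grid, density = dens)
  attr(out, "axis") <- axis
  attr(out, "bandwidth") <- bw
  class(out) <- c("density_curve", "data.frame")
  out
}

# trapezoidal rule on an ordered grid
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Fraction of fish-frames observed in the middle region
#'
#' @param table a frame-table data frame spanning one or more frames.
#' @param geometry a `tube_geometry`.
#' @param within_tube if `TRUE` (default) the denominator counts only
#'   observations inside the tube; otherwise all rows.
#' @return Fraction in [0, 1].
#' @export
occupancy_fraction <- function(table, geometry, within_tube = TRUE) {
  table <- validate_frame_table(table)
  if (nrow(table) == 0) stop("empty frame table")
  region <- classify_points(table$x, table$y, geometry)
  denom <- if (within_tube) sum(region != "outside") else length(region)
  if (denom == 0) return(NaN)
  sum(region == "middle") / denom
}
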