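#' Specification for synthetic frame tables
#'
#' Describes a synthetic recording with known region structure: how many
#' fish, how they split between middle and edge regions (the count split is
#' exact: the middle gets `round(n_fish * r / (1 + r))` fish for target
#' ratio `r`), and the per-region speed distributions (truncated normal,
#' nonnegative) whose means are in the target speed ratio.
#'
#' @param geometry a `tube_geometry`.
#' @param n_fish fish per frame; the study tracked 16.
#' @param n_frames number of frames.
#' @param target_ratio_n target middle/edge count ratio (> 0).
#' @param target_ratio_s target middle/edge mean-speed ratio (> 0).
#' @param edge_speed mean edge-region speed, px/frame; the middle mean is
#'   `target_ratio_s * edge_speed`.
#' @param speed_sd speed noise standard deviation, px/frame.
#' @param placement_jitter Gaussian jitter (px) added to the uniform
#'   placement; jittered points that would leave their region keep the
#'   original draw.
#' @param seed RNG seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(geometry, n_fish = 16, n_frames = 1,
                           target_ratio_n = 3, target_ratio_s = 1.12,
                           edge_speed = 7.42, speed_sd = 0,
                           placement_jitter = 0, seed = 1) {
  stopifnot(inherits(geometry, "tube_geometry"),
            n_fish >= 1, n_frames >= 1,
            target_ratio_n > 0, target_ratio_s > 0, edge_speed > 0,
            speed_sd >= 0, placement_jitter >= 0)
  structure(list(geometry = geometry, n_fish = as.integer(n_fish),
                 n_frames = as.integer(n_frames),
                 target_ratio_n = target_ratio_n,
                 target_ratio_s = target_ratio_s,
                 edge_speed = edge_speed, speed_sd = speed_sd,
                 placement_jitter = placement_jitter, seed = seed),
            class = "synthetic_spec")
}

#' Generate synthetic frame tables
#'
#' Draws, for each frame, the prescribed number of fish uniformly inside
#' their assigned region with speeds from the per-region truncated normal
#' distributions, and emits a tracked-schema frame table. Deterministic for
#' a given spec (the spec's seed is applied on entry).
#'
#' @param spec a [synthetic_spec()].
#' @return A `frame_table` data frame spanning `n_frames` frames, with
#'   attributes `n_middle`/`n_edge` (the exact per-frame split).
#' @export
generate_frames <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  geom <- spec$geometry
  polys <- region_polygons(geom)
  r <- spec$target_ratio_n
  n_mid <- round(spec$n_fish * r / (1 + r))
  n_edge <- spec$n_fish - n_mid
  n_left <- floor(n_edge / 2)
  n_right <- n_edge - n_left
  if (n_mid > 0 && polygon_area(polys$middle) < 1e-9)
    stop("infeasible quota: middle region has zero area")
  if ((n_left > 0 && polygon_area(polys$left_edge) < 1e-9) ||
      (n_right > 0 && polygon_area(polys$right_edge) < 1e-9))
    stop("infeasible quota: edge region too small for requested split")

  mu_mid <- spec$target_ratio_s * spec$edge_speed
  frames <- lapply(seq_len(spec$n_frames), function(f) {
    pos <- rbind(
      sample_region(n_mid, polys$middle, geom, "middle"),
      sample_region(n_left, polys$left_edge, geom, "left_edge"),
      sample_region(n_right, polys$right_edge, geom, "right_edge")
    )
    if (spec$placement_jitter > 0) {
      jit <- pos + matrix(stats::rnorm(2 * nrow(pos), 0, spec$placement_jitter),
                          ncol = 2)
      lab <- rep(c("middle", "left_edge", "right_edge"),
                 c(n_mid, n_left, n_right))
      ok <- classify_points(jit[, 1], jit[, 2], geom) == lab
      pos[ok, ] <- jit[ok, ]
    }
    region <- rep(c("middle", "edge"), c(n_mid, n_edge))
    mu <- ifelse(region == "middle", mu_mid, spec$edge_speed)
    s <- rtruncnorm_nonneg(spec$n_fish, mu, spec$speed_sd)
    az <- stats::rnorm(spec$n_fish, 0, 15) * pi / 180
    frame_table(number = seq_len(spec$n_fish),
                x = pos[, 1], y = pos[, 2],
                speed_x = abs(s * cos(az)), speed_y = s * sin(az),
                speed = s, frame = f)
  })
  out <- validate_frame_table(do.call(rbind, frames))
  attr(out, "n_middle") <- n_mid
  attr(out, "n_edge") <- n_edge
  out
}

# normal truncated at zero via rejection; degenerate sd gives the mean
rtruncnorm_nonneg <- function(n, mean, sd) {
  if (all(sd == 0)) return(rep(mean, length.out = n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < 0)
  }
  out
}

#' Generate synthetic tube summaries from the angle-ratio laws
#'
#' Draws one summary row per angle with the speed ratio on the linear law
#' (plus additive Gaussian noise) and the count ratio on the exponential law
#' (times log-normal noise), for fit-recovery testing.
#'
#' @param angles included angles, degrees.
#' @param slope,intercept linear speed-ratio law coefficients.
#' @param alpha,beta exponential count-ratio law coefficients.
#' @param noise_sd noise scale (additive for ratio_s, on the log for
#'   ratio_n); 0 puts the rows exactly on the laws.
#' @param seed RNG seed.
#' @return data.frame: `tube_id`, `angle_deg`, `cosine`, `mean_ratio_s`,
#'   `mean_ratio_n`.
#' @export
generate_summary_dataset <- function(angles,
                                     slope = 1.5033, intercept = 0.1545,
                                     alpha = 3.5971, beta = 2.0173,
                                     noise_sd = 0, seed = 1) {
  stopifnot(length(angles) >= 2, all(angles >= 0 & angles < 90))
  set.seed(seed)
  co <- cos(angles * pi / 180)
  data.frame(
    tube_id = sprintf("synth%02d", seq_along(angles)),
    angle_deg = angles,
    cosine = co,
    mean_ratio_s = slope * co + intercept +
      stats::rnorm(length(angles), 0, noise_sd),
    mean_ratio_n = exp(alpha * co - beta +
                       stats::rnorm(length(angles), 0, noise_sd))
  )
}
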