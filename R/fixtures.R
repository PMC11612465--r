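#' Included angles of the eight study tubes
#'
#' Named vector of the included angles (degrees) of tubes A through H.
#' @export
tube_angles <- c(A = 29.05, B = 5.52, C = 34.12, D = 22.03,
                 E = 23.84, F = 51.00, G = 36.32, H = 19.48)

#' Build a symmetric trapezoidal tube fixture
#'
#' Constructs a tube symmetric about the x-axis with the requested included
#' angle: the exit opening has width `opening_width` at `x = length`, and the
#' entrance widens by `2 * length * tan(angle/2)`. Only the included angle
#' enters any of the region-ratio laws, so symmetric fixtures stand in for the
#' study tubes whose wall coordinates were never published.
#'
#' @param included_angle_deg opening angle between the walls, degrees, in
#'   [0, 90).
#' @param opening_width exit (narrow) opening width, px.
#' @param length tube length along the x-axis, px.
#' @param tube_id label; defaults to the angle.
#' @return A `tube_geometry`.
#' @examples
#' included_angle(make_tube_fixture(51))
#' @export
make_tube_fixture <- function(included_angle_deg, opening_width = 200,
                              length = 400,
                              tube_id = sprintf("tube%.2f", included_angle_deg)) {
  if (!is.finite(included_angle_deg) ||
      included_angle_deg < 0 || included_angle_deg >= 90)
    stop("included angle must lie in [0, 90) degrees")
  stopifnot(opening_width > 0, length > 0)
  half_out <- opening_width / 2
  half_in <- half_out + length * tan(included_angle_deg / 2 * pi / 180)
  tube_geometry(
    wall_left = rbind(c(0, half_in), c(length, half_out)),
    wall_right = rbind(c(0, -half_in), c(length, -half_out)),
    tube_id = tube_id
  )
}

#' Geometry fixture for one of the study tubes
#'
#' @param tube one of `"A"` ... `"H"`.
#' @param ... passed to [make_tube_fixture()].
#' @export
tube_fixture <- function(tube = names(tube_angles), ...) {
  tube <- match.arg(tube)
  make_tube_fixture(tube_angles[[tube]], tube_id = tube, ...)
}
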