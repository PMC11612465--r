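#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 2 with nonzero variance.
#' @return Pearson r in [-1, 1].
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y, method = "pearson")
}

#' Fit the linear speed-ratio law
#'
#' Ordinary least squares of the middle/edge speed ratio on the cosine of the
#' tube's included angle: `ratio_s = slope * cos(theta) + intercept`.
#'
#' @param cosines cosine of each tube's included angle.
#' @param ratios_s middle/edge mean-speed ratio per tube.
#' @return Object of class `linear_law`: `slope`, `intercept`, `corr`
#'   (Pearson r of the two inputs), `n_points`, `residuals`.
#' @export
fit_linear_law <- function(cosines, ratios_s) {
  stopifnot(length(cosines) == length(ratios_s), length(cosines) >= 2)
  if (stats::sd(cosines) == 0) stop("degenerate regressor: all cosines equal")
  fit <- stats::lm(ratios_s ~ cosines)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         corr = pearson_corr(cosines, ratios_s),
         n_points = length(cosines),
         residuals = unname(stats::resid(fit))),
    class = "linear_law"
  )
}

#' Fit the exponential count-ratio law
#'
#' Log-linear least squares for `ratio_n = exp(alpha * cos(theta) - beta)`:
#' `ln(ratio_n)` is regressed on the cosine by OLS. Rows with nonpositive
#' ratio (an empty middle region) cannot enter the log fit; they are excluded
#' and reported.
#'
#' @param cosines cosine of each tube's included angle.
#' @param ratios_n middle/edge count ratio per tube.
#' @param mse_scale scale on which the mean squared error is reported:
#'   `"linear"` (residuals of the back-transformed ratio, default) or
#'   `"log"` (residuals of ln ratio).
#' @return Object of class `exponential_law`: `alpha`, `beta`, `mse`,
#'   `mse_scale`, `n_points`, `excluded` (indices of dropped rows).
#' @export
fit_exponential_law <- function(cosines, ratios_n,
                                mse_scale = c("linear", "log")) {
  mse_scale <- match.arg(mse_scale)
  stopifnot(length(cosines) == length(ratios_n))
  keep <- which(is.finite(ratios_n) & ratios_n > 0)
  if (length(keep) < 2)
    stop("need at least 2 positive count ratios for the log-linear fit")
  x <- cosines[keep]; ly <- log(ratios_n[keep])
  if (stats::sd(x) == 0) stop("degenerate regressor: all cosines equal")
  fit <- stats::lm(ly ~ x)
  alpha <- unname(stats::coef(fit)[2])
  beta <- -unname(stats::coef(fit)[1])
  pred <- exp(alpha * x - beta)
  err <- if (mse_scale == "linear") mse(ratios_n[keep], pred)
         else mse(ly, log(pred))
  structure(
    list(alpha = alpha, beta = beta, mse = err, mse_scale = mse_scale,
         n_points = length(keep), excluded = setdiff(seq_along(ratios_n), keep)),
    class = "exponential_law"
  )
}

#' Mean squared error
#'
#' @param y observed values.
#' @param y_hat predicted values, same length.
#' @export
mse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch between y and y_hat")
  stopifnot(length(y) >= 1)
  mean((y - y_hat)^2)
}

# published coefficients of the two angle-ratio laws
speed_law_coef <- c(slope = 1.5033, intercept = 0.1545)
count_law_coef <- c(alpha = 3.5971, beta = 2.0173)

check_theta <- function(theta_deg) {
  if (!all(is.finite(theta_deg)) || any(theta_deg < 0) || any(theta_deg > 90))
    stop("included angle must lie in [0, 90] degrees")
  theta_deg
}

#' Predict the middle/edge speed ratio from the tube angle
#'
#' Evaluates the linear speed-ratio law
#' `ratio_s = 1.5033 * cos(theta) + 0.1545` (published coefficients by
#' default; pass a fitted `linear_law` to use its own).
#'
#' @param theta_deg included angle, degrees, in [0, 90].
#' @param law optional `linear_law` with `slope`/`intercept`.
#' @export
predict_speed_ratio <- function(theta_deg, law = NULL) {
  check_theta(theta_deg)
  co <- if (is.null(law)) speed_law_coef
        else c(slope = law$slope, intercept = law$intercept)
  co[["slope"]] * cos(theta_deg * pi / 180) + co[["intercept"]]
}

#' Predict the middle/edge count ratio from the tube angle
#'
#' Evaluates the exponential count-ratio law
#' `ratio_n = exp(3.5971 * cos(theta) - 2.0173)` (published coefficients by
#' default; pass a fitted `exponential_law` to use its own).
#'
#' @inheritParams predict_speed_ratio
#' @param law optional `exponential_law` with `alpha`/`beta`.
#' @export
predict_number_ratio <- function(theta_deg, law = NULL) {
  check_theta(theta_deg)
  co <- if (is.null(law)) count_law_coef
        else c(alpha = law$alpha, beta = law$beta)
  exp(co[["alpha"]] * cos(theta_deg * pi / 180) - co[["beta"]])
}

#' @export
print.linear_law <- function(x, ...) {
  cat(sprintf("<linear_law> ratio_s = %.4f * cos(theta) + %.4f  (r = %.2f, n = %d)\n",
              x$slope, x$intercept, x$corr, x$n_points))
  invisible(x)
}

#' @export
print.exponential_law <- function(x, ...) {
  cat(sprintf("<exponential_law> ratio_n = exp(%.4f * cos(theta) - %.4f)  (MSE[%s] = %.4g, n = %d)\n",
              x$alpha, x$beta, x$mse_scale, x$mse, x$n_points))
  invisible(x)
}

#' Serialize a fitted law to JSON
#'
#' @param law a `linear_law` or `exponential_law`.
#' @param path optional file to write; otherwise the JSON string is returned.
#' @export
law_to_json <- function(law, path = NULL) {
  obj <- if (inherits(law, "linear_law")) {
    list(law = "linear", coefficients = list(slope = law$slope,
                                             intercept = law$intercept),
         corr = law$corr, n_points = law$n_points)
  } else if (inherits(law, "exponential_law")) {
    list(law = "exponential", coefficients = list(alpha = law$alpha,
                                                  beta = law$beta),
         mse = law$mse, mse_scale = law$mse_scale, n_points = law$n_points,
         excluded_rows = law$excluded)
  } else stop("not a fitted law object")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(path)) }
  js
}
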