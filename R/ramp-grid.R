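#' Stress-ramp protocol
#'
#' Describes the logarithmic stress ramp applied by a stress-controlled
#' rheometer: the default reproduces the standard clot protocol of 0.01 Pa
#' to 10,000 Pa with 20 points per decade, dwelling 10 s at each stress.
#'
#' @param sigma_start First applied stress (Pa); must be positive.
#' @param sigma_end Last applied stress (Pa); must exceed `sigma_start`.
#' @param points_per_decade Number of grid points per factor-10 interval;
#'   the grid is `10^(k / points_per_decade)`. The degenerate value 1
#'   (decade endpoints only) is allowed.
#' @param dwell Seconds spent at each stress point.
#'
#' @return An object of class `ramp_protocol`.
#' @seealso [make_ramp_grid()]
#' @export
#' @examples
#' make_ramp_grid(ramp_protocol())[1:5]
ramp_protocol <- function(sigma_start = 0.01, sigma_end = 10000,
                          points_per_decade = 20, dwell = 10) {
  stop_if_not_scalar_pos(sigma_start, "sigma_start")
  stop_if_not_scalar_pos(sigma_end, "sigma_end")
  if (sigma_end <= sigma_start)
    stop("`sigma_end` must be greater than `sigma_start`", call. = FALSE)
  if (!is.numeric(points_per_decade) || points_per_decade < 1)
    stop("`points_per_decade` must be at least 1", call. = FALSE)
  stop_if_not_scalar_pos(dwell, "dwell")
  structure(list(sigma_start = sigma_start, sigma_end = sigma_end,
                 points_per_decade = points_per_decade, dwell = dwell),
            class = "ramp_protocol")
}

#' Logarithmic stress grid for a ramp protocol
#'
#' Builds the ordered sequence of applied stresses: strictly increasing,
#' logarithmically spaced with exactly `points_per_decade` points per
#' factor-10 interval, starting at `sigma_start` and not exceeding
#' `sigma_end` (which is included when it falls on the grid, as it does for
#' the default protocol).
#'
#' @param protocol A [ramp_protocol()].
#' @return Numeric vector of stresses (Pa).
#' @export
make_ramp_grid <- function(protocol = ramp_protocol()) {
  stopifnot(inherits(protocol, "ramp_protocol"))
  step <- 1 / protocol$points_per_decade
  n_dec <- log10(protocol$sigma_end / protocol$sigma_start)
  k <- seq(0, floor(n_dec / step + 1e-9))
  sigma <- protocol$sigma_start * 10^(k * step)
  sigma[sigma <= protocol$sigma_end * (1 + 1e-12)]
}

#' @export
print.ramp_protocol <- function(x, ...) {
  cat(sprintf(
    "<ramp_protocol> %g -> %g Pa, %g points/decade, %g s dwell (%d points)\n",
    x$sigma_start, x$sigma_end, x$points_per_decade, x$dwell,
    length(make_ramp_grid(x))))
  invisible(x)
}
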