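#' Angle utilities for orientation data
#'
#' Orientations live on a 180-degree circle: a grating at 181 degrees is the
#' same stimulus as one at 1 degree. All public interfaces use degrees;
#' Fisher-information arithmetic is done in radians on \[0, pi).
#'
#' @param x numeric vector of angles in degrees.
#' @param period circle period in degrees (180 for orientations).
#' @return `wrap_ori()` returns angles reduced into \[0, period);
#'   `circ_diff_ori()` returns signed differences in \[-period/2, period/2).
#' @examples
#' wrap_ori(c(181, -5))        # 1, 175
#' circ_diff_ori(175, 5)       # -10: 175 deg is 10 deg "below" 5 deg
#' @export
wrap_ori <- function(x, period = 180) {
  out <- x %% period
  # guard against -1e-18 %% 180 == 180 from floating-point roundoff
  out[out >= period] <- 0
  out
}

#' @rdname wrap_ori
#' @param a,b numeric vectors of angles in degrees; the result is `a - b`
#'   reduced onto the half-open interval centred at zero.
#' @export
circ_diff_ori <- function(a, b, period = 180) {
  d <- (a - b) %% period
  d[d >= period / 2] <- d[d >= period / 2] - period
  d
}

deg2rad <- function(x) x * pi / 180

rad2deg <- function(x) x * 180 / pi
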