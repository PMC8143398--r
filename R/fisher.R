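#' Extract the square root of Fisher information from a bias/variance profile
#'
#' Applies the biased-estimator Cramer-Rao bound, assumed tight:
#' \deqn{\sqrt{I_F(\theta)} = \frac{1 + b'(\theta)}{\sigma(\theta)}}
#' with the bias derivative taken by circular central differences on the
#' grid. Bias is converted to orientation radians and the standard
#' deviation is placed on the same scale: the profile's `variance` is the
#' reciprocal concentration 1/kappa of the doubled-angle von Mises fit, so
#' \eqn{\sigma(\theta) = \sqrt{1/\kappa}/2} in orientation radians (the
#' doubled-angle to orientation conversion).
#'
#' Missing grid points are filled by circular linear interpolation and
#' negative raw values (possible in noisy windows) are floored at zero;
#' both are flagged.
#'
#' @param profile a `bias_profile` from [sliding_profile()].
#' @return a `fisher_profile` tibble with columns `theta_deg`, `sqrt_fi`
#'   (1/radian), `prior` (normalized sqrt-FI, integrates to 1 over
#'   \[0, pi)), `floored`; attributes `total` (the trapezoidal
#'   \eqn{\int_0^\pi \sqrt{I_F}\,d\theta}, the total-resource measure),
#'   `total_fi_alt` (\eqn{\int I_F\,d\theta}, reported alongside for
#'   comparison) and `n_floored`.
#' @export
extract_sqrt_fi <- function(profile) {
  if (sum(!profile$missing) < 3) {
    rlang::abort("need at least 3 valid grid points",
                 class = "orienc_empty_error")
  }
  b <- deg2rad(fill_circular(ifelse(profile$missing, NA_real_,
                                    profile$bias_deg)))
  v <- fill_circular(ifelse(profile$missing, NA_real_, profile$variance))
  if (any(v <= 0)) {
    rlang::abort("degenerate (non-positive) variance on the grid",
                 class = "orienc_degenerate_error")
  }
  sigma <- sqrt(v) / 2                      # orientation radians
  n <- length(b)
  step <- deg2rad(profile$theta_deg[2] - profile$theta_deg[1])
  db <- (b[c(2:n, 1)] - b[c(n, 1:(n - 1))]) / (2 * step)
  raw <- (1 + db) / sigma
  floored <- raw < 0
  sqrt_fi <- pmax(raw, 0)
  total <- mean(sqrt_fi) * pi               # circular trapezoid, uniform grid
  fp <- tibble::tibble(theta_deg = profile$theta_deg, sqrt_fi = sqrt_fi,
                       prior = if (total > 0) sqrt_fi / total else NA_real_,
                       floored = floored)
  attr(fp, "total") <- total
  attr(fp, "total_fi_alt") <- mean(sqrt_fi^2) * pi
  attr(fp, "n_floored") <- sum(floored)
  class(fp) <- c("fisher_profile", class(fp))
  fp
}

#' Efficient-coding prior from a Fisher profile
#'
#' Under efficient coding the square root of Fisher information is
#' proportional to the stimulus prior, so the normalized sqrt-FI profile is
#' a direct estimate of the prior density on \[0, pi).
#'
#' @param fp a `fisher_profile`.
#' @return numeric vector of prior densities (1/radian) on the profile
#'   grid; integrates to 1.
#' @export
normalize_prior <- function(fp) {
  total <- mean(fp$sqrt_fi) * pi
  if (total <= 0) {
    rlang::abort("total sqrt-FI is zero; cannot normalize",
                 class = "orienc_degenerate_error")
  }
  fp$sqrt_fi / total
}

#' Total encoding resource
#'
#' The denominator of the prior normalization,
#' \eqn{\int_0^\pi \sqrt{I_F(\theta)}\,d\theta}, is a direct measure of the
#' total amount of resource available for encoding; for data generated
#' exactly from the parametric model it equals lambda.
#'
#' @param fp a `fisher_profile`.
#' @return scalar total resource (dimensionless).
#' @export
total_resource <- function(fp) {
  mean(fp$sqrt_fi) * pi
}
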