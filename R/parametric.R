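# Parametric (lambda, omega) model of the sqrt-FI profile.
#
# sqrt(I_F)(theta; lambda, omega) =
#     lambda * (omega * c * (1 - |sin 2 theta|) + (1 - omega) / pi)
#
# with c = 1/(pi - 2) so the bracketed mixture is a density on [0, pi):
# lambda is the total resource (integral of sqrt-FI) and omega the weight
# on the cardinal-peaked component. The printed rounded constant 0.877 is
# available via `analysis_config(cardinal_norm = "printed")` for
# bit-comparison with legacy analyses; the mixture is then renormalized so
# it still integrates to 1.

#' Parametric square root of Fisher information
#'
#' @param theta_rad orientations in radians, \[0, pi).
#' @param lam lambda > 0, the total sqrt-FI resource.
#' @param omega mixture weight on the cardinal component, in \[0, 1\].
#' @param c_norm cardinal-density normalizer (default the analytic
#'   `1/(pi - 2)`).
#' @return sqrt-FI values in 1/radian; period pi/2 in theta.
#' @export
parametric_sqrt_fi <- function(theta_rad, lam, omega,
                               c_norm = 1 / (pi - 2)) {
  check_fi_params(lam, omega)
  z <- mixture_norm(omega, c_norm)
  lam * (omega * c_norm * (1 - abs(sin(2 * theta_rad))) +
           (1 - omega) / pi) / z
}

check_fi_params <- function(lam, omega) {
  if (!is.finite(lam) || lam <= 0) {
    rlang::abort("lambda must be > 0", class = "orienc_domain_error")
  }
  if (!is.finite(omega) || omega < 0 || omega > 1) {
    rlang::abort("omega must lie in [0, 1]", class = "orienc_domain_error")
  }
  invisible(TRUE)
}

# Integral of the mixture over [0, pi); exactly 1 for the analytic c_norm.
mixture_norm <- function(omega, c_norm) {
  omega * c_norm * (pi - 2) + (1 - omega)
}

# G(theta) = int_0^theta (1 - |sin 2t|) dt, closed form, period pi/2.
cardinal_G <- function(theta) {
  k <- floor(theta / (pi / 2))
  r <- theta - k * pi / 2
  k * (pi / 2 - 1) + r - (1 - cos(2 * r)) / 2
}

# Mixture density and CDF on [0, pi); vectorized over theta and omega.
mixture_pdf <- function(theta, omega, c_norm = 1 / (pi - 2)) {
  (omega * c_norm * (1 - abs(sin(2 * theta))) + (1 - omega) / pi) /
    mixture_norm(omega, c_norm)
}

mixture_cdf <- function(theta, omega, c_norm = 1 / (pi - 2)) {
  (omega * c_norm * cardinal_G(theta) + (1 - omega) * theta / pi) /
    mixture_norm(omega, c_norm)
}

# Inverse CDF by vectorized bisection; u in [0, 1), omega recycled.
mixture_icdf <- function(u, omega, c_norm = 1 / (pi - 2)) {
  n <- max(length(u), length(omega))
  u <- rep_len(u, n); omega <- rep_len(omega, n)
  lo <- rep(0, n); hi <- rep(pi, n)
  for (i in 1:52) {
    mid <- (lo + hi) / 2
    below <- mixture_cdf(mid, omega, c_norm) < u
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Predicted bias under the parametric encoding model
#'
#' Integrates the tight-bound relation: given the model sqrt-FI and the
#' measured standard deviation profile,
#' \deqn{\hat b(\theta) = \int_0^\theta
#'   \left(\sqrt{I_F(t;\lambda,\omega)}\,\sigma(t) - 1\right) dt,}
#' by cumulative trapezoid on the grid, anchored at \eqn{\hat b(0) = 0}.
#' When 90-degree periodicity is enforced the integral is computed on the
#' folded \[0, pi/2) domain, mean-centred per cycle, and tiled.
#'
#' @param lam,omega model parameters.
#' @param sigma_rad measured standard deviation profile in orientation
#'   radians (same length as `grid_rad`).
#' @param grid_rad uniform orientation grid in radians covering \[0, pi).
#' @param enforce_period_90 fold to \[0, pi/2) and tile.
#' @param c_norm cardinal-density normalizer.
#' @return predicted bias in radians on `grid_rad`.
#' @export
predict_bias <- function(lam, omega, sigma_rad, grid_rad,
                         enforce_period_90 = TRUE,
                         c_norm = 1 / (pi - 2)) {
  if (length(sigma_rad) != length(grid_rad)) {
    rlang::abort("sigma and grid must have the same length",
                 class = "orienc_domain_error")
  }
  if (any(!is.finite(sigma_rad)) || any(sigma_rad <= 0)) {
    rlang::abort("sigma profile must be finite and positive on the grid",
                 class = "orienc_degenerate_error")
  }
  n <- length(grid_rad)
  step <- grid_rad[2] - grid_rad[1]
  integrand <- parametric_sqrt_fi(grid_rad, lam, omega, c_norm) *
    sigma_rad - 1
  if (enforce_period_90) {
    half <- n %/% 2
    f <- (integrand[1:half] + integrand[half + (1:half)]) / 2
    b <- cumtrapz(f, step)
    b <- b - mean(b)
    rep(b, 2)[1:n]
  } else {
    cumtrapz(integrand, step)
  }
}

cumtrapz <- function(f, step) {
  n <- length(f)
  c(0, cumsum((f[-n] + f[-1]) / 2 * step))
}

#' Fit the (lambda, omega) encoding model to an observed bias profile
#'
#' Minimizes the sum of squared differences between the bias predicted by
#' [predict_bias()] (using the measured sigma profile, exactly as in the
#' extraction) and the observed bias, with bounded L-BFGS-B from a small
#' deterministic multi-start grid: lambda0 in \{0.5, 1, 2\} times the
#' nonparametric total resource, omega0 in \{0.1, 0.5, 0.9\}.
#'
#' @param profile a `bias_profile` from [sliding_profile()].
#' @param enforce_period_90 fold the prediction to 90-degree periodicity;
#'   `NULL` (default) infers it from the profile's folding.
#' @param c_norm cardinal-density normalizer.
#' @param lambda_bounds search bounds for lambda.
#' @return list of class `fi_params`: `lam`, `omega`, `r2` (against the
#'   observed bias), `converged`, `init` (the winning start), `objective`.
#' @export
fit_fi_params <- function(profile, enforce_period_90 = NULL,
                          c_norm = 1 / (pi - 2),
                          lambda_bounds = c(0.1, 100)) {
  if (is.null(enforce_period_90)) {
    enforce_period_90 <- identical(attr(profile, "period_deg"), 90)
  }
  b_obs <- deg2rad(fill_circular(ifelse(profile$missing, NA_real_,
                                        profile$bias_deg)))
  v <- fill_circular(ifelse(profile$missing, NA_real_, profile$variance))
  sigma <- sqrt(v) / 2
  grid <- deg2rad(profile$theta_deg)
  total0 <- total_resource(extract_sqrt_fi(profile))
  total0 <- min(max(total0, lambda_bounds[1] * 2), lambda_bounds[2] / 2)
  objective <- function(par) {
    sum((predict_bias(par[1], par[2], sigma, grid, enforce_period_90,
                      c_norm) - b_obs)^2)
  }
  starts <- expand.grid(lam = c(0.5, 1, 2) * total0,
                        omega = c(0.1, 0.5, 0.9))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), objective,
                        method = "L-BFGS-B",
                        lower = c(lambda_bounds[1], 0),
                        upper = c(lambda_bounds[2], 1),
                        control = list(factr = 1e2, maxit = 500))
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$init <- as.numeric(starts[i, ])
    }
  }
  ss_res <- best$value
  ss_tot <- sum((b_obs - mean(b_obs))^2)
  structure(list(lam = best$par[1], omega = best$par[2],
                 r2 = 1 - ss_res / ss_tot,
                 converged = best$convergence == 0,
                 init = best$init, objective = best$value),
            class = "fi_params")
}
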