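# Efficient-coding encoder-decoder observer simulation.
#
# The encoder maps the stimulus through the cumulative of its prior onto a
# uniform internal space (the unit circle, scaled to 2*pi), where it is
# corrupted by homogeneous von Mises noise of concentration kappa. Any
# bound-attaining decoder maps the internal measurement back to an
# orientation estimate. Under this construction the encoder's analytic
# sqrt-FI profile is 2*pi*sqrt(kappa)*p(theta) -- proportional to the
# prior, as efficient coding requires -- on the concentration-based
# precision convention (sigma^2 = 1/kappa) used throughout the analysis.

#' Construct a parametric mixture encoder
#'
#' The prior is the (lambda, omega) model's normalized sqrt-FI: a mixture
#' of a cardinal-peaked density and the uniform density. Exactly one of
#' `lam` or `internal_kappa` must be given; they are linked by
#' `lam = 2 * pi * sqrt(internal_kappa)`, so a cohort simulated at a given
#' lambda feeds back that lambda through the extraction pipeline.
#'
#' @param omega mixture weight in \[0, 1\].
#' @param lam target total sqrt-FI resource (> 0).
#' @param internal_kappa concentration of the internal von Mises noise.
#' @param c_norm cardinal-density normalizer.
#' @return an `encoder_spec`: functions `prior`, `cum_map`, `inv_map`,
#'   `sqrt_fi` (all on orientation radians) plus `kappa`, `lam`, `omega`.
#' @examples
#' enc <- encoder_from_params(omega = 0, lam = 10)
#' enc$cum_map(pi / 2)   # 0.5: linear map when the prior is uniform
#' @export
encoder_from_params <- function(omega, lam = NULL, internal_kappa = NULL,
                                c_norm = 1 / (pi - 2)) {
  if (!is.finite(omega) || omega < 0 || omega > 1) {
    rlang::abort("omega must lie in [0, 1]", class = "orienc_domain_error")
  }
  if (is.null(internal_kappa)) {
    check_fi_params(lam, omega)
    internal_kappa <- (lam / (2 * pi))^2
  } else {
    stopifnot(internal_kappa > 0)
    lam <- 2 * pi * sqrt(internal_kappa)
  }
  force(omega); force(c_norm)
  k <- internal_kappa
  structure(list(
    prior = function(theta) mixture_pdf(theta, omega, c_norm),
    cum_map = function(theta) mixture_cdf(theta, omega, c_norm),
    inv_map = function(u) mixture_icdf(u, omega, c_norm),
    sqrt_fi = function(theta) 2 * pi * sqrt(k) *
      mixture_pdf(theta, omega, c_norm),
    kappa = k, lam = lam, omega = omega, kind = "mixture"
  ), class = "encoder_spec")
}

#' Construct an encoder from an arbitrary prior density
#'
#' The density is normalized numerically on a fine grid; its cumulative
#' becomes the stimulus-to-internal-space mapping.
#'
#' @param prior_fn vectorized density function on \[0, pi) (any positive
#'   function; it is renormalized).
#' @param internal_kappa concentration of the internal von Mises noise.
#' @param n_grid grid resolution for the numerical cumulative.
#' @return an `encoder_spec` (see [encoder_from_params()]).
#' @export
encoder_from_prior <- function(prior_fn, internal_kappa, n_grid = 4001) {
  stopifnot(internal_kappa > 0, n_grid >= 101)
  grid <- seq(0, pi, length.out = n_grid)
  p <- prior_fn(grid)
  if (any(!is.finite(p)) || any(p < 0)) {
    rlang::abort("prior density must be finite and nonnegative",
                 class = "orienc_domain_error")
  }
  step <- grid[2] - grid[1]
  Fv <- c(0, cumsum((p[-n_grid] + p[-1]) / 2 * step))
  Z <- Fv[n_grid]
  p <- p / Z
  Fv <- Fv / Z
  pf <- stats::approxfun(grid, p, rule = 2)
  Ff <- stats::approxfun(grid, Fv, yleft = 0, yright = 1)
  Finv <- stats::approxfun(Fv, grid, yleft = 0, yright = pi, ties = "ordered")
  k <- internal_kappa
  structure(list(
    prior = pf, cum_map = Ff, inv_map = Finv,
    sqrt_fi = function(theta) 2 * pi * sqrt(k) * pf(theta),
    kappa = k, lam = 2 * pi * sqrt(k), omega = NA_real_, kind = "numeric"
  ), class = "encoder_spec")
}

#' Decoder specification
#'
#' Three bound-attaining decoder families: `inverse_map` (the MLE-like
#' inverse of the encoder's mapping), `posterior_mean` (circular mean of
#' the posterior over a quadrature grid), and `remapped` (the inverse-map
#' estimate passed through a smooth monotone distortion
#' `g(x) = x + a * sin(4x) / 4`, which preserves the 90-degree period and
#' trades bias against variance while keeping the bound tight to first
#' order). Stimulus-independent late noise (wrapped Gaussian, degrees) can
#' be added after decoding.
#'
#' @param kind decoder family.
#' @param remap_amplitude distortion amplitude `a`, |a| < 1; only used by
#'   `"remapped"`.
#' @param late_noise_sd late-noise standard deviation in degrees, >= 0.
#' @return a `decoder_spec` list.
#' @export
decoder_spec <- function(kind = c("inverse_map", "posterior_mean",
                                  "remapped"),
                         remap_amplitude = 0, late_noise_sd = 0) {
  kind <- match.arg(kind)
  if (abs(remap_amplitude) >= 1) {
    rlang::abort("|remap_amplitude| must be < 1 to keep g monotone",
                 class = "orienc_domain_error")
  }
  if (late_noise_sd < 0) {
    rlang::abort("late_noise_sd must be >= 0",
                 class = "orienc_domain_error")
  }
  structure(list(kind = kind, remap_amplitude = remap_amplitude,
                 late_noise_sd = late_noise_sd), class = "decoder_spec")
}

remap_g <- function(theta, a) {
  (theta + a * sin(4 * theta) / 4) %% pi
}

# Posterior-mean decoder as a lookup table theta_hat(m): the posterior
# depends on the trial only through the internal measurement m, so it is
# tabulated once on a fine m grid and interpolated (via sin/cos of the
# doubled estimate, so interpolation respects the wrap).
posterior_mean_lookup <- function(encoder, n_m = 1024, n_theta = 720) {
  tg <- (seq_len(n_theta) - 0.5) * pi / n_theta
  w <- encoder$prior(tg)
  mu <- 2 * pi * encoder$cum_map(tg)
  mg <- (seq_len(n_m) - 1) * 2 * pi / n_m
  # n_m x n_theta likelihood matrix
  lik <- exp(encoder$kappa * (cos(outer(mg, mu, "-")) - 1))
  post <- lik * rep(w, each = n_m)
  zc <- post %*% cos(2 * tg)
  zs <- post %*% sin(2 * tg)
  est <- (atan2(zs, zc) / 2) %% pi
  mg2 <- c(mg, 2 * pi)
  s2 <- c(sin(2 * est), sin(2 * est[1]))
  c2 <- c(cos(2 * est), cos(2 * est[1]))
  sfun <- stats::approxfun(mg2, s2)
  cfun <- stats::approxfun(mg2, c2)
  function(m) (atan2(sfun(m), cfun(m)) / 2) %% pi
}

#' Simulate responses of an encoder-decoder observer
#'
#' The pipeline per trial: the target is mapped to the internal space,
#' perturbed by von Mises noise of concentration `encoder$kappa`, decoded
#' by the chosen decoder, optionally remapped, and optionally perturbed by
#' wrapped late noise.
#'
#' @param encoder an `encoder_spec`.
#' @param decoder a `decoder_spec`.
#' @param theta_deg target orientations in degrees, \[0, 180).
#' @param seed optional integer seed.
#' @return response orientations in degrees, \[0, 180).
#' @export
simulate_trials <- function(encoder, decoder, theta_deg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- deg2rad(wrap_ori(theta_deg))
  n <- length(theta)
  psi <- 2 * pi * encoder$cum_map(theta)
  m <- (psi + rvonmises(n, encoder$kappa)) %% (2 * pi)
  est <- switch(decoder$kind,
    inverse_map = encoder$inv_map(m / (2 * pi)),
    remapped = remap_g(encoder$inv_map(m / (2 * pi)),
                       decoder$remap_amplitude),
    posterior_mean = {
      if (!is.finite(encoder$kappa)) encoder$inv_map(m / (2 * pi))
      else posterior_mean_lookup(encoder)(m)
    })
  out <- rad2deg(est)
  if (decoder$late_noise_sd > 0) {
    out <- out + stats::rnorm(n, 0, decoder$late_noise_sd)
  }
  wrap_ori(out)
}

#' Add stimulus-independent late noise to recorded responses
#'
#' @param data a `trial_data` tibble.
#' @param sd wrapped-Gaussian noise standard deviation in degrees.
#' @param seed optional integer seed.
#' @return the dataset with perturbed responses; targets untouched.
#' @export
add_late_noise <- function(data, sd, seed = NULL) {
  if (sd < 0) {
    rlang::abort("late-noise sd must be >= 0",
                 class = "orienc_domain_error")
  }
  if (sd == 0) return(data)
  if (!is.null(seed)) set.seed(seed)
  data$response_deg <- wrap_ori(data$response_deg +
                                  stats::rnorm(nrow(data), 0, sd))
  data
}
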