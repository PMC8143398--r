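# Shared fixtures, built in code.

# Small simulated observer dataset (single block, single observer).
sim_observer_data <- function(n = 2000, lam = 15, omega = 0.5, seed = 1,
                              decoder = decoder_spec("inverse_map")) {
  enc <- encoder_from_params(omega = omega, lam = lam)
  set.seed(seed)
  th <- stats::runif(n) * 180
  resp <- simulate_trials(enc, decoder, th, seed = seed + 1)
  tibble::tibble(target_deg = th, response_deg = resp)
}

# Minimal valid trial_data tibble.
tiny_trials <- function() {
  as_trial_data(tibble::tibble(
    participant_id = rep(c("p01", "p02"), each = 3),
    group = rep(c("NT", "ASD"), each = 3),
    block = "woFB",
    trial_index = rep(0:2, 2),
    target_deg = c(10, 45, 90, 135, 170, 5),
    response_deg = c(12, 44, 91, 133, 172, 6),
    rt_s = 1.5))
}

# Analytic bias_profile generated exactly from the parametric model.
model_profile <- function(lam, omega, sigma = 0.25, step = 1) {
  grid_deg <- seq(0, 180 - step, by = step)
  grid <- grid_deg * pi / 180
  sig <- rep(sigma, length(grid))
  b <- predict_bias(lam, omega, sig, grid, enforce_period_90 = TRUE)
  prof <- tibble::tibble(theta_deg = grid_deg, bias_deg = b * 180 / pi,
                         kappa = 1 / (2 * sig)^2, variance = (2 * sig)^2,
                         n = 1000L, missing = FALSE)
  attr(prof, "window_deg") <- 4
  attr(prof, "period_deg") <- 90
  class(prof) <- c("bias_profile", class(prof))
  prof
}
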