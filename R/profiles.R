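#' Sliding-window bias/variance profile
#'
#' Implements the first stage of the encoding analysis: for every grid
#' orientation, all trials whose target falls within a window centred there
#' are pooled, a von Mises distribution is fitted to the (doubled-angle)
#' responses, and the window's bias is the circular difference between the
#' fitted mean and the window centre. The variance proxy is `1/kappa`.
#'
#' Windows are half-open (`center - w/2` inclusive, `center + w/2`
#' exclusive) and wrap across the 0/180 boundary. With `fold_90 = TRUE`
#' orientations are first folded modulo 90 degrees, imposing the 90-degree
#' periodicity of the oblique effect; the returned profile is tiled back
#' onto the full \[0, 180) grid so that downstream stages are agnostic to
#' the folding.
#'
#' @param data a `trial_data` tibble (or any data frame with `target_deg`
#'   and `response_deg`).
#' @param window_deg window width in degrees.
#' @param grid_step_deg grid step in degrees.
#' @param fold_90 impose 90-degree periodicity by folding before windowing.
#' @param kappa_cap clamp for degenerate concentration estimates.
#' @param min_n minimum trials per window; sparser windows are flagged
#'   missing.
#' @param strict escalate the ">20% missing grid points" warning to an
#'   error.
#' @return a `bias_profile` tibble with columns `theta_deg`, `bias_deg`,
#'   `kappa`, `variance` (= 1/kappa), `n`, `missing`, and attributes
#'   `window_deg`, `period_deg`.
#' @export
sliding_profile <- function(data, window_deg, grid_step_deg = 1,
                            fold_90 = FALSE, kappa_cap = 1e4, min_n = 2,
                            strict = FALSE) {
  if (nrow(data) == 0) {
    rlang::abort("empty dataset", class = "orienc_empty_error")
  }
  stopifnot(window_deg > grid_step_deg)
  period <- if (fold_90) 90 else 180
  err <- circ_diff_ori(data$response_deg, data$target_deg)  # [-90, 90)
  target <- wrap_ori(data$target_deg, period)
  centers <- seq(0, period - grid_step_deg, by = grid_step_deg)
  half <- window_deg / 2
  nw <- integer(length(centers))
  C <- numeric(length(centers)); S <- numeric(length(centers))
  # the von Mises fit is done on each trial's deviation from the window
  # centre (target offset reduced modulo the working period, plus the
  # response error), so that under folding trials on either side of the
  # 0/90 boundary pool coherently
  for (i in seq_along(centers)) {
    d <- circ_diff_ori(target, centers[i], period)
    inw <- d >= -half & d < half
    nw[i] <- sum(inw)
    delta <- (d[inw] + err[inw]) * (pi / 90)    # doubled deviation, radians
    C[i] <- sum(cos(delta)); S[i] <- sum(sin(delta))
  }
  ok <- nw >= min_n
  rbar <- rep(NA_real_, length(centers))
  rbar[ok] <- pmin(sqrt(C[ok]^2 + S[ok]^2) / nw[ok], 1)
  kappa <- rep(NA_real_, length(centers))
  clamped <- !is.na(rbar) & rbar >= 1 - 1e-12
  est <- ok & !clamped
  kappa[est] <- pmin(vm_A_inv(rbar[est]), kappa_cap)
  kappa[clamped] <- kappa_cap
  bias <- rep(NA_real_, length(centers))
  bias[ok] <- circ_diff_ori(atan2(S[ok], C[ok]) * 90 / pi, 0)
  frac_missing <- mean(!ok)
  if (frac_missing > 0.2) {
    msg <- sprintf("%.0f%% of grid points have < %d trials in their window",
                   100 * frac_missing, min_n)
    if (strict) rlang::abort(msg, class = "orienc_sparse_error")
    rlang::warn(msg)
  }
  prof <- tibble::tibble(theta_deg = centers, bias_deg = bias, kappa = kappa,
                         variance = 1 / kappa, n = nw, missing = !ok)
  if (fold_90) {                            # tile back onto [0, 180)
    upper <- prof
    upper$theta_deg <- upper$theta_deg + 90
    prof <- dplyr::bind_rows(prof, upper)
  }
  attr(prof, "window_deg") <- window_deg
  attr(prof, "period_deg") <- period
  class(prof) <- c("bias_profile", class(prof))
  prof
}

# Circular linear interpolation of missing grid values (used before FI
# extraction and model fitting). Returns the filled vector.
fill_circular <- function(x) {
  miss <- !is.finite(x)
  if (!any(miss)) return(x)
  if (all(miss)) {
    rlang::abort("profile has no valid grid points",
                 class = "orienc_empty_error")
  }
  n <- length(x)
  idx <- seq_len(n)
  # tile to handle wrap-around, then interpolate the central copy
  xx <- rep(x, 3)
  ii <- c(idx - n, idx, idx + n)
  fit <- stats::approx(ii[is.finite(xx)], xx[is.finite(xx)], xout = idx)$y
  x[miss] <- fit[miss]
  x
}

#' Root-mean-square error profile
#'
#' Per-orientation RMSE of the signed circular estimation error within the
#' same sliding windows as [sliding_profile()], plus the overall RMSE over
#' all trials.
#'
#' @inheritParams sliding_profile
#' @return list with `profile` (tibble `theta_deg`, `rmse_deg`, `n`,
#'   `missing`) and `overall_rmse_deg`.
#' @export
rmse_profile <- function(data, window_deg, grid_step_deg = 1,
                         fold_90 = FALSE, min_n = 2) {
  if (nrow(data) == 0) {
    rlang::abort("empty dataset", class = "orienc_empty_error")
  }
  period <- if (fold_90) 90 else 180
  err <- circ_diff_ori(data$response_deg, data$target_deg)
  target <- wrap_ori(data$target_deg, period)
  centers <- seq(0, period - grid_step_deg, by = grid_step_deg)
  half <- window_deg / 2
  e2 <- err^2
  rmse <- rep(NA_real_, length(centers))
  nw <- integer(length(centers))
  for (i in seq_along(centers)) {
    d <- circ_diff_ori(target, centers[i], period)
    inw <- d >= -half & d < half
    nw[i] <- sum(inw)
    if (nw[i] >= min_n) rmse[i] <- sqrt(mean(e2[inw]))
  }
  prof <- tibble::tibble(theta_deg = centers, rmse_deg = rmse, n = nw,
                         missing = nw < min_n)
  if (fold_90) {
    upper <- prof
    upper$theta_deg <- upper$theta_deg + 90
    prof <- dplyr::bind_rows(prof, upper)
  }
  list(profile = prof, overall_rmse_deg = sqrt(mean(e2)))
}
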