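# von Mises machinery on doubled angles.
#
# Orientation has period 180 deg, so all circular estimation doubles the
# angle (2 theta, period 360) -- the standard axial-statistics treatment --
# and maps results back. kappa is estimated from the mean resultant length
# by the usual piecewise inverse of A(kappa) = I1(kappa)/I0(kappa), refined
# by one Newton step.

# A(kappa) = I1/I0, computed with exponentially scaled Bessel functions so it
# is stable for large kappa.
vm_A <- function(kappa) {
  ifelse(kappa <= 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# Piecewise approximation to A^-1 (Fisher 1993), then one Newton refinement.
vm_A_inv <- function(r) {
  stopifnot(all(r >= 0), all(r <= 1))
  k <- ifelse(r < 0.53,
              2 * r + r^3 + 5 * r^5 / 6,
              ifelse(r < 0.85,
                     -0.4 + 1.39 * r + 0.43 / (1 - r),
                     1 / (r^3 - 4 * r^2 + 3 * r)))
  ok <- is.finite(k) & k > 0 & r < 1
  if (any(ok)) {
    a <- vm_A(k[ok])
    # d/dk A(k) = 1 - A^2 - A/k
    da <- 1 - a^2 - a / k[ok]
    step <- (a - r[ok]) / da
    step[!is.finite(step)] <- 0
    k[ok] <- pmax(k[ok] - step, 0)
  }
  k
}

#' Fit a von Mises distribution to orientation samples
#'
#' Samples are doubled (2 theta, period 360 deg), the circular mean direction
#' and mean resultant length are computed, kappa is recovered by inverting
#' A(kappa), and the mean is mapped back to orientation space.
#'
#' @param samples orientation samples in degrees (period `period`).
#' @param period orientation period in degrees; 180 for gratings.
#' @param kappa_cap upper bound for kappa; degenerate (all-identical) samples
#'   are clamped here and flagged.
#' @return list with `mu` (degrees in \[0, period)), `kappa`, and `clamped`
#'   (TRUE when the resultant length was numerically 1).
#' @examples
#' fit_von_mises_orientation(c(40, 50))$mu   # 45
#' @export
fit_von_mises_orientation <- function(samples, period = 180, kappa_cap = 1e4) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2) {
    rlang::abort("need at least 2 samples to fit a von Mises distribution",
                 class = "orienc_insufficient_data")
  }
  phi <- samples * (2 * pi / period)       # doubled angle in radians
  C <- sum(cos(phi)); S <- sum(sin(phi))
  n <- length(phi)
  rbar <- min(sqrt(C^2 + S^2) / n, 1)
  mu <- (atan2(S, C) %% (2 * pi)) * (period / (2 * pi))
  clamped <- rbar >= 1 - 1e-12
  kappa <- if (clamped) kappa_cap else min(vm_A_inv(rbar), kappa_cap)
  list(mu = wrap_ori(mu, period), kappa = kappa, clamped = clamped)
}

# Best-Fisher (1979) rejection sampler for von Mises(mu = 0, kappa), radians.
# Vectorized; kappa = 0 degenerates to uniform, non-finite kappa to 0 noise.
rvonmises <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out[need[ok]] <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    need <- need[!ok]
  }
  out
}
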