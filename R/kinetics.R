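#' Matured fluorescence after a synthesis pulse
#'
#' Normalized matured fluorescence of a chromophore population synthesized at
#' a constant rate during a pulse `[0, pulse_duration]` with no degradation.
#' A protein cohort of age `a` is matured with probability `1 - exp(-m a)`;
#' the integral over cohorts is normalized so the `t -> Inf` limit is 1
#' (i.e. values are fractions of the eventual fully-matured signal).
#'
#' For `t >= D` the closed form is
#' `(D - exp(-m t) (exp(m D) - 1) / m) / D`, and for `t < D`
#' `(t - (1 - exp(-m t)) / m) / D`.
#'
#' @param t Time since pulse onset, hours. Vectorized.
#' @param pulse_duration Pulse length `D` in hours, `> 0`.
#' @param m Maturation rate constant (1/h), `> 0`.
#' @param lag Expression-onset lag in hours (synthesis starts at `lag`
#'   rather than 0); default 0.
#' @return Matured fraction in `[0, 1)`, strictly increasing in `t`.
#' @examples
#' pulse_matured_fraction(2, 1, log(2) / 3)
#' @export
pulse_matured_fraction <- function(t, pulse_duration = 1, m, lag = 0) {
  if (!is.finite(m) || m <= 0) stop("maturation rate m must be > 0")
  if (!is.finite(pulse_duration) || pulse_duration <= 0)
    stop("pulse_duration must be > 0")
  if (any(t < 0)) stop("t must be >= 0")
  if (lag < 0) stop("lag must be >= 0")
  t <- pmax(t - lag, 0)
  D <- pulse_duration
  during <- t < D
  out <- numeric(length(t))
  tb <- t[during]
  out[during] <- (tb - (1 - exp(-m * tb)) / m) / D
  ta <- t[!during]
  out[!during] <- (D - exp(-m * ta) * (exp(m * D) - 1) / m) / D
  out
}

#' Pulse-chase calibration curve of the timer ratio
#'
#' The normalized slow/fast (Cherry/GFP) fluorescence ratio of a tandem
#' timer after a synthesis pulse, evaluated on a time grid. The ratio
#' starts at the small-age limit `m_slow / m_fast`, increases strictly with
#' age, and approaches 1 as both chromophores mature fully. The returned
#' object is the calibration curve used to translate measured ratios into
#' protein-pool ages ([infer_age()]).
#'
#' @param pair A [fluorophore_pair()].
#' @param pulse_duration Pulse length in hours (default 1 h).
#' @param times Strictly increasing grid of positive times (hours).
#' @return An object of class `calibration_curve` with fields `times`,
#'   `ratio`, `pair`, `pulse_duration` and `source`.
#' @examples
#' cc <- pulse_ratio_curve(default_fluorophore_pair())
#' head(cbind(cc$times, cc$ratio))
#' @export
pulse_ratio_curve <- function(pair, pulse_duration = 1,
                              times = seq(0.25, 12, by = 0.25)) {
  stopifnot(inherits(pair, "fluorophore_pair"))
  if (length(times) == 0) stop("empty time grid")
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("times must be a strictly increasing positive grid")
  ratio <- pulse_matured_fraction(times, pulse_duration, pair$m_slow) /
    pulse_matured_fraction(times, pulse_duration, pair$m_fast)
  structure(
    list(times = times, ratio = ratio, pair = pair,
         pulse_duration = pulse_duration, source = "model"),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> (%s) %d points on [%.3g, %.3g] h; ratio range [%.4f, %.4f]\n",
    x$source, length(x$times), min(x$times), max(x$times),
    min(x$ratio), max(x$ratio)))
  invisible(x)
}

#' Evaluate a calibration curve at arbitrary ages
#'
#' Model-derived curves are evaluated with the closed-form pulse model;
#' curves tabulated from data use monotone linear interpolation on the grid.
#'
#' @param curve A `calibration_curve`.
#' @param t Ages (hours) within the curve's grid range.
#' @return Ratio values.
#' @export
curve_eval <- function(curve, t) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (identical(curve$source, "model") && !is.null(curve$pair)) {
    pulse_matured_fraction(t, curve$pulse_duration, curve$pair$m_slow) /
      pulse_matured_fraction(t, curve$pulse_duration, curve$pair$m_fast)
  } else {
    stats::approx(curve$times, curve$ratio, xout = t, rule = 1)$y
  }
}

#' Steady-state timer ratio of a constitutively synthesized pool
#'
#' For a pool turning over at rate `k` (1/h) under constant synthesis, ages
#' are exponentially distributed with rate `k`, the matured fraction of a
#' chromophore with rate `m` is `m / (m + k)`, and the normalized slow/fast
#' ratio is `(m_slow / (m_slow + k)) * ((m_fast + k) / m_fast)`. The ratio
#' is 1 for `k = 0` (infinitely old pool) and decreases strictly to
#' `m_slow / m_fast` as `k -> Inf`.
#'
#' @param k Turnover rate (1/h), `>= 0`. Vectorized.
#' @param pair A [fluorophore_pair()].
#' @return Ratio in `(m_slow / m_fast, 1]`.
#' @export
steady_state_ratio <- function(k, pair) {
  stopifnot(inherits(pair, "fluorophore_pair"))
  if (any(!is.finite(k)) || any(k < 0)) stop("k must be finite and >= 0")
  (pair$m_slow / (pair$m_slow + k)) * ((pair$m_fast + k) / pair$m_fast)
}

#' Invert the steady-state timer ratio to a turnover rate
#'
#' Algebraic inverse of [steady_state_ratio()]:
#' `k = m_slow m_fast (1 - R) / (R m_fast - m_slow)`, defined for ratios
#' strictly inside `(m_slow / m_fast, 1)`.
#'
#' @param R Normalized slow/fast ratio. Vectorized.
#' @param pair A [fluorophore_pair()].
#' @return Turnover rate `k` (1/h).
#' @export
invert_steady_state_ratio <- function(R, pair) {
  stopifnot(inherits(pair, "fluorophore_pair"))
  lo <- pair$m_slow / pair$m_fast
  if (any(!is.finite(R)) || any(R <= lo) || any(R >= 1))
    stop(sprintf("ratio must lie strictly inside (%.6f, 1)", lo))
  pair$m_slow * pair$m_fast * (1 - R) / (R * pair$m_fast - pair$m_slow)
}

#' Closed-form steady state of the trafficking model
#'
#' Steady state of the linear two-pool system: `B = sigma / k_exit`,
#' `Bmat = m B / (m + k_exit)`, `E = sigma / k_deg`,
#' `Emat = (k_exit Bmat + m E) / (m + k_deg)` per chromophore.
#'
#' @param params A [trafficking_params()].
#' @param pair A [fluorophore_pair()].
#' @return A [pool_state()].
#' @export
steady_state_pools <- function(params, pair) {
  stopifnot(inherits(params, "trafficking_params"),
            inherits(pair, "fluorophore_pair"))
  B <- params$sigma / params$k_exit
  E <- params$sigma / params$k_deg
  mat <- function(m) {
    Bm <- m * B / (m + params$k_exit)
    Em <- (params$k_exit * Bm + m * E) / (m + params$k_deg)
    c(Bm, Em)
  }
  f <- mat(pair$m_fast); s <- mat(pair$m_slow)
  pool_state(B = B, Bmat_fast = f[1], Bmat_slow = s[1],
             E = E, Emat_fast = f[2], Emat_slow = s[2])
}

#' Simulate two-pool trafficking with chromophore maturation
#'
#' Integrates the linear ODE system
#' \deqn{dB/dt = \sigma - k_{exit} B}
#' \deqn{dB_{mat}/dt = m (B - B_{mat}) - k_{exit} B_{mat}}
#' \deqn{dE/dt = k_{exit} B - k_{deg} E}
#' \deqn{dE_{mat}/dt = k_{exit} B_{mat} + m (E - E_{mat}) - k_{deg} E_{mat}}
#' with one matured-amount pair per chromophore, plus bookkeeping states for
#' cumulative synthesis and cumulative degradation (used for the
#' mass-balance check `B + E = initial + synthesized - degraded`).
#'
#' @param params A [trafficking_params()].
#' @param pair A [fluorophore_pair()].
#' @param times Sorted non-negative time grid (hours).
#' @param initial Optional [pool_state()]; default empty pools.
#' @param rtol,atol Integration tolerances passed to [deSolve::lsoda()].
#' @return A `pool_trajectory`: a data frame with columns `time_h`, `B`,
#'   `Bmat_fast`, `Bmat_slow`, `E`, `Emat_fast`, `Emat_slow`, `cum_synth`,
#'   `cum_deg`.
#' @export
simulate_trafficking <- function(params, pair, times = seq(0, 48, by = 0.5),
                                 initial = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "trafficking_params"),
            inherits(pair, "fluorophore_pair"))
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be a sorted non-negative grid")
  if (is.null(initial)) initial <- pool_state()
  stopifnot(inherits(initial, "pool_state"))
  y0 <- c(B = initial$B, Bf = initial$Bmat_fast, Bs = initial$Bmat_slow,
          E = initial$E, Ef = initial$Emat_fast, Es = initial$Emat_slow,
          S = 0, Dg = 0)
  p <- params
  mf <- pair$m_fast; ms <- pair$m_slow
  rhs <- function(t, y, parms) {
    with(as.list(y), {
      dB  <- p$sigma - p$k_exit * B
      dBf <- mf * (B - Bf) - p$k_exit * Bf
      dBs <- ms * (B - Bs) - p$k_exit * Bs
      dE  <- p$k_exit * B - p$k_deg * E
      dEf <- p$k_exit * Bf + mf * (E - Ef) - p$k_deg * Ef
      dEs <- p$k_exit * Bs + ms * (E - Es) - p$k_deg * Es
      list(c(dB, dBf, dBs, dE, dEf, dEs, p$sigma, p$k_deg * E))
    })
  }
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("ODE solver failed near t = %.4g h", max(sol[, "time"])))
  out <- data.frame(
    time_h = sol[, "time"],
    B = sol[, "B"], Bmat_fast = sol[, "Bf"], Bmat_slow = sol[, "Bs"],
    E = sol[, "E"], Emat_fast = sol[, "Ef"], Emat_slow = sol[, "Es"],
    cum_synth = sol[, "S"], cum_deg = sol[, "Dg"]
  )
  class(out) <- c("pool_trajectory", "data.frame")
  attr(out, "params") <- params
  attr(out, "pair") <- pair
  attr(out, "initial") <- initial
  out
}

#' Final state of a trajectory as a pool_state
#'
#' @param traj A `pool_trajectory`.
#' @return A [pool_state()] at the last time point.
#' @export
final_state <- function(traj) {
  stopifnot(inherits(traj, "pool_trajectory"))
  z <- traj[nrow(traj), ]
  # clip tiny negative integration error
  cl <- function(x) max(x, 0)
  pool_state(B = cl(z$B), Bmat_fast = min(cl(z$Bmat_fast), cl(z$B)),
             Bmat_slow = min(cl(z$Bmat_slow), cl(z$B)),
             E = cl(z$E), Emat_fast = min(cl(z$Emat_fast), cl(z$E)),
             Emat_slow = min(cl(z$Emat_slow), cl(z$E)))
}

#' Tidy (long) form of a pool trajectory
#'
#' @param traj A `pool_trajectory`.
#' @return Data frame with columns `time_h`, `pool` (`"B"`/`"E"`), `species`
#'   (`"total"`, `"mat_fast"`, `"mat_slow"`) and `amount`.
#' @export
tidy_trajectory <- function(traj) {
  stopifnot(inherits(traj, "pool_trajectory"))
  map <- list(
    c("B", "B", "total"), c("Bmat_fast", "B", "mat_fast"),
    c("Bmat_slow", "B", "mat_slow"), c("E", "E", "total"),
    c("Emat_fast", "E", "mat_fast"), c("Emat_slow", "E", "mat_slow"))
  do.call(rbind, lapply(map, function(m) {
    data.frame(time_h = traj$time_h, pool = m[2], species = m[3],
               amount = traj[[m[1]]])
  }))
}
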