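#' Fit maturation rates from a two-channel pulse-chase series
#'
#' Joint nonlinear least squares of the fast and slow channels against the
#' pulse model `amp * pulse_matured_fraction(t, D, m_channel)` with a shared
#' amplitude and one maturation rate per channel. Rates are fitted on the
#' log scale. Confidence intervals come from residual-resampling bootstrap.
#'
#' @param series Data frame with columns `time_h`, `channel` (`"fast"` /
#'   `"slow"`) and `value`; replicate rows are allowed.
#' @param pulse_duration Pulse length in hours.
#' @param n_boot Bootstrap replicates for the CIs (default 200).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `maturation_fit` with the fitted
#'   [fluorophore_pair()], half-times, amplitude, residual norm and
#'   95% bootstrap CIs for the half-times.
#' @export
fit_maturation <- function(series, pulse_duration = 1, n_boot = 200, seed = 1) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "channel", "value") %in% names(series)))
  chans <- unique(series$channel)
  if (!all(c("fast", "slow") %in% chans))
    stop("both 'fast' and 'slow' channels are required to fit the timer")
  tt <- sort(unique(series$time_h))
  if (length(tt) < 8) stop("need at least 8 distinct time points")
  df <- series[series$channel %in% c("fast", "slow"), , drop = FALSE]

  # initial values: rate from the time each channel reaches half its plateau,
  # amplitude from the late-time plateau of the fast channel
  init_m <- function(ch) {
    d <- df[df$channel == ch, ]
    mu <- tapply(d$value, d$time_h, mean)
    tg <- as.numeric(names(mu))
    plateau <- max(mu)
    t_half <- tg[which(mu >= plateau / 2)[1]]
    if (!is.finite(t_half) || t_half <= 0) t_half <- stats::median(tg)
    log(2) / t_half
  }
  amp0 <- max(tapply(df$value[df$channel == "fast"],
                     df$time_h[df$channel == "fast"], mean))
  start <- list(lmf = log(init_m("fast")), lms = log(init_m("slow")),
                amp = max(amp0, 1e-3))
  D <- pulse_duration

  model_fn <- function(time_h, channel, lmf, lms, amp) {
    out <- numeric(length(time_h))
    fa <- channel == "fast"
    out[fa] <- amp * pulse_matured_fraction(time_h[fa], D, exp(lmf))
    out[!fa] <- amp * pulse_matured_fraction(time_h[!fa], D, exp(lms))
    out
  }
  fit_once <- function(values, start) {
    dat <- df; dat$value <- values
    minpack.lm::nlsLM(
      value ~ model_fn(time_h, channel, lmf, lms, amp),
      data = dat, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- NULL
  for (i in 0:3) { # jittered restarts on failure
    st <- if (i == 0) start else
      lapply(start, function(v) v + stats::rnorm(1, 0, 0.2))
    fit <- tryCatch(fit_once(df$value, st), error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop(sprintf(
      "maturation fit did not converge (initial values lmf=%.3f lms=%.3f amp=%.3f)",
      start$lmf, start$lms, start$amp))
  cf <- stats::coef(fit)
  fitted_vals <- stats::fitted(fit)
  resid <- df$value - fitted_vals

  ci <- matrix(NA_real_, 2, 2)
  if (n_boot > 0) {
    boot <- withr::with_seed(seed, {
      replicate(n_boot, {
        vb <- fitted_vals + sample(resid, replace = TRUE)
        fb <- tryCatch(fit_once(vb, as.list(cf)), error = function(e) NULL)
        if (is.null(fb)) c(NA_real_, NA_real_) else
          log(2) / exp(stats::coef(fb)[c("lmf", "lms")])
      })
    })
    ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
  }

  pair <- fluorophore_pair(m_fast = exp(cf[["lmf"]]), m_slow = exp(cf[["lms"]]))
  structure(
    list(pair = pair,
         half_fast = log(2) / pair$m_fast, half_slow = log(2) / pair$m_slow,
         amp = cf[["amp"]],
         ci_half_fast = ci[, 1], ci_half_slow = ci[, 2],
         resid_norm = sqrt(sum(resid^2)),
         pulse_duration = pulse_duration, n_boot = n_boot),
    class = "maturation_fit"
  )
}

#' @export
print.maturation_fit <- function(x, ...) {
  cat(sprintf(
    "<maturation_fit> half-times: fast %.3f h [%.3f, %.3f], slow %.3f h [%.3f, %.3f]; amp %.3f\n",
    x$half_fast, x$ci_half_fast[1], x$ci_half_fast[2],
    x$half_slow, x$ci_half_slow[1], x$ci_half_slow[2], x$amp))
  invisible(x)
}

#' Calibration curve from a maturation fit
#'
#' @param fit A `maturation_fit`.
#' @param times Age grid for the curve (hours).
#' @return A `calibration_curve` built from the fitted pair.
#' @export
curve_from_fit <- function(fit, times = seq(0.25, 12, by = 0.25)) {
  stopifnot(inherits(fit, "maturation_fit"))
  pulse_ratio_curve(fit$pair, fit$pulse_duration, times)
}

#' Invert a timer ratio to a protein age on a calibration curve
#'
#' Monotone bisection of the calibration curve: finds the age `t` with
#' `curve(t) = ratio` to within 1e-6 h. Ratios at or beyond the curve range
#' are flagged (`"older_than_horizon"` / `"younger_than_resolution"`)
#' rather than extrapolated.
#'
#' @param ratio Normalized slow/fast ratios. Vectorized.
#' @param curve A `calibration_curve`.
#' @param tol Bisection tolerance in hours.
#' @return Data frame with columns `ratio`, `age_h` (NA when flagged) and
#'   `flag` (`"ok"` or a boundary flag).
#' @export
infer_age <- function(ratio, curve, tol = 1e-6) {
  stopifnot(inherits(curve, "calibration_curve"))
  lo_t <- min(curve$times); hi_t <- max(curve$times)
  lo_r <- curve_eval(curve, lo_t); hi_r <- curve_eval(curve, hi_t)
  one <- function(r) {
    if (!is.finite(r)) return(c(NA_real_, "undefined"))
    if (r >= hi_r) return(c(NA_real_, "older_than_horizon"))
    if (r <= lo_r) return(c(NA_real_, "younger_than_resolution"))
    a <- lo_t; b <- hi_t
    while (b - a > tol) {
      mid <- (a + b) / 2
      if (curve_eval(curve, mid) < r) a <- mid else b <- mid
    }
    c((a + b) / 2, "ok")
  }
  res <- vapply(ratio, one, character(2))
  data.frame(ratio = ratio, age_h = as.numeric(res[1, ]), flag = res[2, ])
}

#' Residence-time estimates from per-region membrane ratios
#'
#' Translates normalized slow/fast membrane ratios into basolateral
#' residence-time estimates, either with the steady-state inversion
#' (default; models the membrane pool as a constitutively synthesized,
#' exponentially age-mixed pool, `tau = 1 / k`) or by looking the ratio up
#' on the pulse calibration curve (treats the pool as a single-age cohort).
#' Ratio confidence intervals are propagated by transforming the interval
#' endpoints through the monotone inverse. Estimates are upper bounds under
#' the assumption that all protein transits the basolateral membrane.
#'
#' @param ratios Data frame as returned by [membrane_ratio()]: columns
#'   `region`, `ratio`, `ci_lo`, `ci_hi` and logical `defined`.
#' @param curve A `calibration_curve` (its fluorophore pair is used for the
#'   steady-state inversion).
#' @param method `"steady_state"` (default) or `"curve_lookup"`.
#' @return Data frame of class `residence_estimates`: `region`, `ratio`,
#'   `residence_h`, `ci_lo_h`, `ci_hi_h`, `method`, `flag`.
#' @export
infer_residence_map <- function(ratios, curve,
                                method = c("steady_state", "curve_lookup")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "calibration_curve"),
            is.data.frame(ratios),
            all(c("region", "ratio") %in% names(ratios)))
  pair <- curve$pair
  if (is.null(pair) && method == "steady_state")
    stop("curve carries no fluorophore pair; steady_state inversion unavailable")
  defined <- if ("defined" %in% names(ratios)) ratios$defined else
    rep(TRUE, nrow(ratios))
  ci_lo <- if ("ci_lo" %in% names(ratios)) ratios$ci_lo else ratios$ratio
  ci_hi <- if ("ci_hi" %in% names(ratios)) ratios$ci_hi else ratios$ratio

  inv_one <- function(r) {
    if (!is.finite(r)) return(c(NA_real_, "undefined"))
    if (method == "steady_state") {
      lo <- pair$m_slow / pair$m_fast
      if (r >= 1) return(c(NA_real_, "older_than_horizon"))
      if (r <= lo) return(c(NA_real_, "younger_than_resolution"))
      k <- invert_steady_state_ratio(r, pair)
      c(1 / k, "ok")
    } else {
      z <- infer_age(r, curve)
      c(z$age_h, z$flag)
    }
  }
  n <- nrow(ratios)
  est <- lo_h <- hi_h <- rep(NA_real_, n)
  flag <- character(n)
  for (i in seq_len(n)) {
    if (!defined[i]) { flag[i] <- "undefined"; next }
    z <- inv_one(ratios$ratio[i])
    est[i] <- as.numeric(z[1]); flag[i] <- z[2]
    if (flag[i] == "ok") {
      # monotone increasing ratio -> age, so CI endpoints map in order
      zl <- inv_one(ci_lo[i]); zh <- inv_one(ci_hi[i])
      lo_h[i] <- suppressWarnings(as.numeric(zl[1]))
      hi_h[i] <- suppressWarnings(as.numeric(zh[1]))
    }
  }
  out <- data.frame(region = ratios$region, ratio = ratios$ratio,
                    residence_h = est, ci_lo_h = lo_h, ci_hi_h = hi_h,
                    method = method, flag = flag)
  class(out) <- c("residence_estimates", "data.frame")
  out
}

#' Fold change between two regional residence-time estimates
#'
#' @param estimates A `residence_estimates` data frame.
#' @param region_a,region_b Region labels; the result is
#'   `residence(region_a) / residence(region_b)`.
#' @return List with `fold`, `ci_lo`, `ci_hi` (endpoint combination of the
#'   per-region CIs, when available).
#' @export
residence_fold_change <- function(estimates, region_a, region_b) {
  stopifnot(inherits(estimates, "residence_estimates"))
  pick <- function(rg) {
    i <- match(rg, estimates$region)
    if (is.na(i)) stop(sprintf("region '%s' not found", rg))
    if (estimates$flag[i] != "ok" || !is.finite(estimates$residence_h[i]))
      stop(sprintf("residence estimate for region '%s' is undefined", rg))
    estimates[i, ]
  }
  a <- pick(region_a); b <- pick(region_b)
  fold <- a$residence_h / b$residence_h
  lo <- hi <- NA_real_
  if (all(is.finite(c(a$ci_lo_h, a$ci_hi_h, b$ci_lo_h, b$ci_hi_h)))) {
    lo <- a$ci_lo_h / b$ci_hi_h
    hi <- a$ci_hi_h / b$ci_lo_h
  }
  list(fold = fold, ci_lo = lo, ci_hi = hi,
       region_a = region_a, region_b = region_b)
}
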