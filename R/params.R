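#' Fluorophore pair parameters
#'
#' Maturation rate constants and acid-quench factors for a tandem timer made
#' of a fast-maturing (GFP-like) and a slow-maturing (Cherry-like)
#' chromophore. Rates are first-order maturation constants in 1/h; the
#' maturation half-time of a chromophore is `log(2) / rate`.
#'
#' @param m_fast Maturation rate of the fast chromophore (1/h). Ignored when
#'   `half_fast` is given.
#' @param m_slow Maturation rate of the slow chromophore (1/h). Ignored when
#'   `half_slow` is given.
#' @param half_fast,half_slow Optional maturation half-times in hours;
#'   convenience alternative to the rates.
#' @param q_fast_acidic Fractional fluorescence retained by the fast
#'   chromophore in acidic compartments, in `[0, 1]`. GFP-like chromophores
#'   are quenched at low pH, so the default is 0.
#' @param q_slow_acidic Same for the slow chromophore; Cherry-like
#'   chromophores are acid-resistant, default 1.
#'
#' @return An object of class `fluorophore_pair`.
#' @examples
#' fluorophore_pair(half_fast = 3, half_slow = 6)
#' @export
fluorophore_pair <- function(m_fast = NULL, m_slow = NULL,
                             half_fast = NULL, half_slow = NULL,
                             q_fast_acidic = 0, q_slow_acidic = 1) {
  if (!is.null(half_fast)) m_fast <- log(2) / half_fast
  if (!is.null(half_slow)) m_slow <- log(2) / half_slow
  if (is.null(m_fast) || is.null(m_slow))
    stop("supply either rates (m_fast, m_slow) or half-times (half_fast, half_slow)")
  if (!is.finite(m_fast) || !is.finite(m_slow) || m_slow <= 0)
    stop("maturation rates must be finite and positive")
  if (m_fast <= m_slow)
    stop("the fast chromophore must mature faster than the slow one (m_fast > m_slow)")
  for (q in c(q_fast_acidic, q_slow_acidic))
    if (!is.finite(q) || q < 0 || q > 1) stop("quench factors must lie in [0, 1]")
  structure(
    list(m_fast = m_fast, m_slow = m_slow,
         q_fast_acidic = q_fast_acidic, q_slow_acidic = q_slow_acidic),
    class = "fluorophore_pair"
  )
}

#' Default calibrated timer
#'
#' The package default timer, with maturation half-times of 3 h (fast, GFP)
#' and 6 h (slow, Cherry) as calibrated from pulse-chase imaging of the
#' tandem fusion in wing discs.
#'
#' @return A [fluorophore_pair()].
#' @export
default_fluorophore_pair <- function() {
  fluorophore_pair(half_fast = 3, half_slow = 6)
}

#' Maturation half-times of a fluorophore pair
#'
#' @param pair A [fluorophore_pair()].
#' @return Named numeric vector `c(fast = , slow = )` in hours.
#' @export
half_times <- function(pair) {
  stopifnot(inherits(pair, "fluorophore_pair"))
  c(fast = log(2) / pair$m_fast, slow = log(2) / pair$m_slow)
}

#' @export
print.fluorophore_pair <- function(x, ...) {
  ht <- half_times(x)
  cat(sprintf(
    "<fluorophore_pair> half-times: fast %.3g h, slow %.3g h; acid quench: fast %.2f, slow %.2f\n",
    ht["fast"], ht["slow"], x$q_fast_acidic, x$q_slow_acidic))
  invisible(x)
}

#' Per-region trafficking parameters
#'
#' First-order rates of the two-pool trafficking model for one region of the
#' epithelium: protein is synthesized at rate `sigma` into the basolateral
#' pool, exits to the apical pool at rate `k_exit` (so the basolateral
#' residence time is `1 / k_exit` hours) and is degraded apically at rate
#' `k_deg`.
#'
#' @param sigma Synthesis rate (protein units per hour), `>= 0`.
#' @param k_exit Basolateral-to-apical exit rate (1/h). Ignored when
#'   `residence_h` is given.
#' @param residence_h Optional basolateral residence time in hours
#'   (`1 / k_exit`).
#' @param k_deg Apical degradation rate (1/h).
#' @param region Free-text region label (e.g. `"P"`, `"ptc_band"`,
#'   `"far_A"`).
#'
#' @return An object of class `trafficking_params`.
#' @export
trafficking_params <- function(sigma = 1, k_exit = NULL, residence_h = NULL,
                               k_deg = 0.5, region = "region") {
  if (!is.null(residence_h)) {
    if (!is.finite(residence_h) || residence_h <= 0)
      stop("residence_h must be positive")
    k_exit <- 1 / residence_h
  }
  if (is.null(k_exit)) stop("supply k_exit or residence_h")
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (!is.finite(k_exit) || k_exit <= 0) stop("k_exit must be > 0")
  if (!is.finite(k_deg) || k_deg <= 0) stop("k_deg must be > 0")
  structure(
    list(sigma = sigma, k_exit = k_exit, k_deg = k_deg,
         region = as.character(region)),
    class = "trafficking_params"
  )
}

#' @export
print.trafficking_params <- function(x, ...) {
  cat(sprintf(
    "<trafficking_params> region '%s': sigma %.3g /h, k_exit %.3g /h (residence %.3g h), k_deg %.3g /h\n",
    x$region, x$sigma, x$k_exit, 1 / x$k_exit, x$k_deg))
  invisible(x)
}

#' Pool state of the trafficking model
#'
#' Amounts of total and matured protein in the basolateral (`B`) and apical
#' (`E`) pools, one matured amount per chromophore. All amounts are in
#' arbitrary protein units.
#'
#' @param B,E Total amounts in the basolateral and apical pools.
#' @param Bmat_fast,Bmat_slow Matured-chromophore amounts in the basolateral
#'   pool.
#' @param Emat_fast,Emat_slow Matured-chromophore amounts in the apical pool.
#' @return An object of class `pool_state`.
#' @export
pool_state <- function(B = 0, Bmat_fast = 0, Bmat_slow = 0,
                       E = 0, Emat_fast = 0, Emat_slow = 0) {
  s <- c(B = B, Bmat_fast = Bmat_fast, Bmat_slow = Bmat_slow,
         E = E, Emat_fast = Emat_fast, Emat_slow = Emat_slow)
  if (any(!is.finite(s)) || any(s < 0)) stop("pool amounts must be finite and >= 0")
  if (Bmat_fast > B + 1e-12 || Bmat_slow > B + 1e-12 ||
      Emat_fast > E + 1e-12 || Emat_slow > E + 1e-12)
    stop("matured amounts cannot exceed total pool amounts")
  structure(as.list(s), class = "pool_state")
}
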