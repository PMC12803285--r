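# shared fixtures, built once per test run

default_pair <- tandemtimer::default_fluorophore_pair()

# numerical-quadrature oracle for the pulse maturation model: integrate the
# matured fraction over synthesis cohorts directly
pulse_fraction_quadrature <- function(t, D, m) {
  sapply(t, function(tt) {
    if (tt <= 0) return(0)
    upper <- min(tt, D)
    f <- function(s) 1 - exp(-m * (tt - s))
    stats::integrate(f, 0, upper, rel.tol = 1e-10)$value / D
  })
}

# memoized wild-type disc + quantification shared across test files
.fixture_env <- new.env(parent = emptyenv())

wt_disc <- function(seed = 42L) {
  key <- paste0("disc_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- tandemtimer::generate_disc_image(
      tandemtimer::scenario_preset("wild_type", seed = seed))
  .fixture_env[[key]]
}

wt_quant <- function(seed = 42L) {
  key <- paste0("quant_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- tandemtimer::quantify_disc(
      wt_disc(seed), n_boot = 300, seed = seed + 1L)
  .fixture_env[[key]]
}

# a fluorophore "pair" with equal maturation rates (bypasses the
# m_fast > m_slow validity check, for null-model tests only)
equal_rate_pair <- function(m = log(2) / 4) {
  structure(list(m_fast = m, m_slow = m, q_fast_acidic = 0,
                 q_slow_acidic = 1),
            class = "fluorophore_pair")
}
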