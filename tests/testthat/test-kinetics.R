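test_that("pulse matured fraction matches the cohort-integral oracle", {
  grid <- expand.grid(t = c(0, 0.3, 0.7, 1, 1.5, 2, 4.5, 8, 20),
                      m = c(log(2) / 3, log(2) / 6, 0.05, 1.2),
                      D = c(0.5, 1, 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(pulse_matured_fraction(g$t, g$D, g$m),
                 pulse_fraction_quadrature(g$t, g$D, g$m),
                 tolerance = 1e-8)
  }
  # frozen closed-form values for the default timer, 1 h pulse
  expect_equal(pulse_matured_fraction(0, 1, log(2) / 3), 0)
  expect_equal(pulse_matured_fraction(2, 1, log(2) / 3), 0.2913193,
               tolerance = 1e-6)
  expect_equal(pulse_matured_fraction(2, 1, log(2) / 6), 0.1586359,
               tolerance = 1e-6)
})

test_that("pulse matured fraction validates its domain", {
  expect_error(pulse_matured_fraction(1, 1, -0.1), "m must be")
  expect_error(pulse_matured_fraction(1, 0, 0.2), "pulse_duration")
  expect_error(pulse_matured_fraction(-1, 1, 0.2), ">= 0")
})

test_that("pulse ratio curve hits frozen values and its limits", {
  cc <- pulse_ratio_curve(default_pair, pulse_duration = 1)
  expect_equal(curve_eval(cc, 2), 0.5445, tolerance = 1e-3)
  expect_equal(curve_eval(cc, 4.5), 0.6138, tolerance = 1e-3)
  expect_equal(curve_eval(cc, 8), 0.7041, tolerance = 1e-3)
  # small-age limit is the rate ratio, here 0.5
  expect_equal(curve_eval(cc, 1e-4), 0.5, tolerance = 1e-3)
  expect_error(pulse_ratio_curve(default_pair, times = numeric(0)),
               "empty")
})

test_that("pulse ratio curve is strictly increasing and bounded for random pairs", {
  withr::with_seed(99, {
    for (rep in 1:25) {
      ms <- sort(stats::runif(2, 0.02, 2))
      pair <- fluorophore_pair(m_fast = ms[2], m_slow = ms[1])
      cc <- pulse_ratio_curve(pair, pulse_duration = stats::runif(1, 0.5, 2),
                              times = seq(0.2, 15, by = 0.2))
      expect_true(all(diff(cc$ratio) > 0))
      expect_true(all(cc$ratio > ms[1] / ms[2]))
      expect_true(all(cc$ratio < 1))
    }
  })
})

test_that("steady-state ratio obeys limits, monotonicity and the MC oracle", {
  expect_equal(steady_state_ratio(0, default_pair), 1)
  expect_equal(steady_state_ratio(1e6, default_pair), 0.5, tolerance = 1e-4)
  expect_equal(steady_state_ratio(1 / 3, default_pair), 0.6287,
               tolerance = 1e-4)
  ks <- 10^seq(-3, 2, length.out = 40)
  expect_true(all(diff(steady_state_ratio(ks, default_pair)) < 0))
  # Monte-Carlo oracle: exponential ages, matured with prob 1 - exp(-m a)
  withr::with_seed(4, {
    ages <- stats::rexp(2e5, rate = 1 / 3)
    mc <- mean(1 - exp(-default_pair$m_slow * ages)) /
      mean(1 - exp(-default_pair$m_fast * ages))
  })
  expect_equal(steady_state_ratio(1 / 3, default_pair), mc,
               tolerance = 0.01)
  expect_error(steady_state_ratio(-1, default_pair), ">= 0")
})

test_that("steady-state ratio inversion round-trips to 1e-9", {
  ks <- 10^seq(-2, 1.5, length.out = 50)
  R <- steady_state_ratio(ks, default_pair)
  expect_equal(invert_steady_state_ratio(R, default_pair), ks,
               tolerance = 1e-9)
  expect_error(invert_steady_state_ratio(1, default_pair), "strictly inside")
  expect_error(invert_steady_state_ratio(0.49, default_pair),
               "strictly inside")
})

test_that("ODE trafficking matches the closed-form steady state", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      params <- trafficking_params(sigma = stats::runif(1, 0.2, 3),
                                   k_exit = stats::runif(1, 0.1, 1.5),
                                   k_deg = stats::runif(1, 0.1, 1.5))
      horizon <- 30 / min(params$k_exit, params$k_deg,
                          default_pair$m_slow)
      traj <- simulate_trafficking(params, default_pair,
                                   times = c(0, horizon / 2, horizon))
      fin <- final_state(traj)
      ss <- steady_state_pools(params, default_pair)
      for (f in c("B", "Bmat_fast", "Bmat_slow", "E", "Emat_fast",
                  "Emat_slow"))
        expect_equal(fin[[f]], ss[[f]], tolerance = 1e-6)
    }
  })
})

test_that("trafficking trajectories conserve mass and respect pool bounds", {
  params <- trafficking_params(sigma = 1, k_exit = 0.25, k_deg = 0.5)
  traj <- simulate_trafficking(params, default_pair,
                               times = seq(0, 60, by = 0.5))
  expect_lt(max(abs(traj$B + traj$E - (traj$cum_synth - traj$cum_deg))),
            1e-6)
  expect_true(all(traj$Bmat_fast <= traj$B + 1e-9))
  expect_true(all(traj$Emat_slow <= traj$E + 1e-9))
  expect_true(all(traj[, -1] >= -1e-9))
  # matured basolateral fraction at steady state is m / (m + k_exit)
  fin <- final_state(traj)
  expect_equal(fin$Bmat_fast / fin$B,
               default_pair$m_fast / (default_pair$m_fast + params$k_exit),
               tolerance = 1e-6)
})

test_that("zero synthesis from an empty state stays identically zero", {
  params <- trafficking_params(sigma = 0, k_exit = 0.3, k_deg = 0.4)
  traj <- simulate_trafficking(params, default_pair,
                               times = seq(0, 10, by = 1))
  expect_true(all(abs(as.matrix(traj[, -1])) < 1e-12))
})

test_that("equal maturation rates make the timer uninformative", {
  pair <- equal_rate_pair()
  cc <- pulse_ratio_curve(pair, times = seq(0.5, 12, 0.5))
  expect_equal(cc$ratio, rep(1, length(cc$times)), tolerance = 1e-12)
  expect_equal(steady_state_ratio(c(0, 0.1, 1, 10), pair), rep(1, 4))
})

test_that("trajectory tidy export is faithful", {
  params <- trafficking_params(sigma = 1, k_exit = 0.25, k_deg = 0.5)
  traj <- simulate_trafficking(params, default_pair, times = seq(0, 5, 1))
  tidy <- tidy_trajectory(traj)
  expect_equal(nrow(tidy), 6 * nrow(traj))
  expect_setequal(unique(tidy$pool), c("B", "E"))
  got <- tidy$amount[tidy$pool == "B" & tidy$species == "mat_fast"]
  expect_equal(got, traj$Bmat_fast)
})
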