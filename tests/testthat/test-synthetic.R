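test_that("noiseless pulse series equals the maturation model exactly", {
  ps <- generate_pulse_series(default_pair, noise_cv = 0, n_replicates = 2,
                              seed = 5)
  for (ch in c("fast", "slow")) {
    m <- if (ch == "fast") default_pair$m_fast else default_pair$m_slow
    d <- ps$series[ps$series$channel == ch & ps$series$replicate == 1, ]
    expect_equal(d$value, pulse_matured_fraction(d$time_h, 1, m))
    d2 <- ps$series[ps$series$channel == ch & ps$series$replicate == 2, ]
    expect_equal(d$value, d2$value)  # replicates differ only by noise
  }
  # default grid: 0-12 h every 15 min = 49 points per channel and replicate
  expect_equal(sum(ps$series$channel == "fast" & ps$series$replicate == 1),
               49)
  # slow/fast ratio of the noiseless series at 4.5 h
  at45 <- ps$series[ps$series$time_h == 4.5 & ps$series$replicate == 1, ]
  expect_equal(at45$value[at45$channel == "slow"] /
                 at45$value[at45$channel == "fast"], 0.614,
               tolerance = 1e-3)
})

test_that("pulse series are reproducible and noise scales as prescribed", {
  a <- generate_pulse_series(default_pair, seed = 9)
  b <- generate_pulse_series(default_pair, seed = 9)
  expect_identical(a$series, b$series)
  c_ <- generate_pulse_series(default_pair, seed = 10)
  expect_false(identical(a$series, c_$series))
})

test_that("disc generation is bit-exact under a fixed seed", {
  d1 <- generate_disc_image(scenario_preset("wild_type", seed = 3))
  d2 <- generate_disc_image(scenario_preset("wild_type", seed = 3))
  expect_identical(d1$images, d2$images)
  expect_identical(d1$truth$hh_puncta, d2$truth$hh_puncta)
  d3 <- generate_disc_image(scenario_preset("wild_type", seed = 4))
  expect_false(identical(d1$images, d3$images))
})

test_that("acid quench silences the apical fast channel; NH4Cl restores it", {
  disc <- wt_disc()
  expect_equal(max(disc$truth$prenoise$apical[, , "fast"]), 0)
  expect_gt(max(disc$truth$prenoise$basolateral[, , "fast"]), 0)
  cfg <- scenario_preset("nh4cl", seed = 8)
  cfg$noise$poisson_gain <- 0  # noise off to read ratios exactly
  nh <- generate_disc_image(cfg)
  expect_gt(max(nh$truth$prenoise$apical[, , "fast"]), 0)
  # apical slow/fast equals the matured apical pool ratio per region
  rm_ <- region_masks(nh$geometry)
  pools <- nh$truth$pools
  for (rg in c("P", "far_A")) {
    f <- get_channel(nh, "apical", "fast")
    s <- get_channel(nh, "apical", "slow")
    got <- sum(s[rm_[[rg]]]) / sum(f[rm_[[rg]]])
    want <- pools$Emat_slow[pools$region == rg] /
      pools$Emat_fast[pools$region == rg]
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("realized Hh partition and overlap stay within 0.02 of intended", {
  for (s in c(42L, 7L)) {
    disc <- wt_disc(s)
    expect_lt(abs(disc$truth$partition$realized -
                    disc$truth$partition$intended), 0.02)
    expect_true(all(abs(disc$truth$overlap$realized -
                          disc$truth$overlap$intended) < 0.02))
  }
})

test_that("detection noise variance scales with the mean (shot noise)", {
  withr::with_seed(11, {
    means <- c(10, 50, 200, 800)
    v <- sapply(means, function(m) {
      img <- matrix(m, 120, 120)
      stats::var(as.numeric(
        tandemtimer:::apply_noise(img, poisson_gain = 1, gaussian_sd = 0)))
    })
    expect_equal(v / means, rep(1, 4), tolerance = 0.1)
    # with gain g, variance is g * mean
    img <- matrix(100, 200, 200)
    vg <- stats::var(as.numeric(
      tandemtimer:::apply_noise(img, poisson_gain = 4, gaussian_sd = 0)))
    expect_equal(vg / 100, 4, tolerance = 0.1)
  })
})

test_that("presets encode the intended regional structure", {
  wt <- scenario_preset("wild_type")
  taus <- sapply(wt$regions, function(p) 1 / p$k_exit)
  expect_true(taus[["P"]] > taus[["ptc_band"]] &&
                taus[["ptc_band"]] > taus[["far_A"]])
  un <- scenario_preset("uniform_turnover")
  expect_equal(un$regions$far_A[c("sigma", "k_exit", "k_deg")],
               un$regions$P[c("sigma", "k_exit", "k_deg")])
  dp <- scenario_preset("disp_mutant")
  expect_true(all(sapply(dp$regions[c("far_A", "ptc_band")],
                         function(p) p$k_exit) >
                    sapply(wt$regions[c("far_A", "ptc_band")],
                           function(p) p$k_exit)))
  u8 <- scenario_preset("usp8_dorsal")
  expect_equal(u8$dorsal_k_exit_factor, 0.5)
  expect_true(scenario_preset("nh4cl")$nh4cl)
  expect_error(scenario_preset("nonsense"), "arg")
})

test_that("disp mutant lowers basolateral GFP and raises apical Cherry anteriorly", {
  wt <- wt_disc(5L)
  dp <- generate_disc_image(scenario_preset("disp_mutant", seed = 5))
  A <- ap_masks(wt$geometry)$A
  expect_lt(mean(get_channel(dp, "basolateral", "fast")[A]),
            mean(get_channel(wt, "basolateral", "fast")[A]))
  expect_gt(mean(get_channel(dp, "apical", "slow")[A]),
            mean(get_channel(wt, "apical", "slow")[A]))
})

test_that("membrane-tethered Hh raises anterior GFP and lowers apical Cherry", {
  wt <- wt_disc(5L)
  cd <- generate_disc_image(scenario_preset("hh_cd2", seed = 5))
  A <- ap_masks(wt$geometry)$A
  expect_gt(mean(get_channel(cd, "basolateral", "fast")[A]),
            mean(get_channel(wt, "basolateral", "fast")[A]))
  expect_lt(mean(get_channel(cd, "apical", "slow")[A]),
            mean(get_channel(wt, "apical", "slow")[A]))
})

test_that("an overcrowded geometry raises a capacity error", {
  cfg <- scenario_preset("wild_type", seed = 1)
  cfg$n_hh_puncta <- c(A = 4000, P = 4000)
  expect_error(generate_disc_image(cfg), "too small")
})

test_that("geometry helpers partition the field", {
  geom <- disc_geometry()
  rm_ <- region_masks(geom)
  total <- rm_$far_A + rm_$ptc_band + rm_$P
  expect_true(all(total == 1))
  apm <- ap_masks(geom)
  expect_true(all((apm$A + apm$P) == 1))
  # ptc band is band_cells * cell_um wide, immediately anterior to boundary
  band_cols <- colSums(rm_$ptc_band) > 0
  expect_equal(sum(band_cols) * geom$pixel_um,
               geom$band_cells * geom$cell_um, tolerance = geom$pixel_um)
  expect_error(disc_geometry(band_cells = 5), "3 or 4")
})
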