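test_that("intensity profile reproduces flat and step images", {
  flat <- matrix(7, 40, 60)
  p <- plot_profile(flat, pixel_um = 0.5)
  expect_equal(p$intensity, rep(7, 60))
  expect_equal(diff(p$x_um), rep(0.5, 59))
  step <- cbind(matrix(5, 40, 30), matrix(95, 40, 30))
  ps <- plot_profile(step, pixel_um = 0.5)
  expect_equal(unique(ps$intensity), c(5, 95))
  expect_equal(ps$intensity[30], 5)
  expect_equal(ps$intensity[31], 95)
  expect_error(plot_profile(flat, 0.5, mask = matrix(FALSE, 40, 60)),
               "empty mask")
})

test_that("wild-type basolateral fast profile is ordered P > ptc band > far A", {
  disc <- wt_disc()
  prof <- plot_profile(get_channel(disc, "basolateral", "fast"),
                       disc$geometry$pixel_um, geom = disc$geometry)
  mu <- tapply(prof$intensity, prof$region, mean)
  expect_gt(mu[["P"]], mu[["ptc_band"]])
  expect_gt(mu[["ptc_band"]], mu[["far_A"]])
})

test_that("background subtraction removes offsets without changing partitions", {
  flat <- matrix(3.2, 50, 50)
  expect_equal(subtract_background(flat), matrix(0, 50, 50))
  geom <- disc_geometry()
  disc <- wt_disc()
  hh <- get_channel(disc, "apical", "hh")
  apm <- ap_masks(geom)
  p0 <- compartment_partition(subtract_background(hh), apm)
  p1 <- compartment_partition(subtract_background(hh + 11.5), apm)
  expect_equal(p0, p1, tolerance = 1e-10)
  # noisy flat field: residual mean within 2 noise sd of zero
  withr::with_seed(2, {
    noisy <- matrix(stats::rnorm(1e4, 100, 3), 100, 100)
    expect_lt(abs(mean(subtract_background(noisy)) - 0), 2 * 3)
  })
})

test_that("compartment partition handles trivial and symmetric splits", {
  img <- matrix(0, 20, 40)
  masks <- list(A = cbind(matrix(TRUE, 20, 20), matrix(FALSE, 20, 20)),
                P = cbind(matrix(FALSE, 20, 20), matrix(TRUE, 20, 20)))
  img[, 21:40] <- 5
  expect_equal(compartment_partition(img, masks),
               c(A = 0, P = 1))
  img[] <- 3  # uniform -> 50/50
  expect_equal(compartment_partition(img, masks), c(A = 0.5, P = 0.5))
  expect_true(abs(sum(compartment_partition(img, masks)) - 1) < 1e-12)
  expect_error(compartment_partition(matrix(0, 20, 40), masks), "zero total")
  overlapping <- list(A = masks$A, B = masks$A)
  expect_error(compartment_partition(img, overlapping), "disjoint")
})

test_that("generator partition 0.95 is recovered within 0.02 under noise", {
  q <- wt_quant()
  expect_equal(unname(q$partition[["P"]]), 0.95, tolerance = 0.021)
  expect_equal(sum(q$partition), 1, tolerance = 1e-12)
})

test_that("puncta detection is accurate and deterministic on generated spots", {
  withr::with_seed(31, {
    n <- 100
    img <- matrix(0, 400, 400)
    pts <- tandemtimer:::sample_points(n, matrix(TRUE, 400, 400),
                                       pixel_um = 0.2, min_sep_um = 3)
    img <- tandemtimer:::render_gaussian_spots(img, 0.2, pts$x_um, pts$y_um,
                                               peak = 120, sigma_um = 0.2)
    img <- tandemtimer:::gaussian_blur(img, 1)
    noisy <- tandemtimer:::apply_noise(img, poisson_gain = 1,
                                       gaussian_sd = 1)
    det <- detect_puncta(noisy, pixel_um = 0.2)
    det2 <- detect_puncta(noisy, pixel_um = 0.2)
    expect_identical(det, det2)
    # match detections to truth within one spot radius
    match_dist <- 0.4
    hits <- sapply(seq_len(nrow(pts)), function(i) {
      any((det$x_um - pts$x_um[i])^2 + (det$y_um - pts$y_um[i])^2 <
            match_dist^2)
    })
    recall <- mean(hits)
    used <- sapply(seq_len(nrow(det)), function(i) {
      any((pts$x_um - det$x_um[i])^2 + (pts$y_um - det$y_um[i])^2 <
            match_dist^2)
    })
    precision <- mean(used)
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.95)
  })
  expect_equal(nrow(detect_puncta(matrix(0, 50, 50), 0.2)), 0)
})

test_that("intensity overlap hits its trivial bounds", {
  withr::with_seed(12, {
    sig <- matrix(stats::runif(2500, 1, 5), 50, 50)
    # partner covering the whole region -> all signal overlaps
    full <- matrix(100, 50, 50)
    expect_equal(intensity_overlap(sig, full, 0.2)$fraction, 1)
    # empty partner -> no overlap
    empty <- matrix(0, 50, 50)
    expect_equal(intensity_overlap(sig, empty, 0.2)$fraction, 0)
    half <- cbind(matrix(0, 50, 25), matrix(100, 50, 25))
    sig_right <- cbind(matrix(0, 50, 25), matrix(10, 50, 25))
    z <- intensity_overlap(sig_right + 1e-3, half, 0.2)
    expect_gt(z$fraction, 0.99)
  })
})

test_that("generated Hh-Rab7 overlaps are recovered in both compartments", {
  q <- wt_quant()
  ovA <- q$overlap[q$overlap$compartment == "A", ]
  ovP <- q$overlap[q$overlap$compartment == "P", ]
  expect_gt(ovA$fraction, 0.80)
  expect_lt(ovA$fraction, 0.90)
  expect_equal(ovP$fraction, 0.50, tolerance = 0.05)
  expect_true(ovA$ci_lo <= ovA$fraction && ovA$fraction <= ovA$ci_hi)
})

test_that("membrane ratio is exact on equal channels and flags dark regions", {
  geom <- disc_geometry()
  lat <- membrane_lattice(geom)
  rm_ <- region_masks(geom)
  img <- 50 * lat  # membrane-shaped signal, dark off-membrane background
  out <- membrane_ratio(img, img, lat, rm_, n_boot = 50)
  expect_true(all(out$defined))
  expect_equal(out$ratio, rep(1, 3), tolerance = 1e-12)
  dark <- matrix(0, geom$ny, geom$nx)
  out2 <- membrane_ratio(img, dark, lat, rm_, n_boot = 50)
  expect_true(all(!out2$defined))
  expect_true(all(is.na(out2$ratio)))
})

test_that("membrane ratios follow the generated residence ordering", {
  disc <- wt_disc()
  q <- wt_quant()
  truth <- disc$truth$pools
  truth_order <- truth$region[order(truth$residence_h)]
  got_order <- q$ratios$region[order(q$ratios$ratio)]
  expect_equal(got_order, truth_order)
  # noiseless single-region check at 3 h residence: ratio ~0.6287
  cfg <- scenario_preset("uniform_turnover", seed = 2)
  cfg$regions <- lapply(cfg$regions, function(p)
    trafficking_params(sigma = p$sigma, residence_h = 3, k_deg = p$k_deg,
                       region = p$region))
  cfg$noise$poisson_gain <- 0
  d3 <- generate_disc_image(cfg)
  q3 <- quantify_disc(d3, n_boot = 20, seed = 1)
  expect_equal(q3$ratios$ratio, rep(0.6287, 3), tolerance = 1e-3)
})

test_that("uniform-turnover null yields flat regional ratios", {
  un <- generate_disc_image(scenario_preset("uniform_turnover", seed = 6))
  q <- quantify_disc(un, n_boot = 100, seed = 7)
  expect_lt(diff(range(q$ratios$ratio)), 0.01)
  est <- infer_residence_map(q$ratios, pulse_ratio_curve(default_pair))
  expect_lt(diff(range(est$residence_h)) / mean(est$residence_h), 0.1)
})

test_that("estimator bootstrap intervals are calibrated across seeds", {
  seeds <- 1:20
  hits <- unlist(lapply(seeds, function(s) {
    disc <- generate_disc_image(scenario_preset("wild_type", seed = s))
    q <- quantify_disc(disc, n_boot = 200, seed = s + 1000L)
    tr <- disc$truth$pools
    r_hit <- sapply(seq_len(nrow(q$ratios)), function(i) {
      truth <- tr$ratio_baso[tr$region == q$ratios$region[i]]
      q$ratios$ci_lo[i] <= truth && truth <= q$ratios$ci_hi[i]
    })
    o_hit <- sapply(c("A", "P"), function(cp) {
      truth <- disc$truth$overlap$realized[
        disc$truth$overlap$compartment == cp]
      row <- q$overlap[q$overlap$compartment == cp, ]
      row$ci_lo <= truth && truth <= row$ci_hi
    })
    c(r_hit, o_hit)
  }))
  expect_gte(mean(hits), 0.90)
})
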