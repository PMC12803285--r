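#' Simulate a two-channel pulse-chase fluorescence series
#'
#' Generates fast- and slow-channel fluorescence time courses after a
#' synthesis pulse, as in a temperature-shift pulse-chase experiment imaged
#' at regular intervals. The noiseless mean is the pulse maturation model
#' ([pulse_matured_fraction()]); replicates differ only by multiplicative
#' Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @param pair A [fluorophore_pair()].
#' @param pulse_duration Pulse length (hours), default 1 h.
#' @param times Sampling grid (hours); default 0-12 h every 15 min.
#' @param noise_cv Coefficient of variation of the measurement noise.
#' @param n_replicates Number of replicate series.
#' @param seed Seed fixing the noise draws.
#' @return A list of class `pulse_series`: `series` (data frame `time_h`,
#'   `channel`, `replicate`, `value`) and `truth` (pair, pulse duration and
#'   the noiseless series).
#' @export
generate_pulse_series <- function(pair, pulse_duration = 1,
                                  times = seq(0, 12, by = 0.25),
                                  noise_cv = 0.05, n_replicates = 3,
                                  seed = 1L) {
  stopifnot(inherits(pair, "fluorophore_pair"), noise_cv >= 0,
            n_replicates >= 1)
  clean <- rbind(
    data.frame(time_h = times, channel = "fast",
               value = pulse_matured_fraction(times, pulse_duration,
                                              pair$m_fast)),
    data.frame(time_h = times, channel = "slow",
               value = pulse_matured_fraction(times, pulse_duration,
                                              pair$m_slow)))
  series <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      out <- clean
      out$replicate <- r
      out$value <- out$value * (1 + stats::rnorm(nrow(out), 0, noise_cv))
      out
    }))
  })
  structure(
    list(series = series[, c("time_h", "channel", "replicate", "value")],
         truth = list(pair = pair, pulse_duration = pulse_duration,
                      noiseless = clean, noise_cv = noise_cv, seed = seed)),
    class = "pulse_series"
  )
}

# --- low-level rendering helpers ------------------------------------------

# add Gaussian spots (peak amplitude `peak`, sd sigma_um) into a matrix
render_gaussian_spots <- function(img, pixel_um, x_um, y_um, peak, sigma_um) {
  ny <- nrow(img); nx <- ncol(img)
  s_px <- sigma_um / pixel_um
  w <- ceiling(4 * s_px)
  peak <- rep_len(peak, length(x_um))
  for (i in seq_along(x_um)) {
    cj <- x_um[i] / pixel_um + 0.5; ci <- y_um[i] / pixel_um + 0.5
    jj <- max(1, floor(cj - w)):min(nx, ceiling(cj + w))
    ii <- max(1, floor(ci - w)):min(ny, ceiling(ci + w))
    gx <- exp(-((jj - cj)^2) / (2 * s_px^2))
    gy <- exp(-((ii - ci)^2) / (2 * s_px^2))
    img[ii, jj] <- img[ii, jj] + peak[i] * outer(gy, gx)
  }
  img
}

# add filled discs into a matrix; radius and amplitude recycle per disc
render_discs <- function(img, pixel_um, x_um, y_um, radius_um, amp) {
  ny <- nrow(img); nx <- ncol(img)
  r_px <- rep_len(radius_um / pixel_um, length(x_um))
  amp <- rep_len(amp, length(x_um))
  for (i in seq_along(x_um)) {
    w <- ceiling(r_px[i] + 1)
    cj <- x_um[i] / pixel_um + 0.5; ci <- y_um[i] / pixel_um + 0.5
    jj <- max(1, floor(cj - w)):min(nx, ceiling(cj + w))
    ii <- max(1, floor(ci - w)):min(ny, ceiling(ci + w))
    d2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
    img[ii, jj] <- img[ii, jj] + amp[i] * (d2 <= r_px[i]^2)
  }
  img
}

# logical union of disc footprints
disc_footprint <- function(ny, nx, pixel_um, x_um, y_um, radius_um) {
  m <- matrix(0, ny, nx)
  m <- render_discs(m, pixel_um, x_um, y_um, radius_um, 1)
  m > 0
}

# erode a mask away from its boundary and the field edge by `margin_um`
shrink_mask <- function(mask, pixel_um, margin_um) {
  b <- max(1L, as.integer(round(margin_um / pixel_um)))
  padded <- matrix(FALSE, nrow(mask) + 2 * b, ncol(mask) + 2 * b)
  padded[b + seq_len(nrow(mask)), b + seq_len(ncol(mask))] <- mask
  er <- EBImage::erode(EBImage::Image(padded * 1),
                       EBImage::makeBrush(2 * b + 1, shape = "box"))
  as.matrix(er)[b + seq_len(nrow(mask)), b + seq_len(ncol(mask))] > 0.5
}

# rejection-sample n points inside `mask` with pairwise separation
# min_sep_um, also keeping min_sep_um from `avoid` points
sample_points <- function(n, mask, pixel_um, min_sep_um, avoid = NULL,
                          max_tries = 400L) {
  idx <- which(mask)
  if (length(idx) == 0 || n > length(idx))
    stop("region too small to place the requested number of puncta")
  ny <- nrow(mask)
  ax <- if (is.null(avoid)) numeric(0) else avoid$x_um
  ay <- if (is.null(avoid)) numeric(0) else avoid$y_um
  xs <- ys <- numeric(n)
  got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries * n)
      stop(sprintf(
        "could not place %d puncta at %.2f um separation: region too small",
        n, min_sep_um))
    k <- idx[sample.int(length(idx), 1)]
    i <- ((k - 1) %% ny) + 1; j <- ((k - 1) %/% ny) + 1
    x <- (j - 1 + stats::runif(1)) * pixel_um
    y <- (i - 1 + stats::runif(1)) * pixel_um
    if (got > 0 &&
        min((xs[1:got] - x)^2 + (ys[1:got] - y)^2) < min_sep_um^2) next
    if (length(ax) > 0 && min((ax - x)^2 + (ay - y)^2) < min_sep_um^2) next
    got <- got + 1L
    xs[got] <- x; ys[got] <- y
  }
  data.frame(x_um = xs, y_um = ys)
}

# Poisson(-Gaussian) detection noise; gain 0 disables shot noise
apply_noise <- function(img, poisson_gain = 1, gaussian_sd = 0) {
  out <- img
  if (poisson_gain > 0) {
    lam <- pmax(img, 0) / poisson_gain
    out <- matrix(stats::rpois(length(lam), lam) * poisson_gain,
                  nrow(img), ncol(img))
  }
  if (gaussian_sd > 0)
    out <- out + matrix(stats::rnorm(length(img), 0, gaussian_sd),
                        nrow(img), ncol(img))
  out
}

gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma_px))
}

# --- disc generator -------------------------------------------------------

#' Generate a synthetic wing-disc image pair with ground truth
#'
#' Renders two optical sections (basolateral, apical) of a wing-disc field
#' spanning the A/P boundary, with five channels each (see
#' [disc_channels()]):
#'
#' * basolateral section: membrane-lattice signal in the `fast` and `slow`
#'   channels proportional to the region's steady-state matured basolateral
#'   pools; `hh` membrane signal in the posterior compartment; the
#'   `membrane` marker lattice.
#' * apical section: timer puncta with per-channel amplitudes proportional
#'   to the matured apical pools times the acid-quench factors (so the
#'   `fast` channel is dark apically unless `nh4cl` is set); `hh` puncta
#'   whose total intensity is split `hh_partition : 1 - hh_partition`
#'   between P and A; `rab7` vesicles rendered as filled discs, co-centered
#'   with the prescribed fraction of Hh puncta so that the realized
#'   intensity overlap matches `overlap_aA` / `overlap_aP`.
#'
#' Every channel is blurred with a Gaussian PSF and then degraded with
#' Poisson (and optionally Gaussian) detection noise. All latent values are
#' returned in `truth`.
#'
#' @param config A [scenario_config()].
#' @return An object of class `synthetic_disc`: list with `images` (named
#'   list of `(ny, nx, 5)` arrays, one per section), `channels`,
#'   `geometry`, `config` and `truth`.
#' @export
generate_disc_image <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  geom <- config$geometry
  withr::with_seed(config$seed, .generate_disc(config, geom))
}

.generate_disc <- function(config, geom) {
  ny <- geom$ny; nx <- geom$nx; px <- geom$pixel_um
  rm_full <- region_masks(geom)
  apm <- ap_masks(geom)
  lattice <- membrane_lattice(geom)
  chans <- disc_channels()
  pair <- config$fluorophores
  qf <- if (config$nh4cl) 1 else pair$q_fast_acidic
  qs <- if (config$nh4cl) 1 else pair$q_slow_acidic

  # effective regions: optionally split dorsoventrally with scaled k_exit
  dm <- dorsal_mask(geom)
  eff <- list()
  for (rg in names(config$regions)) {
    p <- config$regions[[rg]]
    if (config$dorsal_k_exit_factor != 1) {
      pd <- trafficking_params(sigma = p$sigma,
                               k_exit = p$k_exit * config$dorsal_k_exit_factor,
                               k_deg = p$k_deg,
                               region = paste0(rg, "_dorsal"))
      eff[[rg]] <- list(params = p, mask = rm_full[[rg]] & !dm, parent = rg)
      eff[[paste0(rg, "_dorsal")]] <-
        list(params = pd, mask = rm_full[[rg]] & dm, parent = rg)
    } else {
      eff[[rg]] <- list(params = p, mask = rm_full[[rg]], parent = rg)
    }
  }
  pools <- lapply(eff, function(e) steady_state_pools(e$params, pair))
  pool_df <- do.call(rbind, lapply(names(eff), function(nm) {
    ps <- pools[[nm]]; p <- eff[[nm]]$params
    data.frame(region = nm, parent = eff[[nm]]$parent,
               residence_h = 1 / p$k_exit, k_deg = p$k_deg, sigma = p$sigma,
               B = ps$B, Bmat_fast = ps$Bmat_fast, Bmat_slow = ps$Bmat_slow,
               E = ps$E, Emat_fast = ps$Emat_fast, Emat_slow = ps$Emat_slow,
               ratio_baso = ps$Bmat_slow / ps$Bmat_fast)
  }))

  amp <- config$amp_scale
  zero <- function() matrix(0, ny, nx)
  baso <- list(fast = zero(), slow = zero(), hh = zero(), rab7 = zero(),
               membrane = amp * lattice)
  api <- list(fast = zero(), slow = zero(), hh = zero(), rab7 = zero(),
              membrane = 0.5 * amp * lattice)

  # basolateral membrane pools
  for (nm in names(eff)) {
    mm <- lattice & eff[[nm]]$mask
    baso$fast[mm] <- baso$fast[mm] + amp * pools[[nm]]$Bmat_fast
    baso$slow[mm] <- baso$slow[mm] + amp * pools[[nm]]$Bmat_slow
  }
  # basolateral Hh: membrane-associated in the producing (P) compartment
  baso$hh[lattice & apm$P] <- amp

  # apical timer puncta per effective region
  timer_tab <- NULL
  for (nm in names(eff)) {
    frac <- sum(eff[[nm]]$mask) / sum(rm_full[[eff[[nm]]$parent]])
    n <- max(1L, as.integer(round(config$n_timer_puncta * frac)))
    m <- shrink_mask(eff[[nm]]$mask, px, 1.0)
    pts <- sample_points(n, m, px, min_sep_um = 1.2)
    pf <- amp * pools[[nm]]$Emat_fast * qf * 2
    ps <- amp * pools[[nm]]$Emat_slow * qs * 2
    sig <- config$spot_radius_um / 2
    if (pf > 0)
      api$fast <- render_gaussian_spots(api$fast, px, pts$x_um, pts$y_um,
                                        pf, sig)
    if (ps > 0)
      api$slow <- render_gaussian_spots(api$slow, px, pts$x_um, pts$y_um,
                                        ps, sig)
    timer_tab <- rbind(timer_tab,
                       data.frame(x_um = pts$x_um, y_um = pts$y_um,
                                  region = nm, peak_fast = pf,
                                  peak_slow = ps))
  }

  # apical Hh puncta and Rab7 vesicles with controlled overlap
  sep <- 2 * config$vesicle_radius_um + 0.2
  hh_tab <- ves_tab <- NULL
  overlap_intended <- c(A = config$overlap_aA, P = config$overlap_aP)
  sig <- config$spot_radius_um / 2
  for (cp in c("A", "P")) {
    n <- as.integer(config$n_hh_puncta[[cp]])
    m <- shrink_mask(apm[[cp]], px, 1.5)
    pts <- sample_points(n, m, px, min_sep_um = sep)
    n_co <- as.integer(round(overlap_intended[[cp]] * n))
    coloc <- rep(FALSE, n); coloc[seq_len(n_co)] <- TRUE
    w <- if (cp == "P") config$hh_partition else 1 - config$hh_partition
    peak <- config$hh_total * w / n
    api$hh <- render_gaussian_spots(api$hh, px, pts$x_um, pts$y_um, peak, sig)
    # vesicles at co-localized puncta plus Rab7-only vesicles elsewhere
    extra <- sample_points(config$n_rab7_extra, m, px, min_sep_um = sep,
                           avoid = pts)
    vx <- c(pts$x_um[coloc], extra$x_um)
    vy <- c(pts$y_um[coloc], extra$y_um)
    api$rab7 <- render_discs(api$rab7, px, vx, vy,
                             config$vesicle_radius_um, 0.8 * amp)
    hh_tab <- rbind(hh_tab, data.frame(
      x_um = pts$x_um, y_um = pts$y_um, compartment = cp, peak = peak,
      coloc = coloc))
    ves_tab <- rbind(ves_tab, data.frame(
      x_um = vx, y_um = vy, compartment = cp,
      radius_um = config$vesicle_radius_um,
      has_hh = c(rep(TRUE, n_co), rep(FALSE, nrow(extra)))))
  }

  # PSF blur, pre-noise snapshot, realized latents, then detection noise
  s_px <- config$psf_sigma_um / px
  blur_sec <- function(sec) lapply(sec, gaussian_blur, sigma_px = s_px)
  baso <- blur_sec(baso); api <- blur_sec(api)

  part_realized <- sum(api$hh[apm$P]) / sum(api$hh[apm$A | apm$P])
  ov_realized <- vapply(c(A = "A", P = "P"), function(cp) {
    v <- ves_tab[ves_tab$compartment == cp, ]
    fp <- disc_footprint(ny, nx, px, v$x_um, v$y_um, v$radius_um)
    sum(api$hh[fp & apm[[cp]]]) / sum(api$hh[apm[[cp]]])
  }, numeric(1))

  noisy_sec <- function(sec) lapply(sec, apply_noise,
                                    poisson_gain = config$noise$poisson_gain,
                                    gaussian_sd = config$noise$gaussian_sd)
  baso_n <- noisy_sec(baso); api_n <- noisy_sec(api)

  to_array <- function(sec) {
    a <- array(0, dim = c(ny, nx, length(chans)),
               dimnames = list(NULL, NULL, chans))
    for (ch in chans) a[, , ch] <- sec[[ch]]
    a
  }
  structure(
    list(images = list(basolateral = to_array(baso_n),
                       apical = to_array(api_n)),
         channels = chans, geometry = geom, config = config,
         truth = list(
           region_masks = rm_full,
           effective_masks = lapply(eff, `[[`, "mask"),
           ap_masks = apm, membrane_lattice = lattice,
           pools = pool_df,
           timer_puncta = timer_tab, hh_puncta = hh_tab,
           rab7_vesicles = ves_tab,
           partition = list(intended = config$hh_partition,
                            realized = part_realized),
           overlap = data.frame(compartment = c("A", "P"),
                                intended = unname(overlap_intended),
                                realized = unname(ov_realized)),
           prenoise = list(basolateral = to_array(baso),
                           apical = to_array(api)),
           seed = config$seed, nh4cl = config$nh4cl)),
    class = "synthetic_disc"
  )
}

#' @export
print.synthetic_disc <- function(x, ...) {
  g <- x$geometry
  cat(sprintf(
    "<synthetic_disc> %d x %d px, sections: %s; channels: %s; seed %d\n",
    g$ny, g$nx, paste(names(x$images), collapse = ", "),
    paste(x$channels, collapse = ", "), x$truth$seed))
  invisible(x)
}

#' Extract one channel image from a synthetic disc
#'
#' @param disc A `synthetic_disc`.
#' @param section `"basolateral"` or `"apical"`.
#' @param channel One of [disc_channels()].
#' @param prenoise Return the noise-free rendering instead.
#' @return Numeric matrix `(ny, nx)`.
#' @export
get_channel <- function(disc, section, channel, prenoise = FALSE) {
  stopifnot(inherits(disc, "synthetic_disc"))
  src <- if (prenoise) disc$truth$prenoise else disc$images
  if (!section %in% names(src)) stop("unknown section: ", section)
  if (!channel %in% disc$channels) stop("unknown channel: ", channel)
  src[[section]][, , channel]
}
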