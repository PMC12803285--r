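# Otsu threshold on an arbitrary-range image (EBImage::otsu expects [0, 1])
otsu_threshold <- function(img) {
  rng <- range(img, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])
  thr <- EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng)),
                       range = c(0, 1))
  rng[1] + thr * diff(rng)
}

#' Background subtraction
#'
#' Subtracts a robust background level estimated from the image (or from a
#' mask of background-eligible pixels). The default is the 5th percentile
#' of the pixel values, floored at zero, which removes a constant offset
#' without clipping genuine signal.
#'
#' @param img Numeric matrix.
#' @param prob Quantile used as the background level (default 0.05).
#' @param mask Optional logical matrix restricting the pixels used to
#'   estimate (and receive) the subtraction; default whole image.
#' @param floor Clamp negative residuals at zero (default `TRUE`).
#' @return Matrix of the same size.
#' @export
subtract_background <- function(img, prob = 0.05, mask = NULL, floor = TRUE) {
  stopifnot(is.matrix(img))
  px <- if (is.null(mask)) img else {
    if (!any(mask)) stop("empty mask")
    img[mask]
  }
  bg <- stats::quantile(px, prob, names = FALSE)
  out <- img - bg
  if (floor) out[out < 0] <- 0
  out
}

#' Intensity profile along the A/P axis
#'
#' Mean intensity per image column (x position), the in-package equivalent
#' of a line-profile measurement across the compartment boundary. Rows can
#' be restricted with a mask.
#'
#' @param img Numeric matrix (one channel of one section).
#' @param pixel_um Pixel size (um/px).
#' @param mask Optional logical matrix; at each column the mean is taken
#'   over masked pixels only.
#' @param geom Optional [disc_geometry()]; adds a `region` annotation per
#'   position.
#' @return Data frame with `x_um`, `intensity` and (optionally) `region`.
#' @export
plot_profile <- function(img, pixel_um, mask = NULL, geom = NULL) {
  stopifnot(is.matrix(img))
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(img)))
    if (!any(mask)) stop("empty mask")
    v <- img; v[!mask] <- NA
    prof <- colMeans(v, na.rm = TRUE)
  } else {
    prof <- colMeans(img)
  }
  out <- data.frame(x_um = (seq_len(ncol(img)) - 0.5) * pixel_um,
                    intensity = prof)
  if (!is.null(geom)) {
    stopifnot(inherits(geom, "disc_geometry"))
    band_lo <- geom$boundary_x_um - geom$band_cells * geom$cell_um
    out$region <- ifelse(out$x_um >= geom$boundary_x_um, "P",
                         ifelse(out$x_um >= band_lo, "ptc_band", "far_A"))
  }
  out
}

#' Fraction of channel signal per region
#'
#' Integrated intensity per region mask, as fractions of the total over the
#' mask union. Used for compartment partition measurements (e.g. the share
#' of morphogen signal retained in the producing compartment).
#'
#' @param img Numeric matrix (background-subtracted channel).
#' @param masks Named list of disjoint logical masks.
#' @return Named numeric vector of fractions summing to 1.
#' @export
compartment_partition <- function(img, masks) {
  stopifnot(is.matrix(img), is.list(masks), length(masks) >= 2)
  overlap_px <- Reduce(`+`, lapply(masks, function(m) m * 1))
  if (any(overlap_px > 1)) stop("masks must be disjoint")
  sums <- vapply(masks, function(m) sum(img[m]), numeric(1))
  tot <- sum(sums)
  if (tot <= 0) stop("zero total signal over the mask union")
  sums / tot
}

#' Detect puncta with a Laplacian-of-Gaussian filter
#'
#' Blob detection at a known spot scale: the image is filtered with a
#' (negative) Laplacian-of-Gaussian kernel matched to the expected spot
#' size, the response is thresholded with Otsu's method, and connected
#' components become detections. Detections are sorted by position so the
#' result is deterministic.
#'
#' @param img Numeric matrix.
#' @param pixel_um Pixel size (um/px).
#' @param spot_radius_um Expected spot radius (um); the LoG scale is the
#'   quadrature sum of `spot_radius_um / 2` and `psf_sigma_um`.
#' @param psf_sigma_um Optical blur sigma (um).
#' @param region_mask Optional logical matrix restricting detections.
#' @param min_area_px Discard components smaller than this (default 4 px).
#' @return Data frame of class `puncta_set`: `x_um`, `y_um`
#'   (intensity-weighted centroids), `r_um` (equivalent radius),
#'   `intensity` (integrated image intensity over the component) and
#'   `area_px`. May have zero rows.
#' @export
detect_puncta <- function(img, pixel_um, spot_radius_um = 0.4,
                          psf_sigma_um = 0.2, region_mask = NULL,
                          min_area_px = 4L) {
  stopifnot(is.matrix(img), pixel_um > 0)
  sigma_px <- sqrt((spot_radius_um / 2)^2 + psf_sigma_um^2) / pixel_um
  half <- max(2L, ceiling(3 * sigma_px))
  xs <- seq(-half, half)
  g <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma_px^2))
  g <- g / sum(g)
  r2 <- outer(xs^2, xs^2, "+")
  log_k <- g * (r2 - 2 * sigma_px^2) / sigma_px^4  # Laplacian of Gaussian
  log_k <- log_k - mean(log_k)                     # zero-sum: flat -> 0
  resp <- as.matrix(EBImage::filter2(EBImage::Image(img), -log_k))
  if (!is.null(region_mask)) resp[!region_mask] <- 0
  resp[resp < 0] <- 0
  if (max(resp) <= 0) return(empty_puncta())
  thr <- otsu_threshold(resp)
  bw <- resp > thr
  if (!any(bw)) return(empty_puncta())
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  lab <- as.matrix(lab)
  ids <- which(lab > 0)
  if (length(ids) == 0) return(empty_puncta())
  lv <- lab[ids]
  wt <- resp[ids]
  ii <- ((ids - 1) %% nrow(img)) + 1
  jj <- ((ids - 1) %/% nrow(img)) + 1
  area <- tabulate(lv)
  sw <- tapply(wt, lv, sum)
  cx <- tapply(wt * jj, lv, sum) / sw
  cy <- tapply(wt * ii, lv, sum) / sw
  inten <- tapply(img[ids], lv, sum)
  keep <- area[as.integer(names(sw))] >= min_area_px
  out <- data.frame(
    x_um = (as.numeric(cx) - 0.5) * pixel_um,
    y_um = (as.numeric(cy) - 0.5) * pixel_um,
    r_um = sqrt(area[as.integer(names(sw))] / pi) * pixel_um,
    intensity = as.numeric(inten),
    area_px = area[as.integer(names(sw))])[keep, , drop = FALSE]
  out <- out[order(out$x_um, out$y_um), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("puncta_set", "data.frame")
  out
}

empty_puncta <- function() {
  out <- data.frame(x_um = numeric(0), y_um = numeric(0), r_um = numeric(0),
                    intensity = numeric(0), area_px = integer(0))
  class(out) <- c("puncta_set", "data.frame")
  out
}

#' Intensity-weighted colocalization (Manders M1) with bootstrap CI
#'
#' Fraction of the signal channel's intensity that falls inside the
#' partner channel's Otsu mask, after per-region background subtraction —
#' the Manders M1 coefficient. The confidence interval is obtained by
#' bootstrap over detected signal puncta (each punctum contributes its
#' integrated intensity and its own in-mask fraction), so it reflects
#' punctum-to-punctum sampling variability.
#'
#' @param signal_img,partner_img Numeric matrices (same section).
#' @param pixel_um Pixel size (um/px).
#' @param region_mask Optional logical matrix restricting the measurement.
#' @param spot_radius_um,psf_sigma_um Passed to [detect_puncta()].
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @param region Label stored in the result.
#' @return A list of class `coloc_result`: `fraction`, `ci_lo`, `ci_hi`,
#'   `n_puncta`, `region`.
#' @export
intensity_overlap <- function(signal_img, partner_img, pixel_um,
                              region_mask = NULL, spot_radius_um = 0.4,
                              psf_sigma_um = 0.2, n_boot = 1000, seed = 1L,
                              region = NA_character_) {
  stopifnot(is.matrix(signal_img),
            identical(dim(signal_img), dim(partner_img)))
  if (is.null(region_mask))
    region_mask <- matrix(TRUE, nrow(signal_img), ncol(signal_img))
  if (!any(region_mask)) stop("empty region mask")
  sig <- subtract_background(signal_img, mask = region_mask)
  tot <- sum(sig[region_mask])
  if (tot <= 0) stop("zero total signal in region")
  # partner mask from the raw partner channel (Otsu above background);
  # a uniform positive partner counts as covering the whole region
  pin <- partner_img[region_mask]
  pmask <- matrix(FALSE, nrow(partner_img), ncol(partner_img))
  if (any(pin > 0)) {
    if (stats::sd(pin) > 0) {
      thr <- otsu_threshold(pin)
      pmask <- partner_img > thr & region_mask
    } else {
      pmask <- partner_img > 0 & region_mask
    }
  }
  m1 <- sum(sig[pmask]) / tot

  # per-punctum in-mask fractions for the bootstrap
  pts <- detect_puncta(sig, pixel_um, spot_radius_um, psf_sigma_um,
                       region_mask = region_mask)
  ci <- c(NA_real_, NA_real_)
  if (nrow(pts) >= 2 && n_boot > 0) {
    # recompute per-component membership
    w <- pts$intensity
    frac <- vapply(seq_len(nrow(pts)), function(i) {
      cj <- pts$x_um[i] / pixel_um + 0.5
      ci_ <- pts$y_um[i] / pixel_um + 0.5
      r_px <- max(2, 2 * pts$r_um[i] / pixel_um)
      jj <- max(1, floor(cj - r_px)):min(ncol(sig), ceiling(cj + r_px))
      ii <- max(1, floor(ci_ - r_px)):min(nrow(sig), ceiling(ci_ + r_px))
      s <- sig[ii, jj]; m <- pmask[ii, jj]
      if (sum(s) <= 0) return(0) else sum(s[m]) / sum(s)
    }, numeric(1))
    bb <- withr::with_seed(as.integer(seed), {
      replicate(n_boot, {
        k <- sample.int(length(w), replace = TRUE)
        sum(w[k] * frac[k]) / sum(w[k])
      })
    })
    ci <- stats::quantile(bb, c(0.025, 0.975), names = FALSE)
    ci[1] <- min(ci[1], m1); ci[2] <- max(ci[2], m1)
  }
  structure(list(fraction = m1, ci_lo = ci[1], ci_hi = ci[2],
                 n_puncta = nrow(pts), region = region),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result>%s M1 = %.3f [%.3f, %.3f], n_puncta = %d\n",
    if (is.na(x$region)) "" else paste0(" ", x$region, ":"),
    x$fraction, x$ci_lo, x$ci_hi, x$n_puncta))
  invisible(x)
}

#' Membrane mask from a junctional-marker channel
#'
#' Otsu threshold on the membrane-marker channel. For external data a mask
#' file can be supplied instead of calling this.
#'
#' @param img Numeric matrix (membrane channel).
#' @return Logical matrix.
#' @export
membrane_mask_from_channel <- function(img) {
  stopifnot(is.matrix(img))
  img > otsu_threshold(img)
}

#' Per-region normalized slow/fast membrane ratio
#'
#' Ratio of integrated slow-channel to fast-channel intensity over the
#' membrane pixels of each region, after per-region background
#' subtraction, divided by `norm` (the fully-matured calibration constant;
#' 1 for the synthetic generator's normalized units) so that a ratio of 1
#' means an infinitely old pool. Uncertainty comes from a pixel bootstrap
#' over membrane pixels. Regions whose fast-channel membrane signal does
#' not exceed `noise_floor` are flagged `defined = FALSE` (the
#' fast-chromophore-undetectable regime) instead of reporting a number.
#'
#' @param img_slow,img_fast Numeric matrices (same section).
#' @param membrane_mask Logical matrix of membrane pixels.
#' @param region_masks Named list of logical region masks.
#' @param norm Fully-matured slow/fast calibration constant.
#' @param noise_floor Minimum mean fast-channel membrane intensity for the
#'   ratio to be defined; `NULL` estimates it as 3 standard deviations of
#'   the off-membrane region pixels.
#' @param n_boot Pixel-bootstrap resamples (default 500).
#' @param seed Seed for the bootstrap.
#' @return Data frame: `region`, `ratio`, `ci_lo`, `ci_hi`, `n_px`,
#'   `defined`.
#' @export
membrane_ratio <- function(img_slow, img_fast, membrane_mask, region_masks,
                           norm = 1, noise_floor = NULL, n_boot = 500,
                           seed = 1L) {
  stopifnot(is.matrix(img_slow), identical(dim(img_slow), dim(img_fast)),
            is.list(region_masks), length(region_masks) >= 1)
  res <- lapply(names(region_masks), function(rg) {
    rmask <- region_masks[[rg]]
    mm <- membrane_mask & rmask
    n_px <- sum(mm)
    if (n_px == 0)
      return(data.frame(region = rg, ratio = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n_px = 0L, defined = FALSE))
    s <- subtract_background(img_slow, mask = rmask)
    f <- subtract_background(img_fast, mask = rmask)
    nf <- noise_floor
    if (is.null(nf)) {
      off <- img_fast[rmask & !membrane_mask]
      nf <- if (length(off) > 1) 3 * stats::sd(off) else 0
    }
    fs <- f[mm]; ss <- s[mm]
    if (mean(fs) <= nf)
      return(data.frame(region = rg, ratio = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n_px = n_px, defined = FALSE))
    ratio <- (sum(ss) / sum(fs)) / norm
    ci <- c(ratio, ratio)
    if (n_boot > 0) {
      bb <- withr::with_seed(as.integer(seed), {
        replicate(n_boot, {
          k <- sample.int(n_px, replace = TRUE)
          (sum(ss[k]) / sum(fs[k])) / norm
        })
      })
      ci <- stats::quantile(bb, c(0.025, 0.975), names = FALSE)
    }
    data.frame(region = rg, ratio = ratio,
               ci_lo = min(ci[1], ratio), ci_hi = max(ci[2], ratio),
               n_px = n_px, defined = TRUE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Quantify a synthetic disc
#'
#' Convenience wrapper running the standard measurement set on a
#' [generate_disc_image()] result: A/P partition of the apical Hh channel,
#' Hh-Rab7 intensity overlap per apical compartment, and the per-region
#' basolateral slow/fast membrane ratio.
#'
#' @param disc A `synthetic_disc`.
#' @param n_boot Bootstrap resamples for the component estimators.
#' @param seed Seed for all bootstraps.
#' @return List with `partition` (named fractions), `overlap` (data frame
#'   per compartment), `ratios` (data frame from [membrane_ratio()]).
#' @export
quantify_disc <- function(disc, n_boot = 500, seed = 1L) {
  stopifnot(inherits(disc, "synthetic_disc"))
  geom <- disc$geometry
  apm <- ap_masks(geom)
  rm_ <- region_masks(geom)
  hh <- get_channel(disc, "apical", "hh")
  hh_bs <- subtract_background(hh)
  part <- compartment_partition(hh_bs, apm)
  rab7 <- get_channel(disc, "apical", "rab7")
  cfg <- disc$config
  ov <- do.call(rbind, lapply(c("A", "P"), function(cp) {
    z <- intensity_overlap(hh, rab7, geom$pixel_um, region_mask = apm[[cp]],
                           spot_radius_um = cfg$spot_radius_um,
                           psf_sigma_um = cfg$psf_sigma_um,
                           n_boot = n_boot, seed = seed, region = cp)
    data.frame(compartment = cp, fraction = z$fraction, ci_lo = z$ci_lo,
               ci_hi = z$ci_hi, n_puncta = z$n_puncta)
  }))
  memb <- membrane_mask_from_channel(get_channel(disc, "basolateral",
                                                 "membrane"))
  # erode region masks away from region borders so PSF bleed from the
  # neighbouring region does not contaminate the membrane ratio
  rm_er <- lapply(rm_, shrink_mask, pixel_um = geom$pixel_um,
                  margin_um = 1.0)
  ratios <- membrane_ratio(get_channel(disc, "basolateral", "slow"),
                           get_channel(disc, "basolateral", "fast"),
                           memb, rm_er, n_boot = n_boot, seed = seed)
  list(partition = part, overlap = ov, ratios = ratios)
}
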