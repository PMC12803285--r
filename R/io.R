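#' Write a multichannel image section to TIFF (+ JSON sidecar)
#'
#' Pixel data go into a multi-page 32-bit float TIFF (one page per channel,
#' in [disc_channels()] order for synthetic discs). Because float TIFF
#' pages are stored in `[0, 1]`, the image is divided by a common scale
#' factor which is recorded, together with the channel names and pixel
#' size, in a JSON sidecar next to the TIFF (`<file>.json`).
#'
#' @param img 3D array `(ny, nx, n_channels)` with channel dimnames, or a
#'   numeric matrix (single channel).
#' @param path Output TIFF path.
#' @param pixel_um Pixel size recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, pixel_um = NA_real_) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1))
  stopifnot(length(dim(img)) == 3)
  chans <- dimnames(img)[[3]]
  if (is.null(chans)) chans <- paste0("ch", seq_len(dim(img)[3]))
  scale <- max(img, 1e-12)
  pages <- lapply(seq_len(dim(img)[3]),
                  function(k) pmin(pmax(img[, , k] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(scale = scale, channels = chans, pixel_um = pixel_um,
               ny = dim(img)[1], nx = dim(img)[2])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multichannel image written by [write_image()]
#'
#' Plain multichannel TIFFs from other sources are read too; without a
#' sidecar the pixel values are returned as stored and channels are named
#' `ch1, ch2, ...`.
#'
#' @param path TIFF path.
#' @return 3D array `(ny, nx, n_channels)` with channel dimnames and
#'   attributes `pixel_um` and `scale`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  meta_path <- paste0(path, ".json")
  scale <- 1; chans <- paste0("ch", seq_along(pages)); pxum <- NA_real_
  if (file.exists(meta_path)) {
    meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                     error = function(e)
                       stop("malformed image sidecar ", meta_path, ": ",
                            conditionMessage(e)))
    scale <- meta$scale; chans <- meta$channels; pxum <- meta$pixel_um
  }
  out <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)),
               dimnames = list(NULL, NULL, chans))
  for (k in seq_along(pages)) out[, , k] <- pages[[k]] * scale
  attr(out, "pixel_um") <- pxum
  attr(out, "scale") <- scale
  out
}

#' Write / read a data table as CSV
#'
#' UTF-8, header row, `.` decimal separator.
#'
#' @param df Data frame.
#' @param path CSV path.
#' @return `path` invisibly (write) or the data frame (read).
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such table file: ", path)
  utils::read.csv(path, fileEncoding = "UTF-8")
}

# scenario_config <-> plain list (for YAML round-trip)
config_to_list <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  g <- config$geometry
  list(
    geometry = list(field_um = g$field_um, pixel_um = g$pixel_um,
                    cell_um = g$cell_um, band_cells = g$band_cells,
                    boundary_x_um = g$boundary_x_um),
    fluorophores = list(m_fast = config$fluorophores$m_fast,
                        m_slow = config$fluorophores$m_slow,
                        q_fast_acidic = config$fluorophores$q_fast_acidic,
                        q_slow_acidic = config$fluorophores$q_slow_acidic),
    regions = lapply(config$regions, function(p)
      list(sigma = p$sigma, k_exit = p$k_exit, k_deg = p$k_deg)),
    hh_partition = config$hh_partition,
    overlap_aA = config$overlap_aA, overlap_aP = config$overlap_aP,
    n_hh_puncta = as.list(config$n_hh_puncta),
    n_timer_puncta = config$n_timer_puncta,
    n_rab7_extra = config$n_rab7_extra,
    spot_radius_um = config$spot_radius_um,
    vesicle_radius_um = config$vesicle_radius_um,
    psf_sigma_um = config$psf_sigma_um,
    amp_scale = config$amp_scale, hh_total = config$hh_total,
    noise = config$noise, nh4cl = config$nh4cl,
    dorsal_k_exit_factor = config$dorsal_k_exit_factor,
    seed = config$seed)
}

list_to_config <- function(x) {
  need <- function(f) {
    if (is.null(x[[f]])) stop("config is missing required field: ", f)
    x[[f]]
  }
  g <- need("geometry")
  fl <- need("fluorophores")
  rg <- need("regions")
  geometry <- disc_geometry(field_um = unlist(g$field_um),
                            pixel_um = g$pixel_um, cell_um = g$cell_um,
                            band_cells = g$band_cells,
                            boundary_x_um = g$boundary_x_um)
  pair <- fluorophore_pair(m_fast = fl$m_fast, m_slow = fl$m_slow,
                           q_fast_acidic = fl$q_fast_acidic,
                           q_slow_acidic = fl$q_slow_acidic)
  regions <- lapply(names(rg), function(nm)
    trafficking_params(sigma = rg[[nm]]$sigma, k_exit = rg[[nm]]$k_exit,
                       k_deg = rg[[nm]]$k_deg, region = nm))
  names(regions) <- names(rg)
  scenario_config(
    geometry = geometry, regions = regions, fluorophores = pair,
    hh_partition = need("hh_partition"),
    overlap_aA = x$overlap_aA %||% 0.85, overlap_aP = x$overlap_aP %||% 0.5,
    n_hh_puncta = unlist(x$n_hh_puncta %||% c(A = 40, P = 90)),
    n_timer_puncta = x$n_timer_puncta %||% 30,
    n_rab7_extra = x$n_rab7_extra %||% 20,
    spot_radius_um = x$spot_radius_um %||% 0.4,
    vesicle_radius_um = x$vesicle_radius_um %||% 0.9,
    psf_sigma_um = x$psf_sigma_um %||% 0.2,
    amp_scale = x$amp_scale %||% 100, hh_total = x$hh_total %||% 40000,
    noise = x$noise %||% list(poisson_gain = 1, gaussian_sd = 0),
    nh4cl = x$nh4cl %||% FALSE,
    dorsal_k_exit_factor = x$dorsal_k_exit_factor %||% 1,
    seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a scenario configuration as YAML
#'
#' A YAML file either names a preset (`preset: wild_type`, optionally with
#' a `seed`) or spells out the full configuration (as produced by
#' [write_config()]); the two round-trip.
#'
#' @param config A [scenario_config()].
#' @param path YAML path.
#' @return `path` invisibly (write) or a `scenario_config` (read).
#' @export
write_config <- function(config, path) {
  # precision 17 so rate constants survive the YAML round-trip bit-exactly
  yaml::write_yaml(config_to_list(config), path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  x <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed YAML config ", path, ": ", conditionMessage(e)))
  if (!is.null(x$preset))
    return(scenario_preset(x$preset, seed = x$seed %||% 1L))
  list_to_config(x)
}
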