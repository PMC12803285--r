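#' Channel order of synthetic disc images
#'
#' Fixed channel order used throughout: `fast` and `slow` are the two timer
#' chromophores on the tagged protein, `hh` is the morphogen channel,
#' `rab7` marks late endosomes and `membrane` is the junctional marker.
#'
#' @return Character vector of channel names.
#' @export
disc_channels <- function() c("fast", "slow", "hh", "rab7", "membrane")

#' Scenario configuration for the synthetic disc generator
#'
#' Bundles the geometry, per-region trafficking parameters, fluorophore
#' pair, morphogen-channel settings and noise model that define one
#' synthetic imaging experiment. All randomness in the generator is fixed
#' by `seed`.
#'
#' @param geometry A [disc_geometry()].
#' @param regions Named list of [trafficking_params()] for exactly the
#'   regions `far_A`, `ptc_band`, `P`.
#' @param fluorophores A [fluorophore_pair()].
#' @param hh_partition Fraction of total Hh-channel signal in the posterior
#'   compartment (default 0.95).
#' @param overlap_aA,overlap_aP Intended intensity-weighted Hh-Rab7 overlap
#'   in the apical anterior / posterior compartments (defaults 0.85, 0.50).
#' @param n_hh_puncta Named vector `c(A = , P = )` of apical Hh puncta.
#' @param n_timer_puncta Apical timer (tagged-protein) puncta per region.
#' @param n_rab7_extra Rab7-only vesicles per compartment.
#' @param spot_radius_um Radius of Gaussian puncta (um).
#' @param vesicle_radius_um Radius of Rab7 vesicle discs (um); vesicles are
#'   rendered as filled discs larger than the diffraction-limited puncta.
#' @param psf_sigma_um Gaussian PSF sigma applied to every channel (um).
#' @param amp_scale Arbitrary intensity unit scale (photons per protein
#'   unit at the membrane).
#' @param hh_total Total apical Hh-channel intensity budget (peak units).
#' @param noise List with `poisson_gain` (0 disables shot noise) and
#'   `gaussian_sd` (read noise sd; 0 disables).
#' @param nh4cl Logical; ammonium-chloride treatment neutralizes acidic
#'   compartments, setting both acid-quench factors to 1.
#' @param dorsal_k_exit_factor Multiplier on `k_exit` in the dorsal half
#'   (default 1 = no dorsoventral difference).
#' @param seed Integer seed fixing all generator randomness.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(geometry = disc_geometry(),
                            regions,
                            fluorophores = default_fluorophore_pair(),
                            hh_partition = 0.95,
                            overlap_aA = 0.85, overlap_aP = 0.50,
                            n_hh_puncta = c(A = 40, P = 90),
                            n_timer_puncta = 30,
                            n_rab7_extra = 20,
                            spot_radius_um = 0.4,
                            vesicle_radius_um = 0.9,
                            psf_sigma_um = 0.2,
                            amp_scale = 100,
                            hh_total = 40000,
                            noise = list(poisson_gain = 1, gaussian_sd = 0),
                            nh4cl = FALSE,
                            dorsal_k_exit_factor = 1,
                            seed = 1L) {
  stopifnot(inherits(geometry, "disc_geometry"),
            inherits(fluorophores, "fluorophore_pair"))
  if (!setequal(names(regions), c("far_A", "ptc_band", "P")))
    stop("regions must be a named list with exactly far_A, ptc_band, P")
  for (r in regions) stopifnot(inherits(r, "trafficking_params"))
  for (fr in c(hh_partition, overlap_aA, overlap_aP))
    if (!is.finite(fr) || fr < 0 || fr > 1) stop("fractions must lie in [0, 1]")
  stopifnot(all(c("A", "P") %in% names(n_hh_puncta)),
            spot_radius_um > 0, vesicle_radius_um > 0, psf_sigma_um >= 0,
            amp_scale > 0, hh_total > 0, dorsal_k_exit_factor > 0)
  structure(
    list(geometry = geometry, regions = regions[c("far_A", "ptc_band", "P")],
         fluorophores = fluorophores, hh_partition = hh_partition,
         overlap_aA = overlap_aA, overlap_aP = overlap_aP,
         n_hh_puncta = n_hh_puncta, n_timer_puncta = n_timer_puncta,
         n_rab7_extra = n_rab7_extra, spot_radius_um = spot_radius_um,
         vesicle_radius_um = vesicle_radius_um, psf_sigma_um = psf_sigma_um,
         amp_scale = amp_scale, hh_total = hh_total, noise = noise,
         nh4cl = nh4cl, dorsal_k_exit_factor = dorsal_k_exit_factor,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Built-in scenario presets
#'
#' Named parameter sets for the imaging scenarios the package emulates:
#'
#' * `wild_type` — basolateral residence times ordered P (8 h) > ptc band
#'   (4.0 h) > far anterior (1.8 h). The 4.0 h and 1.8 h values are
#'   generator choices consistent with the measured upper bounds (4.5 h and
#'   2 h) and their roughly two-fold contrast; 8 h places the posterior
#'   pool near the old end of the timer's dynamic range.
#' * `disp_mutant` — Hh transport to the anterior is lost; anterior regions
#'   take short residence times and a large, slowly cleared apical pool.
#' * `hh_cd2` — membrane-tethered Hh signals to the anterior; anterior
#'   regions take posterior-like parameters.
#' * `usp8_dorsal` — deubiquitinase overexpression in the dorsal half
#'   halves `k_exit` there (reduced internalization from the basolateral
#'   membrane).
#' * `nh4cl` — wild type imaged under ammonium chloride (acid quench
#'   neutralized).
#' * `uniform_turnover` — identical parameters in all regions; the
#'   spatially uninformative null in which the timer ratio is flat.
#'
#' @param name One of the preset names above.
#' @param seed Seed stored in the config.
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name = c("wild_type", "disp_mutant", "hh_cd2",
                                     "usp8_dorsal", "nh4cl",
                                     "uniform_turnover"),
                            seed = 1L) {
  name <- match.arg(name)
  tp <- function(res, kdeg, rg) trafficking_params(
    sigma = 1, residence_h = res, k_deg = kdeg, region = rg)
  wt <- list(far_A = tp(1.8, 0.25, "far_A"),
             ptc_band = tp(4.0, 0.40, "ptc_band"),
             P = tp(8.0, 0.50, "P"))
  cfg <- switch(
    name,
    wild_type = scenario_config(regions = wt, seed = seed),
    disp_mutant = scenario_config(
      regions = list(far_A = tp(1.5, 0.20, "far_A"),
                     ptc_band = tp(1.8, 0.25, "ptc_band"),
                     P = wt$P),
      seed = seed),
    hh_cd2 = scenario_config(
      regions = list(far_A = tp(8.0, 0.50, "far_A"),
                     ptc_band = tp(8.0, 0.50, "ptc_band"),
                     P = wt$P),
      seed = seed),
    usp8_dorsal = scenario_config(regions = wt, dorsal_k_exit_factor = 0.5,
                                  seed = seed),
    nh4cl = scenario_config(regions = wt, nh4cl = TRUE, seed = seed),
    uniform_turnover = scenario_config(
      regions = list(far_A = tp(4.0, 0.40, "far_A"),
                     ptc_band = tp(4.0, 0.40, "ptc_band"),
                     P = tp(4.0, 0.40, "P")),
      seed = seed)
  )
  attr(cfg, "preset") <- name
  cfg
}
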