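#' Simulation configuration for synthetic tumouroid plates
#'
#' Bundles and validates every parameter of the synthetic time-lapse plate
#' generator. Defaults reproduce the reference screening scenario: a 5-step,
#' 10-fold SN-38 ladder from 0.1 to 1000 nM plus vehicle, four technical
#' replicates, treatment starting 2 days after seeding and lasting 7 days,
#' with imaging up to day 14.
#'
#' Objects are rendered darker than the background (brightfield polarity);
#' set \code{object_level > background_level} to simulate the opposite
#' polarity.
#'
#' @param image_size integer vector (H, W) of the frame in pixels.
#' @param n_planes number of Z-planes per acquisition.
#' @param plane_spacing distance between adjacent Z-planes, um.
#' @param pixel_size lateral calibration, um/pixel.
#' @param n_objects tumouroids seeded per well.
#' @param radius_range (min, max) day-0 tumouroid radius, um.
#' @param growth_rate per-day relative radius growth rate g; radii grow as
#'   \code{r0 * exp(g * t)} when unperturbed.
#' @param days imaging days (strictly increasing), days post-seeding.
#' @param doses concentrations in nM; 0 denotes vehicle control.
#' @param ic50_true,hill_true Hill inhibition parameters used to scale the
#'   growth rate of treated wells.
#' @param treatment_start day treatment begins.
#' @param treatment_days duration of drug exposure, days; growth is
#'   uninhibited again after drug removal.
#' @param background_level,object_level rendered intensities in [0, 1];
#'   objects must differ from background.
#' @param noise_sd additive Gaussian pixel noise, intensity units.
#' @param blur_per_um_defocus Gaussian PSF sigma gained per um of defocus,
#'   px/um.
#' @param min_separation minimum centre-to-centre distance between seeded
#'   objects, um; 0 permits arbitrary overlap.
#' @param n_replicates technical replicate wells per dose.
#' @param sample_id,drug labels written to the plate map.
#' @param rng_seed integer seed governing all simulator randomness.
#'
#' @return an object of class \code{sim_config} (a validated named list).
#' @examples
#' cfg <- sim_config(image_size = c(128, 128), n_objects = 3, days = c(1, 5))
#' cfg$doses
#' @export
sim_config <- function(image_size = c(256L, 256L),
                       n_planes = 5L,
                       plane_spacing = 20,
                       pixel_size = 3,
                       n_objects = 8L,
                       radius_range = c(25, 45),
                       growth_rate = 0.08,
                       days = c(1, 2, 3, 5, 7, 9, 12, 14),
                       doses = c(0, 0.1, 1, 10, 100, 1000),
                       ic50_true = 10,
                       hill_true = 1,
                       treatment_start = 2,
                       treatment_days = 7,
                       background_level = 0.85,
                       object_level = 0.35,
                       noise_sd = 0.02,
                       blur_per_um_defocus = 0.03,
                       min_separation = 60,
                       n_replicates = 4L,
                       sample_id = "S1",
                       drug = "SN-38",
                       rng_seed = 1L) {
  cfg <- list(image_size = as.integer(image_size), n_planes = as.integer(n_planes),
              plane_spacing = plane_spacing, pixel_size = pixel_size,
              n_objects = as.integer(n_objects), radius_range = radius_range,
              growth_rate = growth_rate, days = days, doses = doses,
              ic50_true = ic50_true, hill_true = hill_true,
              treatment_start = treatment_start, treatment_days = treatment_days,
              background_level = background_level, object_level = object_level,
              noise_sd = noise_sd, blur_per_um_defocus = blur_per_um_defocus,
              min_separation = min_separation, n_replicates = as.integer(n_replicates),
              sample_id = sample_id, drug = drug, rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$image_size) != 2L || any(cfg$image_size < 16L))
    stop("image_size must be (H, W) with both >= 16 px")
  if (cfg$n_planes < 1L) stop("n_planes must be >= 1")
  if (cfg$plane_spacing <= 0) stop("plane_spacing must be > 0")
  if (cfg$pixel_size <= 0) stop("pixel_size must be > 0")
  if (cfg$n_objects < 0L) stop("n_objects must be >= 0")
  if (length(cfg$radius_range) != 2L || cfg$radius_range[1] <= 0 ||
      diff(cfg$radius_range) < 0)
    stop("radius_range must be (min, max) with min > 0")
  if (length(cfg$days) < 1L || any(diff(cfg$days) <= 0))
    stop("days must be strictly increasing")
  if (any(cfg$doses < 0)) stop("doses must be >= 0 (0 = vehicle)")
  if (cfg$ic50_true <= 0 || cfg$hill_true <= 0)
    stop("ic50_true and hill_true must be > 0")
  if (!(cfg$background_level >= 0 && cfg$background_level <= 1 &&
        cfg$object_level >= 0 && cfg$object_level <= 1))
    stop("background_level and object_level must lie in [0, 1]")
  if (cfg$object_level == cfg$background_level)
    stop("object_level must differ from background_level")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$blur_per_um_defocus < 0) stop("blur_per_um_defocus must be >= 0")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  cfg
}

#' Hill inhibition fraction
#'
#' Fractional growth inhibition at concentration \code{c} under a Hill
#' model: \code{c^h / (c^h + ic50^h)}. Monotone non-decreasing in \code{c},
#' 0 at zero dose and 0.5 at \code{c = ic50}.
#'
#' @param c concentration, nM (>= 0); vectorized.
#' @param ic50 half-maximal inhibitory concentration, nM (> 0).
#' @param h Hill coefficient (> 0).
#' @return inhibition fraction(s) in [0, 1].
#' @examples
#' inhibition_fraction(c(0, 10, 100), ic50 = 10, h = 1)
#' @export
inhibition_fraction <- function(c, ic50, h) {
  if (ic50 <= 0) stop("ic50 must be > 0")
  if (h <= 0) stop("h must be > 0")
  if (any(c < 0)) stop("concentrations must be >= 0")
  ch <- c^h
  ch / (ch + ic50^h)
}

#' Exponential radius growth under inhibition
#'
#' Radius after \code{t} days of growth at rate \code{g} scaled by
#' \code{(1 - inhibition)}: \code{r0 * exp(g * (1 - inhibition) * t)}.
#'
#' @param r0 starting radius, um (> 0).
#' @param g per-day relative growth rate.
#' @param inhibition fraction in [0, 1]; 1 freezes growth.
#' @param t elapsed time, days (>= 0).
#' @return radius in um.
#' @examples
#' grow_radius(30, 0.2, inhibition = 0, t = 5) # 30 * e
#' @export
grow_radius <- function(r0, g, inhibition, t) {
  if (any(r0 <= 0)) stop("r0 must be > 0")
  if (any(t < 0)) stop("t must be >= 0")
  if (any(inhibition < 0 | inhibition > 1)) stop("inhibition must lie in [0, 1]")
  r0 * exp(g * (1 - inhibition) * t)
}

# Radius on a given day under the treatment timeline: free growth before
# treatment_start, inhibited growth during the exposure window, free growth
# after drug removal.
radius_on_day <- function(r0, day, inhibition, cfg) {
  pre <- pmin(day, cfg$treatment_start)
  during <- pmax(0, pmin(day, cfg$treatment_start + cfg$treatment_days) -
                   cfg$treatment_start)
  post <- pmax(0, day - cfg$treatment_start - cfg$treatment_days)
  r <- grow_radius(r0, cfg$growth_rate, 0, pre)
  r <- grow_radius(r, cfg$growth_rate, inhibition, during)
  grow_radius(r, cfg$growth_rate, 0, post)
}
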