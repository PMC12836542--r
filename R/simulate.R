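# Synthetic plate simulator: seeded disk "tumouroids" growing (or not) under
# a Hill dose-response, rendered into defocus-blurred Z-stacks with known
# per-object and per-well ground truth.

# Anti-aliased disk coverage on a pixel window. Coverage of a pixel is
# clamp(r - d + 0.5, 0, 1) with d the distance from the pixel centre, i.e. an
# ~1 px linear edge ramp; a pixel has coverage > 0 iff d < r + 0.5.
.disk_coverage <- function(canvas, cx, cy, r_px) {
  H <- nrow(canvas); W <- ncol(canvas)
  x0 <- max(1L, floor(cx - r_px - 1)); x1 <- min(W, ceiling(cx + r_px + 1))
  y0 <- max(1L, floor(cy - r_px - 1)); y1 <- min(H, ceiling(cy + r_px + 1))
  if (x0 > x1 || y0 > y1) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  cov <- pmin(1, pmax(0, r_px - d + 0.5))
  # union with what is already on the canvas
  canvas[ys, xs] <- 1 - (1 - canvas[ys, xs]) * (1 - cov)
  canvas
}

# Pixel count of the union of anti-aliased disks (any coverage > 0), clipped
# to the frame: what a perfect segmenter recovers from the rendering.
.union_area_px <- function(centers, r_px, dim_hw) {
  mask <- matrix(FALSE, dim_hw[1], dim_hw[2])
  if (nrow(centers) == 0L) return(0L)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; r <- r_px[i]
    x0 <- max(1L, floor(cx - r - 1)); x1 <- min(dim_hw[2], ceiling(cx + r + 1))
    y0 <- max(1L, floor(cy - r - 1)); y1 <- min(dim_hw[1], ceiling(cy + r + 1))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    mask[ys, xs] <- mask[ys, xs] | (d2 < (r + 0.5)^2)
  }
  sum(mask)
}

# Rejection-sample object centres (px) honouring the minimum separation and
# keeping day-0 disks fully inside the frame.
.place_objects <- function(cfg) {
  n <- cfg$n_objects
  if (n == 0L)
    return(data.frame(cx_px = numeric(0), cy_px = numeric(0),
                      z_plane = integer(0), r0_um = numeric(0)))
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  r0 <- runif(n, cfg$radius_range[1], cfg$radius_range[2])
  r0_px <- r0 / cfg$pixel_size
  sep_px <- cfg$min_separation / cfg$pixel_size
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    margin <- r0_px[i] + 1
    if (2 * margin >= min(H, W))
      stop("day-0 objects do not fit the frame; enlarge image_size")
    ok <- FALSE
    for (try in 1:2000) {
      px <- runif(1, margin, W - margin)
      py <- runif(1, margin, H - margin)
      if (i == 1L || all(sqrt((px - cx[seq_len(i - 1)])^2 +
                              (py - cy[seq_len(i - 1)])^2) >= sep_px)) {
        cx[i] <- px; cy[i] <- py; ok <- TRUE; break
      }
    }
    if (!ok) stop("object placement failed: min_separation too large for frame")
  }
  data.frame(cx_px = cx, cy_px = cy,
             z_plane = sample.int(cfg$n_planes, n, replace = TRUE) - 1L,
             r0_um = r0)
}

#' Render one well/day acquisition as a Z-stack
#'
#' Renders every ground-truth object as a dark anti-aliased disk into each
#' Z-plane. An object sitting at plane \code{q} appears in plane \code{p}
#' blurred by an isotropic Gaussian PSF of width
#' \code{|p - q| * plane_spacing * blur_per_um_defocus} px, then additive
#' Gaussian noise (\code{noise_sd}) is applied. Fully reproducible from the
#' seed.
#'
#' @param truth data.frame with one row per object: \code{cx_px},
#'   \code{cy_px}, \code{z_plane} (0-based), \code{radius_um}.
#' @param day imaging day (must belong to \code{config$days}); recorded in
#'   the output.
#' @param config a [sim_config()].
#' @param seed integer seed for the noise; defaults to \code{config$rng_seed}.
#' @param well_id label recorded in the output stack.
#' @return a [zstack()].
#' @export
render_zstack <- function(truth, day, config, seed = config$rng_seed,
                          well_id = "W1") {
  validate_sim_config(config)
  if (!day %in% config$days) stop("day must be one of config$days")
  set.seed(as.integer(seed %% .Machine$integer.max))
  H <- config$image_size[1]; W <- config$image_size[2]
  r_px <- truth$radius_um / config$pixel_size
  planes <- vector("list", config$n_planes)
  zs <- sort(unique(truth$z_plane))
  # union coverage per z-group, computed once, blurred per plane
  cov_by_z <- lapply(zs, function(z) {
    canvas <- matrix(0, H, W)
    for (i in which(truth$z_plane == z))
      canvas <- .disk_coverage(canvas, truth$cx_px[i], truth$cy_px[i], r_px[i])
    canvas
  })
  for (p in seq_len(config$n_planes) - 1L) {
    total <- matrix(0, H, W)
    for (k in seq_along(zs)) {
      sigma <- abs(p - zs[k]) * config$plane_spacing * config$blur_per_um_defocus
      cv <- cov_by_z[[k]]
      if (sigma > 0.05 && any(cv > 0))
        cv <- matrix(pmin(1, pmax(0, EBImage::gblur(cv, sigma = sigma))), H, W)
      total <- 1 - (1 - total) * (1 - cv)
    }
    img <- config$background_level +
      (config$object_level - config$background_level) * total
    if (config$noise_sd > 0)
      img <- img + matrix(rnorm(H * W, 0, config$noise_sd), H, W)
    planes[[p + 1L]] <- matrix(pmin(1, pmax(0, img)), H, W)
  }
  zstack(planes, pixel_size = config$pixel_size,
         plane_spacing = config$plane_spacing, well_id = well_id, day = day)
}

#' Simulate a full drug-screening plate with ground truth
#'
#' Creates one well per (dose, replicate), seeds objects, grows them across
#' the imaging days under Hill dose-dependent inhibition during the treatment
#' window, and (optionally) renders and writes multi-page TIFF Z-stacks. All
#' randomness derives from \code{config$rng_seed}; identical configurations
#' give bit-identical output.
#'
#' @param config a [sim_config()]; \code{config$n_replicates} wells are
#'   created per dose, and wells at dose 0 are flagged as vehicle controls.
#' @param dir if non-NULL, a directory to write \code{\{well_id\}_d\{day\}.tif}
#'   stacks, \code{plate_map.csv}, \code{ground_truth.csv} (per object/day)
#'   and \code{ground_truth_wells.csv} (per well/day true union area).
#' @param render if FALSE, skip image rendering (and TIFF writing) and return
#'   geometry-level ground truth only; much faster for model-level checks.
#' @return (invisibly when writing) a list of class \code{sim_plate}:
#'   \describe{
#'     \item{plate_map}{data.frame: well_id, sample_id, drug,
#'       concentration_nM, replicate, is_vehicle.}
#'     \item{objects}{per object/day ground truth: object_id, well_id, day,
#'       cx_px, cy_px, z_plane, radius_um.}
#'     \item{well_truth}{per well/day: true_total_area_um2, the union-of-disks
#'       pixel area at render resolution.}
#'     \item{stacks}{when rendered and \code{dir} is NULL, a nested list
#'       \code{stacks[[well_id]][[as.character(day)]]} of [zstack()]s.}
#'   }
#' @examples
#' plate <- simulate_plate(sim_config(n_objects = 2, days = c(1, 5),
#'                                    doses = c(0, 10), n_replicates = 1,
#'                                    image_size = c(96, 96)), render = FALSE)
#' plate$plate_map
#' @export
simulate_plate <- function(config, dir = NULL, render = TRUE) {
  validate_sim_config(config)
  set.seed(config$rng_seed)
  doses <- config$doses
  reps <- seq_len(config$n_replicates)
  grid <- expand.grid(replicate = reps, dose_idx = seq_along(doses))
  plate_map <- data.frame(
    well_id = paste0(LETTERS[grid$replicate], grid$dose_idx),
    sample_id = config$sample_id,
    drug = config$drug,
    concentration_nM = doses[grid$dose_idx],
    replicate = grid$replicate,
    is_vehicle = doses[grid$dose_idx] == 0,
    stringsAsFactors = FALSE)

  objects <- NULL
  well_truth <- NULL
  placements <- vector("list", nrow(plate_map))
  for (w in seq_len(nrow(plate_map))) {
    pl <- .place_objects(config)
    placements[[w]] <- pl
    inh <- if (plate_map$concentration_nM[w] > 0)
      inhibition_fraction(plate_map$concentration_nM[w],
                          config$ic50_true, config$hill_true) else 0
    for (day in config$days) {
      r_day <- if (nrow(pl)) radius_on_day(pl$r0_um, day, inh, config) else numeric(0)
      if (nrow(pl))
        objects <- rbind(objects, data.frame(
          object_id = paste0(plate_map$well_id[w], "_", seq_len(nrow(pl))),
          well_id = plate_map$well_id[w], day = day,
          cx_px = pl$cx_px, cy_px = pl$cy_px, z_plane = pl$z_plane,
          radius_um = r_day, stringsAsFactors = FALSE))
      area_px <- .union_area_px(cbind(pl$cx_px, pl$cy_px),
                                r_day / config$pixel_size, config$image_size)
      well_truth <- rbind(well_truth, data.frame(
        well_id = plate_map$well_id[w], day = day,
        concentration_nM = plate_map$concentration_nM[w],
        true_total_area_um2 = area_px * config$pixel_size^2,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(objects))
    objects <- data.frame(object_id = character(0), well_id = character(0),
                          day = numeric(0), cx_px = numeric(0),
                          cy_px = numeric(0), z_plane = integer(0),
                          radius_um = numeric(0))

  stacks <- NULL
  if (render) {
    if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    stacks <- list()
    for (w in seq_len(nrow(plate_map))) {
      wid <- plate_map$well_id[w]
      for (di in seq_along(config$days)) {
        day <- config$days[di]
        tr <- objects[objects$well_id == wid & objects$day == day, , drop = FALSE]
        seed <- (config$rng_seed * 10133L + w * 131L + di) %% .Machine$integer.max
        st <- render_zstack(tr, day, config, seed = seed, well_id = wid)
        if (!is.null(dir)) {
          write_zstack(st, file.path(dir, sprintf("%s_d%g.tif", wid, day)))
        } else {
          if (is.null(stacks[[wid]])) stacks[[wid]] <- list()
          stacks[[wid]][[as.character(day)]] <- st
        }
      }
    }
  }
  out <- structure(list(config = config, plate_map = plate_map,
                        objects = objects, well_truth = well_truth,
                        stacks = stacks, dir = dir), class = "sim_plate")
  if (!is.null(dir)) {
    write.csv(plate_map, file.path(dir, "plate_map.csv"), row.names = FALSE)
    write.csv(objects, file.path(dir, "ground_truth.csv"), row.names = FALSE)
    write.csv(well_truth, file.path(dir, "ground_truth_wells.csv"),
              row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @export
print.sim_plate <- function(x, ...) {
  cat("Simulated plate:", nrow(x$plate_map), "wells,",
      length(x$config$days), "imaging days,",
      length(x$config$doses), "doses\n")
  cat("  sample:", x$config$sample_id, " drug:", x$config$drug,
      " ic50_true:", x$config$ic50_true, "nM\n")
  if (!is.null(x$dir)) cat("  written to:", x$dir, "\n")
  invisible(x)
}
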