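# Shared fixtures: rasterized shapes and small simulator configurations.

# hard-edged (non-anti-aliased) disk mask, for pixel-count oracles
raster_disk <- function(r_px, pad = 5L) {
  n <- 2L * ceiling(r_px) + 2L * pad + 1L
  cx <- (n + 1) / 2
  d2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, "+")
  d2 <= r_px^2
}

# connected random blob grown by a seeded lattice random walk
random_component <- function(n_steps = 60L, size = 41L) {
  m <- matrix(FALSE, size, size)
  pos <- c(ceiling(size / 2), ceiling(size / 2))
  m[pos[1], pos[2]] <- TRUE
  moves <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (s in seq_len(n_steps)) {
    pos <- pos + moves[sample.int(4L, 1L), ]
    pos <- pmin(pmax(pos, 2L), size - 1L)
    m[pos[1], pos[2]] <- TRUE
  }
  m
}

# two-level test image: bright background with one dark anti-aliased disk
aa_disk_image <- function(n = 101L, r_px = 20, bg = 0.8, fg = 0.2,
                          cx = (n + 1) / 2, cy = (n + 1) / 2) {
  d <- sqrt(outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, "+"))
  cov <- pmin(1, pmax(0, r_px - d + 0.5))
  matrix(bg + (fg - bg) * cov, n, n)
}

# small noiseless plate configuration used across segmentation-level tests
tiny_plate_config <- function(...) {
  args <- list(image_size = c(160L, 160L), n_planes = 3L, n_objects = 3L,
               days = c(1, 5, 9), doses = c(0, 10), n_replicates = 1L,
               noise_sd = 0, min_separation = 150, radius_range = c(25, 35),
               rng_seed = 7L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
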