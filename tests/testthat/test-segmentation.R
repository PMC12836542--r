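test_that("background-anchored cutoff separates a two-level image", {
  img <- matrix(0.8, 60, 60)
  img[20:30, 20:30] <- 0.2 # minority object population
  thr <- select_threshold(img, "dark_objects", k = 3)
  expect_true(all(img[img == 0.2] < thr$cutoff))
  expect_true(all(img[img == 0.8] > thr$cutoff))
  expect_equal(thr$background_mode, 0.8, tolerance = 0.01)
  # bright-object polarity mirrors the rule
  thr_b <- select_threshold(1 - img, "bright_objects", k = 3)
  expect_true(all((1 - img)[img == 0.2] > thr_b$cutoff))
})

test_that("constant images are rejected; extreme cutoffs are clamped", {
  expect_error(select_threshold(matrix(0.5, 10, 10)), "constant")
  set.seed(1)
  img <- matrix(rnorm(2500, 0.5, 0.02), 50, 50)
  expect_warning(thr <- select_threshold(img, k = 1000), "clamped")
  expect_true(thr$clamped)
  expect_gte(thr$cutoff, min(img))
})

test_that("classification is invariant under affine intensity rescaling", {
  set.seed(7)
  img <- aa_disk_image() + matrix(rnorm(101 * 101, 0, 0.01), 101, 101)
  for (k in c(1, 2, 3, 5)) {
    m0 <- img < select_threshold(img, k = k)$cutoff
    for (ab in list(c(2, 0.1), c(0.5, -0.2), c(10, 3))) {
      img2 <- ab[1] * img + ab[2]
      m2 <- img2 < select_threshold(img2, k = k)$cutoff
      expect_identical(m2, m0)
    }
  }
})

test_that("pure-noise images yield at most a 1% object fraction at k = 3", {
  set.seed(12)
  for (i in 1:5) {
    img <- matrix(rnorm(200 * 200, 0.7, 0.03), 200, 200)
    thr <- select_threshold(img, k = 3)
    mask <- img < thr$cutoff
    expect_lte(mean(mask), 0.01)
  }
})

test_that("binarize recovers disks, fills holes, and keeps empty masks empty", {
  img <- aa_disk_image(n = 101, r_px = 20)
  thr <- select_threshold(img)
  # threshold applied to an all-background frame of the same image family
  expect_false(any(binarize(matrix(0.8, 50, 50), thr)))

  mask <- binarize(img, thr)
  d <- sqrt(outer((1:101 - 51)^2, (1:101 - 51)^2, "+"))
  truth <- d <= 20
  inter <- sum(mask & truth); uni <- sum(mask | truth)
  expect_gte(inter / uni, 0.95)

  # dark annulus: interior must be filled
  n <- 81; cx <- 41
  d <- sqrt(outer((1:n - cx)^2, (1:n - cx)^2, "+"))
  ring <- matrix(0.8, n, n); ring[d >= 12 & d <= 18] <- 0.2
  rmask <- binarize(ring, select_threshold(ring))
  expect_true(all(rmask[d <= 12]))
})

test_that("labelling is 8-connected, raster-ordered, and filters debris", {
  # two disks separated by background -> two objects
  img <- matrix(0.9, 120, 120)
  d1 <- sqrt(outer((1:120 - 30)^2, (1:120 - 30)^2, "+"))
  d2 <- sqrt(outer((1:120 - 85)^2, (1:120 - 85)^2, "+"))
  img[d1 < 15] <- 0.2; img[d2 < 15] <- 0.2
  mask <- binarize(img, select_threshold(img))
  obj <- label_and_filter(mask, pixel_size = 1, min_area = 0)
  expect_equal(nrow(obj), 2L)
  expect_lt(obj$cy[1], obj$cy[2]) # raster order: top object labelled first

  # overlapping disks merge into one object
  img2 <- matrix(0.9, 120, 120)
  d3 <- sqrt(outer((1:120 - 60)^2, (1:120 - 50)^2, "+"))
  d4 <- sqrt(outer((1:120 - 60)^2, (1:120 - 70)^2, "+"))
  img2[d3 < 15 | d4 < 15] <- 0.2
  obj2 <- label_and_filter(binarize(img2, select_threshold(img2)),
                           pixel_size = 1, min_area = 0)
  expect_equal(nrow(obj2), 1L)

  # diagonal touch counts as connected (8-connectivity)
  m <- matrix(FALSE, 10, 10); m[3, 3] <- TRUE; m[4, 4] <- TRUE
  expect_equal(nrow(label_and_filter(m, 1, min_area = 0)), 1L)

  # a disk below the 40-um-diameter floor is debris
  small <- raster_disk(15.9) # area ~794 um^2 at 1 um/px
  expect_equal(nrow(label_and_filter(small, 1, min_area = pi * 20^2)), 0L)
  expect_equal(nrow(label_and_filter(small, 1, min_area = 0)), 1L)

  # border exclusion
  mb <- matrix(FALSE, 20, 20); mb[1:5, 8:12] <- TRUE
  expect_equal(nrow(label_and_filter(mb, 1, min_area = 0,
                                     exclude_border = TRUE)), 0L)
  expect_equal(nrow(label_and_filter(mb, 1, min_area = 0)), 1L)
})

test_that("morphometrics: disks measure true, lines score low, pixels clamp", {
  disk <- raster_disk(50)
  m <- measure_component(disk, pixel_size = 1)
  expect_equal(m$area_um2, sum(disk))                   # pixel-count oracle
  expect_lt(abs(m$area_um2 - pi * 2500) / (pi * 2500), 0.02)
  expect_lt(abs(m$diameter_um - 100) / 100, 0.01)
  expect_gte(m$circularity, 0.9); expect_lte(m$circularity, 1)
  expect_equal(m$diameter_um, 2 * sqrt(m$area_um2 / pi))

  line <- matrix(FALSE, 14, 20); line[7, 6:15] <- TRUE
  ml <- measure_component(line, pixel_size = 1)
  expect_lt(ml$circularity, 0.5)

  px <- matrix(FALSE, 9, 9); px[5, 5] <- TRUE
  mp <- measure_component(px, pixel_size = 2)
  expect_equal(mp$perimeter_um, 8) # 4 pixel edges at 2 um/px
  expect_equal(mp$circularity, 1)
  expect_equal(mp$area_um2, 4)
  expect_error(measure_component(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("areas are conserved and physical units scale correctly", {
  set.seed(21)
  img <- aa_disk_image(n = 121, r_px = 25) +
    matrix(rnorm(121^2, 0, 0.01), 121, 121)
  mask <- binarize(img, select_threshold(img))
  obj <- label_and_filter(mask, pixel_size = 2, min_area = 0)
  expect_equal(sum(obj$area_um2), sum(mask) * 4) # px count * pixel_size^2
  expect_lte(sum(obj$area_um2), length(mask) * 4)
})

test_that("circularity never exceeds 1 on random components and grows with radius", {
  set.seed(99)
  for (i in 1:300) {
    comp <- random_component(n_steps = sample(10:120, 1))
    m <- measure_component(comp, pixel_size = 1)
    expect_lte(m$circularity, 1)
    expect_gte(m$circularity, 0)
  }
  circ <- vapply(c(5, 10, 20, 40, 80),
                 function(r) measure_component(raster_disk(r), 1)$circularity,
                 numeric(1))
  expect_true(all(diff(circ) >= 0))
  expect_gt(circ[length(circ)], 0.98)
})
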