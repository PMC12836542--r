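test_that("dose ladders are exact geometric sequences", {
  expect_identical(dose_ladder(0.1, 1000, 10), c(0.1, 1, 10, 100, 1000))
  expect_identical(dose_ladder(5, 5, 2), 5)
  expect_identical(dose_ladder(1, 8, 2), c(1, 2, 4, 8))
  expect_error(dose_ladder(1, 10, 3), "nearest valid endpoints")
  expect_error(dose_ladder(0, 10, 2), "min")
  expect_error(dose_ladder(1, 10, 1), "fold")
})

test_that("the 5PL function honours midpoint, asymptotes and closed forms", {
  expect_equal(ll5(10, b = 2, c = 0.2, d = 1, e = 10, f = 1), 0.6)
  expect_equal(ll5(10, b = 1, c = 0, d = 1, e = 10, f = 2), 0.25)
  expect_equal(ll5(1e12, b = 1, c = 0.3, d = 1, e = 10, f = 1), 0.3,
               tolerance = 1e-6)
  expect_equal(ll5(1e-12, b = 1, c = 0.3, d = 1, e = 10, f = 1), 1,
               tolerance = 1e-6)
  # monotone in x for fixed-sign b
  xs <- 10^seq(-2, 4, length.out = 50)
  expect_true(all(diff(ll5(xs, 1.3, 0.1, 1, 15, 2.2)) < 0))
  expect_true(all(diff(ll5(xs, -1.3, 0.1, 1, 15, 2.2)) > 0))
  expect_error(ll5(-1, 1, 0, 1, 10, 1), "doses")
  expect_error(ll5(1, 1, 0, 1, -10, 1), "e must")
  expect_error(ll5(1, 1, 0, 1, 10, 0), "f must")
})

test_that("vehicle normalization divides by the control mean per replicate", {
  wells <- data.frame(
    well_id = c("V1", "V2", "T1", "T2"), sample_id = "S1",
    concentration_nM = c(0, 0, 10, 10), replicate = c(1, 2, 1, 2),
    is_vehicle = c(TRUE, TRUE, FALSE, FALSE), day = 7,
    relative_total_area = c(1.0, 1.0, 0.5, 0.7))
  pts <- normalize_to_control(wells)
  expect_equal(sort(pts$response), c(0.5, 0.7))
  expect_false(any(pts$concentration_nM == 0)) # vehicle is never a point
  wells$relative_total_area[3] <- 1.0
  expect_equal(normalize_to_control(wells)$response[1], 1)
  # missing treated value is skipped, not fatal
  wells$relative_total_area[4] <- NA
  pts2 <- normalize_to_control(wells)
  expect_equal(nrow(pts2), 1L)
  expect_equal(attr(pts2, "skipped"), "T2")
  # no usable vehicle -> error
  wells$relative_total_area[1:2] <- NA
  expect_error(normalize_to_control(wells), "vehicle")
})

test_that("normalized response at the true IC50 matches the growth model", {
  cfg <- sim_config(image_size = c(224L, 224L), n_objects = 3L,
                    days = c(1, 9), doses = c(0, 10), n_replicates = 2L,
                    min_separation = 200, radius_range = c(20, 30),
                    rng_seed = 13L)
  pl <- simulate_plate(cfg, render = FALSE)
  wt <- pl$well_truth
  rel <- do.call(rbind, lapply(split(wt, wt$well_id), function(w) {
    w <- w[order(w$day), ]
    data.frame(well_id = w$well_id[1], concentration_nM = w$concentration_nM[1],
               rel = w$true_total_area_um2[2] / w$true_total_area_um2[1])
  }))
  resp <- mean(rel$rel[rel$concentration_nM == 10]) /
    mean(rel$rel[rel$concentration_nM == 0])
  # at c = ic50, h = 1: inhibition 1/2, area ratio exp(-2 g * t_treat / 2);
  # pixel quantization of the union mask leaves a few percent of slack
  expected <- exp(-cfg$growth_rate * cfg$treatment_days)
  expect_lt(abs(resp / expected - 1), 0.05)
})

test_that("noiseless 5PL points are recovered essentially exactly", {
  x <- rep(dose_ladder(), each = 4)
  y <- ll5(x, b = 1.2, c = 0.1, d = 1.0, e = 15, f = 1.5)
  fit <- fit_ll5(response ~ dose, data.frame(dose = x, response = y))
  cf <- coef(fit)
  expect_true(fit$converged)
  expect_lt(abs(cf["e"] - 15) / 15, 0.10)
  expect_lt(fit$rss, 1e-8)
  expect_equal(unname(cf["c"]), 0.1, tolerance = 1e-3)
  expect_equal(unname(cf["d"]), 1.0, tolerance = 1e-3)
  # fitted curve is monotone over the ladder
  expect_true(all(diff(predict(fit, dose_ladder())) < 0))
})

test_that("seeded noisy points still locate the curve", {
  set.seed(2024)
  x <- rep(dose_ladder(), each = 4)
  y <- ll5(x, 1.2, 0.1, 1.0, 15, 1.5) + rnorm(length(x), 0, 0.05)
  fit <- fit_ll5(response ~ dose, data.frame(dose = x, response = y))
  true_ed50 <- 15 * (2^(1 / 1.5) - 1)^(1 / 1.2)
  expect_gt(coef(fit)["b"], 0)
  expect_lt(abs(ed50(fit) - true_ed50) / true_ed50, 0.25)
})

test_that("fewer than five concentrations fall back to the symmetric 4PL", {
  x <- rep(c(1, 10, 100, 1000), each = 4)
  set.seed(5)
  y <- ll5(x, 1, 0.1, 1, 20, 1) + rnorm(length(x), 0, 0.02)
  fit <- fit_ll5(response ~ dose, data.frame(dose = x, response = y))
  expect_true(fit$four_param)
  expect_equal(unname(coef(fit)["f"]), 1)
})

test_that("degenerate and flat inputs are flagged, not mis-fitted", {
  x <- rep(dose_ladder(), each = 2)
  expect_error(fit_ll5(response ~ dose,
                       data.frame(dose = x, response = rep(1, length(x)))),
               "identical")
  set.seed(9)
  y <- 1 + rnorm(length(x), 0, 0.01) # inactive drug
  fit <- fit_ll5(response ~ dose, data.frame(dose = x, response = y))
  cf <- coef(fit)
  expect_lt(abs(cf["d"] - cf["c"]), 0.2)
  expect_error(fit_ll5(response ~ dose, data.frame(dose = c(0, 1, 10, 100),
                                                   response = c(1, 1, .5, .2))),
               "> 0")
})

test_that("ED50 closed form matches the symmetric case and numeric inversion", {
  expect_equal(ed50(c(b = 1.7, c = 0, d = 1, e = 12, f = 1)), 12)
  expect_equal(ed50(c(b = 1, c = 0, d = 1, e = 10, f = 2)),
               10 * (sqrt(2) - 1))
  set.seed(77)
  for (i in 1:200) {
    cf <- c(b = sample(c(-1, 1), 1) * runif(1, 0.3, 3), c = runif(1, 0, 0.4),
            d = runif(1, 0.6, 1.4), e = 10^runif(1, -1, 3),
            f = runif(1, 0.2, 5))
    target <- (cf["c"] + cf["d"]) / 2
    g <- function(x) ll5(x, cf["b"], cf["c"], cf["d"], cf["e"], cf["f"]) - target
    lo <- cf["e"] * 1e-8; hi <- cf["e"] * 1e8
    for (k in 1:100) {
      mid <- sqrt(lo * hi)
      if (sign(g(mid)) == sign(g(lo))) lo <- mid else hi <- mid
    }
    expect_equal(ed50(cf), unname(sqrt(lo * hi)), tolerance = 1e-9)
  }
  expect_warning(v <- ed50(c(b = 1, c = 0.5, d = 0.5, e = 10, f = 1)), "flat")
  expect_true(is.na(v))
})

test_that("GI50 inverts the model at 50% of control or is undefined", {
  expect_equal(gi50(c(b = 1, c = 0, d = 1, e = 10, f = 1)), 10)
  expect_true(is.na(gi50(c(b = 1, c = 0.6, d = 1.0, e = 10, f = 1))))
  expect_equal(gi50(c(b = 1, c = 0.1, d = 1.1, e = 20, f = 1)), 30)
  # numeric check of the inversion
  cf <- c(b = 1.4, c = 0.05, d = 1.15, e = 33, f = 2.4)
  x50 <- gi50(cf)
  expect_equal(ll5(x50, cf["b"], cf["c"], cf["d"], cf["e"], cf["f"]),
               0.5, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fitted inhibition span grows with treatment duration", {
  cfg <- sim_config()
  doses <- dose_ladder()
  spans <- vapply(c(3, 5, 7, 9), function(day) {
    t_treat <- min(day, cfg$treatment_start + cfg$treatment_days) -
      cfg$treatment_start
    resp <- exp(-2 * cfg$growth_rate *
                  inhibition_fraction(doses, cfg$ic50_true, cfg$hill_true) *
                  t_treat)
    x <- rep(doses, each = 4); y <- rep(resp, each = 4)
    cf <- coef(fit_ll5(response ~ dose, data.frame(dose = x, response = y)))
    unname(cf["d"] - cf["c"])
  }, numeric(1))
  expect_true(all(diff(spans) > -1e-6))
})

test_that("sensitivity ranking orders by each criterion with NAs last", {
  f1 <- structure(list(coefficients = c(b = 1, c = 0.1, d = 1, e = 5, f = 1)),
                  class = "ll5_fit")
  f2 <- structure(list(coefficients = c(b = 1, c = 0.4, d = 1, e = 50, f = 1)),
                  class = "ll5_fit")
  f3 <- structure(list(coefficients = c(b = 1, c = 0.7, d = 1, e = 500, f = 1)),
                  class = "ll5_fit") # never reaches 0.5: GI50 undefined
  r <- rank_sensitivity(list(A = f1, B = f2, C = f3), "max_inhibition")
  expect_equal(r$sample_id, c("A", "B", "C"))
  r2 <- rank_sensitivity(list(B = f2, A = f1, C = f3), "ed50")
  expect_equal(r2$sample_id[1], "A")
  r3 <- rank_sensitivity(list(C = f3, A = f1, B = f2), "gi50")
  expect_equal(r3$sample_id, c("A", "B", "C")) # undefined GI50 ranks last
  expect_true(is.na(r3$gi50[3]))
  expect_error(rank_sensitivity(list(A = f1)), ">= 2")
})

test_that("simulated samples of graded potency are ranked in true order", {
  cfg <- sim_config()
  doses <- dose_ladder()
  t_treat <- cfg$treatment_days
  set.seed(606)
  fits <- lapply(c(S_5 = 5, S_50 = 50, S_500 = 500), function(ic50) {
    resp <- exp(-2 * cfg$growth_rate *
                  inhibition_fraction(doses, ic50, 1) * t_treat)
    x <- rep(doses, each = 4)
    y <- rep(resp, each = 4) * exp(rnorm(length(x), 0, 0.02))
    fit_ll5(response ~ dose, data.frame(dose = x, response = y))
  })
  expect_equal(rank_sensitivity(fits, "ed50")$sample_id,
               c("S_5", "S_50", "S_500"))
  expect_equal(rank_sensitivity(fits, "gi50")$sample_id,
               c("S_5", "S_50", "S_500"))
})
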