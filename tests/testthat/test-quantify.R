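tg <- gm1_species_targets()
axis <- seq(1535, 1585, by = 0.02)

test_that("the apex is found at the predicted m/z within one bin", {
  sp <- gaussian_spectrum(axis, tg$d18$predicted_mz, 5)
  corr <- remove_local_baseline(sp, tg$d18)
  pk <- find_highest_peak(corr, tg$d18)
  expect_true(pk$found)
  expect_lt(abs(pk$mz - tg$d18$predicted_mz), 0.02)
})

test_that("equal maxima equidistant from the prediction pick the lower m/z", {
  target <- species_target("sym", "H2O", predicted_mz = 1545,
                           search_halfwidth = 0.5)
  d <- seq(-1.9, 1.9, by = 0.01)
  sp <- mass_spectrum(1545 + d, exp(-((d^2 - 0.09)^2) / 0.002))
  pk <- find_highest_peak(sp, target)  # equal maxima at 1544.7 and 1545.3
  expect_true(pk$found)
  expect_equal(pk$mz, 1544.7)
})

test_that("an all-zero window reports peak not found", {
  sp <- mass_spectrum(axis, rep(0, length(axis)))
  pk <- find_highest_peak(sp, tg$d18)
  expect_false(pk$found)
  expect_equal(pk$window,
               tg$d18$predicted_mz + c(-1, 1) * tg$d18$search_halfwidth)
})

test_that("an apex below the detection floor reports peak not found", {
  set.seed(8)
  noise_only <- mass_spectrum(axis, abs(rnorm(length(axis), 0, 1)))
  pk <- find_highest_peak(noise_only, tg$d18, floor_k = 10)
  expect_false(pk$found)
})

test_that("AUC matches the closed-form Gaussian area within 1%", {
  A <- 7
  sp <- gaussian_spectrum(axis, tg$d18$predicted_mz, A)
  corr <- remove_local_baseline(sp, tg$d18)
  pk <- find_highest_peak(corr, tg$d18)
  auc <- integrate_auc(corr, pk$mz, tg$d18)
  expect_equal(auc, A, tolerance = 0.01)
  # and the truncation-corrected area to 0.1%
  frac <- pnorm(0.4 / 0.15) - pnorm(-0.4 / 0.15)
  expect_equal(auc, A * frac, tolerance = 1e-3)
})

test_that("AUC is linear and zero on the zero spectrum", {
  sp <- gaussian_spectrum(axis, tg$d18$predicted_mz, 4)
  doubled <- mass_spectrum(sp$mz, sp$intensity * 2)
  a1 <- integrate_auc(sp, tg$d18$predicted_mz, tg$d18)
  a2 <- integrate_auc(doubled, tg$d18$predicted_mz, tg$d18)
  expect_identical(a2, a1 * 2)
  zero <- mass_spectrum(axis, rep(0, length(axis)))
  expect_equal(integrate_auc(zero, tg$d18$predicted_mz, tg$d18), 0)
  expect_error(integrate_auc(sp, max(axis), tg$d18), "exceed")
})

test_that("analytic two-species mixtures recover their amplitude ratio", {
  # closed-form oracle: ratio of highest-peak areas equals amplitude ratio
  for (true_ratio in c(0.5, 2, 6)) {
    sp <- gaussian_spectrum(axis,
                            c(tg$d18$predicted_mz, tg$d20$predicted_mz),
                            c(true_ratio, 1) * 10, baseline = 2)
    r18 <- local({
      c1 <- remove_local_baseline(sp, tg$d18)
      integrate_auc(c1, find_highest_peak(c1, tg$d18)$mz, tg$d18)
    })
    r20 <- local({
      c2 <- remove_local_baseline(sp, tg$d20)
      integrate_auc(c2, find_highest_peak(c2, tg$d20)$mz, tg$d20)
    })
    expect_equal(r18 / r20, true_ratio, tolerance = 0.005)
  }
})

test_that("symmetric noise-free simulation quantifies to ratio 1", {
  cfg <- tiny_config(list(r1 = list(total = 100, ratio = 1)), n_animals = 1,
                     noise_sd = 0, gain_sdlog = 0, animal_cv = 0,
                     baseline = list(constant = 0, slope = 0,
                                     bump_amplitude = 0))
  st <- simulate_study(cfg, build_phantom("single", c(8, 8), labels = "r1"))
  r <- quantify_rois(st$datasets, st$rois)
  # bin-quantization floor of the grid-aligned trapezoid (see vignette)
  expect_equal(r$ratio, rep(1, 4), tolerance = 1e-4)
})

test_that("a missing denominator species flags the record invalid", {
  cfg <- tiny_config(list(r1 = list(total = 100, ratio = 1)), n_animals = 1,
                     noise_sd = 0, gain_sdlog = 0, animal_cv = 0)
  st <- simulate_study(cfg, build_phantom("single", c(8, 8), labels = "r1"))
  ds <- st$datasets[[1]]
  # erase the d20:1 cluster so only d18:1 remains
  kill <- ds$mz > tg$d20$predicted_mz - 2 & ds$mz < tg$d20$predicted_mz + 6
  ds$intensities[, kill] <- 0
  rec <- roi_ratio(ds, st$rois[[1]])
  expect_false(rec$valid)
  expect_match(rec$reason, "peak not found")
  expect_true(is.na(rec$ratio))
})

test_that("ratio is insensitive to the integration half-width", {
  cfg <- tiny_config(list(r1 = list(total = 100, ratio = 3)), n_animals = 1,
                     noise_sd = 0, gain_sdlog = 0, animal_cv = 0)
  st <- simulate_study(cfg, build_phantom("single", c(8, 8), labels = "r1"))
  r <- vapply(c(0.3, 0.45), function(hw) {
    targets <- gm1_species_targets(integration_halfwidth = hw)
    quantify_rois(st$datasets, st$rois[1], targets)$ratio
  }, numeric(1))
  expect_lt(abs(r[2] / r[1] - 1), 0.01)
})

test_that("cortical bands preserve the superficial < deep ordering", {
  ph <- build_phantom("cortex3", c(24, 8))
  for (seed in 1:5) {
    cfg <- sim_config(regions = list(superficial = list(total = 100,
                                                        ratio = 2.55),
                                     intermediate = list(total = 100,
                                                         ratio = 3.3),
                                     deep = list(total = 100, ratio = 4.43)),
                      mz_range = c(1500, 1620), n_animals = 1,
                      sections_per_animal = 1, seed = seed)
    st <- simulate_study(cfg, ph)
    r <- quantify_rois(st$datasets, st$rois)
    m <- tapply(r$ratio, r$region, mean)
    expect_lt(m[["superficial"]], m[["deep"]])
  }
})
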