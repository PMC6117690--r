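test_that("population generation is deterministic and includes wild type", {
  cfg <- small_config(n = 50, seed = 123)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1, p2)
  expect_equal(p1$strain_id[1], "WT")
  expect_true(p1$stable[1])
  expect_equal(p1$true_car[1], 10.3)
  expect_true(all(p1$true_car > 0))
  expect_true(all(p1$true_chl > 0))
  expect_true(all(p1$mu0 >= 0))
})

test_that("zero lethality keeps every strain", {
  pop <- generate_population(small_config(n = 40, lethality = 0, seed = 2))
  expect_equal(nrow(pop), 41)  # 40 mutants + WT
})

test_that("survivorship is binomial thinning", {
  # single draw at the 0.1 M EMS lethality: survivors within 4 binomial SDs
  cfg <- generator_config(n_strains = 1000, lethality = 0.423, seed = 7)
  pop <- generate_population(cfg)
  expect_equal(pop$lineage[1], "WT")
  n_surv <- nrow(pop) - 1
  sd_bin <- sqrt(1000 * 0.423 * 0.577)
  expect_lt(abs(n_surv - 577), 4 * sd_bin)
  # mean over repetitions within 3 standard errors of n * (1 - lethality)
  reps <- vapply(1:200, function(i) {
    nrow(generate_population(generator_config(
      n_strains = 200, lethality = 0.423, seed = 1000 + i))) - 1
  }, numeric(1))
  se <- sqrt(200 * 0.423 * 0.577) / sqrt(200)
  expect_lt(abs(mean(reps) - 200 * 0.577), 3 * se)
})

test_that("mutant carotenoid spread covers the reported dose-group range", {
  # a 0.1 M EMS plate of ~25 survivors ranged 8.8-11.1 mg/g DW around a
  # 10.3 wild type; the generator's effect distribution must reach both
  # sides of that interval in a library-sized draw
  pop <- generate_population(small_config(n = 500, seed = 5))
  mut <- pop[pop$strain_id != "WT", ]
  expect_lt(min(mut$true_car), 8.8)
  expect_gt(max(mut$true_car), 11.1)
  expect_lt(mean(mut$true_car), 10.3)  # most mutations deleterious
})

test_that("molar ratios stay inside the physiological band", {
  pop <- generate_population(small_config(n = 300, seed = 9))
  ratio <- chl_car_molar_ratio(pop$true_chl, pop$true_car)
  expect_true(all(ratio >= 1.27 - 1e-9 & ratio <= 1.42 + 1e-9))
})

test_that("plate reads have the declared shape and determinism", {
  cfg <- small_config(n = 20, seed = 3)
  pop <- generate_population(cfg)
  # at such a small n the noise calibration may warn; irrelevant here
  plate <- suppressWarnings(
    simulate_plate_reads(pop, "exponential", cfg, n_replicates = 3))
  expect_equal(nrow(plate), 3 * nrow(pop))
  expect_equal(unname(table(plate$strain_id)[pop$strain_id]),
               rep(3L, nrow(pop)), ignore_attr = TRUE)
  expect_true(all(plate$phase == "exponential"))
  plate2 <- suppressWarnings(
    simulate_plate_reads(pop, "exponential", cfg, n_replicates = 3))
  expect_identical(plate, plate2)
  expect_error(simulate_plate_reads(pop, "lag", cfg), "arg")
})

test_that("noiseless plate reads refit with R-squared of 1", {
  cfg <- small_config(n = 30, seed = 4, chl_noise_sd = 0, nr_noise_sd = 0,
                      od_noise_sd = 0, molar_ratio_sd = 0,
                      lipid_jitter_sd = 0)
  pop <- generate_population(cfg)
  plate <- simulate_plate_reads(pop, "exponential", cfg)
  fit <- refit_calibration(plate, pop, "chla")
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
  fitn <- refit_calibration(plate, pop, "nilered")
  expect_equal(fitn$r_squared, 1.0, tolerance = 1e-9)
})

test_that("generator realizes its configured calibration per phase", {
  cfg <- small_config(n = 100, seed = 11)
  pop <- generate_population(cfg)
  plate <- simulate_plate_reads(pop, "exponential", cfg, n_replicates = 3)
  fit <- refit_calibration(plate, pop, "chla")
  imp <- implied_calibration(cfg, "exponential", "chla")
  expect_equal(fit$r_squared, imp$r_squared, tolerance = 0.05)
  expect_lt(abs(fit$slope - imp$slope) / imp$slope, 0.05)
  # stationary phase: same structure, weaker correlation (more noise)
  plate_s <- simulate_plate_reads(pop, "stationary", cfg, n_replicates = 3)
  fit_s <- refit_calibration(plate_s, pop, "chla")
  expect_lt(fit_s$r_squared, fit$r_squared)
})

test_that("absorbance inversion round-trips exactly in the noiseless limit", {
  # anchor: Ca = 15.65 with no carotenoids gives the unit-A665 triple
  ab <- simulate_extract_absorbances(15.65, 0)
  expect_equal(ab$a665, 1.0)
  expect_equal(ab$a652, 0.0)
  expect_equal(ab$a470, 2.86 * 15.65 / 1000)
  ab0 <- simulate_extract_absorbances(0, 0)
  expect_equal(unlist(ab0), c(a665 = 0, a652 = 0, a470 = 0))
  set.seed(7)
  for (i in 1:20) {
    ca <- runif(1, 0, 30); xc <- runif(1, 0, 15)
    frac <- runif(1, 0, 1)
    ab <- simulate_extract_absorbances(ca, xc, a652_frac = frac)
    ca_back <- chlorophyll_a_content(ab$a665, ab$a652)
    xc_back <- total_carotenoid_content(ab$a470, ca_back)
    expect_equal(ca_back, ca, tolerance = 1e-9)
    expect_equal(xc_back, xc, tolerance = 1e-9)
  }
  expect_error(simulate_extract_absorbances(-1, 0), ">= 0")
})

test_that("simulated extract tables quantify back to the latent contents", {
  cfg <- small_config(n = 15, seed = 8)
  pop <- generate_population(cfg)
  extracts <- simulate_extracts(pop, cfg, noise_sd = 0, extract_ml = 2,
                                biomass_mg = 3, dilution = 2)
  prof <- pigment_profile(extracts)
  expect_equal(prof$xcar_per_dw, pop$true_car, tolerance = 1e-9)
  expect_equal(prof$ca_per_dw, pop$true_chl, tolerance = 1e-9)
})

test_that("DPA dose response follows the calibrated anchors", {
  expect_equal(dpa_growth_rate(0.645, 0), 0.645)
  expect_equal(dpa_growth_rate(0.645, 10), 0.431)
  expect_equal(dpa_growth_rate(0.645, 40), 0)
  expect_lt(dpa_growth_rate(0.645, 50), 0)
  # monotone non-increasing in dose
  doses <- seq(0, 60, by = 5)
  expect_true(all(diff(dpa_growth_rate(0.645, doses)) <= 0))
  expect_error(dpa_growth_rate(0.645, -1), ">= 0")
})

test_that("growth curves are log-linear without noise and seeded with it", {
  cv <- simulate_growth_curve(0.645, 0, t_grid = 0:4, noise_sd = 0)
  expect_equal(diff(log(cv$od625)), rep(0.645, 4))
  # decline above the zero-growth dose: strictly decreasing OD
  cv50 <- simulate_growth_curve(0.645, 50, t_grid = 0:4, noise_sd = 0)
  expect_true(all(diff(cv50$od625) < 0))
  a <- simulate_growth_curve(0.5, 20, noise_sd = 0.05, seed = 31)
  b <- simulate_growth_curve(0.5, 20, noise_sd = 0.05, seed = 31)
  expect_identical(a, b)
  expect_error(simulate_growth_curve(0.5, 0, t_grid = numeric(0)),
               "non-empty")
})

test_that("stability series keeps stable strains within 10% and reverts unstable ones", {
  cfg <- small_config(n = 200, seed = 21)
  pop <- generate_population(cfg)
  ser <- simulate_stability_series(pop, n_batches = 16, config = cfg)
  rel <- abs(ser$final_car - ser$initial_car) / ser$initial_car
  expect_true(all(rel[ser$stable] < 0.10))
  # unstable strains decay toward the wild-type content
  uns <- ser[!ser$stable & ser$initial_car > 11, ]
  expect_true(all(abs(uns$final_car - cfg$wt_car) <
                    abs(uns$initial_car - cfg$wt_car)))
  # an unstable strain seeded at 13.3 lands near the 10.3 wild type
  hi <- pop[1, ]; hi$true_car <- 13.3; hi$stable <- FALSE
  one <- simulate_stability_series(hi, n_batches = 16, config = cfg)
  expect_lt(abs(one$final_car - cfg$wt_car) / cfg$wt_car, 0.10)
  # degenerate settings: one batch, zero decay = identity
  none <- simulate_stability_series(hi, n_batches = 1, config = cfg,
                                    decay = 0)
  expect_equal(none$final_car, none$initial_car)
  expect_error(simulate_stability_series(pop, n_batches = 0, config = cfg),
               ">= 1")
})

test_that("generator configuration is validated", {
  expect_error(generator_config(lethality = 1.2), "lethality")
  expect_error(generator_config(n_strains = 0), "n_strains")
  expect_error(generator_config(car_sd = -1), "SD")
  expect_error(generator_config(unstable_frac = 2), "unstable_frac")
  expect_error(generator_config(chl_car_r2 = c(exponential = 1.5,
                                               stationary = 0.5)),
               "R-squared")
})
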