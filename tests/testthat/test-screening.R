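test_that("colony selection equals a brute-force double-quantile filter", {
  set.seed(17)
  colonies <- data.frame(
    strain_id = sprintf("M%03d", 1:200),
    size = rlnorm(200), color_intensity = rlnorm(200))
  kept <- colony_select(colonies, 0.8, 0.8)
  qs <- quantile(colonies$size, 0.8, names = FALSE)
  qc <- quantile(colonies$color_intensity, 0.8, names = FALSE)
  oracle <- sort(colonies$strain_id[colonies$size >= qs &
                                      colonies$color_intensity >= qc])
  expect_identical(kept$strain_id, oracle)
})

test_that("colony selection boundary quantiles behave as set operations", {
  colonies <- data.frame(strain_id = c("A", "B", "C"), size = c(1, 1, 1),
                         color_intensity = c(1, 1, 1))
  expect_equal(nrow(colony_select(colonies, 0, 0)), 3)
  # identical scores: everyone is the maximum
  expect_equal(nrow(colony_select(colonies, 1, 1)), 3)
  distinct <- data.frame(strain_id = c("A", "B", "C"), size = 1:3,
                         color_intensity = 3:1)
  # only joint maxima survive quantile 1; no colony is max in both here
  expect_equal(nrow(colony_select(distinct, 1, 1)), 0)
  expect_error(colony_select(distinct[0, ]), "empty")
})

test_that("fluorescence filter evaluates both threshold lines on means", {
  plate <- data.frame(
    strain_id = rep(c("pass", "fail_chl", "boundary"), each = 1),
    od625 = 0.10,
    rfu_chla = c(250, 200, 2309 * 0.10 - 24.3),
    rfu_nilered = c(20, 20, 167.1 * 0.10 - 0.21))
  res <- fluorescence_filter(plate)
  res <- res[match(c("pass", "fail_chl", "boundary"), res$strain_id), ]
  expect_equal(res$chl_threshold, rep(206.6, 3))
  expect_equal(res$nr_threshold, rep(16.5, 3), tolerance = 1e-12)
  expect_true(res$pass[1])
  expect_false(res$pass[2])
  expect_false(res$pass_chl[2])
  expect_true(res$pass_nr[2])  # fails only on the chlorophyll rule
  # inclusive boundary: equality passes
  expect_true(res$pass[3])
  expect_equal(res$chl_margin[3], 0)
})

test_that("fluorescence filter averages replicates before thresholding", {
  # replicate means pass even though one replicate alone would fail
  plate <- data.frame(
    strain_id = "S", od625 = c(0.10, 0.10, 0.10),
    rfu_chla = c(150, 250, 250), rfu_nilered = c(30, 30, 30))
  res <- fluorescence_filter(plate)
  expect_true(res$pass)  # mean 216.67 >= 206.6
})

test_that("fluorescence filter applies the NA and bad-OD policy", {
  plate <- data.frame(
    strain_id = c("S", "S", "S", "T"),
    od625 = c(0.1, 0.1, -1, 0.1),
    rfu_chla = c(250, NA, 250, 100), rfu_nilered = c(20, 20, 20, 5))
  expect_warning(expect_warning(res <- fluorescence_filter(plate),
                                "non-positive OD"), "NA fluorescence")
  expect_equal(res$mean_rfu_chla[res$strain_id == "S"], 250)
  expect_false(res$pass[res$strain_id == "T"])
  expect_error(fluorescence_filter(plate[, -3]), "rfu_chla")
})

test_that("fluorescence filter is monotone in either channel", {
  set.seed(23)
  for (i in 1:30) {
    od <- runif(1, 0.05, 0.5)
    chl <- runif(1, 0, 2 * (2309 * od))
    nr <- runif(1, 0, 2 * (167.1 * od))
    base <- data.frame(strain_id = "S", od625 = od, rfu_chla = chl,
                       rfu_nilered = nr)
    up <- base
    up$rfu_chla <- up$rfu_chla + runif(1, 0, 500)
    up$rfu_nilered <- up$rfu_nilered + runif(1, 0, 50)
    if (fluorescence_filter(base)$pass) {
      expect_true(fluorescence_filter(up)$pass)
    }
  }
})

test_that("carotenoid filter applies the 15%-over-WT rule inclusively", {
  profiles <- data.frame(
    strain_id = c("WT", "just_in", "just_out", "same"),
    xcar_per_dw = c(10.3, 11.9, 11.8, 10.3))
  pos <- carotenoid_filter(profiles)
  expect_equal(attr(pos, "threshold"), 10.3 * 1.15)
  expect_identical(pos$strain_id, "just_in")
  # raising the bar never enlarges the positive set
  for (pct in c(15, 20, 30, 50)) {
    p <- carotenoid_filter(profiles, min_increase_pct = pct)
    expect_true(all(p$strain_id %in% pos$strain_id))
  }
  expect_error(carotenoid_filter(profiles[-1, ]), "missing")
})

test_that("stability assessment flags the reverting mutant", {
  one <- stability_assess(13.3, 10.2, wt_car = 10.3)
  expect_equal(one$status, "unstable")
  expect_true(one$reverted)
  expect_equal(stability_assess(10.0, 10.5)$status, "stable")
  expect_equal(stability_assess(12, 12)$status, "stable")
  # any change strictly below 10% is stable, at/above is not
  for (d in c(-0.099, -0.05, 0, 0.05, 0.099)) {
    expect_equal(stability_assess(10, 10 * (1 + d))$status, "stable")
  }
  for (d in c(-0.2, -0.1, 0.1, 0.2)) {
    expect_equal(stability_assess(10, 10 * (1 + d))$status, "unstable")
  }
  expect_error(stability_assess(0, 1), "> 0")
})

test_that("full screen nests survivors and traces every exclusion", {
  cfg <- small_config(n = 300, seed = 31)
  pop <- generate_population(cfg)
  colonies <- simulate_colonies(pop, cfg)
  plate <- simulate_plate_reads(pop, "exponential", cfg)
  profiles <- pigment_profile(simulate_extracts(pop, cfg))
  stab <- simulate_stability_series(pop, config = cfg)
  rep <- run_screen(pop, colonies, plate, profiles, stab)
  # survivor sets nested, counts equal cardinalities
  surv <- rep$survivors
  expect_true(all(surv$fluorescence %in% surv$colony))
  expect_true(all(surv$carotenoid %in% surv$fluorescence))
  expect_true(all(surv$stability %in% surv$carotenoid))
  expect_equal(rep$stages$n_out,
               vapply(surv, length, integer(1)), ignore_attr = TRUE)
  expect_true(all(diff(rep$stages$n_out) <= 0))
  # every non-selected candidate carries the stage that excluded it
  excluded <- setdiff(pop$strain_id, c("WT", rep$selected))
  tr <- rep$trace
  expect_true(all(!is.na(tr$excluded_at[tr$strain_id %in% excluded])))
  expect_true(all(is.na(tr$excluded_at[tr$strain_id %in% rep$selected])))
})

test_that("screen stage 2 equals brute-force threshold evaluation", {
  cfg <- small_config(n = 350, seed = 37)
  pop <- generate_population(cfg)
  plate <- simulate_plate_reads(pop, "exponential", cfg)
  profiles <- pigment_profile(simulate_extracts(pop, cfg))
  rep <- run_screen(pop, colonies = NULL, plate, profiles)
  oracle <- brute_force_fluorescence(plate[plate$strain_id != "WT", ])
  expect_identical(sort(rep$survivors$fluorescence), oracle)
})

test_that("planted true positives survive every stage", {
  cfg <- small_config(n = 200, seed = 41)
  pop <- generate_population(cfg)
  planted <- sprintf("TP%02d", 1:5)
  extra <- pop[rep(1, 5), ]
  extra$strain_id <- planted
  extra$lineage <- "EMS_0.1M"
  extra$stable <- TRUE
  pop2 <- rbind(pop, extra)
  colonies <- simulate_colonies(pop2, cfg)
  plate <- simulate_plate_reads(pop2, "exponential", cfg)
  profiles <- pigment_profile(simulate_extracts(pop2, cfg))
  stab <- data.frame(strain_id = pop2$strain_id,
                     initial_car = pop2$true_car,
                     final_car = pop2$true_car)
  # construct the positives strictly above every threshold
  hit <- colonies$strain_id %in% planted
  colonies$size[hit] <- max(colonies$size) * 2
  colonies$color_intensity[hit] <- max(colonies$color_intensity) * 2
  hitp <- plate$strain_id %in% planted
  plate$rfu_chla[hitp] <- (2309 * plate$od625[hitp] - 24.3) * 2 + 100
  plate$rfu_nilered[hitp] <- (167.1 * plate$od625[hitp] - 0.21) * 2 + 100
  wt_x <- profiles$xcar_per_dw[profiles$strain_id == "WT"]
  profiles$xcar_per_dw[profiles$strain_id %in% planted] <- wt_x * 1.5
  stab$initial_car[stab$strain_id %in% planted] <- wt_x * 1.5
  stab$final_car[stab$strain_id %in% planted] <- wt_x * 1.5
  rep <- run_screen(pop2, colonies, plate, profiles, stab)
  expect_true(all(planted %in% rep$selected))
})

test_that("screen validates ids and handles the empty population", {
  cfg <- small_config(n = 10, seed = 43)
  pop <- generate_population(cfg)
  plate <- simulate_plate_reads(pop, "exponential", cfg)
  profiles <- pigment_profile(simulate_extracts(pop, cfg))
  expect_error(run_screen(pop, NULL, plate[plate$strain_id != "M0003", ],
                          profiles), "M0003")
  empty <- run_screen(pop[pop$strain_id == "WT", ], NULL, plate, profiles)
  expect_s3_class(empty, "screening_report")
  expect_equal(length(empty$selected), 0)
  expect_equal(nrow(empty$stages), 0)
})
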