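# Seeded synthetic-data generator for the screening pipeline: mutant
# populations with latent pigment/lipid/growth parameters, plate-reader
# wells, extract absorbances, growth curves under DPA, colony scores and
# long-term stability trajectories. All stochastic structure is calibrated
# against the quantities a real screening campaign reports (wild-type
# carotenoid level, per-dose lethality, fluorescence-vs-carotenoid
# coefficients of determination per growth phase, DPA dose anchors).

#' Configuration for the synthetic screening-campaign generator
#'
#' Collects every latent parameter of the generator with defaults that
#' emulate an EMS-mutagenized *Phaeodactylum tricornutum* library:
#' wild-type total carotenoids of 10.3 mg/g DW, mutant effects drawn from a
#' truncated normal centred slightly below wild type (most mutations are
#' deleterious) whose spread reproduces the 8.8-11.1 mg/g range seen in a
#' 0.1 M EMS dose group of ~25 strains, 42.3% lethality at that dose, a
#' chlorophyll-a-fluorescence-versus-carotenoid coefficient of
#' determination of 0.8687 in exponential phase (0.6356 for the Nile red
#' channel), and a wild-type specific growth rate of 0.645 day^-1.
#'
#' @param n_strains Number of mutagenized strains plated (before lethality).
#' @param lethality Fraction of strains killed by the mutagen dose (0-1).
#' @param lineage Label for the mutagen/dose group, e.g. `"EMS_0.1M"`.
#' @param wt_car Wild-type total carotenoid content, mg/g DW.
#' @param car_mean_shift Mean shift of mutant carotenoid content relative to
#'   wild type, mg/g DW (negative: most mutations lower the content).
#' @param car_sd Standard deviation of mutant carotenoid content, mg/g DW.
#' @param molar_ratio_mean,molar_ratio_sd,molar_ratio_band Chlorophyll a :
#'   carotenoid molar ratio across strains: mean, per-strain jitter SD, and
#'   hard clamp band.
#' @param mw_chl,mw_car Molar masses (g/mol) used to convert the molar ratio
#'   into a chlorophyll mass content.
#' @param wt_lipid Wild-type neutral-lipid index (arbitrary units).
#' @param lipid_jitter_sd Log-normal SD of the lipid index around its
#'   carotenoid-proportional mean.
#' @param mu0_wt Wild-type specific growth rate, day^-1.
#' @param mu0_sd SD of mutant intrinsic growth rates, day^-1.
#' @param dpa_anchor_doses,dpa_anchor_fracs Doses (uM) and growth-rate
#'   fractions defining the piecewise-linear DPA dose response; the final
#'   segment is extrapolated beyond the last anchor so growth turns into
#'   decline above it.
#' @param unstable_frac Fraction of mutants whose phenotype reverts over
#'   repeated batches (diploid reversion).
#' @param stability_decay Per-batch fractional decay of an unstable mutant's
#'   carotenoid excess toward wild type.
#' @param stability_jitter SD of the total log-drift of a stable strain's
#'   content over a full stability series (clamped so stable strains always
#'   change < 10%).
#' @param k_chl,k_nr Plate-reader gains: RFU per (mg/L chlorophyll a in the
#'   well) and RFU per (lipid-index unit x g DW/L). Chosen so the screening
#'   threshold lines sit below the wild-type operating point at the default
#'   exponential-phase OD — the screen must pass above-average strains.
#' @param od_dw_coeff Dry weight per OD625 unit, g/L.
#' @param od_exponential,od_stationary Typical well OD625 per growth phase.
#' @param od_noise_sd Log-normal SD of per-well OD noise.
#' @param chl_car_r2,nr_car_r2 Named vectors (`exponential`, `stationary`)
#'   of target coefficients of determination for strain-mean fluorescence
#'   versus carotenoid content; the generator back-computes the replicate
#'   noise SD needed to realize them (the phase effect is purely a larger
#'   noise SD in stationary phase).
#' @param chl_noise_sd,nr_noise_sd Optional explicit per-replicate RFU noise
#'   SDs; when non-`NULL` they override the R-squared calibration (use 0 for
#'   noiseless wells).
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_strains = 1000,
                             lethality = 0.423,
                             lineage = "EMS_0.1M",
                             wt_car = 10.3,
                             car_mean_shift = -0.35,
                             car_sd = 0.6,
                             molar_ratio_mean = 1.35,
                             molar_ratio_sd = 0.02,
                             molar_ratio_band = c(1.27, 1.42),
                             mw_chl = 893.5,
                             mw_car = 658.9,
                             wt_lipid = 1.0,
                             lipid_jitter_sd = 0.04,
                             mu0_wt = 0.645,
                             mu0_sd = 0.05,
                             dpa_anchor_doses = c(0, 10, 40),
                             dpa_anchor_fracs = c(1, 0.431 / 0.645, 0),
                             unstable_frac = 0.2,
                             stability_decay = 0.15,
                             stability_jitter = 0.03,
                             k_chl = 440,
                             k_nr = 670,
                             od_dw_coeff = 0.3,
                             od_exponential = 0.15,
                             od_stationary = 0.9,
                             od_noise_sd = 0.02,
                             chl_car_r2 = c(exponential = 0.8687,
                                            stationary = 0.50),
                             nr_car_r2 = c(exponential = 0.6356,
                                           stationary = 0.25),
                             chl_noise_sd = NULL,
                             nr_noise_sd = NULL,
                             seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (!is.numeric(n_strains) || n_strains < 1) {
      stop("n_strains must be >= 1", call. = FALSE)
    }
    if (lethality < 0 || lethality > 1) {
      stop("lethality must be in [0, 1]", call. = FALSE)
    }
    sds <- c(car_sd, molar_ratio_sd, lipid_jitter_sd, mu0_sd, od_noise_sd,
             stability_jitter)
    if (any(sds < 0)) stop("noise SDs must be >= 0", call. = FALSE)
    if (wt_car <= 0 || wt_lipid <= 0) {
      stop("wild-type contents must be > 0", call. = FALSE)
    }
    if (length(dpa_anchor_doses) != length(dpa_anchor_fracs) ||
        length(dpa_anchor_doses) < 2 || any(diff(dpa_anchor_doses) <= 0) ||
        any(diff(dpa_anchor_fracs) > 0)) {
      stop("DPA anchors must be increasing doses with non-increasing ",
           "growth fractions", call. = FALSE)
    }
    if (unstable_frac < 0 || unstable_frac > 1) {
      stop("unstable_frac must be in [0, 1]", call. = FALSE)
    }
    for (r2 in list(chl_car_r2, nr_car_r2)) {
      if (!all(c("exponential", "stationary") %in% names(r2)) ||
          any(r2 <= 0) || any(r2 > 1)) {
        stop("R-squared targets must be named (exponential, stationary) ",
             "values in (0, 1]", call. = FALSE)
      }
    }
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
      stop("seed must be a single finite number", call. = FALSE)
    }
    invisible(TRUE)
  })
}

# one-sided truncated normal via rejection (support x >= lower)
rtruncnorm_lower <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

#' Generate a mutagenized strain population
#'
#' Draws `n_strains` mutants, thins them by binomial survival at the
#' configured lethality, and prepends the wild-type reference strain. Each
#' survivor carries latent true values: total carotenoids (truncated normal
#' centred `car_mean_shift` below wild type), chlorophyll a (via a tightly
#' banded chlorophyll:carotenoid molar ratio), a neutral-lipid index
#' (proportional to carotenoids with log-normal jitter), an intrinsic growth
#' rate, and a stability flag (`unstable_frac` of mutants revert).
#'
#' @param config A [generator_config()].
#' @return Data frame of class `strain_population` with columns `strain_id`,
#'   `lineage`, `true_car`, `true_chl`, `true_lipid`, `mu0`, `stable`. The
#'   wild type (`strain_id == "WT"`) is always the first row and always
#'   stable.
#' @export
generate_population <- function(config = generator_config()) {
  validate_generator_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_strains
    survived <- stats::rbinom(n, 1, 1 - config$lethality) == 1
    n_surv <- sum(survived)
    true_car <- rtruncnorm_lower(n_surv,
                                 config$wt_car + config$car_mean_shift,
                                 config$car_sd, lower = 0.5)
    ratio <- stats::rnorm(n_surv, config$molar_ratio_mean,
                          config$molar_ratio_sd)
    ratio <- pmin(pmax(ratio, config$molar_ratio_band[1]),
                  config$molar_ratio_band[2])
    true_chl <- ratio * true_car * config$mw_chl / config$mw_car
    true_lipid <- config$wt_lipid * (true_car / config$wt_car) *
      exp(stats::rnorm(n_surv, 0, config$lipid_jitter_sd))
    mu0 <- rtruncnorm_lower(n_surv, config$mu0_wt, config$mu0_sd,
                            lower = 0.01)
    stable <- stats::runif(n_surv) >= config$unstable_frac
    ids <- sprintf("M%04d", which(survived))
    wt <- data.frame(
      strain_id = "WT", lineage = "WT",
      true_car = config$wt_car,
      true_chl = config$molar_ratio_mean * config$wt_car *
        config$mw_chl / config$mw_car,
      true_lipid = config$wt_lipid,
      mu0 = config$mu0_wt, stable = TRUE,
      stringsAsFactors = FALSE)
    mut <- data.frame(
      strain_id = ids, lineage = config$lineage,
      true_car = true_car, true_chl = true_chl, true_lipid = true_lipid,
      mu0 = mu0, stable = stable, stringsAsFactors = FALSE)
    pop <- rbind(wt, mut)
    rownames(pop) <- NULL
    class(pop) <- c("strain_population", "data.frame")
    pop
  })
}

# per-replicate RFU noise SD that realizes a target strain-mean R^2, given
# the deterministic per-strain mean signal m, the regressor x, residual
# variance already present in m, and the OD-jitter contribution
calibrate_noise_sd <- function(m, x, r2_target, od_noise_sd, n_replicates) {
  if (length(m) < 3 || stats::var(x) == 0) return(0)
  fit <- stats::lm.fit(cbind(1, x), m)
  var_expl <- stats::var(m - fit$residuals)
  var_res0 <- stats::var(fit$residuals)
  var_od <- mean(m^2) * (exp(od_noise_sd^2) - 1) / n_replicates
  var_res_target <- var_expl * (1 / r2_target - 1)
  extra <- var_res_target - var_res0 - var_od
  if (extra < 0) {
    warning("strain-level scatter already exceeds the residual variance ",
            "implied by the target R-squared; realized R-squared will be ",
            "lower than configured", call. = FALSE)
    return(0)
  }
  sqrt(extra * n_replicates)
}

#' Simulate plate-reader wells for a strain population
#'
#' Generates one row per strain per replicate with OD625 (log-normal noise
#' around the phase-typical OD), chlorophyll-a fluorescence (RFU,
#' proportional to chlorophyll concentration in the well) and Nile red
#' fluorescence (RFU, proportional to neutral lipid x biomass), plus
#' additive Gaussian instrument noise. Unless an explicit noise SD is set in
#' the config, the noise is calibrated at generation time so that an
#' ordinary-least-squares refit of strain-mean RFU against true carotenoid
#' content recovers the configured coefficient of determination for the
#' requested phase; stationary phase differs from exponential purely by a
#' larger calibrated noise SD.
#'
#' @param strains A `strain_population` from [generate_population()].
#' @param phase `"exponential"` or `"stationary"`.
#' @param config The [generator_config()] used to create `strains`.
#' @param n_replicates Wells per strain (>= 1); screening campaigns
#'   conventionally use 3.
#' @return Data frame with columns `strain_id`, `well`, `replicate`,
#'   `phase`, `od625`, `rfu_chla`, `rfu_nilered`.
#' @export
simulate_plate_reads <- function(strains, phase = c("exponential",
                                                    "stationary"),
                                 config = generator_config(),
                                 n_replicates = 3) {
  phase <- match.arg(phase)
  stopifnot(is.data.frame(strains),
            all(c("strain_id", "true_car", "true_chl", "true_lipid") %in%
                  names(strains)))
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  od_base <- switch(phase, exponential = config$od_exponential,
                    stationary = config$od_stationary)
  n <- nrow(strains)
  m_chl <- config$k_chl * strains$true_chl * od_base * config$od_dw_coeff
  m_nr <- config$k_nr * strains$true_lipid * od_base * config$od_dw_coeff
  sd_chl <- if (!is.null(config$chl_noise_sd)) config$chl_noise_sd else
    calibrate_noise_sd(m_chl, strains$true_car, config$chl_car_r2[[phase]],
                       config$od_noise_sd, n_replicates)
  sd_nr <- if (!is.null(config$nr_noise_sd)) config$nr_noise_sd else
    calibrate_noise_sd(m_nr, strains$true_car, config$nr_car_r2[[phase]],
                       config$od_noise_sd, n_replicates)
  seed_offset <- switch(phase, exponential = 1L, stationary = 2L)
  withr::with_seed(config$seed + seed_offset, {
    idx <- rep(seq_len(n), each = n_replicates)
    od <- od_base * exp(stats::rnorm(n * n_replicates, 0,
                                     config$od_noise_sd))
    dw <- od * config$od_dw_coeff
    rfu_chla <- config$k_chl * strains$true_chl[idx] * dw +
      stats::rnorm(n * n_replicates, 0, sd_chl)
    rfu_nr <- config$k_nr * strains$true_lipid[idx] * dw +
      stats::rnorm(n * n_replicates, 0, sd_nr)
    data.frame(
      strain_id = strains$strain_id[idx],
      well = sprintf("W%05d", seq_len(n * n_replicates)),
      replicate = rep(seq_len(n_replicates), times = n),
      phase = phase,
      od625 = od,
      rfu_chla = rfu_chla,
      rfu_nilered = rfu_nr,
      stringsAsFactors = FALSE)
  })
}

#' Refit the fluorescence-versus-carotenoid calibration from plate data
#'
#' Averages replicates per strain, joins the strain carotenoid contents and
#' fits `mean RFU ~ carotenoid` by ordinary least squares. Used to check
#' that the generator realizes its configured calibration, and applicable
#' unchanged to real plate tables joined with measured pigment profiles.
#'
#' @param plate Plate table as from [simulate_plate_reads()].
#' @param car_content Data frame with `strain_id` and a carotenoid content
#'   column (`true_car` or `xcar_per_dw`).
#' @param channel `"chla"` or `"nilered"`.
#' @return List with `slope`, `intercept`, `r_squared`, `n_strains`.
#' @export
refit_calibration <- function(plate, car_content,
                              channel = c("chla", "nilered")) {
  channel <- match.arg(channel)
  col <- paste0("rfu_", channel)
  if (!col %in% names(plate)) stop("plate table lacks ", col, call. = FALSE)
  car_col <- intersect(c("true_car", "xcar_per_dw"), names(car_content))[1]
  if (is.na(car_col)) {
    stop("car_content needs a true_car or xcar_per_dw column", call. = FALSE)
  }
  mean_rfu <- tapply(plate[[col]], plate$strain_id, mean, na.rm = TRUE)
  df <- data.frame(strain_id = names(mean_rfu), rfu = as.numeric(mean_rfu),
                   stringsAsFactors = FALSE)
  df <- merge(df, car_content[, c("strain_id", car_col)], by = "strain_id")
  fit <- stats::lm.fit(cbind(1, df[[car_col]]), df$rfu)
  rss <- sum(fit$residuals^2)
  tss <- sum((df$rfu - mean(df$rfu))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       n_strains = nrow(df))
}

#' Calibration implied by a generator configuration
#'
#' The expected slope/intercept of strain-mean RFU versus carotenoid content
#' and the target coefficient of determination, as implied by the config's
#' gains and typical OD — the reference values a refit should recover.
#'
#' @inheritParams simulate_plate_reads
#' @param channel `"chla"` or `"nilered"`.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
implied_calibration <- function(config = generator_config(),
                                phase = c("exponential", "stationary"),
                                channel = c("chla", "nilered")) {
  phase <- match.arg(phase)
  channel <- match.arg(channel)
  od_base <- switch(phase, exponential = config$od_exponential,
                    stationary = config$od_stationary)
  slope <- switch(channel,
    chla = config$k_chl * od_base * config$od_dw_coeff *
      config$molar_ratio_mean * config$mw_chl / config$mw_car,
    nilered = config$k_nr * od_base * config$od_dw_coeff *
      config$wt_lipid / config$wt_car)
  r2 <- switch(channel, chla = config$chl_car_r2[[phase]],
               nilered = config$nr_car_r2[[phase]])
  list(slope = slope, intercept = 0, r_squared = r2)
}

#' Invert the pigment equations to synthetic extract absorbances
#'
#' Given chlorophyll a and total carotenoid concentrations (mg/L of
#' extract), produces an (A665, A652, A470) triple that the quantification
#' equations map back to those concentrations exactly in the noiseless
#' limit. Because the chlorophyll equation mixes two absorbances, A652 is
#' pinned to a configurable fraction of A665 (default 0) to make the
#' inverse unique.
#'
#' @param ca_mg_l,xcar_mg_l Pigment concentrations, mg/L of extract (>= 0).
#' @param noise_sd Additive Gaussian absorbance noise SD (0 = exact).
#' @param a652_frac A652 as a fraction of A665 (in `[0, 15.65/7.34)`).
#' @return Data frame with columns `a665`, `a652`, `a470`.
#' @export
simulate_extract_absorbances <- function(ca_mg_l, xcar_mg_l, noise_sd = 0,
                                         a652_frac = 0) {
  stopifnot(is.numeric(ca_mg_l), is.numeric(xcar_mg_l))
  if (any(ca_mg_l < 0) || any(xcar_mg_l < 0)) {
    stop("pigment concentrations must be >= 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (a652_frac < 0 || a652_frac >= 15.65 / 7.34) {
    stop("a652_frac must be in [0, 15.65/7.34)", call. = FALSE)
  }
  a665 <- ca_mg_l / (15.65 - 7.34 * a652_frac)
  a652 <- a652_frac * a665
  a470 <- (221 * xcar_mg_l + 2.86 * ca_mg_l) / 1000
  n <- length(a665)
  if (noise_sd > 0) {
    a665 <- a665 + stats::rnorm(n, 0, noise_sd)
    a652 <- a652 + stats::rnorm(n, 0, noise_sd)
    a470 <- a470 + stats::rnorm(n, 0, noise_sd)
  }
  data.frame(a665 = a665, a652 = a652, a470 = a470)
}

#' Simulate a full extract-absorbance table for a population
#'
#' Converts each strain's true per-dry-weight pigment contents into extract
#' concentrations for the given extraction geometry, then inverts the
#' quantification equations via [simulate_extract_absorbances()].
#'
#' @inheritParams simulate_plate_reads
#' @param noise_sd Additive absorbance noise SD.
#' @param extract_ml,biomass_mg,dilution Extraction geometry (recycled).
#' @return Data frame with columns `strain_id`, `a665`, `a652`, `a470`,
#'   `extract_ml`, `biomass_mg`, `dilution` — the schema read by
#'   [read_extract_csv()] and [pigment_profile()].
#' @export
simulate_extracts <- function(strains, config = generator_config(),
                              noise_sd = 0, extract_ml = 1, biomass_mg = 1,
                              dilution = 1) {
  stopifnot(all(c("strain_id", "true_car", "true_chl") %in% names(strains)))
  ca_conc <- strains$true_chl * biomass_mg / (extract_ml * dilution)
  xc_conc <- strains$true_car * biomass_mg / (extract_ml * dilution)
  abs_tab <- withr::with_seed(config$seed + 3L,
    simulate_extract_absorbances(ca_conc, xc_conc, noise_sd = noise_sd))
  data.frame(strain_id = strains$strain_id, abs_tab,
             extract_ml = extract_ml, biomass_mg = biomass_mg,
             dilution = dilution, stringsAsFactors = FALSE)
}

#' Specific growth rate under a diphenylamine dose
#'
#' Piecewise-linear dose response through the configured anchors, scaled by
#' the strain's intrinsic rate `mu0`. With the default anchors, a wild-type
#' rate of 0.645 day^-1 drops to 0.431 day^-1 at 10 uM, reaches zero at
#' 40 uM, and the last segment is extrapolated beyond the final anchor, so
#' the culture declines (mu < 0) for doses above it.
#'
#' @param mu0 Intrinsic (dose-0) specific growth rate, day^-1.
#' @param dose_uM DPA dose, uM (>= 0).
#' @param anchor_doses,anchor_fracs Dose-response anchors (see
#'   [generator_config()]).
#' @return Specific growth rate at the dose, day^-1.
#' @export
dpa_growth_rate <- function(mu0, dose_uM,
                            anchor_doses = c(0, 10, 40),
                            anchor_fracs = c(1, 0.431 / 0.645, 0)) {
  if (any(dose_uM < 0)) stop("dose must be >= 0", call. = FALSE)
  k <- length(anchor_doses)
  frac <- stats::approx(anchor_doses, anchor_fracs, xout = pmin(dose_uM,
                        anchor_doses[k]), method = "linear")$y
  over <- dose_uM > anchor_doses[k]
  if (any(over)) {
    last_slope <- (anchor_fracs[k] - anchor_fracs[k - 1]) /
      (anchor_doses[k] - anchor_doses[k - 1])
    frac[over] <- anchor_fracs[k] + last_slope *
      (dose_uM[over] - anchor_doses[k])
  }
  mu0 * frac
}

#' Simulate an optical-density growth curve under DPA
#'
#' Exponential growth `OD(t) = OD0 * exp(mu(dose) * t)` with multiplicative
#' log-normal noise (keeping OD positive); `mu(dose)` follows
#' [dpa_growth_rate()].
#'
#' @param mu0 Intrinsic specific growth rate, day^-1.
#' @param dpa_dose_uM DPA dose, uM.
#' @param t_grid Increasing vector of times, days.
#' @param noise_sd Log-scale noise SD (0 = exact exponential).
#' @param seed Integer seed.
#' @param od0 Seeding density (OD625), default 0.06.
#' @param anchor_doses,anchor_fracs Dose-response anchors.
#' @return Data frame with columns `time_days`, `od625`, `dpa_uM`.
#' @export
simulate_growth_curve <- function(mu0, dpa_dose_uM = 0,
                                  t_grid = seq(0, 4, by = 0.5),
                                  noise_sd = 0, seed = 1L, od0 = 0.06,
                                  anchor_doses = c(0, 10, 40),
                                  anchor_fracs = c(1, 0.431 / 0.645, 0)) {
  if (length(t_grid) == 0) stop("t_grid must be non-empty", call. = FALSE)
  if (any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  mu <- dpa_growth_rate(mu0, dpa_dose_uM, anchor_doses, anchor_fracs)
  withr::with_seed(seed, {
    eps <- if (noise_sd > 0) exp(stats::rnorm(length(t_grid), 0, noise_sd))
           else rep(1, length(t_grid))
    data.frame(time_days = t_grid,
               od625 = od0 * exp(mu * t_grid) * eps,
               dpa_uM = dpa_dose_uM)
  })
}

#' Simulate colony size/color scores for the first screening stage
#'
#' Colony size grows with the strain's intrinsic growth rate over the plate
#' incubation; color intensity tracks chlorophyll content. Both carry
#' log-normal scatter.
#'
#' @inheritParams simulate_plate_reads
#' @param incubation_days Days on the agar plate.
#' @return Data frame with columns `strain_id`, `size`, `color_intensity`.
#' @export
simulate_colonies <- function(strains, config = generator_config(),
                              incubation_days = 15) {
  stopifnot(all(c("strain_id", "mu0", "true_chl") %in% names(strains)))
  wt_chl <- config$molar_ratio_mean * config$wt_car *
    config$mw_chl / config$mw_car
  withr::with_seed(config$seed + 4L, {
    n <- nrow(strains)
    size <- exp((strains$mu0 - config$mu0_wt) * incubation_days +
                  stats::rnorm(n, 0, 0.2))
    color <- (strains$true_chl / wt_chl) * exp(stats::rnorm(n, 0, 0.1))
    data.frame(strain_id = strains$strain_id, size = size,
               color_intensity = color, stringsAsFactors = FALSE)
  })
}

#' Simulate carotenoid stability over repeated batch cultivation
#'
#' Emulates a two-month repeated-batch series (~16 generations): stable
#' strains drift by a clamped log-normal amount that always stays below a
#' 10% total change; unstable strains decay geometrically toward the
#' wild-type content (the diploid-reversion phenotype), by a fraction
#' `stability_decay` of their remaining excess per batch.
#'
#' @inheritParams simulate_plate_reads
#' @param n_batches Number of reseeding batches (>= 1), default 16.
#' @param decay Per-batch decay of the excess over wild type for unstable
#'   strains (default from `config$stability_decay`).
#' @return Data frame with columns `strain_id`, `stable`, `initial_car`,
#'   `final_car`.
#' @export
simulate_stability_series <- function(strains, n_batches = 16,
                                      config = generator_config(),
                                      decay = config$stability_decay) {
  stopifnot(all(c("strain_id", "true_car", "stable") %in% names(strains)))
  if (n_batches < 1) stop("n_batches must be >= 1", call. = FALSE)
  if (decay < 0 || decay > 1) stop("decay must be in [0, 1]", call. = FALSE)
  withr::with_seed(config$seed + 5L, {
    n <- nrow(strains)
    initial <- strains$true_car
    # stable strains: total log drift clamped strictly inside +/-10%
    drift <- stats::rnorm(n, 0, config$stability_jitter)
    clamp <- log(1.09)
    drift <- pmin(pmax(drift, -clamp), clamp)
    final_stable <- initial * exp(drift)
    # unstable strains: geometric reversion of the excess toward wild type
    final_unstable <- config$wt_car +
      (initial - config$wt_car) * (1 - decay)^n_batches
    final <- ifelse(strains$stable, final_stable, final_unstable)
    data.frame(strain_id = strains$strain_id, stable = strains$stable,
               initial_car = initial, final_car = final,
               stringsAsFactors = FALSE)
  })
}
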