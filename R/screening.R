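# Three-stage high-throughput screen for carotenoid-hyperproducing mutants:
# (1) colony size/color selection, (2) fluorescence thresholds on
# chlorophyll-a and Nile red channels against OD625, (3) extract-based
# carotenoid gain over wild type; followed by a long-term stability check.
# Every exclusion is traced to the stage and rule that caused it.

#' Screening configuration
#'
#' Thresholds and rule parameters for [run_screen()] and the individual
#' stage functions. The fluorescence threshold lines are
#' `RFU_chla >= 2309 * OD625 - 24.3` and
#' `RFU_nr >= 167.1 * OD625 - 0.21`, evaluated on replicate means with
#' inclusive boundaries; both must hold (the stricter AND combination — the
#' decision trace records each rule separately so an OR re-analysis stays
#' possible).
#'
#' @param size_quantile,color_quantile Colony-stage quantile cutoffs: keep
#'   colonies at or above both quantiles (defaults keep the top 20% in each
#'   score).
#' @param chl_slope,chl_intercept Chlorophyll-a threshold line (RFU vs OD).
#' @param nr_slope,nr_intercept Nile red threshold line (RFU vs OD).
#' @param min_increase_pct Minimum percent carotenoid gain over wild type in
#'   stage 3.
#' @param stability_tolerance_pct Maximum percent change that still counts
#'   as stable over repeated batch cultivation.
#' @param wt_id Strain id of the wild-type reference in the profile table.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(size_quantile = 0.8, color_quantile = 0.8,
                          chl_slope = 2309, chl_intercept = -24.3,
                          nr_slope = 167.1, nr_intercept = -0.21,
                          min_increase_pct = 15,
                          stability_tolerance_pct = 10,
                          wt_id = "WT") {
  cfg <- as.list(environment())
  if (any(c(size_quantile, color_quantile) < 0) ||
      any(c(size_quantile, color_quantile) > 1)) {
    stop("quantiles must be in [0, 1]", call. = FALSE)
  }
  if (min_increase_pct < 0) stop("min_increase_pct must be >= 0",
                                 call. = FALSE)
  if (stability_tolerance_pct <= 0) {
    stop("stability_tolerance_pct must be > 0", call. = FALSE)
  }
  class(cfg) <- "screen_config"
  cfg
}

#' Stage 1: colony selection by size and color
#'
#' Keeps colonies whose size and color intensity both lie at or above the
#' configured sample quantiles — a reproducible stand-in for picking the
#' largest, most deeply colored colonies off an agar plate. Output is
#' ordered by `strain_id` for deterministic downstream behaviour.
#'
#' @param colonies Data frame with columns `strain_id`, `size`,
#'   `color_intensity`.
#' @param size_quantile,color_quantile Quantile cutoffs in `[0, 1]`.
#' @return Data frame of surviving colonies with attached attribute
#'   `thresholds` (the two quantile values used).
#' @export
colony_select <- function(colonies, size_quantile = 0.8,
                          color_quantile = 0.8) {
  stopifnot(is.data.frame(colonies))
  if (nrow(colonies) == 0) stop("empty colony table", call. = FALSE)
  req <- c("strain_id", "size", "color_intensity")
  if (!all(req %in% names(colonies))) {
    stop("colony table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  qs <- stats::quantile(colonies$size, size_quantile, names = FALSE)
  qc <- stats::quantile(colonies$color_intensity, color_quantile,
                        names = FALSE)
  keep <- colonies$size >= qs & colonies$color_intensity >= qc
  out <- colonies[keep, , drop = FALSE]
  out <- out[order(out$strain_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(size = qs, color = qc)
  out
}

#' Stage 2: fluorescence-threshold filter on plate wells
#'
#' Averages the replicates of each strain (OD625 and both fluorescence
#' channels), then applies the two threshold lines: a strain passes iff
#' `mean RFU_chla >= chl_slope * mean OD625 + chl_intercept` AND
#' `mean RFU_nr >= nr_slope * mean OD625 + nr_intercept` (inclusive at the
#' boundary). Rows with missing or non-positive OD are dropped with a
#' warning; missing fluorescence cells are excluded from that channel's
#' mean with a warning (strains are screened on the replicates available,
#' not silently discarded).
#'
#' @param plate Plate table with columns `strain_id`, `od625`, `rfu_chla`,
#'   `rfu_nilered`.
#' @param config A [screen_config()].
#' @return Data frame with one row per strain: replicate means, the two
#'   threshold values, the two margins (`mean RFU - threshold`), per-rule
#'   pass flags `pass_chl`, `pass_nr`, and the combined `pass`.
#' @export
fluorescence_filter <- function(plate, config = screen_config()) {
  stopifnot(is.data.frame(plate))
  req <- c("strain_id", "od625", "rfu_chla", "rfu_nilered")
  miss <- setdiff(req, names(plate))
  if (length(miss)) {
    stop("plate table lacks channel column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_od <- !is.finite(plate$od625) | plate$od625 <= 0
  if (any(bad_od)) {
    warning(sum(bad_od), " well(s) with missing or non-positive OD625 ",
            "rejected", call. = FALSE)
    plate <- plate[!bad_od, , drop = FALSE]
  }
  if (nrow(plate) == 0) stop("no usable wells after OD filtering",
                             call. = FALSE)
  if (anyNA(plate$rfu_chla) || anyNA(plate$rfu_nilered)) {
    warning("NA fluorescence cells excluded from replicate means",
            call. = FALSE)
  }
  agg <- function(v) tapply(v, plate$strain_id, mean, na.rm = TRUE)
  mean_od <- agg(plate$od625)
  mean_chl <- agg(plate$rfu_chla)
  mean_nr <- agg(plate$rfu_nilered)
  thr_chl <- config$chl_slope * mean_od + config$chl_intercept
  thr_nr <- config$nr_slope * mean_od + config$nr_intercept
  out <- data.frame(
    strain_id = names(mean_od),
    mean_od625 = as.numeric(mean_od),
    mean_rfu_chla = as.numeric(mean_chl),
    mean_rfu_nilered = as.numeric(mean_nr),
    chl_threshold = as.numeric(thr_chl),
    nr_threshold = as.numeric(thr_nr),
    chl_margin = as.numeric(mean_chl - thr_chl),
    nr_margin = as.numeric(mean_nr - thr_nr),
    stringsAsFactors = FALSE)
  out$pass_chl <- out$mean_rfu_chla >= out$chl_threshold
  out$pass_nr <- out$mean_rfu_nilered >= out$nr_threshold
  out$pass <- out$pass_chl & out$pass_nr
  out <- out[order(out$strain_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stage 3: carotenoid-gain filter against the wild type
#'
#' Keeps strains whose per-dry-weight total carotenoid content is at least
#' `min_increase_pct` percent above the wild-type profile (inclusive).
#'
#' @param profiles Pigment profile table (see [pigment_profile()]) with
#'   columns `strain_id` and `xcar_per_dw`.
#' @param wt_id Strain id of the wild-type row in `profiles` (its row is the
#'   reference and is never itself selected).
#' @param min_increase_pct Minimum percent gain over wild type.
#' @return Data frame of profile rows for selected strains, with attribute
#'   `threshold` (the absolute content cutoff, mg/g DW) and `wt_xcar`.
#' @export
carotenoid_filter <- function(profiles, wt_id = "WT",
                              min_increase_pct = 15) {
  stopifnot(is.data.frame(profiles),
            all(c("strain_id", "xcar_per_dw") %in% names(profiles)))
  wt_row <- profiles[profiles$strain_id == wt_id, , drop = FALSE]
  if (nrow(wt_row) != 1) {
    stop("wild-type reference '", wt_id,
         "' missing (or duplicated) in profile table", call. = FALSE)
  }
  wt_xcar <- wt_row$xcar_per_dw
  if (!is.finite(wt_xcar) || wt_xcar <= 0) {
    stop("wild-type carotenoid content must be > 0", call. = FALSE)
  }
  threshold <- wt_xcar * (1 + min_increase_pct / 100)
  keep <- profiles$strain_id != wt_id & profiles$xcar_per_dw >= threshold
  out <- profiles[keep, , drop = FALSE]
  out <- out[order(out$strain_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "wt_xcar") <- wt_xcar
  out
}

#' Stability assessment over repeated batch cultivation
#'
#' A strain is `stable` when its carotenoid content changed by less than
#' `tolerance_pct` percent between the initial and final measurement of the
#' repeated-batch series (strict inequality). The `reverted` flag marks
#' strains whose final content is within `tolerance_pct` of the wild-type
#' level — the signature of a diploid mutant losing its phenotype.
#'
#' @param initial_car,final_car Carotenoid contents, mg/g DW (initial > 0).
#' @param tolerance_pct Percent-change tolerance (default 10).
#' @param wt_car Wild-type content used for the reversion flag (optional;
#'   `NA` disables the flag).
#' @return Data frame with columns `initial_car`, `final_car`,
#'   `change_pct`, `status` (`"stable"`/`"unstable"`), `reverted`.
#' @examples
#' stability_assess(13.3, 10.2, wt_car = 10.3)  # unstable, reverted
#' @export
stability_assess <- function(initial_car, final_car, tolerance_pct = 10,
                             wt_car = NA_real_) {
  stopifnot(is.numeric(initial_car), is.numeric(final_car))
  if (any(!is.finite(initial_car)) || any(initial_car <= 0)) {
    stop("initial carotenoid content must be > 0", call. = FALSE)
  }
  if (tolerance_pct <= 0) stop("tolerance_pct must be > 0", call. = FALSE)
  change_pct <- 100 * abs(final_car - initial_car) / initial_car
  status <- ifelse(change_pct < tolerance_pct, "stable", "unstable")
  reverted <- if (all(is.na(wt_car))) rep(NA, length(change_pct)) else
    100 * abs(final_car - wt_car) / wt_car < tolerance_pct
  data.frame(initial_car = initial_car, final_car = final_car,
             change_pct = change_pct, status = status,
             reverted = reverted, stringsAsFactors = FALSE)
}

#' Run the full three-stage screen with stability follow-up
#'
#' Composes [colony_select()], [fluorescence_filter()] and
#' [carotenoid_filter()] over tables keyed by `strain_id`, then (when a
#' stability series is supplied) applies [stability_assess()] to the stage-3
#' positives. Survivor sets are nested by construction; the per-strain
#' decision trace records, for every strain entering the screen, the last
#' stage reached and the rule that excluded it.
#'
#' @param population Data frame with at least `strain_id` (e.g. a
#'   [generate_population()] output). Defines the screened universe; the
#'   wild type is carried through fluorescence/extract stages as reference
#'   but is not a selectable candidate.
#' @param colonies Colony score table for stage 1, or `NULL` to start at
#'   stage 2 with the whole population.
#' @param plates Plate-reader table for stage 2 (all screened strains must
#'   be present).
#' @param profiles Pigment profile table for stage 3 (must contain the
#'   wild-type row).
#' @param stability Optional data frame with `strain_id`, `initial_car`,
#'   `final_car` for the stability follow-up.
#' @param config A [screen_config()].
#' @param wt_car Wild-type carotenoid content for the reversion flag;
#'   defaults to the wild-type profile row.
#' @return An object of class `screening_report`: a list with `stages`
#'   (counts in/out per stage), `survivors` (strain-id vector per stage),
#'   `trace` (per-strain decision table), `fluorescence` (the stage-2 margin
#'   table), `stability` (assessment table or `NULL`) and `selected` (final
#'   strain ids).
#' @export
run_screen <- function(population, colonies = NULL, plates, profiles,
                       stability = NULL, config = screen_config(),
                       wt_car = NULL) {
  stopifnot(is.data.frame(population), "strain_id" %in% names(population))
  candidates <- setdiff(population$strain_id, config$wt_id)
  check_ids <- function(tab, what, required) {
    orphans <- setdiff(required, tab$strain_id)
    if (length(orphans)) {
      stop("strain ids missing from ", what, " table: ",
           paste(utils::head(orphans, 10), collapse = ", "),
           if (length(orphans) > 10) sprintf(" (and %d more)",
                                             length(orphans) - 10) else "",
           call. = FALSE)
    }
  }
  if (length(candidates) == 0) {
    rep0 <- structure(list(
      stages = data.frame(stage = character(), n_in = integer(),
                          n_out = integer()),
      survivors = list(), trace = data.frame(strain_id = character(),
                                             excluded_at = character()),
      fluorescence = NULL, stability = NULL, selected = character()),
      class = "screening_report")
    return(rep0)
  }

  trace <- data.frame(strain_id = sort(candidates),
                      excluded_at = NA_character_,
                      stringsAsFactors = FALSE)
  mark <- function(ids, stage_rule) {
    i <- trace$strain_id %in% ids & is.na(trace$excluded_at)
    trace$excluded_at[i] <<- stage_rule
    invisible(NULL)
  }
  stages <- list()
  survivors <- list()

  # stage 1: colony selection
  if (!is.null(colonies)) {
    check_ids(colonies, "colony", candidates)
    col_cand <- colonies[colonies$strain_id %in% candidates, , drop = FALSE]
    kept <- colony_select(col_cand, config$size_quantile,
                          config$color_quantile)
    s1 <- kept$strain_id
    mark(setdiff(candidates, s1), "stage1:colony")
  } else {
    s1 <- sort(candidates)
  }
  stages$colony <- c(n_in = length(candidates), n_out = length(s1))
  survivors$colony <- s1

  # stage 2: fluorescence thresholds on replicate means
  check_ids(plates, "plate", s1)
  plate_s1 <- plates[plates$strain_id %in% s1, , drop = FALSE]
  fluo <- fluorescence_filter(plate_s1, config)
  s2 <- fluo$strain_id[fluo$pass]
  s2 <- intersect(s1, s2)
  fail_chl <- fluo$strain_id[!fluo$pass_chl]
  fail_nr <- fluo$strain_id[fluo$pass_chl & !fluo$pass_nr]
  mark(intersect(s1, fail_chl), "stage2:chlorophyll_rule")
  mark(intersect(s1, fail_nr), "stage2:nile_red_rule")
  mark(setdiff(s1, c(s2, fail_chl, fail_nr)), "stage2:no_usable_wells")
  stages$fluorescence <- c(n_in = length(s1), n_out = length(s2))
  survivors$fluorescence <- s2

  # stage 3: carotenoid gain over wild type
  check_ids(profiles, "profile", c(s2, config$wt_id))
  prof_s2 <- profiles[profiles$strain_id %in% c(s2, config$wt_id), ,
                      drop = FALSE]
  pos <- carotenoid_filter(prof_s2, config$wt_id, config$min_increase_pct)
  s3 <- intersect(s2, pos$strain_id)
  mark(setdiff(s2, s3), "stage3:carotenoid_gain")
  stages$carotenoid <- c(n_in = length(s2), n_out = length(s3))
  survivors$carotenoid <- s3

  # stability follow-up on the selected positives
  stab_tab <- NULL
  if (!is.null(stability) && length(s3)) {
    check_ids(stability, "stability", s3)
    st <- stability[match(s3, stability$strain_id), , drop = FALSE]
    if (is.null(wt_car)) {
      wt_car <- profiles$xcar_per_dw[profiles$strain_id == config$wt_id]
    }
    ass <- stability_assess(st$initial_car, st$final_car,
                            config$stability_tolerance_pct, wt_car)
    stab_tab <- cbind(data.frame(strain_id = s3, stringsAsFactors = FALSE),
                      ass)
    s4 <- s3[ass$status == "stable"]
    mark(setdiff(s3, s4), "stability:reversion")
  } else {
    s4 <- s3
  }
  stages$stability <- c(n_in = length(s3), n_out = length(s4))
  survivors$stability <- s4

  stage_df <- data.frame(
    stage = names(stages),
    n_in = vapply(stages, `[[`, integer(1), "n_in"),
    n_out = vapply(stages, `[[`, integer(1), "n_out"),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(stages = stage_df, survivors = survivors, trace = trace,
                 fluorescence = fluo, stability = stab_tab,
                 selected = sort(s4)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Mutant screening report\n")
  if (nrow(x$stages) == 0) {
    cat("  (empty population)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-13s %5d -> %5d\n", x$stages$stage[i],
                x$stages$n_in[i], x$stages$n_out[i]))
  }
  cat("  selected:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
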