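# Growth-rate estimation, mutagen lethality and DPA dose-response summaries.

#' Specific growth rate from an optical-density time series
#'
#' Ordinary least-squares slope of `ln(OD625)` versus time over the
#' exponential window, in day^-1. The default window keeps the points whose
#' OD is at most half the series maximum (a simple exponential-phase
#' heuristic); if fewer than two points satisfy it (e.g. a flat series), all
#' points are used. An explicit `window` of time bounds overrides the
#' heuristic.
#'
#' @param curve Data frame with numeric columns `time_days` (strictly
#'   increasing) and `od625` (> 0).
#' @param window Optional numeric length-2 vector `c(t_min, t_max)` in days;
#'   only points with `t_min <= t <= t_max` are fitted.
#' @param half_max_fraction Fraction of the series maximum OD below which
#'   points are considered exponential by the default heuristic.
#' @return Specific growth rate mu, day^-1 (negative when the culture
#'   declines).
#' @examples
#' t <- 0:4
#' specific_growth_rate(data.frame(time_days = t, od625 = 0.06 * exp(0.645 * t)))
#' @export
specific_growth_rate <- function(curve, window = NULL,
                                 half_max_fraction = 0.5) {
  stopifnot(is.data.frame(curve),
            all(c("time_days", "od625") %in% names(curve)))
  t <- curve$time_days
  od <- curve$od625
  if (length(t) < 2) stop("need at least two time points", call. = FALSE)
  if (any(diff(t) <= 0)) stop("time_days must be strictly increasing",
                              call. = FALSE)
  if (any(!is.finite(od)) || any(od <= 0)) {
    stop("od625 must be positive and finite (log fit)", call. = FALSE)
  }
  if (is.null(window)) {
    keep <- od <= half_max_fraction * max(od)
    if (sum(keep) < 2) keep <- rep(TRUE, length(od))
  } else {
    stopifnot(is.numeric(window), length(window) == 2)
    keep <- t >= window[1] & t <= window[2]
    if (sum(keep) < 2) {
      stop("fewer than two points in the requested window", call. = FALSE)
    }
  }
  fit <- stats::lm.fit(cbind(1, t[keep]), log(od[keep]))
  unname(fit$coefficients[2])
}

#' Mutagen lethality from survivor counts
#'
#' Percentage of cells/colonies killed by a treatment relative to an
#' untreated control plated identically:
#' `100 * (1 - treated_survivors / control_survivors)`.
#'
#' @param treated_survivors Count of survivors after treatment (>= 0).
#' @param control_survivors Count of survivors in the untreated control (> 0).
#' @return Lethality in percent (can be negative if the treated plate
#'   outgrew the control).
#' @examples
#' lethality(577, 1000)  # 42.3
#' @export
lethality <- function(treated_survivors, control_survivors) {
  stopifnot(is.numeric(treated_survivors), is.numeric(control_survivors))
  if (any(treated_survivors < 0)) {
    stop("survivor counts must be >= 0", call. = FALSE)
  }
  if (any(control_survivors <= 0)) {
    stop("control survivor count must be > 0", call. = FALSE)
  }
  100 * (1 - treated_survivors / control_survivors)
}

#' DPA dose-response table from growth curves
#'
#' Estimates the specific growth rate for each diphenylamine (DPA) dose via
#' [specific_growth_rate()] and classifies each dose as `"grows"` (mu >= 0)
#' or `"declines"` (mu < 0). The attribute `max_growing_dose` records the
#' largest tested dose at which the culture still grows — the basis for
#' choosing a working concentration that maximizes selective pressure
#' without killing the wild type.
#'
#' @param curves A list of growth-curve data frames, each with columns
#'   `time_days`, `od625` and a single `dpa_uM` value (column or attribute);
#'   alternatively one long data frame with a `dpa_uM` column.
#' @param ... Passed to [specific_growth_rate()].
#' @return Data frame with columns `dpa_uM`, `mu`, `classification`, ordered
#'   by dose, with attribute `max_growing_dose`.
#' @export
dpa_dose_response <- function(curves, ...) {
  if (is.data.frame(curves)) {
    if (is.null(curves$dpa_uM)) {
      stop("long-format growth table needs a dpa_uM column", call. = FALSE)
    }
    curves <- split(curves, curves$dpa_uM)
  }
  if (length(curves) == 0) stop("no growth curves supplied", call. = FALSE)
  rows <- lapply(curves, function(cv) {
    dose <- unique(cv$dpa_uM)
    if (length(dose) != 1) {
      stop("each curve must carry exactly one dpa_uM dose", call. = FALSE)
    }
    data.frame(dpa_uM = dose, mu = specific_growth_rate(cv, ...))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dpa_uM), , drop = FALSE]
  rownames(out) <- NULL
  out$classification <- ifelse(out$mu < 0, "declines", "grows")
  growing <- out$dpa_uM[out$mu >= 0]
  attr(out, "max_growing_dose") <- if (length(growing)) max(growing) else NA_real_
  out
}
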