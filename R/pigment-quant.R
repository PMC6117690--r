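# Spectrophotometric pigment arithmetic for methanol extracts of diatom
# biomass: chlorophyll a and total carotenoids from A665/A652/A470, biomass
# normalization, molar ratios and percent-versus-reference summaries.

#' Chlorophyll a concentration from extract absorbances
#'
#' Computes chlorophyll a concentration in a 100% methanol extract from the
#' blank-subtracted optical absorbances at 665 nm and 652 nm using the
#' standard two-wavelength equation
#' \deqn{C_a = 15.65 \, A_{665} - 7.34 \, A_{652}.}
#'
#' Output units are mg/L of extract, as conventional for these published
#' coefficients. Negative results (possible for unphysical inputs, e.g. a
#' blank-subtraction error) are returned as-is with a warning rather than
#' clamped, so calibration problems stay visible.
#'
#' @param a665,a652 Numeric vectors of blank-subtracted absorbances at
#'   665 nm and 652 nm. Recycled to a common length.
#' @return Numeric vector of chlorophyll a concentrations (mg/L extract).
#' @seealso [total_carotenoid_content()], [pigment_profile()]
#' @examples
#' chlorophyll_a_content(1.0, 0.0)   # 15.65
#' chlorophyll_a_content(0.5, 0.5)   # 0.5 * (15.65 - 7.34)
#' @export
chlorophyll_a_content <- function(a665, a652) {
  stopifnot(is.numeric(a665), is.numeric(a652))
  if (!all(is.finite(a665)) || !all(is.finite(a652))) {
    stop("absorbances must be finite", call. = FALSE)
  }
  ca <- 15.65 * a665 - 7.34 * a652
  if (any(ca < 0)) {
    warning("negative chlorophyll a concentration computed; ",
            "check blank subtraction", call. = FALSE)
  }
  ca
}

#' Total carotenoid concentration from extract absorbances
#'
#' Computes total carotenoid concentration in a methanol extract from the
#' absorbance at 470 nm and the chlorophyll a concentration (typically from
#' [chlorophyll_a_content()]):
#' \deqn{X_{car} = \frac{1000 \, A_{470} - 2.86 \, C_a}{221}.}
#'
#' @param a470 Numeric vector of blank-subtracted absorbance at 470 nm.
#' @param ca Numeric vector of chlorophyll a concentrations (mg/L extract).
#' @return Numeric vector of total carotenoid concentrations (mg/L extract).
#'   Negative values are returned with a warning, not clamped.
#' @examples
#' total_carotenoid_content(0.221, 0)          # 1.0
#' ca <- chlorophyll_a_content(1.0, 0.0)
#' total_carotenoid_content(1.0, ca)
#' @export
total_carotenoid_content <- function(a470, ca) {
  stopifnot(is.numeric(a470), is.numeric(ca))
  if (!all(is.finite(a470)) || !all(is.finite(ca))) {
    stop("inputs must be finite", call. = FALSE)
  }
  xcar <- (1000 * a470 - 2.86 * ca) / 221
  if (any(xcar < 0)) {
    warning("negative carotenoid concentration computed; ",
            "check blank subtraction", call. = FALSE)
  }
  xcar
}

#' Convert extract concentration to content per gram dry weight
#'
#' Plumbing from the equation output (mg pigment per litre of extract) to
#' biomass-specific content: `conc * volume * dilution / biomass` with
#' mg/L * mL / mg = mg/g.
#'
#' @param conc_mg_l Pigment concentration in the (diluted) extract, mg/L.
#' @param extract_volume_ml Extract volume, mL.
#' @param biomass_dw_mg Extracted biomass dry weight, mg. Must be > 0.
#' @param dilution Dilution factor applied before reading (>= 1 typically).
#' @return Pigment content in mg per g dry weight.
#' @examples
#' per_dw_content(10.3, 1, 1)   # 10.3 mg/g DW
#' @export
per_dw_content <- function(conc_mg_l, extract_volume_ml, biomass_dw_mg,
                           dilution = 1) {
  stopifnot(is.numeric(conc_mg_l), is.numeric(extract_volume_ml),
            is.numeric(biomass_dw_mg), is.numeric(dilution))
  if (any(!is.finite(biomass_dw_mg)) || any(biomass_dw_mg <= 0)) {
    stop("biomass_dw_mg must be positive", call. = FALSE)
  }
  if (any(extract_volume_ml < 0) || any(dilution <= 0)) {
    stop("extract volume must be >= 0 and dilution > 0", call. = FALSE)
  }
  conc_mg_l * extract_volume_ml * dilution / biomass_dw_mg
}

#' Convert optical density at 625 nm to dry-weight concentration
#'
#' Linear through the origin: `dw = od625 * coeff`. The slope is an
#' instrument/strain calibration parameter (g DW per L per OD unit), not a
#' universal constant; the package default used by the synthetic-data
#' generator is 0.3 g/L per OD625 unit, a typical value for dilute diatom
#' cultures.
#'
#' @param od625 Optical density at 625 nm (>= 0).
#' @param coeff Calibration slope, g DW L^-1 per OD625 unit (> 0).
#' @return Dry weight concentration, g/L.
#' @export
od_to_dw <- function(od625, coeff = 0.3) {
  stopifnot(is.numeric(od625), is.numeric(coeff))
  if (any(od625 < 0)) stop("od625 must be >= 0", call. = FALSE)
  if (any(coeff <= 0)) stop("coeff must be > 0", call. = FALSE)
  od625 * coeff
}

#' Molar ratio of chlorophyll a to total carotenoids
#'
#' Converts mass contents to molar amounts and returns their ratio:
#' `(ca/mw_chl) / (xcar/mw_car)`. The default carotenoid molar mass is that
#' of fucoxanthin (658.9 g/mol), the dominant carotenoid in
#' *Phaeodactylum tricornutum*; chlorophyll a is 893.5 g/mol. In healthy
#' exponential-phase cultures this ratio is expected to sit in a narrow band
#' (roughly 1.27-1.42) across strains.
#'
#' @param ca_mg Chlorophyll a mass content (any mass unit, same as `xcar_mg`).
#' @param xcar_mg Total carotenoid mass content. Must be > 0.
#' @param mw_chl,mw_car Molar masses, g/mol.
#' @return Dimensionless molar ratio chlorophyll a : carotenoid.
#' @export
chl_car_molar_ratio <- function(ca_mg, xcar_mg, mw_chl = 893.5,
                                mw_car = 658.9) {
  stopifnot(is.numeric(ca_mg), is.numeric(xcar_mg))
  if (any(!is.finite(xcar_mg)) || any(xcar_mg <= 0)) {
    stop("carotenoid content must be > 0 for a molar ratio", call. = FALSE)
  }
  if (any(mw_chl <= 0) || any(mw_car <= 0)) {
    stop("molar masses must be > 0", call. = FALSE)
  }
  (ca_mg / mw_chl) / (xcar_mg / mw_car)
}

#' Percent difference of a value versus a reference
#'
#' `100 * (value - ref) / ref`, the convention used to report mutant pigment
#' gains over wild type.
#'
#' @param value Numeric vector of measured values.
#' @param ref Reference value (e.g. the wild-type content). Must be > 0.
#' @return Percent difference (positive = above reference).
#' @examples
#' percent_vs_reference(17.44, 10.3)  # ~ +69.3
#' @export
percent_vs_reference <- function(value, ref) {
  stopifnot(is.numeric(value), is.numeric(ref))
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    stop("reference must be > 0", call. = FALSE)
  }
  100 * (value - ref) / ref
}

#' Quantify pigments for a table of extract absorbances
#'
#' Applies [chlorophyll_a_content()] and [total_carotenoid_content()] to each
#' row of an extract table and normalizes to biomass dry weight. Two
#' normalization modes are supported: `"weighed"` uses the `biomass_mg`
#' column directly; `"od"` derives dry weight from an `od625` column and the
#' OD-to-DW calibration slope via [od_to_dw()] (biomass = od_to_dw * volume
#' of culture extracted, `culture_ml`).
#'
#' @param extracts Data frame with columns `strain_id`, `a665`, `a652`,
#'   `a470`, `extract_ml`, `dilution`, and either `biomass_mg` (mode
#'   `"weighed"`) or `od625` + `culture_ml` (mode `"od"`).
#' @param normalization `"weighed"` or `"od"`.
#' @param od_dw_coeff OD-to-dry-weight slope (g/L per OD unit), used only in
#'   `"od"` mode.
#' @return A data frame (pigment profile) with columns `strain_id`, `ca_mg_l`,
#'   `xcar_mg_l`, `ca_per_dw`, `xcar_per_dw` (mg/g DW), `molar_ratio`, and a
#'   logical `flag_negative` marking rows with any negative computed
#'   concentration.
#' @export
pigment_profile <- function(extracts, normalization = c("weighed", "od"),
                            od_dw_coeff = 0.3) {
  normalization <- match.arg(normalization)
  req <- c("strain_id", "a665", "a652", "a470", "extract_ml", "dilution")
  missing_cols <- setdiff(req, names(extracts))
  if (length(missing_cols)) {
    stop("extract table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ca <- withCallingHandlers(
    chlorophyll_a_content(extracts$a665, extracts$a652),
    warning = function(w) invokeRestart("muffleWarning"))
  xcar <- withCallingHandlers(
    total_carotenoid_content(extracts$a470, ca),
    warning = function(w) invokeRestart("muffleWarning"))
  biomass_mg <- switch(normalization,
    weighed = {
      if (is.null(extracts$biomass_mg)) {
        stop("normalization = 'weighed' needs a biomass_mg column",
             call. = FALSE)
      }
      extracts$biomass_mg
    },
    od = {
      if (is.null(extracts$od625) || is.null(extracts$culture_ml)) {
        stop("normalization = 'od' needs od625 and culture_ml columns",
             call. = FALSE)
      }
      # g/L * mL = mg
      od_to_dw(extracts$od625, od_dw_coeff) * extracts$culture_ml
    })
  ca_dw <- per_dw_content(ca, extracts$extract_ml, biomass_mg,
                          extracts$dilution)
  xcar_dw <- per_dw_content(xcar, extracts$extract_ml, biomass_mg,
                            extracts$dilution)
  flag <- ca < 0 | xcar < 0
  if (any(flag)) {
    warning(sum(flag), " extract(s) produced a negative pigment ",
            "concentration (flagged, not clamped)", call. = FALSE)
  }
  ratio <- rep(NA_real_, nrow(extracts))
  ok <- is.finite(xcar_dw) & xcar_dw > 0
  ratio[ok] <- chl_car_molar_ratio(ca_dw[ok], xcar_dw[ok])
  data.frame(strain_id = extracts$strain_id,
             ca_mg_l = ca, xcar_mg_l = xcar,
             ca_per_dw = ca_dw, xcar_per_dw = xcar_dw,
             molar_ratio = ratio,
             flag_negative = flag,
             stringsAsFactors = FALSE)
}
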