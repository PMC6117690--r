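# Format plumbing: validated CSV/TSV readers and writers for plate tables,
# extract tables and growth curves, report serialization, and provenance
# sidecars. All text formats use explicit headers, '.' decimal points,
# UTF-8, and ignore '#' comment lines; CRLF and LF files parse identically.

read_validated_csv <- function(path, required, numeric_cols, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop(basename(path), ": header lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in numeric_cols) {
    raw <- tab[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      stop(basename(path), ": non-numeric value '", raw[bad[1]],
           "' in column '", col, "', row ", bad[1], call. = FALSE)
    }
    tab[[col]] <- val
  }
  tab
}

#' Read a plate-reader measurement table
#'
#' Expects the header `strain_id,well,replicate,phase,od625,rfu_chla,
#' rfu_nilered`. NA policy: NA fluorescence cells are retained (the
#' screening stage excludes them from replicate means with a warning); a
#' row with NA or non-positive OD625 cannot be screened and is dropped
#' here with a warning.
#'
#' @param path CSV path.
#' @return Validated plate table (data frame).
#' @export
read_plate_csv <- function(path) {
  tab <- read_validated_csv(path,
    required = c("strain_id", "well", "replicate", "phase", "od625",
                 "rfu_chla", "rfu_nilered"),
    numeric_cols = c("replicate", "od625", "rfu_chla", "rfu_nilered"))
  bad_phase <- !tab$phase %in% c("exponential", "stationary")
  if (any(bad_phase)) {
    stop(basename(path), ": unknown phase label(s): ",
         paste(unique(tab$phase[bad_phase]), collapse = ", "),
         call. = FALSE)
  }
  bad_od <- is.na(tab$od625) | tab$od625 <= 0
  if (any(bad_od)) {
    warning(sum(bad_od), " row(s) with NA or non-positive od625 dropped",
            call. = FALSE)
    tab <- tab[!bad_od, , drop = FALSE]
  }
  tab
}

#' Write a plate-reader table as CSV
#'
#' @param plate Plate table (see [read_plate_csv()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pigment-extract absorbance table
#'
#' Expects the header `strain_id,a665,a652,a470,extract_ml,biomass_mg,
#' dilution`.
#'
#' @param path CSV path.
#' @return Validated extract table (data frame).
#' @export
read_extract_csv <- function(path) {
  read_validated_csv(path,
    required = c("strain_id", "a665", "a652", "a470", "extract_ml",
                 "biomass_mg", "dilution"),
    numeric_cols = c("a665", "a652", "a470", "extract_ml", "biomass_mg",
                     "dilution"))
}

#' Write an extract table as CSV
#' @param extracts Extract table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extract_csv <- function(extracts, path) {
  utils::write.csv(extracts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read growth curves
#'
#' Expects the header `time_days,od625,dpa_uM` (one or more doses stacked).
#'
#' @param path CSV path.
#' @return Validated growth table (data frame).
#' @export
read_growth_csv <- function(path) {
  read_validated_csv(path,
    required = c("time_days", "od625", "dpa_uM"),
    numeric_cols = c("time_days", "od625", "dpa_uM"))
}

#' Write growth curves as CSV
#' @param growth Growth table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(growth, path) {
  utils::write.csv(growth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a strain population manifest as TSV
#' @param population A [generate_population()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_tsv <- function(population, path) {
  utils::write.table(population, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a screening report
#'
#' Writes `report.json` (the full nested report), `stages.tsv` (per-stage
#' counts), `trace.tsv` (per-strain decision trace) and `selected.txt`
#' into `dir`.
#'
#' @param report A [run_screen()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_screening_report <- function(report, dir) {
  stopifnot(inherits(report, "screening_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.table(report$stages, file.path(dir, "stages.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$trace, file.path(dir, "trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$selected, file.path(dir, "selected.txt"))
  invisible(dir)
}

#' Serialize a flux-correlation classification
#'
#' Writes `correlations.tsv` (`rxn_id  subsystem  r  class`) and
#' `summary.json` (per-subsystem counts and the threshold).
#'
#' @param classification A [classify_correlations()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_correlation_report <- function(classification, dir) {
  stopifnot(inherits(classification, "correlation_classification"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep_tab <- classification$report
  rep_tab$class <- as.character(rep_tab$class)
  utils::write.table(rep_tab[, c("rxn_id", "subsystem", "r", "class")],
                     file.path(dir, "correlations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(threshold = classification$threshold,
         subsystems = classification$subsystem_summary),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Write a provenance sidecar
#'
#' Records the configuration, seed and package version next to generated
#' outputs so every file is reproducible from the sidecar alone.
#'
#' @param config A configuration object (e.g. [generator_config()] or
#'   [screen_config()]).
#' @param path Output JSON path.
#' @param extra Optional named list of additional fields to record.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(config, path, extra = list()) {
  payload <- c(list(
    package = "fucoscreen",
    version = as.character(utils::packageVersion("fucoscreen")),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config_class = class(config)[1],
    config = unclass(config)),
    extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
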