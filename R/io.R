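# Plain-text I/O: the titration CSV dialect (columns titrant_conc, signal,
# optional blank; concentrations in M; comma-separated, '.' decimal), the ITC
# CSV (injection_volume_uL, heat_uJ), and JSON fit reports.

#' Read a titration CSV
#'
#' Expects a header row with columns `titrant_conc` (M) and `signal`, plus an
#' optional `blank` column which is subtracted via [background_subtract()].
#'
#' @param path CSV path.
#' @param mode Titration direction for the resulting series.
#' @param fixed_species_total Fixed-species concentration (M).
#' @param membrane,electrolyte Optional context objects.
#' @return A [titration_series].
#' @export
read_titration_csv <- function(path,
                               mode = c("peptide_into_lipid", "lipid_into_peptide"),
                               fixed_species_total,
                               membrane = NULL, electrolyte = NULL) {
  mode <- match.arg(mode)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("titrant_conc", "signal")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  sig <- tab$signal
  if ("blank" %in% names(tab)) sig <- background_subtract(sig, tab$blank)
  titration_series(mode, fixed_species_total, tab$titrant_conc,
                   as.numeric(sig), membrane, electrolyte)
}

#' Write a titration series to CSV
#'
#' @param series A [titration_series] (or data frame with `titrant_conc`,
#'   `signal`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  tab <- if (inherits(series, "titration_series"))
    data.frame(titrant_conc = series$titrant_totals, signal = series$signal)
  else series[, c("titrant_conc", "signal")]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ITC CSV
#'
#' Expects columns `injection_volume_uL` and `heat_uJ`; the experiment
#' geometry (cell volume, concentrations) comes from the arguments.
#'
#' @param path CSV path.
#' @param ... Geometry arguments forwarded to [itc_experiment()]
#'   (`peptide_cell_conc`, `cell_volume`, `syringe_lipid_total`, ...).
#' @return An [itc_experiment] with heats filled (J).
#' @export
read_itc_csv <- function(path, ...) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("injection_volume_uL", "heat_uJ")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  itc_experiment(injection_volumes = tab$injection_volume_uL * 1e-6,
                 heats = tab$heat_uJ * 1e-6, ...)
}

#' Write an ITC experiment's heats to CSV
#'
#' @param experiment An [itc_experiment] with heats.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_itc_csv <- function(experiment, path) {
  stopifnot(inherits(experiment, "itc_experiment"))
  if (is.null(experiment$heats)) stop("experiment carries no heats")
  utils::write.csv(data.frame(
    injection_volume_uL = experiment$injection_volumes * 1e6,
    heat_uJ = experiment$heats * 1e6), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit report as JSON
#'
#' Serializes any fit object (binding parameters, ITC thermodynamics,
#' saturation fit, ...) together with free-form metadata (conventions,
#' engaged flags, config echo) and the package version.
#'
#' @param fit A fit object (list-like).
#' @param path Output path.
#' @param metadata Optional named list merged into the report.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, metadata = list()) {
  report <- c(list(package = "membind",
                   version = as.character(utils::packageVersion("membind")),
                   generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
              metadata,
              list(fit = unclass(fit)))
  # drop non-serialisable context objects
  report$fit$membrane <- NULL
  report$fit$electrolyte <- report$fit$electrolyte
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
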