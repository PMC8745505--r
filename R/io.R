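#' Read spectra from a long-format CSV file
#'
#' Expects columns `wavelength_nm`, `value` and optionally `sample_id` and
#' `temperature_K`; one spectrum per `sample_id`. Rows may be interleaved
#' across samples; each returned spectrum is sorted by wavelength.
#'
#' @param path Path to the CSV file.
#' @param channel Signal channel of all spectra in the file; one of
#'   `"fluorescence"`, `"absorbance"`, `"cd_mdeg"`.
#' @return A named list of [spectrum()] objects, one per sample_id.
#' @export
read_spectra_csv <- function(path, channel = "fluorescence") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("wavelength_nm", "value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$sample_id)) df$sample_id <- "sample"
  if (is.null(df$temperature_K)) df$temperature_K <- 298
  out <- lapply(split(df, df$sample_id), function(g) {
    g <- g[order(g$wavelength_nm), , drop = FALSE]
    if (any(duplicated(g$wavelength_nm)))
      stop("duplicated wavelength within sample '", g$sample_id[1], "'",
           call. = FALSE)
    spectrum(g$wavelength_nm, g$value, channel = channel,
             temperature_K = g$temperature_K[1], sample_id = g$sample_id[1])
  })
  out[unique(df$sample_id)]
}

#' Write spectra to a long-format CSV file
#'
#' Inverse of [read_spectra_csv()]: the round trip reproduces wavelengths and
#' values exactly (full precision, no rounding).
#'
#' @param spectra A list of [spectrum()] objects (or a single one).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  rows <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(sample_id = s$sample_id, wavelength_nm = s$wavelengths_nm,
               value = s$values, temperature_K = s$temperature_K,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read titration series from CSV
#'
#' Expects columns `system`, `temperature_K`, `quencher_conc_M`, `f_obs` and
#' optionally `a_ex`, `a_em`. Returns the nested structure consumed by
#' [run_full_analysis()]: a list keyed by system, each element a list keyed by
#' temperature (as character) of [titration_series()] objects.
#'
#' @param path Path to the CSV file.
#' @return Nested list of titration series.
#' @export
read_titrations_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("system", "temperature_K", "quencher_conc_M", "f_obs")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$system), function(sys_df) {
    series <- lapply(split(sys_df, sys_df$temperature_K), function(g) {
      cols <- intersect(c("quencher_conc_M", "f_obs", "a_ex", "a_em"), names(g))
      titration_series(g[, cols, drop = FALSE],
                       temperature_K = g$temperature_K[1],
                       system_label = g$system[1])
    })
    series[order(as.numeric(names(series)))]
  })
}

#' Write titration series to CSV
#'
#' @param titrations Nested list as produced by [read_titrations_csv()] or
#'   [simulate_multitemperature()] wrapped in a named list of systems.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_titrations_csv <- function(titrations, path) {
  rows <- list()
  for (sys in names(titrations)) {
    for (ser in titrations[[sys]]) {
      p <- ser$points
      rows[[length(rows) + 1L]] <- data.frame(
        system = sys, temperature_K = ser$temperature_K,
        quencher_conc_M = p$quencher_conc_M, f_obs = p$f_obs,
        a_ex = if (is.null(p$a_ex)) NA_real_ else p$a_ex,
        a_em = if (is.null(p$a_em)) NA_real_ else p$a_em,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Albumin concentration from absorbance at 280 nm
#'
#' Beer-Lambert: `c = A / (epsilon * l)`.
#'
#' @param a280 Absorbance at 280 nm (AU, >= 0).
#' @param epsilon Molar extinction coefficient (cm^-1 M^-1); 43824 for BSA.
#' @param path_cm Optical path length (cm).
#' @return Concentration in M.
#' @examples
#' albumin_conc_from_a280(0.087648)  # 2e-6 M
#' @export
albumin_conc_from_a280 <- function(a280, epsilon = 43824, path_cm = 1) {
  if (any(a280 < 0)) stop("a280 must be >= 0", call. = FALSE)
  if (epsilon <= 0 || path_cm <= 0)
    stop("epsilon and path_cm must be positive", call. = FALSE)
  a280 / (epsilon * path_cm)
}

#' Read an experiment configuration from JSON
#'
#' @param path Path to a JSON file whose keys match the arguments of
#'   [experiment_config()]; absent keys take the defaults.
#' @return An `experiment_config` object.
#' @export
read_config_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(experiment_config))
  do.call(experiment_config, raw[intersect(names(raw), known)])
}

#' Write an analysis report to JSON
#'
#' Serializes the full report (all fits, thermodynamics, CD results and
#' flags) at full numeric precision; [read_report()] reproduces every numeric
#' field exactly.
#'
#' @param report An `analysis_report` from [run_full_analysis()] (an empty
#'   report is valid).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read an analysis report from JSON
#'
#' @param path Path written by [write_report()].
#' @return The report as a nested list; numeric fields are restored at full
#'   precision.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  class(rep) <- "analysis_report"
  rep
}

# Recursively drop S3 classes so jsonlite serializes plain lists; named
# atomic vectors become lists so their names survive as JSON object keys.
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(lapply(as.list(unclass(x)), unclass_deep))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (!is.null(attributes(x))) {
    a <- attributes(x)
    attributes(x) <- a[intersect(names(a), "names")]
  }
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}
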