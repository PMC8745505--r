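#' @keywords internal
"_PACKAGE"

## Gas constant, J mol^-1 K^-1. Fixed: all reported free energies assume it.
.R_GAS <- 8.314

#' Universal gas constant used throughout the package
#'
#' @return The gas constant R in J mol^-1 K^-1 (8.314).
#' @export
gas_constant <- function() .R_GAS

.spectrum_channels <- c("fluorescence", "absorbance", "cd_mdeg")

#' Construct a single-channel spectrum
#'
#' A `spectrum` couples a strictly increasing wavelength grid with one signal
#' channel: fluorescence emission (arbitrary units), absorbance (AU) or
#' circular dichroism ellipticity (millidegrees).
#'
#' @param wavelengths_nm Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param values Numeric vector of signal values, same length as
#'   `wavelengths_nm`.
#' @param channel One of `"fluorescence"`, `"absorbance"`, `"cd_mdeg"`.
#' @param temperature_K Sample temperature in Kelvin (must be positive).
#' @param sample_id Free-text sample identifier.
#' @return An object of class `spectrum`.
#' @examples
#' s <- spectrum(c(340, 341, 342), c(10, 11, 12), "fluorescence")
#' @export
spectrum <- function(wavelengths_nm, values, channel = "fluorescence",
                     temperature_K = 298, sample_id = "sample") {
  channel <- match.arg(channel, .spectrum_channels)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values must have the same length", call. = FALSE)
  if (length(wavelengths_nm) < 1L)
    stop("spectrum must contain at least one point", call. = FALSE)
  if (any(!is.finite(wavelengths_nm)) || any(!is.finite(values)))
    stop("spectrum contains non-finite entries", call. = FALSE)
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing (duplicates or disorder found)",
         call. = FALSE)
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be a single positive number", call. = FALSE)
  if (channel == "absorbance" && any(values < 0))
    stop("absorbance values must be >= 0", call. = FALSE)
  structure(
    list(wavelengths_nm = wavelengths_nm, values = values, channel = channel,
         temperature_K = as.numeric(temperature_K),
         sample_id = as.character(sample_id)),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s | %s | %d points, %.1f-%.1f nm | %g K\n",
              x$sample_id, x$channel, length(x$values),
              min(x$wavelengths_nm), max(x$wavelengths_nm), x$temperature_K))
  invisible(x)
}

#' Construct a fluorescence titration series
#'
#' One temperature's quencher titration: ordered quencher concentrations with
#' observed peak fluorescence, optional paired absorbances at the excitation
#' and emission wavelengths, and the corrected fluorescence. The zero-quencher
#' point defines `f0`, the unquenched fluorescence.
#'
#' @param points A data.frame with columns `quencher_conc_M`, `f_obs` and
#'   optionally `a_ex`, `a_em`, `f_cor`. If `f_cor` is absent it is computed
#'   via [inner_filter_correct()] when both absorbances are present and
#'   non-missing for every point, otherwise set to `f_obs`.
#' @param temperature_K Temperature in Kelvin.
#' @param system_label Text naming the system, e.g. `"BSA-ATN-GLICL"`.
#' @return An object of class `titration_series` with fields `points`
#'   (concentration-sorted data.frame), `temperature_K`, `f0`, `system_label`
#'   and `inner_filter_applied`.
#' @export
titration_series <- function(points, temperature_K, system_label = "") {
  stopifnot(is.data.frame(points))
  req <- c("quencher_conc_M", "f_obs")
  if (!all(req %in% names(points)))
    stop("points must have columns quencher_conc_M and f_obs", call. = FALSE)
  if (!is.numeric(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be positive", call. = FALSE)
  points <- points[order(points$quencher_conc_M), , drop = FALSE]
  rownames(points) <- NULL
  q <- points$quencher_conc_M
  if (any(q < 0)) stop("quencher concentrations must be >= 0", call. = FALSE)
  if (sum(q == 0) != 1L)
    stop("series must contain exactly one zero-quencher point", call. = FALSE)
  if (any(duplicated(q)))
    stop("duplicate quencher concentrations", call. = FALSE)
  if (nrow(points) < 4L)
    stop("series must contain at least 4 points", call. = FALSE)
  if (any(points$f_obs <= 0))
    stop("observed fluorescence must be positive", call. = FALSE)

  has_abs <- all(c("a_ex", "a_em") %in% names(points)) &&
    !anyNA(points$a_ex) && !anyNA(points$a_em)
  if (has_abs && any(points$a_ex < 0 | points$a_em < 0))
    stop("absorbances must be >= 0", call. = FALSE)
  if (is.null(points$f_cor) || anyNA(points$f_cor)) {
    points$f_cor <- if (has_abs)
      inner_filter_correct(points$f_obs, points$a_ex, points$a_em)
    else points$f_obs
  }
  f0 <- points$f_cor[q == 0]
  structure(
    list(points = points, temperature_K = as.numeric(temperature_K), f0 = f0,
         system_label = as.character(system_label),
         inner_filter_applied = has_abs),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %s | %g K | %d points | Q up to %.2g M | F0 = %.4g%s\n",
              if (nzchar(x$system_label)) x$system_label else "(unnamed)",
              x$temperature_K, nrow(x$points), max(x$points$quencher_conc_M),
              x$f0,
              if (x$inner_filter_applied) " | inner-filter corrected" else ""))
  invisible(x)
}

#' Experiment configuration
#'
#' Bundles the experiment-level constants shared by all analysis stages:
#' concentrations, temperatures, the molar extinction coefficient of albumin
#' at 280 nm, the residue count used for mean residue ellipticity, and the CD
#' cuvette path length. Defaults describe a 2 uM bovine serum albumin
#' solution pre-incubated with an 8 uM interfering drug (a 4:1 drug:albumin
#' molar ratio) studied at 298, 303 and 310 K.
#'
#' @param protein_conc_M Albumin concentration (M).
#' @param drug_conc_M Interfering-drug concentration (M).
#' @param temperatures_K Temperatures (K) at which titrations were measured.
#' @param epsilon_280 Molar extinction coefficient of the albumin at 280 nm
#'   (cm^-1 M^-1); 43824 for BSA.
#' @param n_residues Amino-acid residue count (583 for BSA).
#' @param cd_path_cm CD cuvette path length (cm).
#' @param fix_fa Logical; fix the accessible fraction at 1 in the modified
#'   Stern-Volmer fit instead of estimating it.
#' @param use_inner_filter Logical; apply the inner filter correction when
#'   paired absorbances are available.
#' @param peak_window_nm Wavelength window (nm) in which the emission peak is
#'   read; defaults to the tryptophan emission region under 280 nm excitation.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(protein_conc_M = 2e-6, drug_conc_M = 8e-6,
                              temperatures_K = c(298, 303, 310),
                              epsilon_280 = 43824, n_residues = 583L,
                              cd_path_cm = 0.1, fix_fa = FALSE,
                              use_inner_filter = TRUE,
                              peak_window_nm = c(320, 360)) {
  if (protein_conc_M <= 0 || drug_conc_M <= 0)
    stop("concentrations must be positive", call. = FALSE)
  if (any(temperatures_K <= 0)) stop("temperatures must be positive", call. = FALSE)
  if (cd_path_cm <= 0) stop("cd_path_cm must be positive", call. = FALSE)
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues <= 0L)
    stop("n_residues must be a positive integer", call. = FALSE)
  if (epsilon_280 <= 0) stop("epsilon_280 must be positive", call. = FALSE)
  structure(
    list(protein_conc_M = protein_conc_M, drug_conc_M = drug_conc_M,
         temperatures_K = sort(as.numeric(temperatures_K)),
         epsilon_280 = epsilon_280, n_residues = n_residues,
         cd_path_cm = cd_path_cm, gas_constant = .R_GAS,
         fix_fa = isTRUE(fix_fa), use_inner_filter = isTRUE(use_inner_filter),
         peak_window_nm = as.numeric(peak_window_nm)),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> protein %.3g M, drug %.3g M | T = %s K | eps280 = %g | %d residues | CD path %.2g cm\n",
    x$protein_conc_M, x$drug_conc_M,
    paste(x$temperatures_K, collapse = "/"), x$epsilon_280, x$n_residues,
    x$cd_path_cm))
  invisible(x)
}
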