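#' Subtract a blank spectrum
#'
#' Pointwise subtraction of a buffer blank measured on the identical
#' wavelength grid. No interpolation is attempted: a grid mismatch is an
#' error. Metadata of `sample` is preserved.
#'
#' @param sample,blank [spectrum()] objects with identical grids and channel.
#' @param floor Values falling at or below zero after subtraction are clipped
#'   to this small positive floor (downstream log transforms require
#'   positivity); a `"clipped"` attribute records whether clipping occurred.
#' @return The blank-subtracted `spectrum`.
#' @export
subtract_blank <- function(sample, blank, floor = 1e-9) {
  stopifnot(inherits(sample, "spectrum"), inherits(blank, "spectrum"))
  if (sample$channel != blank$channel)
    stop("channel mismatch between sample and blank", call. = FALSE)
  if (length(sample$wavelengths_nm) != length(blank$wavelengths_nm) ||
      any(sample$wavelengths_nm != blank$wavelengths_nm))
    stop("wavelength grids differ; no silent interpolation is performed",
         call. = FALSE)
  vals <- sample$values - blank$values
  clipped <- FALSE
  # CD signals are legitimately negative; fluorescence/absorbance are not
  if (sample$channel != "cd_mdeg" && any(vals < 0)) {
    vals[vals < 0] <- floor
    clipped <- TRUE
    warning("negative values after blank subtraction clipped to floor")
  }
  out <- spectrum(sample$wavelengths_nm, vals, channel = sample$channel,
                  temperature_K = sample$temperature_K,
                  sample_id = sample$sample_id)
  attr(out, "clipped") <- clipped
  out
}

#' Inner filter effect correction
#'
#' Corrects observed fluorescence for attenuation of the excitation beam and
#' reabsorption of emitted light:
#' `F_cor = F_obs * exp((A_ex + A_em) / 2)`. The correction is the identity
#' at zero absorbance and depends only on the sum `A_ex + A_em`.
#'
#' @param f_obs Observed fluorescence (a.u., positive). Vectorized.
#' @param a_ex Absorbance at the excitation wavelength (AU, >= 0).
#' @param a_em Absorbance at the emission wavelength (AU, >= 0).
#' @return Corrected fluorescence, always `>= f_obs`.
#' @examples
#' inner_filter_correct(100, 0.1, 0.1)  # 100 * exp(0.1)
#' @export
inner_filter_correct <- function(f_obs, a_ex, a_em) {
  if (any(f_obs <= 0)) stop("f_obs must be positive", call. = FALSE)
  if (any(a_ex < 0) || any(a_em < 0))
    stop("absorbances must be >= 0", call. = FALSE)
  f_obs * exp((a_ex + a_em) / 2)
}

#' Extract the emission peak within a wavelength window
#'
#' @param spec A fluorescence [spectrum()].
#' @param window_nm Length-2 wavelength interval (nm). Ties are broken toward
#'   the shorter wavelength.
#' @return A list with `peak_wavelength_nm` and `peak_value`.
#' @export
extract_peak_intensity <- function(spec, window_nm = c(320, 360)) {
  stopifnot(inherits(spec, "spectrum"))
  if (spec$channel != "fluorescence")
    stop("peak extraction expects a fluorescence spectrum", call. = FALSE)
  sel <- spec$wavelengths_nm >= min(window_nm) &
    spec$wavelengths_nm <= max(window_nm)
  if (!any(sel))
    stop("window does not intersect the wavelength grid", call. = FALSE)
  w <- spec$wavelengths_nm[sel]
  v <- spec$values[sel]
  i <- which.max(v)  # grid ascending, so the first maximum is the shortest wavelength
  list(peak_wavelength_nm = w[i], peak_value = v[i])
}

#' Percent fluorescence quench along a titration
#'
#' Per point, `100 * (F0 - F) / F0` using corrected fluorescence; the
#' zero-quencher point maps to 0.
#'
#' @param series A [titration_series()].
#' @return Numeric vector of percentages, one per point.
#' @export
percent_quench <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  if (series$f0 <= 0) stop("F0 must be positive", call. = FALSE)
  100 * (series$f0 - series$points$f_cor) / series$f0
}

#' Assemble a titration series from raw emission spectra
#'
#' For each spectrum: subtracts the blank (when given), extracts the peak in
#' `window_nm`, pairs it with the matching absorbances (when given) so the
#' inner filter correction of `titration_series` applies, and sorts by
#' quencher concentration. The zero-concentration point fixes `f0`. The
#' result is invariant to the input ordering of the spectra.
#'
#' @param spectra List of fluorescence [spectrum()] objects, one per
#'   concentration (same order as `concentrations_M`).
#' @param concentrations_M Quencher concentrations (M); must include 0.
#' @param temperature_K Temperature (K).
#' @param absorbances Optional data.frame with columns `a_ex`, `a_em`, one
#'   row per concentration. When omitted, `f_cor = f_obs`.
#' @param blank Optional blank [spectrum()] on the same grid.
#' @param window_nm Peak-extraction window, nm.
#' @param system_label Text label for the ternary system.
#' @return A [titration_series()].
#' @export
build_titration_series <- function(spectra, concentrations_M, temperature_K,
                                   absorbances = NULL, blank = NULL,
                                   window_nm = c(320, 360),
                                   system_label = "") {
  if (length(spectra) != length(concentrations_M))
    stop("one spectrum per concentration is required", call. = FALSE)
  if (!any(concentrations_M == 0))
    stop("concentrations must include the zero-quencher point", call. = FALSE)
  if (!is.null(absorbances) && nrow(absorbances) != length(concentrations_M))
    stop("one absorbance pair per concentration is required", call. = FALSE)
  peaks <- vapply(spectra, function(s) {
    if (!is.null(blank)) s <- subtract_blank(s, blank)
    extract_peak_intensity(s, window_nm)$peak_value
  }, numeric(1))
  pts <- data.frame(quencher_conc_M = as.numeric(concentrations_M),
                    f_obs = peaks)
  if (!is.null(absorbances)) {
    pts$a_ex <- absorbances$a_ex
    pts$a_em <- absorbances$a_em
  }
  titration_series(pts, temperature_K = temperature_K,
                   system_label = system_label)
}
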