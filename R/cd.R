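## Far-UV circular dichroism: mean residue ellipticity and alpha-helix
## content from the 208 nm band.

.MRE_HELIX_208 <- 33000  # |MRE| of a pure alpha-helix at 208 nm
.MRE_COIL_208 <- 4000    # |MRE| where beta-form and random coil cross at 208 nm

#' Mean residue ellipticity
#'
#' `MRE = theta_obs / (c_p * n_residues * path_cm * 10)` in
#' deg cm^2 dmol^-1, where `theta_obs` is the observed ellipticity in
#' millidegrees.
#'
#' @param theta_obs Observed ellipticity (mdeg). Vectorized.
#' @param c_p Protein molar concentration (M, positive).
#' @param n_residues Residue count (583 for BSA).
#' @param path_cm Cuvette path length (cm).
#' @return MRE in deg cm^2 dmol^-1.
#' @export
mean_residue_ellipticity <- function(theta_obs, c_p, n_residues = 583,
                                     path_cm = 0.1) {
  if (c_p <= 0 || n_residues <= 0 || path_cm <= 0)
    stop("c_p, n_residues and path_cm must be positive", call. = FALSE)
  theta_obs / (c_p * n_residues * path_cm * 10)
}

#' Alpha-helix content from MRE at 208 nm
#'
#' Affine interpolation of |MRE at 208 nm| between the random-coil/beta
#' reference (4000, 0% helix) and the pure-helix reference (33000, 100%
#' helix):
#' `alpha% = 100 * (|MRE_208| - 4000) / (33000 - 4000)`.
#' The magnitude is used because the 208 nm helix band is negative. Results
#' are clamped to \[0, 100\]; a `"clamped"` attribute records when clamping
#' occurred.
#'
#' @param mre_208 MRE at 208 nm (deg cm^2 dmol^-1); normally negative.
#' @return Percentage in \[0, 100\] with logical attribute `"clamped"`.
#' @examples
#' alpha_helix_percent(-21000)  # 58.62
#' @export
alpha_helix_percent <- function(mre_208) {
  raw <- 100 * (abs(mre_208) - .MRE_COIL_208) / (.MRE_HELIX_208 - .MRE_COIL_208)
  out <- pmin(pmax(raw, 0), 100)
  attr(out, "clamped") <- any(raw < 0 | raw > 100)
  out
}

#' Analyze a CD spectrum for alpha-helix content
#'
#' Converts an ellipticity spectrum (mdeg) to an MRE curve, reads MRE at
#' 208 nm (nearest grid point, or linear interpolation when 208 nm is
#' bracketed but absent), and computes the alpha-helix percentage. The
#' spectral range considered is restricted to 205-250 nm.
#'
#' @param spec A [spectrum()] with channel `"cd_mdeg"`.
#' @param c_p Protein molar concentration (M).
#' @param n_residues Residue count.
#' @param path_cm Cuvette path length (cm).
#' @return A `cd_result` with fields `mre_curve` (data.frame
#'   wavelength_nm/mre), `mre_208`, `alpha_helix_pct`, `sample_id`, `flags`.
#' @export
analyze_cd_spectrum <- function(spec, c_p, n_residues = 583, path_cm = 0.1) {
  stopifnot(inherits(spec, "spectrum"))
  if (spec$channel != "cd_mdeg")
    stop("expected a CD spectrum (channel 'cd_mdeg')", call. = FALSE)
  sel <- spec$wavelengths_nm >= 205 & spec$wavelengths_nm <= 250
  w <- spec$wavelengths_nm[sel]
  if (length(w) < 2L)
    stop("CD spectrum does not cover the 205-250 nm analysis range",
         call. = FALSE)
  mre <- mean_residue_ellipticity(spec$values[sel], c_p, n_residues, path_cm)
  if (min(w) > 208 || max(w) < 208)
    stop("CD grid does not cover 208 nm", call. = FALSE)
  mre_208 <- if (any(w == 208)) mre[w == 208][1]
  else stats::approx(w, mre, xout = 208)$y
  alpha <- alpha_helix_percent(mre_208)
  flags <- if (isTRUE(attr(alpha, "clamped"))) "alpha_clamped" else character()
  structure(
    list(mre_curve = data.frame(wavelength_nm = w, mre = mre),
         mre_208 = mre_208, alpha_helix_pct = as.numeric(alpha),
         sample_id = spec$sample_id, flags = flags),
    class = "cd_result"
  )
}

#' @export
print.cd_result <- function(x, ...) {
  cat(sprintf("<cd_result> %s | MRE(208) = %.4g deg cm^2/dmol | alpha-helix %.2f%%\n",
              x$sample_id, x$mre_208, x$alpha_helix_pct))
  invisible(x)
}

#' Alpha-helix change between a reference and a modified sample
#'
#' Positive values indicate helix reduction in the modified (ligand-bound)
#' sample relative to the reference.
#'
#' @param reference,modified `cd_result` objects (or bare percentages).
#' @return Percentage-point difference
#'   `reference$alpha_helix_pct - modified$alpha_helix_pct`.
#' @export
alpha_change <- function(reference, modified) {
  a <- function(x) if (inherits(x, "cd_result")) x$alpha_helix_pct else as.numeric(x)
  a(reference) - a(modified)
}
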