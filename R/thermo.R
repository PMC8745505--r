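## van't Hoff thermodynamics of the binding equilibrium.
##
## Free energies are held in J/mol internally; the reporting layer converts
## to kJ/mol for display. Published tables in this field print mixed units
## (kJ/mol for dH, dG; J mol^-1 K^-1 for dS), which is reproduced only at
## rendering time.

#' Free energy change from a binding constant
#'
#' `dG = -R * T * ln(K_a)` with R = 8.314 J mol^-1 K^-1.
#'
#' @param k_a Binding constant (M^-1, positive). Vectorized.
#' @param temperature_K Temperature (K, positive).
#' @return Free energy change in J/mol.
#' @examples
#' delta_g_from_ka(1.65e4, 298) / 1000  # approx -24.06 kJ/mol
#' @export
delta_g_from_ka <- function(k_a, temperature_K) {
  if (any(k_a <= 0)) stop("k_a must be positive", call. = FALSE)
  if (any(temperature_K <= 0)) stop("temperature must be positive", call. = FALSE)
  -.R_GAS * temperature_K * log(k_a)
}

#' Free energy change from enthalpy and entropy
#'
#' `dG = dH - T * dS`.
#'
#' @param delta_h Enthalpy change (J/mol).
#' @param delta_s Entropy change (J mol^-1 K^-1).
#' @param temperature_K Temperature (K, positive).
#' @return Free energy change in J/mol.
#' @export
delta_g_from_enthalpy <- function(delta_h, delta_s, temperature_K) {
  if (any(temperature_K <= 0)) stop("temperature must be positive", call. = FALSE)
  delta_h - temperature_K * delta_s
}

#' Classify the dominant binding forces from thermodynamic signs
#'
#' Positive enthalpy and entropy changes indicate hydrophobic interactions;
#' negative values of both indicate hydrogen bonding and van der Waals
#' forces; negative enthalpy with positive entropy indicates electrostatic
#' interactions. Exact zeros fall to `"mixed"` since the sign rules are
#' stated only for strict signs.
#'
#' @param delta_h Enthalpy change (J/mol).
#' @param delta_s Entropy change (J mol^-1 K^-1).
#' @return One of `"hydrophobic"`, `"hbond_vdw"`, `"electrostatic"`,
#'   `"mixed"`.
#' @export
classify_forces <- function(delta_h, delta_s) {
  if (delta_h > 0 && delta_s > 0) "hydrophobic"
  else if (delta_h < 0 && delta_s < 0) "hbond_vdw"
  else if (delta_h < 0 && delta_s > 0) "electrostatic"
  else "mixed"
}

#' van't Hoff decomposition of binding constants across temperatures
#'
#' Uses `ln(K_a) = -dH/(R*T) + dS/R`. With exactly two temperatures the
#' closed form is used: `dH = R * ln(K2/K1) / (1/T1 - 1/T2)` and
#' `dS = (dH - dG(T1)) / T1` with `dG(T1) = -R*T1*ln(K1)`. With three or
#' more, OLS of `ln(K_a)` on `1/T` gives `dH = -slope * R` and
#' `dS = intercept * R`. Free energies at the evaluation temperatures are
#' filled via `dG = dH - T*dS` (the convention used in reported tables for
#' this analysis), and the dominant force class is attached.
#'
#' @param temperatures_K Temperatures (K), no duplicates, length >= 2.
#' @param k_a Binding constants (M^-1, positive), one per temperature.
#' @param eval_temperatures_K Temperatures at which to evaluate dG; defaults
#'   to `temperatures_K`.
#' @return A `thermo_result` with fields `delta_h` (J/mol), `delta_s`
#'   (J mol^-1 K^-1), `delta_g_by_T` (named, J/mol), `method`
#'   (`"two_point"` or `"regression"`), `r_squared` (regression only),
#'   `force_class` and `spontaneous` (named logical per T).
#' @examples
#' vant_hoff_fit(c(298, 310), c(0.58e4, 0.87e4))
#' @export
vant_hoff_fit <- function(temperatures_K, k_a,
                          eval_temperatures_K = temperatures_K) {
  if (length(temperatures_K) != length(k_a))
    stop("one k_a per temperature is required", call. = FALSE)
  if (length(temperatures_K) < 2L)
    stop("at least two temperatures are required", call. = FALSE)
  if (any(duplicated(temperatures_K)))
    stop("duplicate temperatures", call. = FALSE)
  if (any(k_a <= 0)) stop("k_a must be positive", call. = FALSE)
  if (any(temperatures_K <= 0)) stop("temperatures must be positive", call. = FALSE)
  o <- order(temperatures_K)
  temps <- temperatures_K[o]
  ka <- k_a[o]
  if (length(temps) == 2L) {
    dh <- .R_GAS * log(ka[2] / ka[1]) / (1 / temps[1] - 1 / temps[2])
    ds <- (dh - delta_g_from_ka(ka[1], temps[1])) / temps[1]
    method <- "two_point"
    r2 <- NA_real_
  } else {
    fit <- stats::lm(log(ka) ~ I(1 / temps))
    dh <- -stats::coef(fit)[[2]] * .R_GAS
    ds <- stats::coef(fit)[[1]] * .R_GAS
    method <- "regression"
    r2 <- suppressWarnings(summary(fit))$r.squared
  }
  dg <- stats::setNames(delta_g_from_enthalpy(dh, ds, eval_temperatures_K),
                        as.character(eval_temperatures_K))
  structure(
    list(delta_h = dh, delta_s = ds, delta_g_by_T = dg, method = method,
         r_squared = r2, force_class = classify_forces(dh, ds),
         spontaneous = dg < 0,
         temperatures_K = temps, k_a = ka),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> dH = %.2f kJ/mol, dS = %.2f J/(mol K) [%s, %s]\n",
              x$delta_h / 1000, x$delta_s, x$method, x$force_class))
  for (tn in names(x$delta_g_by_T))
    cat(sprintf("  dG(%s K) = %.2f kJ/mol%s\n", tn,
                x$delta_g_by_T[[tn]] / 1000,
                if (x$spontaneous[[tn]]) " (spontaneous)" else ""))
  invisible(x)
}
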