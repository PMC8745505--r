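## Modified Stern-Volmer and double-log binding fits.
##
## Both models are linearized and fitted by unweighted OLS on the transformed
## variables; the published R^2 values for these systems are consistent with
## plain linear regression, so no variance weighting is used.

.R2_LINEARITY_THRESHOLD <- 0.97

new_quenching_fit <- function(k_sv = NA_real_, f_a = NA_real_,
                              r_squared = NA_real_, se_k_sv = NA_real_,
                              se_f_a = NA_real_, n_points = 0L,
                              temperature_K = NA_real_, flags = character()) {
  structure(list(k_sv = k_sv, f_a = f_a, r_squared = r_squared,
                 se_k_sv = se_k_sv, se_f_a = se_f_a,
                 n_points = as.integer(n_points),
                 temperature_K = temperature_K, flags = flags),
            class = "quenching_fit")
}

#' @export
print.quenching_fit <- function(x, ...) {
  cat(sprintf("<quenching_fit> K_SV = %.4g M^-1 (se %.2g), f_a = %.3g, R^2 = %.4f, n = %d%s\n",
              x$k_sv, x$se_k_sv, x$f_a, x$r_squared, x$n_points,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

new_binding_fit <- function(k_a = NA_real_, n_sites = NA_real_,
                            r_squared = NA_real_, se_log10_ka = NA_real_,
                            se_n = NA_real_, n_points = 0L,
                            temperature_K = NA_real_, flags = character()) {
  structure(list(k_a = k_a, n_sites = n_sites, r_squared = r_squared,
                 se_log10_ka = se_log10_ka, se_n = se_n,
                 n_points = as.integer(n_points),
                 temperature_K = temperature_K, flags = flags),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> K_a = %.4g M^-1, n = %.3g, R^2 = %.4f, n_pts = %d%s\n",
              x$k_a, x$n_sites, x$r_squared, x$n_points,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

fit_accepted <- function(fit) {
  !is.na(fit$k_sv %||% fit$k_a) && !("rejected" %in% fit$flags) &&
    !("fit_failure" %in% fit$flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Usable titration points for the linearized fits: positive quencher and a
# genuine fluorescence decrease. Points violating this are dropped, flagged.
usable_points <- function(series) {
  p <- series$points
  use <- p$quencher_conc_M > 0 & p$f_cor < series$f0 & p$f_cor > 0
  list(q = p$quencher_conc_M[use], f = p$f_cor[use],
       dropped = sum(p$quencher_conc_M > 0) - sum(use))
}

#' Fit the modified Stern-Volmer model
#'
#' Fits `F0 / (F0 - F) = 1 / (f_a * K_SV * Q) + 1 / f_a` by OLS of
#' `y = F0/(F0-F)` against `x = 1/Q`: the intercept `b` gives the accessible
#' fraction `f_a = 1/b` and the slope `m` gives `K_SV = b/m`. Standard errors
#' are propagated to (K_SV, f_a) to first order, including the
#' slope-intercept covariance. The zero-quencher point is excluded; points
#' with `F >= F0` are dropped with a flag. Fewer than 3 usable points yields
#' a fit-failure result rather than an error.
#'
#' @param series A [titration_series()].
#' @param fix_fa Fix `f_a = 1` (regress `y - 1` on `1/Q` through the origin)
#'   instead of estimating it.
#' @return A `quenching_fit` with fields `k_sv`, `f_a`, `r_squared`,
#'   `se_k_sv`, `se_f_a`, `n_points`, `flags`.
#' @export
fit_modified_stern_volmer <- function(series, fix_fa = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  u <- usable_points(series)
  flags <- character()
  if (u$dropped > 0) flags <- c(flags, "points_dropped")
  if (length(u$q) < 3L) {
    if (length(u$q) == 0L && u$dropped > 0) flags <- c(flags, "no quenching")
    return(new_quenching_fit(n_points = length(u$q),
                             temperature_K = series$temperature_K,
                             flags = c(flags, "fit_failure")))
  }
  y <- series$f0 / (series$f0 - u$f)
  x <- 1 / u$q
  if (fix_fa) {
    fit <- stats::lm((y - 1) ~ 0 + x)
    m <- stats::coef(fit)[["x"]]
    vm <- suppressWarnings(stats::vcov(fit))[1, 1]
    k_sv <- 1 / m
    se_k_sv <- sqrt(vm) / m^2
    f_a <- 1
    se_f_a <- 0
    r2 <- suppressWarnings(summary(fit))$r.squared
    flags <- c(flags, "f_a_fixed")
    if (m <= 0) flags <- c(flags, "rejected")
  } else {
    fit <- stats::lm(y ~ x)
    b <- stats::coef(fit)[["(Intercept)"]]
    m <- stats::coef(fit)[["x"]]
    vc <- suppressWarnings(stats::vcov(fit))
    f_a <- 1 / b
    k_sv <- b / m
    # first-order (delta-method) propagation with covariance
    se_f_a <- sqrt(vc[1, 1]) / b^2
    grad <- c(1 / m, -b / m^2)
    se_k_sv <- sqrt(drop(t(grad) %*% vc %*% grad))
    r2 <- suppressWarnings(summary(fit))$r.squared
    if (b <= 0 || m <= 0) flags <- c(flags, "rejected")
  }
  if (is.finite(r2) && r2 < .R2_LINEARITY_THRESHOLD)
    flags <- c(flags, "poor linearity")
  new_quenching_fit(k_sv = k_sv, f_a = f_a, r_squared = r2,
                    se_k_sv = se_k_sv, se_f_a = se_f_a,
                    n_points = length(u$q),
                    temperature_K = series$temperature_K, flags = flags)
}

#' Fit the double-logarithm binding model
#'
#' Fits `log10((F0 - F)/F) = log10(K_a) + n * log10(Q)` by OLS: the slope is
#' the number of binding sites `n` and the intercept is `log10(K_a)`. The
#' zero-quencher point is excluded. An R^2 below the linearity threshold
#' (0.97) retains the fit but flags it `"poor linearity"`; the reporting
#' layer renders such rejected fits as "-".
#'
#' @param series A [titration_series()].
#' @return A `binding_fit` with fields `k_a`, `n_sites`, `r_squared`,
#'   `se_log10_ka`, `se_n`, `n_points`, `flags`.
#' @export
fit_double_log <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  u <- usable_points(series)
  flags <- character()
  if (u$dropped > 0) flags <- c(flags, "points_dropped")
  if (length(u$q) < 3L) {
    if (length(u$q) == 0L && u$dropped > 0) flags <- c(flags, "no quenching")
    return(new_binding_fit(n_points = length(u$q),
                           temperature_K = series$temperature_K,
                           flags = c(flags, "fit_failure")))
  }
  y <- log10((series$f0 - u$f) / u$f)
  x <- log10(u$q)
  fit <- stats::lm(y ~ x)
  b <- stats::coef(fit)[["(Intercept)"]]
  m <- stats::coef(fit)[["x"]]
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  r2 <- suppressWarnings(summary(fit))$r.squared
  if (m <= 0) flags <- c(flags, "rejected")
  if (is.finite(r2) && r2 < .R2_LINEARITY_THRESHOLD)
    flags <- c(flags, "poor linearity")
  new_binding_fit(k_a = 10^b, n_sites = m, r_squared = r2,
                  se_log10_ka = se[[1]], se_n = se[[2]],
                  n_points = length(u$q),
                  temperature_K = series$temperature_K, flags = flags)
}

#' Classify the quenching mechanism from the temperature trend
#'
#' Static quenching (ground-state complex formation) shows a Stern-Volmer
#' constant that decreases with temperature; dynamic (collisional) quenching
#' shows the opposite. The call compares K_SV at the lowest and highest
#' temperatures with accepted fits: relative change
#' `(K_SV_low - K_SV_high) / K_SV_low` above `+threshold` is static, below
#' `-threshold` dynamic, otherwise indeterminate.
#'
#' @param fits Named list of `quenching_fit` objects; names are temperatures
#'   in Kelvin (or the fits carry `temperature_K`).
#' @param threshold Relative-change threshold (default 0.05).
#' @return A `mechanism_call` with fields `label`
#'   (`"static"`/`"dynamic"`/`"indeterminate"`), `k_sv_by_temperature`,
#'   `relative_change` and `flags`.
#' @export
classify_mechanism <- function(fits, threshold = 0.05) {
  temps <- vapply(seq_along(fits), function(i) {
    tk <- fits[[i]]$temperature_K
    if (!is.null(tk) && is.finite(tk)) tk else as.numeric(names(fits)[i])
  }, numeric(1))
  ok <- vapply(fits, fit_accepted, logical(1)) & is.finite(temps)
  res <- structure(list(label = "indeterminate",
                        k_sv_by_temperature = stats::setNames(
                          vapply(fits, function(f) f$k_sv, numeric(1)),
                          as.character(temps)),
                        relative_change = NA_real_, flags = character()),
                   class = "mechanism_call")
  if (sum(ok) < 2L) {
    res$flags <- "insufficient accepted fits"
    return(res)
  }
  temps_ok <- temps[ok]
  ksv_ok <- vapply(fits[ok], function(f) f$k_sv, numeric(1))
  k_lo <- ksv_ok[which.min(temps_ok)]
  k_hi <- ksv_ok[which.max(temps_ok)]
  rel <- (k_lo - k_hi) / k_lo
  res$relative_change <- rel
  res$label <- if (rel > threshold) "static"
  else if (rel < -threshold) "dynamic"
  else "indeterminate"
  res
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s (relative K_SV change %.3g)\n",
              x$label, x$relative_change))
  invisible(x)
}
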