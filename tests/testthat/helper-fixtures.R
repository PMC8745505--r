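# Shared fixture builders and independent closed-form oracles.

# Titration series with F computed from the double-log relation
# (F0-F)/F = ka * q^n, exactly.
series_from_double_log <- function(ka, n = 1, q = seq(2e-6, 14e-6, by = 2e-6),
                                   f0 = 1000, temperature_K = 298) {
  f <- f0 / (1 + ka * q^n)
  titration_series(
    data.frame(quencher_conc_M = c(0, q), f_obs = c(f0, f)),
    temperature_K = temperature_K)
}

# Titration series with F computed from the modified Stern-Volmer relation
# F0/(F0-F) = 1/(fa*ksv*q) + 1/fa, exactly.
series_from_stern_volmer <- function(ksv, fa = 1,
                                     q = seq(2e-6, 14e-6, by = 2e-6),
                                     f0 = 1000, temperature_K = 298) {
  f <- f0 * (1 - fa * ksv * q / (1 + ksv * q))
  titration_series(
    data.frame(quencher_conc_M = c(0, q), f_obs = c(f0, f)),
    temperature_K = temperature_K)
}

# Independent oracle: exact line through two (x, y) points; no lm() involved.
two_point_line <- function(x1, y1, x2, y2) {
  slope <- (y2 - y1) / (x2 - x1)
  list(slope = slope, intercept = y1 - slope * x1)
}

# Oracle for the modified Stern-Volmer parameters from two titration points.
oracle_stern_volmer <- function(series, i = 1L, j = 3L) {
  p <- series$points[series$points$quencher_conc_M > 0, ]
  y <- series$f0 / (series$f0 - p$f_cor)
  x <- 1 / p$quencher_conc_M
  ln <- two_point_line(x[i], y[i], x[j], y[j])
  list(f_a = 1 / ln$intercept, k_sv = ln$intercept / ln$slope)
}

# Oracle for the double-log parameters from two titration points.
oracle_double_log <- function(series, i = 1L, j = 3L) {
  p <- series$points[series$points$quencher_conc_M > 0, ]
  y <- log10((series$f0 - p$f_cor) / p$f_cor)
  x <- log10(p$quencher_conc_M)
  ln <- two_point_line(x[i], y[i], x[j], y[j])
  list(k_a = 10^ln$intercept, n_sites = ln$slope)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
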