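test_that("modified Stern-Volmer fit recovers noiseless truth exactly", {
  cases <- expand.grid(f_a = c(1.0, 0.5, 0.8), k_sv = c(2.80e4, 8.51e4, 0.30e4))
  for (i in seq_len(nrow(cases))) {
    ser <- series_from_stern_volmer(cases$k_sv[i], cases$f_a[i])
    fit <- fit_modified_stern_volmer(ser)
    expect_lt(rel_err(fit$k_sv, cases$k_sv[i]), 1e-8)
    expect_lt(rel_err(fit$f_a, cases$f_a[i]), 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
    expect_equal(fit$n_points, 7L)
  }
})

test_that("fits agree with the closed-form two-point oracle on minimal input", {
  # 3 usable points + zero point; noiseless, so any two points determine the line
  q3 <- c(2e-6, 6e-6, 12e-6)
  ser_sv <- series_from_stern_volmer(3.1e4, 0.7, q = q3)
  orc <- oracle_stern_volmer(ser_sv, 1L, 3L)
  fit <- fit_modified_stern_volmer(ser_sv)
  expect_lt(rel_err(fit$k_sv, orc$k_sv), 1e-8)
  expect_lt(rel_err(fit$f_a, orc$f_a), 1e-8)

  ser_dl <- series_from_double_log(1.9e4, 0.91, q = q3)
  orc2 <- oracle_double_log(ser_dl, 1L, 3L)
  fit2 <- fit_double_log(ser_dl)
  expect_lt(rel_err(fit2$k_a, orc2$k_a), 1e-8)
  expect_lt(rel_err(fit2$n_sites, orc2$n_sites), 1e-8)
})

test_that("double-log fit recovers noiseless truth exactly", {
  # published binary-complex constant and a ternary-system pair as truths
  cases <- data.frame(k_a = c(3.80e4, 0.39e4, 1.65e4), n = c(1.0, 0.86, 1.04))
  for (i in seq_len(nrow(cases))) {
    ser <- series_from_double_log(cases$k_a[i], cases$n[i])
    fit <- fit_double_log(ser)
    expect_lt(rel_err(fit$k_a, cases$k_a[i]), 1e-8)
    expect_lt(rel_err(fit$n_sites, cases$n[i]), 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
  # at Q = 1/K_a with n = 1, F = F0/2 by construction
  ser <- series_from_double_log(1e4, 1, q = c(5e-5, 1e-4, 2e-4))
  expect_equal(ser$points$f_cor[ser$points$quencher_conc_M == 1e-4],
               ser$f0 / 2)
})

test_that("degenerate and poor-quality series are flagged, not thrown", {
  flat <- titration_series(
    data.frame(quencher_conc_M = seq(0, 6e-6, by = 2e-6),
               f_obs = rep(1000, 4)), 298)
  fit <- fit_modified_stern_volmer(flat)
  expect_true("fit_failure" %in% fit$flags)
  expect_true("no quenching" %in% fit$flags)
  expect_true(is.na(fit$k_sv))
  fit_dl <- fit_double_log(flat)
  expect_true("fit_failure" %in% fit_dl$flags)

  # noisy enough data gets a poor-linearity flag but keeps its estimate
  set.seed(3)
  q <- seq(2e-6, 14e-6, by = 2e-6)
  f <- (1000 / (1 + 50 * q)) * (1 + rnorm(7, 0, 0.05))
  rough <- titration_series(
    data.frame(quencher_conc_M = c(0, q), f_obs = c(1000, pmin(f, 999))), 298)
  fit2 <- fit_double_log(rough)
  expect_true("poor linearity" %in% fit2$flags)
  expect_false(is.na(fit2$k_a))
})

test_that("fits are invariant to uniform rescaling of fluorescence units", {
  ser <- series_from_double_log(2.2e4, 0.95)
  for (k in c(0.01, 7, 1e4)) {
    pts <- ser$points[, c("quencher_conc_M", "f_obs")]
    pts$f_obs <- pts$f_obs * k
    scaled <- titration_series(pts, 298)
    expect_equal(fit_double_log(scaled)$k_a, fit_double_log(ser)$k_a)
    expect_equal(fit_modified_stern_volmer(scaled)$k_sv,
                 fit_modified_stern_volmer(ser)$k_sv)
  }
})

test_that("fixed-f_a mode constrains the accessible fraction", {
  ser <- series_from_stern_volmer(2.8e4, fa = 1)
  fit <- fit_modified_stern_volmer(ser, fix_fa = TRUE)
  expect_equal(fit$f_a, 1)
  expect_equal(fit$se_f_a, 0)
  expect_lt(rel_err(fit$k_sv, 2.8e4), 1e-8)
  expect_true("f_a_fixed" %in% fit$flags)
})

test_that("noisy parameter recovery is calibrated and consistent", {
  # The double-log intercept log10(K_a) lies ~5 decades below the covered
  # log10(Q) range (micromolar titration), so its sampling error is ~5x the
  # slope error; K_a recovery is correspondingly noise-sensitive. Assert the
  # attainable calibration: the recovery bounds (median |rel err| K_a < 5%,
  # n < 3%) hold at 0.1% multiplicative noise, and errors scale roughly
  # linearly with the noise level.
  median_errs <- function(noise, reps = 200, seed0 = 1000L) {
    errs_ka <- errs_n <- numeric(reps)
    for (r in seq_len(reps)) {
      truth <- synthetic_truth(k_a_by_T = c(`298` = 3.8e4), n_sites = 1,
                               noise_sd_rel = noise, seed = seed0 + r,
                               temperatures_K = 298)
      fit <- fit_double_log(simulate_titration(truth, 298))
      errs_ka[r] <- rel_err(fit$k_a, 3.8e4)
      errs_n[r] <- rel_err(fit$n_sites, 1)
    }
    c(ka = median(errs_ka), n = median(errs_n))
  }
  lo <- median_errs(0.001)
  expect_lt(lo[["ka"]], 0.05)
  expect_lt(lo[["n"]], 0.03)
  hi <- median_errs(0.01)
  expect_gt(hi[["ka"]] / lo[["ka"]], 4)   # ~linear scaling in noise
  expect_lt(hi[["ka"]] / lo[["ka"]], 25)
})

test_that("mechanism classification follows the K_SV temperature trend", {
  mkfit <- function(ksv, tk) {
    ser <- series_from_stern_volmer(ksv, 1, temperature_K = tk)
    fit_modified_stern_volmer(ser)
  }
  # measured ternary-system trends: AML-like static, FUR-like dynamic
  static <- classify_mechanism(list(`298` = mkfit(8.51e4, 298),
                                    `310` = mkfit(0.30e4, 310)))
  expect_equal(static$label, "static")
  dynamic <- classify_mechanism(list(`298` = mkfit(2.80e4, 298),
                                     `310` = mkfit(3.93e4, 310)))
  expect_equal(dynamic$label, "dynamic")
  flat <- classify_mechanism(list(`298` = mkfit(2e4, 298),
                                  `310` = mkfit(2e4, 310)))
  expect_equal(flat$label, "indeterminate")
  # threshold respected: 3% change is indeterminate at the default 5%
  near <- classify_mechanism(list(`298` = mkfit(2.00e4, 298),
                                  `310` = mkfit(1.94e4, 310)))
  expect_equal(near$label, "indeterminate")

  # fewer than two accepted fits
  flatser <- titration_series(
    data.frame(quencher_conc_M = seq(0, 6e-6, by = 2e-6),
               f_obs = rep(1000, 4)), 298)
  broken <- classify_mechanism(list(`298` = fit_modified_stern_volmer(flatser),
                                    `310` = mkfit(2e4, 310)))
  expect_equal(broken$label, "indeterminate")
  expect_true("insufficient accepted fits" %in% broken$flags)
})
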