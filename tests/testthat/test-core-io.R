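test_that("spectrum constructor enforces its invariants", {
  s <- spectrum(c(340, 341, 342), c(10, 11, 12), "fluorescence")
  expect_s3_class(s, "spectrum")
  expect_length(s$values, 3)

  expect_error(spectrum(c(340, 340, 342), c(1, 2, 3)), "strictly increasing")
  expect_error(spectrum(c(342, 341, 340), c(1, 2, 3)), "strictly increasing")
  expect_error(spectrum(c(340, 341), c(1, 2, 3)), "same length")
  expect_error(spectrum(340, 1, temperature_K = -1), "positive")
  expect_error(spectrum(c(340, 341), c(-0.1, 0.2), "absorbance"), ">= 0")
  # CD values may be negative
  expect_silent(spectrum(c(206, 208), c(-24, -20), "cd_mdeg"))
})

test_that("spectra CSV reading groups, sorts and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  # two samples interleaved, wavelengths deliberately out of order
  writeLines(c("sample_id,wavelength_nm,value",
               "a,342,12", "b,341,21", "a,340,10", "b,340,20", "a,341,11",
               "b,342,22"), path)
  sp <- read_spectra_csv(path)
  expect_named(sp, c("a", "b"))
  expect_equal(sp$a$wavelengths_nm, c(340, 341, 342))
  expect_equal(sp$a$values, c(10, 11, 12))
  expect_equal(sp$b$values, c(20, 21, 22))

  writeLines(c("sample_id,wavelength_nm,value", "a,340,1", "a,340,2"), path)
  expect_error(read_spectra_csv(path), "duplicated wavelength")

  writeLines(c("wavelength,value", "340,1"), path)
  expect_error(read_spectra_csv(path), "missing required columns")
})

test_that("spectra CSV round trip is exact", {
  set.seed(11)
  s <- spectrum(seq(300, 400, by = 0.5), rnorm(201, 500, 100) + pi * 1e-8,
                "fluorescence", temperature_K = 303, sample_id = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(s, path)
  back <- read_spectra_csv(path)[["rt"]]
  expect_identical(back$wavelengths_nm, s$wavelengths_nm)
  expect_identical(back$values, s$values)
  expect_identical(back$temperature_K, s$temperature_K)
})

test_that("Beer-Lambert conversion is linear and validated", {
  expect_equal(albumin_conc_from_a280(0), 0)
  expect_equal(albumin_conc_from_a280(0.087648, 43824, 1), 2e-6)
  expect_equal(albumin_conc_from_a280(0.43824, 43824, 1), 1e-5)
  # linearity in a280
  a <- c(0.01, 0.2, 0.9)
  for (k in c(0, 0.5, 3))
    expect_equal(albumin_conc_from_a280(k * a), k * albumin_conc_from_a280(a))
  expect_error(albumin_conc_from_a280(0.1, epsilon = 0), "positive")
  expect_error(albumin_conc_from_a280(-0.1), ">= 0")
})

test_that("titration series constructor sorts and validates", {
  pts <- data.frame(quencher_conc_M = c(4e-6, 0, 2e-6, 6e-6),
                    f_obs = c(700, 1000, 840, 610))
  ser <- titration_series(pts, 298, system_label = "BSA-X-GLICL")
  expect_equal(ser$points$quencher_conc_M, c(0, 2e-6, 4e-6, 6e-6))
  expect_equal(ser$f0, 1000)
  expect_false(ser$inner_filter_applied)

  expect_error(titration_series(pts[-2, ], 298), "zero-quencher")
  expect_error(titration_series(pts[1:3, ], 298), "at least 4 points")
  pts4 <- rbind(pts, data.frame(quencher_conc_M = 0, f_obs = 990))
  expect_error(titration_series(pts4, 298), "exactly one zero-quencher")
  pts$f_obs[2] <- -5
  expect_error(titration_series(pts, 298), "positive")
})

test_that("config JSON reading applies defaults and validates", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"protein_conc_M": 2e-6, "drug_conc_M": 8e-6, "fix_fa": true}',
             path)
  cfg <- read_config_json(path)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$temperatures_K, c(298, 303, 310))
  expect_equal(cfg$epsilon_280, 43824)
  expect_equal(cfg$n_residues, 583L)
  expect_equal(cfg$cd_path_cm, 0.1)
  expect_equal(cfg$gas_constant, 8.314)
  expect_true(cfg$fix_fa)
  expect_error(experiment_config(protein_conc_M = 0), "positive")
  expect_error(experiment_config(n_residues = -1), "positive")
})

# "full precision" here means the full printed precision of a double:
# jsonlite serializes ~16 significant digits, so equality is asserted at
# 1e-14 relative tolerance rather than bit-exactness.
test_that("report JSON round trip preserves numeric fields at full precision", {
  # empty report
  empty <- run_full_analysis(experiment_config(), list())
  path <- withr::local_tempfile(fileext = ".json")
  write_report(empty, path)
  expect_length(read_report(path)$systems, 0)

  truth <- quenching_preset("static", noise_sd_rel = 0.01, seed = 42)
  tit <- list(SYS = simulate_multitemperature(truth))
  rep <- run_full_analysis(experiment_config(), tit)
  write_report(rep, path)
  back <- read_report(path)

  orig_fit <- rep$systems$SYS$binding[["298"]]
  back_fit <- back$systems$SYS$binding[["298"]]
  for (fld in c("k_a", "n_sites", "r_squared", "se_log10_ka", "se_n"))
    expect_equal(back_fit[[fld]], orig_fit[[fld]], tolerance = 1e-14,
                 label = fld)
  expect_equal(back$systems$SYS$thermo$delta_h,
               rep$systems$SYS$thermo$delta_h, tolerance = 1e-14)
  expect_equal(back$systems$SYS$thermo$delta_g_by_T[["303"]],
               unname(rep$systems$SYS$thermo$delta_g_by_T[["303"]]),
               tolerance = 1e-14)
  qf <- rep$systems$SYS$quenching[["310"]]
  expect_equal(back$systems$SYS$quenching[["310"]]$k_sv, qf$k_sv,
               tolerance = 1e-14)
})
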