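## End-to-end orchestration and table-shaped rendering.

#' Run the full ternary-system analysis
#'
#' Per system: a modified Stern-Volmer fit per temperature, mechanism
#' classification from the K_SV temperature trend, a double-log binding fit
#' per temperature, van't Hoff decomposition of the accepted binding
#' constants, binding-force classification, and (optionally) alpha-helix
#' quantification of matching CD spectra. Partial failures are recorded per
#' system and never abort the batch; every input system appears exactly once
#' in the report.
#'
#' @param config An [experiment_config()].
#' @param titrations Nested list: system -> temperature (character) ->
#'   [titration_series()], e.g. from [read_titrations_csv()]. May be empty.
#' @param cd_spectra Optional named list of CD [spectrum()] objects; entries
#'   whose names match a system are analyzed with it, the entry named
#'   `"reference"` (if present) provides the helix-change baseline.
#' @return An `analysis_report`: list with `config`, `systems` (one entry per
#'   system carrying `quenching`, `mechanism`, `binding`, `thermo`, `cd`,
#'   `flags` or an `error` record) and `provenance`.
#' @export
run_full_analysis <- function(config = experiment_config(),
                              titrations = list(), cd_spectra = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  reference_cd <- if (!is.null(cd_spectra) && "reference" %in% names(cd_spectra))
    analyze_cd_spectrum(cd_spectra[["reference"]], config$protein_conc_M,
                        config$n_residues, config$cd_path_cm)
  else NULL
  systems <- lapply(names(titrations), function(sys) {
    tryCatch(
      analyze_system(sys, titrations[[sys]], config, cd_spectra, reference_cd),
      error = function(e) list(system = sys, error = conditionMessage(e))
    )
  })
  names(systems) <- names(titrations)
  structure(
    list(config = config, systems = systems,
         provenance = list(
           fix_fa = config$fix_fa,
           inner_filter_requested = config$use_inner_filter,
           gas_constant = config$gas_constant,
           package_version = as.character(utils::packageVersion("bindspec")))),
    class = "analysis_report"
  )
}

analyze_system <- function(sys, series_by_T, config, cd_spectra, reference_cd) {
  flags <- character()
  if (length(series_by_T) < 2L)
    flags <- c(flags, "fewer than 2 temperatures")
  quenching <- lapply(series_by_T, fit_modified_stern_volmer,
                      fix_fa = config$fix_fa)
  mechanism <- if (length(quenching) >= 2L) classify_mechanism(quenching)
  else NULL
  binding <- lapply(series_by_T, fit_double_log)
  accepted <- vapply(binding, fit_accepted, logical(1))
  thermo <- NULL
  if (sum(accepted) >= 2L) {
    temps <- vapply(binding[accepted], function(f) f$temperature_K, numeric(1))
    kas <- vapply(binding[accepted], function(f) f$k_a, numeric(1))
    thermo <- vant_hoff_fit(temps, kas,
                            eval_temperatures_K = config$temperatures_K)
  } else {
    flags <- c(flags, "thermodynamics skipped: < 2 accepted binding fits")
  }
  cd <- NULL
  if (!is.null(cd_spectra) && sys %in% names(cd_spectra)) {
    cd <- analyze_cd_spectrum(cd_spectra[[sys]], config$protein_conc_M,
                              config$n_residues, config$cd_path_cm)
    if (!is.null(reference_cd))
      cd$alpha_change_vs_reference <- alpha_change(reference_cd, cd)
  }
  inner <- vapply(series_by_T, function(s) s$inner_filter_applied, logical(1))
  list(system = sys,
       temperatures_K = vapply(series_by_T, function(s) s$temperature_K,
                               numeric(1)),
       inner_filter_applied = unname(inner),
       quenching = quenching, mechanism = mechanism, binding = binding,
       thermo = thermo, cd = cd, flags = flags, error = NULL)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d system(s)\n", length(x$systems)))
  for (s in x$systems) {
    if (!is.null(s$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", s$system, s$error))
    } else {
      mech <- if (!is.null(s$mechanism)) s$mechanism$label else "?"
      cat(sprintf("  %s: %d temperature(s), mechanism %s%s\n", s$system,
                  length(s$temperatures_K), mech,
                  if (!is.null(s$thermo))
                    sprintf(", dH = %.2f kJ/mol (%s)", s$thermo$delta_h / 1000,
                            s$thermo$force_class) else ""))
    }
  }
  invisible(x)
}

fmt_1e4 <- function(x) sprintf("%.2f", x / 1e4)

#' Render a quenching/binding constants table
#'
#' One row per system and temperature with the Stern-Volmer constant, the
#' binding constant and the site count in display units (constants in units
#' of 1e4 M^-1, two decimals). Rejected or failed binding fits render as
#' `"-"`.
#'
#' @param report An `analysis_report`.
#' @return A data.frame of character-formatted cells plus a `flags` column.
#' @export
render_constants_table <- function(report) {
  rows <- list()
  for (s in report$systems) {
    if (!is.null(s$error)) next
    for (tn in names(s$quenching)) {
      qf <- s$quenching[[tn]]
      bf <- s$binding[[tn]]
      q_ok <- fit_accepted(qf)
      b_ok <- fit_accepted(bf) && !("poor linearity" %in% bf$flags)
      rows[[length(rows) + 1L]] <- data.frame(
        system = s$system, temperature_K = qf$temperature_K,
        K_SV_1e4 = if (q_ok) fmt_1e4(qf$k_sv) else "-",
        R2_SV = if (q_ok) sprintf("%.4f", qf$r_squared) else "-",
        K_a_1e4 = if (b_ok) fmt_1e4(bf$k_a) else "-",
        n = if (b_ok) sprintf("%.2f", bf$n_sites) else "-",
        R2_dl = if (b_ok) sprintf("%.4f", bf$r_squared) else "-",
        flags = paste(unique(c(qf$flags, bf$flags)), collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(system = character(), temperature_K = numeric(),
                      K_SV_1e4 = character(), R2_SV = character(),
                      K_a_1e4 = character(), n = character(),
                      R2_dl = character(), flags = character()))
  do.call(rbind, rows)
}

#' Render a thermodynamic parameters table
#'
#' One row per system with enthalpy (kJ/mol), entropy (J mol^-1 K^-1), free
#' energy at each configured temperature (kJ/mol, two decimals) and the
#' binding-force class.
#'
#' @param report An `analysis_report`.
#' @return A data.frame.
#' @export
render_thermo_table <- function(report) {
  temps <- report$config$temperatures_K
  rows <- list()
  for (s in report$systems) {
    if (!is.null(s$error) || is.null(s$thermo)) next
    th <- s$thermo
    row <- data.frame(system = s$system,
                      dH_kJ_mol = sprintf("%.2f", th$delta_h / 1000),
                      dS_J_molK = sprintf("%.2f", th$delta_s),
                      stringsAsFactors = FALSE)
    for (tk in temps)
      row[[sprintf("dG_%g_kJ_mol", tk)]] <-
        sprintf("%.2f", th$delta_g_by_T[[as.character(tk)]] / 1000)
    row$force_class <- th$force_class
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    out <- data.frame(system = character(), dH_kJ_mol = character(),
                      dS_J_molK = character(), stringsAsFactors = FALSE)
    for (tk in temps) out[[sprintf("dG_%g_kJ_mol", tk)]] <- character()
    out$force_class <- character()
    return(out)
  }
  do.call(rbind, rows)
}

#' Published reference constants for the albumin-gliclazide ternary systems
#'
#' Measured Stern-Volmer and binding constants (and site counts) for bovine
#' serum albumin titrated with gliclazide in the presence of five hypotensive
#' drugs (AML, ATN, FUR, QUI, VAL) at 298 and 310 K, as published for these
#' systems. Constants are in units of 1e4 M^-1; unavailable cells (the
#' rejected FUR fit at 298 K) are NA. Used as fixtures by the acceptance
#' checks.
#'
#' @return A data.frame with columns `system`, `temperature_K`, `k_sv_1e4`,
#'   `r2_sv`, `k_a_1e4`, `n_sites`, `r2_dl`.
#' @export
reference_ternary_constants <- function() {
  path <- system.file("extdata", "ternary_reference_constants.csv",
                      package = "bindspec", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published reference thermodynamic parameters for the ternary systems
#'
#' Enthalpy (kJ/mol), entropy (J mol^-1 K^-1) and free energy (kJ/mol at
#' 298/303/310 K) published for the albumin-gliclazide ternary systems.
#'
#' @return A data.frame with columns `system`, `delta_h_kJ_mol`,
#'   `delta_s_J_molK`, `dg_298_kJ_mol`, `dg_303_kJ_mol`, `dg_310_kJ_mol`.
#' @export
reference_ternary_thermo <- function() {
  path <- system.file("extdata", "ternary_reference_thermo.csv",
                      package = "bindspec", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
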