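# End-to-end pipeline: quenching fits per temperature, Van 't Hoff block,
# FRET chain, and structural summaries, assembled into one reproducible
# report object.

#' Run the full binding-analysis pipeline
#'
#' Executes, in order: Stern-Volmer and double-log fits for every supplied
#' titration; Van 't Hoff regression when at least two temperatures are
#' available; the FRET chain when a donor/acceptor pair is given; and the
#' structural summaries (CD, EEM peaks, synchronous traces) when their
#' inputs are given. The result is deterministic for fixed inputs and
#' config, and every numeric cell of the report traces to one exported
#' function.
#'
#' @param titrations list of [titration_series()] (at least one), each at a
#'   distinct temperature.
#' @param config a [run_config()].
#' @param donor,acceptor optional donor-emission / acceptor-extinction
#'   [spectrum()] pair for FRET.
#' @param fret_efficiency optional transfer efficiency in (0, 1); when NULL
#'   and a donor/acceptor pair is present, E is read from the first
#'   titration as the fractional quench of its last point.
#' @param eem_input optional [eem()] for peak extraction and synchronous
#'   traces.
#' @param cd_input optional list `theta` ([spectrum()] of kind
#'   `ellipticity_mdeg`), `conc_mg_ml`, `path_cm`; mean residue weight
#'   comes from `config`.
#' @param min_peak_separation_nm peak separation for [eem_peaks()].
#' @return an object of class `run_report`: quenching/binding table
#'   (one row per temperature), `thermo` block (or a reason string when
#'   fewer than two temperatures are supplied), `force`, `fret`, `shift`
#'   per temperature, `eem_peaks`, `cd`, plus the config echo and package
#'   version.
#' @export
run_pipeline <- function(titrations, config = run_config(),
                         donor = NULL, acceptor = NULL,
                         fret_efficiency = NULL,
                         eem_input = NULL, cd_input = NULL,
                         min_peak_separation_nm = 10) {
  if (!is.list(titrations) || length(titrations) == 0L ||
      !all(vapply(titrations, inherits, logical(1), "titration_series")))
    stop("titrations must be a non-empty list of titration_series objects",
         call. = FALSE)
  temps <- vapply(titrations, `[[`, numeric(1), "temperature_K")
  if (anyDuplicated(temps))
    stop("each titration must be at a distinct temperature", call. = FALSE)
  ord <- order(temps)
  titrations <- titrations[ord]
  temps <- temps[ord]

  quench <- lapply(titrations, stern_volmer_fit, config = config)
  binding <- lapply(titrations, double_log_fit, config = config)
  shifts <- lapply(titrations, emission_shift)
  qtab <- data.frame(
    temperature_K = temps,
    Ksv_M1 = vapply(quench, `[[`, numeric(1), "Ksv_M1"),
    kq_M1s1 = vapply(quench, `[[`, numeric(1), "kq_M1s1"),
    sv_intercept = vapply(quench, `[[`, numeric(1), "intercept"),
    sv_r_squared = vapply(quench, `[[`, numeric(1), "r_squared"),
    Kb_M1 = vapply(binding, `[[`, numeric(1), "Kb_M1"),
    n_sites = vapply(binding, `[[`, numeric(1), "n_sites"),
    dl_r_squared = vapply(binding, `[[`, numeric(1), "r_squared"),
    n_excluded = vapply(binding, `[[`, numeric(1), "n_excluded"),
    shift_nm = vapply(shifts, `[[`, numeric(1), "shift_nm"))

  thermo <- NULL
  force <- NULL
  if (length(temps) >= 2L) {
    thermo <- vant_hoff_fit(temps, qtab$Kb_M1)
    force <- binding_force_classification(thermo$dH_kcal_mol,
                                          thermo$dS_cal_mol_K)
  } else {
    thermo <- "insufficient temperatures (need >= 2)"
  }

  fret <- NULL
  if (!is.null(donor) && !is.null(acceptor)) {
    eff <- fret_efficiency
    if (is.null(eff)) {
      f <- intensity_at_readout(titrations[[1]], config)
      eff <- efficiency_from_quenching(f[length(f)], f[1])
    }
    fret <- fret_analysis(donor, acceptor, efficiency = eff, config = config)
  }

  eem_pk <- NULL
  if (!is.null(eem_input))
    eem_pk <- eem_peaks(eem_input, min_peak_separation_nm)

  cd <- NULL
  if (!is.null(cd_input))
    cd <- cd_analysis(cd_input$theta, cd_input$conc_mg_ml, cd_input$path_cm,
                      config$mean_residue_weight_Da)

  structure(
    list(quenching_table = qtab, quenching = quench, binding = binding,
         shifts = shifts, thermo = thermo, force = force, fret = fret,
         eem_peaks = eem_pk, cd = cd, config = config,
         package_version = as.character(utils::packageVersion("albuquench"))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== Binding-analysis report ==\n\n")
  cat("Quenching / binding fits (per temperature):\n")
  print(x$quenching_table, row.names = FALSE, digits = 6)
  cat("\nThermodynamics:\n")
  if (inherits(x$thermo, "thermo_result")) {
    print(x$thermo)
    if (!is.null(x$force)) print(x$force)
  } else cat("  ", x$thermo, "\n", sep = "")
  if (!is.null(x$fret)) { cat("\nFRET:\n"); print(x$fret) }
  if (!is.null(x$eem_peaks)) { cat("\nEEM peaks:\n"); print(x$eem_peaks) }
  if (!is.null(x$cd)) { cat("\nCD:\n"); print(x$cd) }
  cat(sprintf("\nconfig: tau0 = %g s, readout = %s; package %s\n",
              x$config$tau0_s, x$config$intensity_readout,
              x$package_version))
  invisible(x)
}

#' Write a run report to a directory of delimited tables
#'
#' Writes `quenching.tsv` (per-temperature fits), `thermo.tsv`, `fret.tsv`,
#' `eem_peaks.tsv`, `cd.tsv` (each when present) and a human-readable
#' `summary.txt`. Regeneration from the same report is byte-identical.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_result_table(report$quenching_table, file.path(dir, "quenching.tsv"))
  if (inherits(report$thermo, "thermo_result"))
    write_result_table(report$thermo, file.path(dir, "thermo.tsv"))
  if (!is.null(report$fret))
    write_result_table(report$fret, file.path(dir, "fret.tsv"))
  if (!is.null(report$eem_peaks) && nrow(report$eem_peaks$peaks))
    write_result_table(report$eem_peaks, file.path(dir, "eem_peaks.tsv"))
  if (!is.null(report$cd))
    write_result_table(report$cd, file.path(dir, "cd.tsv"))
  con <- file(file.path(dir, "summary.txt"), "w", encoding = "UTF-8")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(dir)
}
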