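# Recognised signal kinds. "mre_deg_cm2_dmol" is the unit of a mean-residue
# ellipticity spectrum produced by mean_residue_ellipticity().
SPECTRUM_KINDS <- c("emission_au", "absorbance", "molar_extinction_M1cm1",
                    "ellipticity_mdeg", "mre_deg_cm2_dmol")

#' Gas constant in kcal mol-1 K-1
#'
#' CODATA value of R expressed in the energy unit used throughout the
#' thermodynamics functions.
#' @export
GAS_CONSTANT_KCAL <- 1.987204e-3

#' Construct a wavelength-indexed spectrum
#'
#' A `spectrum` is one signal trace on a strictly increasing wavelength grid
#' (nanometres) together with a declared signal kind. Rows are sorted by
#' wavelength on construction; duplicated wavelengths are rejected.
#'
#' @param wavelengths_nm numeric vector of wavelengths in nm, all positive.
#' @param values numeric vector of the same length (units depend on `kind`).
#' @param kind one of `"emission_au"`, `"absorbance"`,
#'   `"molar_extinction_M1cm1"`, `"ellipticity_mdeg"`, `"mre_deg_cm2_dmol"`.
#'   Absorbance and molar-extinction values must be non-negative.
#' @param label free-text label carried through analyses.
#' @return an object of class `spectrum` with fields `wavelengths_nm`,
#'   `values`, `kind`, `label`.
#' @examples
#' s <- spectrum(c(300, 340, 400), c(0, 1, 0.1), "emission_au")
#' peak_wavelength(s)
#' @export
spectrum <- function(wavelengths_nm, values, kind, label = "") {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values must have identical length", call. = FALSE)
  if (length(wavelengths_nm) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(wavelengths_nm) || anyNA(values))
    stop("NA values are not allowed in a spectrum", call. = FALSE)
  if (any(wavelengths_nm <= 0))
    stop("wavelengths must be positive (nm)", call. = FALSE)
  ord <- order(wavelengths_nm)
  wavelengths_nm <- wavelengths_nm[ord]
  values <- values[ord]
  if (any(diff(wavelengths_nm) == 0))
    stop("duplicate wavelengths are not allowed", call. = FALSE)
  if (kind %in% c("absorbance", "molar_extinction_M1cm1") && any(values < 0))
    stop(kind, " values must be >= 0", call. = FALSE)
  structure(
    list(wavelengths_nm = wavelengths_nm, values = values,
         kind = kind, label = as.character(label)[1]),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d points, %.1f-%.1f nm%s\n",
              x$kind, length(x$values),
              min(x$wavelengths_nm), max(x$wavelengths_nm),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths_nm, value = x$values)
}

#' Wavelength of the grid maximum of a spectrum
#'
#' Ties are broken toward the shortest wavelength.
#' @param s a `spectrum`.
#' @return wavelength in nm of the first grid point attaining the maximum.
#' @export
peak_wavelength <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  s$wavelengths_nm[which.max(s$values)]
}

#' Value of a spectrum at a wavelength (linear interpolation)
#' @param s a `spectrum`.
#' @param lambda_nm query wavelength, must lie within the grid range.
#' @return interpolated signal value.
#' @export
spectrum_at <- function(s, lambda_nm) {
  stopifnot(inherits(s, "spectrum"))
  rng <- range(s$wavelengths_nm)
  if (lambda_nm < rng[1] || lambda_nm > rng[2])
    stop(sprintf("wavelength %.2f nm outside grid range [%.2f, %.2f]",
                 lambda_nm, rng[1], rng[2]), call. = FALSE)
  stats::approx(s$wavelengths_nm, s$values, xout = lambda_nm)$y
}

#' Construct a fluorescence titration series
#'
#' A baseline protein spectrum plus spectra at increasing quencher
#' concentrations, recorded at one temperature. All spectra must share one
#' wavelength grid and one signal kind; the first concentration must be 0
#' (the unquenched reference).
#'
#' @param temperature_K temperature in Kelvin (> 0).
#' @param protein_conc_M protein concentration in mol/L (> 0).
#' @param quencher_concs_M strictly increasing quencher concentrations in
#'   mol/L; first element must be 0.
#' @param spectra list of `spectrum` objects, one per concentration.
#' @param path_length_cm cuvette path length in cm.
#' @param excitation_absorbances,emission_absorbances optional per-point
#'   absorbances at the excitation and emission wavelengths, used for
#'   inner-filter correction.
#' @return an object of class `titration_series`.
#' @export
titration_series <- function(temperature_K, protein_conc_M, quencher_concs_M,
                             spectra, path_length_cm = 1,
                             excitation_absorbances = NULL,
                             emission_absorbances = NULL) {
  quencher_concs_M <- as.numeric(quencher_concs_M)
  n <- length(quencher_concs_M)
  if (n < 1L) stop("at least one titration point is required", call. = FALSE)
  if (quencher_concs_M[1] != 0)
    stop("first quencher concentration must be 0 (unquenched reference)",
         call. = FALSE)
  if (n > 1L && any(diff(quencher_concs_M) <= 0))
    stop("quencher concentrations must be strictly increasing", call. = FALSE)
  if (!is.list(spectra) || length(spectra) != n)
    stop("spectra must be a list with one spectrum per concentration",
         call. = FALSE)
  if (!all(vapply(spectra, inherits, logical(1), "spectrum")))
    stop("all elements of spectra must be spectrum objects", call. = FALSE)
  grid <- spectra[[1]]$wavelengths_nm
  kind <- spectra[[1]]$kind
  for (sp in spectra[-1]) {
    if (!isTRUE(all.equal(sp$wavelengths_nm, grid)))
      stop("all spectra in a titration must share one wavelength grid",
           call. = FALSE)
    if (!identical(sp$kind, kind))
      stop("all spectra in a titration must share one signal kind",
           call. = FALSE)
  }
  if (!is.numeric(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be > 0", call. = FALSE)
  if (!is.numeric(protein_conc_M) || protein_conc_M <= 0)
    stop("protein_conc_M must be > 0", call. = FALSE)
  for (a in list(excitation_absorbances, emission_absorbances)) {
    if (!is.null(a)) {
      if (length(a) != n) stop("absorbance vectors must have one value per ",
                               "titration point", call. = FALSE)
      if (any(a < 0)) stop("absorbances must be >= 0", call. = FALSE)
    }
  }
  structure(
    list(temperature_K = temperature_K, protein_conc_M = protein_conc_M,
         quencher_concs_M = quencher_concs_M, spectra = spectra,
         path_length_cm = path_length_cm,
         excitation_absorbances = excitation_absorbances,
         emission_absorbances = emission_absorbances),
    class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> %d points, [Q] %.3g-%.3g M, %.0f K, %s\n",
    length(x$quencher_concs_M), min(x$quencher_concs_M),
    max(x$quencher_concs_M), x$temperature_K, x$spectra[[1]]$kind))
  invisible(x)
}

#' Construct an excitation-emission matrix (3D fluorescence surface)
#'
#' @param excitation_nm strictly increasing excitation wavelengths (nm).
#' @param emission_nm strictly increasing emission wavelengths (nm).
#' @param intensities numeric matrix, rows = excitation, cols = emission.
#' @return an object of class `eem`.
#' @export
eem <- function(excitation_nm, emission_nm, intensities) {
  excitation_nm <- as.numeric(excitation_nm)
  emission_nm <- as.numeric(emission_nm)
  intensities <- as.matrix(intensities)
  for (ax in list(excitation_nm, emission_nm)) {
    if (length(ax) < 2L || any(diff(ax) <= 0) || any(ax <= 0))
      stop("EEM axes must be strictly increasing positive wavelengths",
           call. = FALSE)
  }
  if (nrow(intensities) != length(excitation_nm) ||
      ncol(intensities) != length(emission_nm))
    stop("intensity matrix dimensions must match the axes", call. = FALSE)
  if (anyNA(intensities)) stop("NA intensities are not allowed", call. = FALSE)
  structure(list(excitation_nm = excitation_nm, emission_nm = emission_nm,
                 intensities = unname(intensities)),
            class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> %d x %d (ex %.0f-%.0f nm, em %.0f-%.0f nm)\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$excitation_nm), max(x$excitation_nm),
              min(x$emission_nm), max(x$emission_nm)))
  invisible(x)
}

#' Photophysical and readout configuration
#'
#' Holds every constant the quenching/FRET/CD calculations use so that none
#' is hard-coded at a call site. Defaults are the conventional values for a
#' tryptophan donor in aqueous buffer: unquenched lifetime tau0 ~ 1e-8 s,
#' donor quantum yield 0.118, orientation factor kappa^2 = 2/3, refractive
#' index 1.33, mean residue weight 112.8 Da. The gas constant is fixed.
#'
#' @param tau0_s unquenched fluorescence lifetime in seconds.
#' @param quantum_yield donor fluorescence quantum yield.
#' @param kappa2 dipole orientation factor, in (0, 4].
#' @param refractive_index medium refractive index.
#' @param mean_residue_weight_Da mean residue weight of the protein (Da).
#' @param intensity_readout how titration intensities are read:
#'   `"fixed_at_reference_peak"` reads every spectrum at the emission maximum
#'   of the unquenched reference; `"per_spectrum_max"` reads each spectrum at
#'   its own maximum.
#' @return an object of class `run_config`.
#' @export
run_config <- function(tau0_s = 1e-8,
                       quantum_yield = 0.118,
                       kappa2 = 2 / 3,
                       refractive_index = 1.33,
                       mean_residue_weight_Da = 112.8,
                       intensity_readout = c("fixed_at_reference_peak",
                                             "per_spectrum_max")) {
  intensity_readout <- match.arg(intensity_readout)
  for (v in list(tau0_s, quantum_yield, kappa2, refractive_index,
                 mean_residue_weight_Da)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("all run_config constants must be positive finite scalars",
           call. = FALSE)
  }
  if (kappa2 > 4) stop("kappa2 must lie in (0, 4]", call. = FALSE)
  structure(
    list(tau0_s = tau0_s, quantum_yield = quantum_yield, kappa2 = kappa2,
         refractive_index = refractive_index,
         mean_residue_weight_Da = mean_residue_weight_Da,
         gas_constant_kcal = GAS_CONSTANT_KCAL,
         intensity_readout = intensity_readout),
    class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  tau0_s            %g\n", x$tau0_s))
  cat(sprintf("  quantum_yield     %g\n", x$quantum_yield))
  cat(sprintf("  kappa2            %g\n", x$kappa2))
  cat(sprintf("  refractive_index  %g\n", x$refractive_index))
  cat(sprintf("  mean_residue_wt   %g Da\n", x$mean_residue_weight_Da))
  cat(sprintf("  intensity_readout %s\n", x$intensity_readout))
  invisible(x)
}
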