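# Fluorescence-quenching analysis: inner-filter correction, Stern-Volmer
# fit, bimolecular quenching rate, double-logarithmic binding fit, and
# emission-maximum shift metrics.

#' Inner-filter correction of fluorescence intensities
#'
#' Corrects observed intensities for attenuation of the excitation and
#' emission beams by sample absorbance:
#' `F_corr = F_obs * exp((A_ex + A_em) / 2)`.
#' Vectorised over all three arguments.
#'
#' @param F_obs observed intensity (arbitrary units, >= 0).
#' @param A_ex absorbance at the excitation wavelength (>= 0).
#' @param A_em absorbance at the emission wavelength (>= 0).
#' @return corrected intensity, same shape as `F_obs`.
#' @examples
#' correct_inner_filter(100, 0, 0)     # 100: identity at zero absorbance
#' correct_inner_filter(50, 0.2, 0.1)  # 50 * exp(0.15)
#' @export
correct_inner_filter <- function(F_obs, A_ex, A_em) {
  if (any(A_ex < 0) || any(A_em < 0))
    stop("absorbances must be >= 0", call. = FALSE)
  if (any(F_obs < 0))
    stop("observed intensities must be >= 0", call. = FALSE)
  F_obs * exp((A_ex + A_em) / 2)
}

#' Per-point fluorescence intensities of a titration
#'
#' Extracts one intensity per titration point. Under
#' `fixed_at_reference_peak` every spectrum is read at the emission maximum
#' of the unquenched (`[Q] = 0`) spectrum; under `per_spectrum_max` each
#' spectrum is read at its own grid maximum. When the series carries
#' excitation/emission absorbances the inner-filter correction is applied
#' first.
#'
#' @param series a [titration_series()] of emission spectra.
#' @param config a [run_config()]; `intensity_readout` selects the mode.
#' @return numeric vector of intensities, one per titration point.
#' @export
intensity_at_readout <- function(series, config = run_config()) {
  stopifnot(inherits(series, "titration_series"),
            inherits(config, "run_config"))
  if (series$spectra[[1]]$kind != "emission_au")
    stop("intensity readout requires emission spectra", call. = FALSE)
  if (config$intensity_readout == "fixed_at_reference_peak") {
    idx <- which.max(series$spectra[[1]]$values)
    f <- vapply(series$spectra, function(s) s$values[idx], numeric(1))
  } else {
    f <- vapply(series$spectra, function(s) max(s$values), numeric(1))
  }
  if (!is.null(series$excitation_absorbances) &&
      !is.null(series$emission_absorbances)) {
    f <- correct_inner_filter(f, series$excitation_absorbances,
                              series$emission_absorbances)
  }
  f
}

# r-squared of a simple linear fit that degrades gracefully when the
# response is constant (a constant is fit perfectly by slope 0).
fit_r_squared <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst < .Machine$double.eps * length(y) * max(1, mean(y)^2)) return(1)
  1 - sum(stats::residuals(fit)^2) / sst
}

#' Stern-Volmer fit of a quenching titration
#'
#' Ordinary least-squares fit of `F0/F` against quencher concentration.
#' The slope is the Stern-Volmer constant `Ksv` (M^-1); the intercept is
#' estimated rather than constrained to 1 and its deviation from 1 is a fit
#' diagnostic. The bimolecular quenching rate constant `kq = Ksv / tau0`
#' uses the lifetime from `config`.
#'
#' @param series a [titration_series()] with at least 3 points.
#' @param config a [run_config()].
#' @return an object of class `quenching_result` with fields
#'   `temperature_K`, `Ksv_M1`, `kq_M1s1`, `intercept`, `r_squared`,
#'   `n_points`, `tau0_s`.
#' @export
stern_volmer_fit <- function(series, config = run_config()) {
  q <- series$quencher_concs_M
  if (length(q) < 3L)
    stop("Stern-Volmer fit needs at least 3 titration points", call. = FALSE)
  f <- intensity_at_readout(series, config)
  if (any(f <= 0))
    stop("all intensities must be positive for a Stern-Volmer fit",
         call. = FALSE)
  ratio <- f[1] / f
  fit <- stats::lm(ratio ~ q)
  ksv <- unname(stats::coef(fit)[2])
  structure(
    list(temperature_K = series$temperature_K,
         Ksv_M1 = ksv,
         kq_M1s1 = bimolecular_rate(ksv, config$tau0_s),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = fit_r_squared(fit, ratio),
         n_points = length(q),
         tau0_s = config$tau0_s),
    class = "quenching_result")
}

#' @export
print.quenching_result <- function(x, ...) {
  cat(sprintf(
    "<quenching_result> %.0f K: Ksv = %.4g M-1, kq = %.4g M-1 s-1 (tau0 = %g s)\n  intercept = %.6g, r2 = %.6g, n = %d\n",
    x$temperature_K, x$Ksv_M1, x$kq_M1s1, x$tau0_s, x$intercept,
    x$r_squared, x$n_points))
  invisible(x)
}

#' @export
as.data.frame.quenching_result <- function(x, ...) {
  data.frame(temperature_K = x$temperature_K, Ksv_M1 = x$Ksv_M1,
             kq_M1s1 = x$kq_M1s1, intercept = x$intercept,
             r_squared = x$r_squared, n_points = x$n_points,
             tau0_s = x$tau0_s)
}

#' Bimolecular quenching rate constant
#'
#' `kq = Ksv / tau0`, where `tau0` is the unquenched donor lifetime. Values
#' far above the diffusion limit (~1e10 M^-1 s^-1) indicate static
#' quenching via a ground-state complex.
#'
#' @param Ksv_M1 Stern-Volmer constant (M^-1).
#' @param tau0_s unquenched lifetime (s, > 0).
#' @return rate constant in M^-1 s^-1.
#' @export
bimolecular_rate <- function(Ksv_M1, tau0_s) {
  if (!is.numeric(tau0_s) || tau0_s <= 0)
    stop("tau0_s must be > 0", call. = FALSE)
  Ksv_M1 / tau0_s
}

#' Double-logarithmic binding fit
#'
#' Fits `log10((F0 - F)/F) = log10(Kb) + n * log10([Q])` by ordinary least
#' squares over titration points with `[Q] > 0` and `F < F0`. The intercept
#' gives the binding constant `Kb = 10^intercept` (M^-1) and the slope the
#' apparent number of binding sites `n`. Points with `F >= F0` (no net
#' quenching) are excluded and counted in `n_excluded`.
#'
#' @param series a [titration_series()].
#' @param config a [run_config()].
#' @return an object of class `binding_result` with fields `temperature_K`,
#'   `Kb_M1`, `n_sites`, `r_squared`, `n_points`, `n_excluded`.
#' @export
double_log_fit <- function(series, config = run_config()) {
  q <- series$quencher_concs_M
  f <- intensity_at_readout(series, config)
  if (any(f <= 0))
    stop("all intensities must be positive for a binding fit", call. = FALSE)
  f0 <- f[1]
  candidate <- q > 0
  usable <- candidate & f < f0
  n_excluded <- sum(candidate & !usable)
  if (sum(usable) < 3L)
    stop("double-log fit needs at least 3 points with [Q] > 0 and F < F0",
         call. = FALSE)
  x <- log10(q[usable])
  y <- log10((f0 - f[usable]) / f[usable])
  fit <- stats::lm(y ~ x)
  structure(
    list(temperature_K = series$temperature_K,
         Kb_M1 = 10^unname(stats::coef(fit)[1]),
         n_sites = unname(stats::coef(fit)[2]),
         r_squared = fit_r_squared(fit, y),
         n_points = sum(usable),
         n_excluded = n_excluded),
    class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf(
    "<binding_result> %.0f K: Kb = %.4g M-1, n = %.4g, r2 = %.6g (%d points, %d excluded)\n",
    x$temperature_K, x$Kb_M1, x$n_sites, x$r_squared, x$n_points,
    x$n_excluded))
  invisible(x)
}

#' @export
as.data.frame.binding_result <- function(x, ...) {
  data.frame(temperature_K = x$temperature_K, Kb_M1 = x$Kb_M1,
             n_sites = x$n_sites, r_squared = x$r_squared,
             n_points = x$n_points, n_excluded = x$n_excluded)
}

# Refine a grid argmax by fitting a parabola through the three points
# around it (exact for a locally quadratic band top).
parabolic_peak <- function(wl, values) {
  i <- which.max(values)
  if (i == 1L || i == length(values)) return(wl[i])
  y <- values[(i - 1L):(i + 1L)]
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom >= 0) return(wl[i])       # not a concave triple
  delta <- 0.5 * (y[1] - y[3]) / denom
  wl[i] + delta * (wl[i + 1L] - wl[i])
}

#' Emission-maximum shift across a titration
#'
#' Compares the emission-maximum wavelength of the first (unquenched) and
#' last spectra of a titration; a negative shift is a blue shift (movement
#' of the fluorophore to a more hydrophobic environment). Maxima are grid
#' argmaxes with ties broken toward the shorter wavelength; an optional
#' three-point parabolic refinement interpolates off-grid band centres.
#'
#' @param series a [titration_series()] with at least 2 spectra.
#' @param refine logical; apply parabolic refinement of the maxima.
#' @return an object of class `shift_result` with fields
#'   `lambda_max_start_nm`, `lambda_max_end_nm`, `shift_nm`, and `flat`
#'   (TRUE when either endpoint spectrum has a tied, non-unique maximum).
#' @export
emission_shift <- function(series, refine = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  if (length(series$spectra) < 2L)
    stop("emission_shift needs at least 2 spectra", call. = FALSE)
  first <- series$spectra[[1]]
  last <- series$spectra[[length(series$spectra)]]
  flat <- any(vapply(list(first, last), function(s)
    sum(s$values == max(s$values)) > 1L, logical(1)))
  locate <- if (refine) {
    function(s) parabolic_peak(s$wavelengths_nm, s$values)
  } else {
    peak_wavelength
  }
  l0 <- locate(first)
  l1 <- locate(last)
  structure(list(lambda_max_start_nm = l0, lambda_max_end_nm = l1,
                 shift_nm = l1 - l0, flat = flat),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  dir <- if (x$shift_nm < 0) "blue" else if (x$shift_nm > 0) "red" else "no"
  cat(sprintf("<shift_result> %.2f -> %.2f nm (%+.2f nm, %s shift)%s\n",
              x$lambda_max_start_nm, x$lambda_max_end_nm, x$shift_nm, dir,
              if (x$flat) " [flat spectrum: tie broken to shorter wavelength]"
              else ""))
  invisible(x)
}
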