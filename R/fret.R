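# Forster-theory calculations: spectral overlap integral, Forster radius,
# transfer efficiency, donor-acceptor distance, and the validity window
# 0.5*R0 < r < 1.5*R0.

NM_TO_CM <- 1e-7

#' Spectral overlap integral J of a donor-acceptor pair
#'
#' Computes the donor-normalised overlap of donor emission with acceptor
#' extinction,
#' `J = integral(F(l) * eps(l) * l^4 dl) / integral(F(l) dl)`,
#' with the wavelength in cm and eps in M^-1 cm^-1, giving J in M^-1 cm^3.
#' The acceptor extinction is linearly interpolated onto the donor grid
#' restricted to the overlap region and both integrals use the trapezoid
#' rule; the denominator integrates the donor over its full support (the
#' standard normalisation of the donor emission). Disjoint supports give
#' J = 0.
#'
#' @param donor_emission a [spectrum()] of kind `emission_au`.
#' @param acceptor_extinction a [spectrum()] of kind
#'   `molar_extinction_M1cm1`.
#' @return the overlap integral in M^-1 cm^3.
#' @export
overlap_integral <- function(donor_emission, acceptor_extinction) {
  stopifnot(inherits(donor_emission, "spectrum"),
            inherits(acceptor_extinction, "spectrum"))
  if (donor_emission$kind != "emission_au")
    stop("donor spectrum must have kind 'emission_au'", call. = FALSE)
  if (acceptor_extinction$kind != "molar_extinction_M1cm1")
    stop("acceptor spectrum must have kind 'molar_extinction_M1cm1'",
         call. = FALSE)
  dwl <- donor_emission$wavelengths_nm
  dint <- donor_emission$values
  denom <- pracma::trapz(dwl, dint)
  if (denom <= 0)
    stop("donor spectrum integrates to zero; overlap integral undefined",
         call. = FALSE)
  lo <- max(min(dwl), min(acceptor_extinction$wavelengths_nm))
  hi <- min(max(dwl), max(acceptor_extinction$wavelengths_nm))
  if (lo >= hi) return(0)
  sel <- dwl >= lo & dwl <= hi
  if (sum(sel) < 2L) return(0)
  grid <- dwl[sel]
  eps <- stats::approx(acceptor_extinction$wavelengths_nm,
                       acceptor_extinction$values, xout = grid)$y
  num <- pracma::trapz(grid, dint[sel] * eps * (grid * NM_TO_CM)^4)
  num / denom
}

#' Forster critical radius from the overlap integral
#'
#' `R0^6 = 8.79e-25 * kappa^2 * n^-4 * Phi * J` with J in M^-1 cm^3 yields
#' R0^6 in cm^6; the sixth root is converted to nm. R0 is the
#' donor-acceptor separation at 50% transfer efficiency.
#'
#' @param J_M1cm3 overlap integral (M^-1 cm^3, >= 0).
#' @param config a [run_config()] supplying `quantum_yield`, `kappa2`, and
#'   `refractive_index`.
#' @return Forster radius in nm.
#' @examples
#' forster_radius(5.99e-15)  # ~2.26 nm for a Trp donor in water
#' @export
forster_radius <- function(J_M1cm3, config = run_config()) {
  if (J_M1cm3 < 0) stop("J must be >= 0", call. = FALSE)
  r0_6_cm6 <- 8.79e-25 * config$kappa2 * config$refractive_index^(-4) *
    config$quantum_yield * J_M1cm3
  (r0_6_cm6)^(1 / 6) / NM_TO_CM
}

#' Transfer efficiency from donor quenching
#'
#' `E = 1 - F/F0`, the fraction of donor excitations transferred to the
#' acceptor, read from donor intensities without (`F0`) and with (`F`) the
#' acceptor present at equimolar concentration.
#'
#' @param F_au donor intensity with acceptor (0 <= F <= F0).
#' @param F0_au donor intensity without acceptor (> 0).
#' @return efficiency in `[0, 1]`.
#' @export
efficiency_from_quenching <- function(F_au, F0_au) {
  if (F0_au <= 0) stop("F0 must be > 0", call. = FALSE)
  if (F_au < 0) stop("F must be >= 0", call. = FALSE)
  if (F_au > F0_au)
    stop("F > F0 would imply negative transfer efficiency", call. = FALSE)
  1 - F_au / F0_au
}

#' Donor-acceptor distance from transfer efficiency
#'
#' Inverts `E = R0^6 / (R0^6 + r^6)`: `r = R0 * ((1 - E)/E)^(1/6)`.
#'
#' @param E transfer efficiency, strictly inside (0, 1).
#' @param R0_nm Forster radius (nm, > 0).
#' @return distance in nm.
#' @examples
#' distance_from_efficiency(0.45, 2.26)  # ~2.33 nm
#' @export
distance_from_efficiency <- function(E, R0_nm) {
  if (E <= 0 || E >= 1)
    stop("efficiency must lie strictly inside (0, 1)", call. = FALSE)
  if (R0_nm <= 0) stop("R0 must be > 0", call. = FALSE)
  R0_nm * ((1 - E) / E)^(1 / 6)
}

#' Transfer efficiency from a donor-acceptor distance
#'
#' `E = R0^6 / (R0^6 + r^6)`.
#'
#' @param R0_nm Forster radius (nm, > 0).
#' @param r_nm donor-acceptor distance (nm, > 0).
#' @return efficiency in (0, 1).
#' @export
efficiency_from_distance <- function(R0_nm, r_nm) {
  if (R0_nm <= 0 || r_nm <= 0)
    stop("R0 and r must both be > 0", call. = FALSE)
  ratio6 <- (r_nm / R0_nm)^6
  1 / (1 + ratio6)
}

#' Full FRET chain: overlap integral to donor-acceptor distance
#'
#' Convenience wrapper running the complete Forster calculation: J from the
#' spectra, R0 from J and the photophysical constants, E from either a
#' donor intensity pair or a supplied efficiency, r from E and R0, and the
#' Forster-window validity check `0.5*R0 < r < 1.5*R0`.
#'
#' @param donor_emission donor emission [spectrum()].
#' @param acceptor_extinction acceptor molar-extinction [spectrum()].
#' @param F_au,F0_au donor intensities with/without acceptor (used when
#'   `efficiency` is NULL).
#' @param efficiency transfer efficiency supplied directly, in (0, 1).
#' @param config a [run_config()].
#' @return an object of class `fret_result` with fields `J_M1cm3`, `R0_nm`,
#'   `E`, `r_nm`, `constants_used`, `window_ok`.
#' @export
fret_analysis <- function(donor_emission, acceptor_extinction,
                          F_au = NULL, F0_au = NULL, efficiency = NULL,
                          config = run_config()) {
  J <- overlap_integral(donor_emission, acceptor_extinction)
  R0 <- forster_radius(J, config)
  E <- if (is.null(efficiency)) {
    if (is.null(F_au) || is.null(F0_au))
      stop("supply either efficiency or the pair F_au, F0_au", call. = FALSE)
    efficiency_from_quenching(F_au, F0_au)
  } else efficiency
  r <- distance_from_efficiency(E, R0)
  structure(
    list(J_M1cm3 = J, R0_nm = R0, E = E, r_nm = r,
         constants_used = list(quantum_yield = config$quantum_yield,
                               kappa2 = config$kappa2,
                               refractive_index = config$refractive_index),
         window_ok = (r > 0.5 * R0) && (r < 1.5 * R0)),
    class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf(
    "<fret_result> J = %.4g M-1 cm3, R0 = %.3f nm, E = %.3f, r = %.3f nm\n  window 0.5*R0 < r < 1.5*R0: %s\n",
    x$J_M1cm3, x$R0_nm, x$E, x$r_nm, if (x$window_ok) "ok" else "VIOLATED"))
  invisible(x)
}

#' @export
as.data.frame.fret_result <- function(x, ...) {
  data.frame(J_M1cm3 = x$J_M1cm3, R0_nm = x$R0_nm, E = x$E, r_nm = x$r_nm,
             quantum_yield = x$constants_used$quantum_yield,
             kappa2 = x$constants_used$kappa2,
             refractive_index = x$constants_used$refractive_index,
             window_ok = x$window_ok)
}
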