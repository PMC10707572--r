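# Structural-spectroscopy summaries: CD mean-residue ellipticity and helix
# content, UV-Vis molar absorptivity and hyperchromicity, synchronous
# fluorescence traces, and EEM peak extraction.

#' Mean-residue ellipticity spectrum from raw CD ellipticity
#'
#' Converts observed ellipticity (mdeg) to mean-residue ellipticity,
#' `MRE(l) = theta(l) * M0 / (10 * l * c)`, in deg cm^2 dmol^-1, with the
#' protein concentration in mg/cm^3 and the path length in cm.
#'
#' @param theta_mdeg a [spectrum()] of kind `ellipticity_mdeg`.
#' @param conc_mg_ml protein concentration in mg/cm^3 (> 0).
#' @param path_cm cuvette path length in cm (> 0).
#' @param M0_Da mean residue weight in Da (> 0).
#' @return a [spectrum()] of kind `mre_deg_cm2_dmol`.
#' @export
mean_residue_ellipticity <- function(theta_mdeg, conc_mg_ml, path_cm,
                                     M0_Da = 112.8) {
  stopifnot(inherits(theta_mdeg, "spectrum"))
  if (theta_mdeg$kind != "ellipticity_mdeg")
    stop("input must have kind 'ellipticity_mdeg'", call. = FALSE)
  if (conc_mg_ml <= 0 || path_cm <= 0 || M0_Da <= 0)
    stop("concentration, path length, and M0 must all be > 0", call. = FALSE)
  spectrum(theta_mdeg$wavelengths_nm,
           theta_mdeg$values * M0_Da / (10 * path_cm * conc_mg_ml),
           kind = "mre_deg_cm2_dmol", label = theta_mdeg$label)
}

#' Alpha-helix content from the 222 nm mean-residue ellipticity
#'
#' `%helix = (-MRE222 - 2340) / 30300 * 100`. Values outside `[0, 100]`
#' are returned unclamped with a warning.
#'
#' @param mre_222 mean-residue ellipticity at 222 nm (deg cm^2 dmol^-1).
#' @return helix content in percent.
#' @examples
#' helix_percent(-17490)  # 50
#' @export
helix_percent <- function(mre_222) {
  h <- (-mre_222 - 2340) / 30300 * 100
  if (any(h < 0 | h > 100))
    warning("helix percent outside [0, 100]; returned unclamped",
            call. = FALSE)
  h
}

#' CD summary: MRE spectrum, MRE at 222 nm, helix content
#'
#' Runs the full far-UV CD chain. The 222 nm value is read at the grid
#' point nearest 222 nm (no interpolation); the wavelength actually used is
#' recorded in the result.
#'
#' @inheritParams mean_residue_ellipticity
#' @return an object of class `cd_result`: `mre_spectrum`, `mre_222`,
#'   `lambda_222_nm` (grid point used), `helix_percent`,
#'   `helix_out_of_range`, and the `inputs` record.
#' @export
cd_analysis <- function(theta_mdeg, conc_mg_ml, path_cm, M0_Da = 112.8) {
  mre <- mean_residue_ellipticity(theta_mdeg, conc_mg_ml, path_cm, M0_Da)
  i <- which.min(abs(mre$wavelengths_nm - 222))
  mre_222 <- mre$values[i]
  h <- withCallingHandlers(
    helix_percent(mre_222),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(
    list(mre_spectrum = mre, mre_222 = mre_222,
         lambda_222_nm = mre$wavelengths_nm[i],
         helix_percent = h,
         helix_out_of_range = (h < 0 || h > 100),
         inputs = list(protein_conc_mg_ml = conc_mg_ml,
                       path_length_cm = path_cm,
                       mean_residue_weight_Da = M0_Da)),
    class = "cd_result")
}

#' @export
print.cd_result <- function(x, ...) {
  cat(sprintf(
    "<cd_result> MRE(%g nm) = %.4g deg cm2 dmol-1, helix = %.2f%%%s\n",
    x$lambda_222_nm, x$mre_222, x$helix_percent,
    if (x$helix_out_of_range) " [outside 0-100%]" else ""))
  invisible(x)
}

#' @export
as.data.frame.cd_result <- function(x, ...) {
  data.frame(lambda_222_nm = x$lambda_222_nm, mre_222 = x$mre_222,
             helix_percent = x$helix_percent,
             helix_out_of_range = x$helix_out_of_range,
             protein_conc_mg_ml = x$inputs$protein_conc_mg_ml,
             path_length_cm = x$inputs$path_length_cm,
             mean_residue_weight_Da = x$inputs$mean_residue_weight_Da)
}

#' Molar absorptivity spectrum from an absorbance spectrum
#'
#' Beer-Lambert conversion `eps(l) = A(l) / (c * path)` in M^-1 cm^-1.
#'
#' @param absorbance a [spectrum()] of kind `absorbance`.
#' @param conc_M chromophore concentration in mol/L (> 0).
#' @param path_cm path length in cm (> 0).
#' @return a [spectrum()] of kind `molar_extinction_M1cm1`.
#' @export
molar_absorptivity <- function(absorbance, conc_M, path_cm) {
  stopifnot(inherits(absorbance, "spectrum"))
  if (absorbance$kind != "absorbance")
    stop("input must have kind 'absorbance'", call. = FALSE)
  if (conc_M <= 0 || path_cm <= 0)
    stop("concentration and path length must be > 0", call. = FALSE)
  spectrum(absorbance$wavelengths_nm,
           absorbance$values / (conc_M * path_cm),
           kind = "molar_extinction_M1cm1", label = absorbance$label)
}

#' Percent intensity change at one wavelength across a titration
#'
#' `100 * (A_last(l) - A_first(l)) / A_first(l)` between the first and
#' last spectra of a series; positive values indicate hyperchromicity.
#' The wavelength is read by linear interpolation on the shared grid.
#'
#' @param series a [titration_series()] (typically of absorbance spectra).
#' @param lambda_nm wavelength within the grid range.
#' @return percent change.
#' @export
hyperchromicity <- function(series, lambda_nm) {
  stopifnot(inherits(series, "titration_series"))
  a0 <- spectrum_at(series$spectra[[1]], lambda_nm)
  a1 <- spectrum_at(series$spectra[[length(series$spectra)]], lambda_nm)
  if (a0 == 0)
    stop("baseline intensity at the query wavelength is zero", call. = FALSE)
  100 * (a1 - a0) / a0
}

#' Synchronous-fluorescence trace from an EEM
#'
#' Samples the surface along the diagonal `em = ex + delta` by bilinear
#' interpolation and returns the trace indexed by excitation wavelength.
#' Offsets of 15 nm and 60 nm select the tyrosine and tryptophan
#' microenvironments respectively.
#'
#' @param x an [eem()].
#' @param delta_nm positive wavelength offset (nm).
#' @return a [spectrum()] (kind `emission_au`) indexed by excitation
#'   wavelength over the part of the diagonal inside the EEM domain.
#' @export
synchronous_trace <- function(x, delta_nm) {
  stopifnot(inherits(x, "eem"))
  if (delta_nm <= 0) stop("delta_nm must be > 0", call. = FALSE)
  em_rng <- range(x$emission_nm)
  keep <- x$excitation_nm + delta_nm >= em_rng[1] &
    x$excitation_nm + delta_nm <= em_rng[2]
  if (sum(keep) < 2L)
    stop("diagonal em = ex + delta does not intersect the EEM domain",
         call. = FALSE)
  ex <- x$excitation_nm[keep]
  vals <- vapply(which(keep), function(i)
    stats::approx(x$emission_nm, x$intensities[i, ],
                  xout = x$excitation_nm[i] + delta_nm)$y,
    numeric(1))
  spectrum(ex, vals, kind = "emission_au",
           label = sprintf("synchronous dl = %g nm", delta_nm))
}

#' Local-maximum peaks of an excitation-emission matrix
#'
#' Finds strict local maxima of the intensity surface in each cell's
#' 8-neighbourhood (border cells use their available neighbours), then
#' greedily keeps the most intense peaks subject to a minimum separation:
#' a candidate is dropped only when it lies within `min_separation_nm` of
#' an accepted peak on *both* axes. Peaks are returned sorted by intensity,
#' descending.
#'
#' @param x an [eem()].
#' @param min_separation_nm minimum centre-to-centre separation (nm).
#' @return an object of class `eem_peaks`: data frame `peaks` with columns
#'   `ex_nm`, `em_nm`, `intensity` (possibly zero rows).
#' @export
eem_peaks <- function(x, min_separation_nm = 10) {
  stopifnot(inherits(x, "eem"))
  m <- x$intensities
  nr <- nrow(m); nc <- ncol(m)
  cand <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- m[i, j]
      nbr <- m[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      # strict maximum over the neighbourhood (self excluded by count)
      cand[i, j] <- sum(nbr < v) == (length(nbr) - 1L)
    }
  }
  idx <- which(cand, arr.ind = TRUE)
  peaks <- data.frame(ex_nm = numeric(0), em_nm = numeric(0),
                      intensity = numeric(0))
  if (nrow(idx) > 0) {
    df <- data.frame(ex_nm = x$excitation_nm[idx[, 1]],
                     em_nm = x$emission_nm[idx[, 2]],
                     intensity = m[idx])
    df <- df[order(-df$intensity), , drop = FALSE]
    for (k in seq_len(nrow(df))) {
      if (nrow(peaks) == 0) { peaks <- df[k, , drop = FALSE]; next }
      clash <- abs(peaks$ex_nm - df$ex_nm[k]) < min_separation_nm &
        abs(peaks$em_nm - df$em_nm[k]) < min_separation_nm
      if (!any(clash)) peaks <- rbind(peaks, df[k, , drop = FALSE])
    }
    rownames(peaks) <- NULL
  }
  structure(list(peaks = peaks, min_separation_nm = min_separation_nm),
            class = "eem_peaks")
}

#' @export
print.eem_peaks <- function(x, ...) {
  cat(sprintf("<eem_peaks> %d peak(s), min separation %g nm\n",
              nrow(x$peaks), x$min_separation_nm))
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.eem_peaks <- function(x, ...) x$peaks
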