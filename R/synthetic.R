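# Seeded generator of every input the pipeline consumes, with known ground
# truth: static-quenching titrations, donor/acceptor band pairs, EEMs, and
# CD spectra. One global seed drives an independent stream per output
# object, so generating one object never perturbs another.

gaussian_band <- function(x, centre, sigma, height = 1) {
  height * exp(-(x - centre)^2 / (2 * sigma^2))
}

# Evaluate `expr` under a deterministic RNG stream derived from
# (seed, stream), restoring the caller's RNG state afterwards.
with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) %% 20000L) * 100000L + as.integer(stream))
  eval.parent(substitute(expr))
}

#' Ground-truth specification for the synthetic-spectra generator
#'
#' Bundles every parameter of the simulated study: binding thermodynamics,
#' titration design, emission-band geometry, acceptor band, CD helix
#' content, and EEM peaks. Defaults are the conditions of a serum-albumin
#' drug-binding titration: four temperatures 298-315 K, quencher 0-25 uM in
#' 5 uM steps, 4 uM protein, tryptophan emission band at 339 nm shifting to
#' 329 nm at saturation, dH = -6.80 kcal/mol, dS = -3.30 cal/mol/K,
#' stoichiometry n = 0.93.
#'
#' @param seed integer master seed; each generated object derives its own
#'   deterministic stream from it.
#' @param temperatures_K distinct simulation temperatures (Kelvin).
#' @param dH_kcal_mol,dS_cal_mol_K binding enthalpy/entropy generating
#'   `Kb(T) = exp(-dH/(R T) + dS/R)`.
#' @param n_sites binding stoichiometry of the generating law
#'   `(F0 - F)/F = Kb [Q]^n`.
#' @param kb_override optional named numeric vector (names = temperatures in
#'   K) fixing `Kb` per temperature directly instead of the thermodynamic
#'   law.
#' @param band_centre_start_nm,band_centre_end_nm emission-band centre of
#'   the unquenched and fully quenched protein; the centre moves linearly in
#'   fractional quench between them (equal values = stationary band).
#' @param band_sigma_nm Gaussian band width (nm).
#' @param F0_peak unquenched peak intensity (arbitrary units).
#' @param quencher_concs_M titration concentrations (mol/L, first 0).
#' @param protein_conc_M protein concentration (mol/L).
#' @param noise_cv coefficient of variation of multiplicative Gaussian
#'   intensity noise (0 = noiseless).
#' @param emission_grid_nm wavelength grid of generated emission spectra.
#' @param acceptor_band list `centre_nm`, `sigma_nm`, `eps_max_M1cm1`
#'   describing the acceptor extinction band.
#' @param cd_helix_percent helix content encoded in the generated CD
#'   spectrum (0-100).
#' @param cd_conc_mg_ml,cd_path_cm,cd_M0_Da CD acquisition parameters used
#'   to convert the encoded MRE back to observed millidegrees.
#' @param eem_peak_list list of peaks, each `list(ex_nm, em_nm, height,
#'   sigma_nm)`, defining the EEM surface.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           temperatures_K = c(298, 303, 310, 315),
                           dH_kcal_mol = -6.80,
                           dS_cal_mol_K = -3.30,
                           n_sites = 0.93,
                           kb_override = NULL,
                           band_centre_start_nm = 339,
                           band_centre_end_nm = 329,
                           band_sigma_nm = 25,
                           F0_peak = 1000,
                           quencher_concs_M = seq(0, 25e-6, by = 5e-6),
                           protein_conc_M = 4e-6,
                           noise_cv = 0,
                           emission_grid_nm = seq(300, 400, by = 0.5),
                           acceptor_band = list(centre_nm = 360,
                                                sigma_nm = 20,
                                                eps_max_M1cm1 = 1e4),
                           cd_helix_percent = 62,
                           cd_conc_mg_ml = 0.264,
                           cd_path_cm = 0.1,
                           cd_M0_Da = 112.8,
                           eem_peak_list = list(
                             list(ex_nm = 280, em_nm = 335,
                                  height = 3736, sigma_nm = 12),
                             list(ex_nm = 230, em_nm = 330,
                                  height = 1097, sigma_nm = 12))) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (band_sigma_nm <= 0) stop("band_sigma_nm must be > 0", call. = FALSE)
  if (anyDuplicated(temperatures_K))
    stop("temperatures must be distinct", call. = FALSE)
  if (cd_helix_percent < 0 || cd_helix_percent > 100)
    stop("cd_helix_percent must lie in [0, 100]", call. = FALSE)
  seed <- as.integer(seed)
  structure(as.list(environment()), class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf(
    "<generator_spec> seed %d; T = %s K; dH = %.3g kcal/mol, dS = %.3g cal/mol/K, n = %.3g; noise_cv = %g\n",
    x$seed, paste(x$temperatures_K, collapse = "/"), x$dH_kcal_mol,
    x$dS_cal_mol_K, x$n_sites, x$noise_cv))
  invisible(x)
}

#' Binding constant implied by fixed enthalpy and entropy
#'
#' `Kb(T) = exp(-dH/(R T) + dS/R)` with R in kcal/mol/K — the generating
#' law inverted by [vant_hoff_fit()].
#'
#' @param dH_kcal_mol binding enthalpy (kcal/mol).
#' @param dS_cal_mol_K binding entropy (cal/mol/K).
#' @param temperature_K temperature(s) in Kelvin.
#' @return binding constant(s) in M^-1.
#' @export
kb_from_thermo <- function(dH_kcal_mol, dS_cal_mol_K, temperature_K) {
  R <- GAS_CONSTANT_KCAL
  exp(-dH_kcal_mol / (R * temperature_K) + (dS_cal_mol_K / 1000) / R)
}

#' Simulate one static-quenching titration
#'
#' Intensities follow `(F0 - F)/F = Kb [Q]^n` (the static ground-state
#' complex law; at n = 1 it reduces to `F0/F = 1 + Kb [Q]`), with `Kb` at
#' the requested temperature taken from the spec's thermodynamic law or its
#' `kb_override`. Each spectrum is a Gaussian band of amplitude `F` whose
#' centre moves linearly in fractional quench `1 - F/F0` from the start to
#' the end centre (the last titration point reaches the end centre
#' exactly). Multiplicative Gaussian noise of the spec's `noise_cv` is
#' applied per wavelength under a deterministic per-temperature stream.
#'
#' @param gspec a [generator_spec()].
#' @param temperature_K one of `gspec$temperatures_K`.
#' @return a [titration_series()].
#' @export
make_titration <- function(gspec, temperature_K) {
  stopifnot(inherits(gspec, "generator_spec"))
  ti <- match(temperature_K, gspec$temperatures_K)
  if (is.na(ti))
    stop("temperature ", temperature_K, " K is not in the generator spec",
         call. = FALSE)
  kb <- if (!is.null(gspec$kb_override)) {
    v <- gspec$kb_override[as.character(temperature_K)]
    if (is.na(v)) stop("kb_override has no entry for ", temperature_K, " K",
                       call. = FALSE)
    unname(v)
  } else {
    kb_from_thermo(gspec$dH_kcal_mol, gspec$dS_cal_mol_K, temperature_K)
  }
  q <- gspec$quencher_concs_M
  f <- gspec$F0_peak / (1 + kb * ifelse(q > 0, q^gspec$n_sites, 0))
  fq <- 1 - f / gspec$F0_peak
  centre <- if (max(fq) > 0) {
    gspec$band_centre_start_nm +
      (gspec$band_centre_end_nm - gspec$band_centre_start_nm) * fq / max(fq)
  } else rep(gspec$band_centre_start_nm, length(q))
  grid <- gspec$emission_grid_nm
  spectra <- with_stream_seed(gspec$seed, 100L + ti, {
    lapply(seq_along(q), function(i) {
      v <- gaussian_band(grid, centre[i], gspec$band_sigma_nm, f[i])
      if (gspec$noise_cv > 0)
        v <- v * (1 + gspec$noise_cv * stats::rnorm(length(v)))
      spectrum(grid, v, kind = "emission_au",
               label = sprintf("[Q]=%.3g M, %g K", q[i], temperature_K))
    })
  })
  titration_series(temperature_K = temperature_K,
                   protein_conc_M = gspec$protein_conc_M,
                   quencher_concs_M = q, spectra = spectra)
}

#' Simulate an overlapping donor-emission / acceptor-extinction band pair
#'
#' Gaussian donor emission (centre and width from the spec's emission band)
#' and Gaussian acceptor extinction (the spec's `acceptor_band`), both on
#' 0.5 nm grids. Because both bands are analytic Gaussians, the exact
#' overlap integral is available from a dense-grid quadrature of the same
#' band functions, which the test-suite uses as an independent oracle.
#'
#' @param gspec a [generator_spec()].
#' @param grid_step_nm grid spacing (nm).
#' @return list with elements `donor` and `acceptor`, both [spectrum()]s.
#' @export
make_fret_pair <- function(gspec, grid_step_nm = 0.5) {
  stopifnot(inherits(gspec, "generator_spec"))
  ab <- gspec$acceptor_band
  dgrid <- seq(280, 460, by = grid_step_nm)
  agrid <- seq(250, 470, by = grid_step_nm)
  donor <- spectrum(dgrid,
                    gaussian_band(dgrid, gspec$band_centre_start_nm,
                                  gspec$band_sigma_nm, gspec$F0_peak),
                    kind = "emission_au", label = "synthetic donor")
  acceptor <- spectrum(agrid,
                       gaussian_band(agrid, ab$centre_nm, ab$sigma_nm,
                                     ab$eps_max_M1cm1),
                       kind = "molar_extinction_M1cm1",
                       label = "synthetic acceptor")
  list(donor = donor, acceptor = acceptor)
}

#' Simulate an excitation-emission matrix
#'
#' Sum of separable Gaussian peaks at the spec's positions and heights, on
#' a 5 nm excitation grid (the conventional 3D-scan increment) and a 5 nm
#' emission grid. Optional multiplicative noise uses its own seed stream.
#'
#' @param gspec a [generator_spec()].
#' @param excitation_nm,emission_nm wavelength grids.
#' @return an [eem()].
#' @export
make_eem <- function(gspec,
                     excitation_nm = seq(220, 400, by = 5),
                     emission_nm = seq(250, 450, by = 5)) {
  stopifnot(inherits(gspec, "generator_spec"))
  if (length(gspec$eem_peak_list) < 1L)
    stop("the generator spec defines no EEM peaks", call. = FALSE)
  m <- matrix(0, nrow = length(excitation_nm), ncol = length(emission_nm))
  for (p in gspec$eem_peak_list) {
    m <- m + outer(gaussian_band(excitation_nm, p$ex_nm, p$sigma_nm),
                   gaussian_band(emission_nm, p$em_nm, p$sigma_nm)) * p$height
  }
  if (gspec$noise_cv > 0) {
    m <- with_stream_seed(gspec$seed, 200L,
                          m * (1 + gspec$noise_cv *
                                 matrix(stats::rnorm(length(m)), nrow(m))))
  }
  eem(excitation_nm, emission_nm, m)
}

#' Simulate a far-UV CD spectrum of known helix content
#'
#' Builds a double-minimum ellipticity spectrum (negative Gaussian bands
#' near 209 and 222 nm, the alpha-helical signature) whose mean-residue
#' ellipticity at the 222 nm grid point is exactly
#' `-(2340 + 303 * helix_percent)`, then converts to observed millidegrees
#' for the spec's concentration, path length and mean residue weight. The
#' full CD pipeline therefore recovers `helix_percent` exactly.
#'
#' @param gspec a [generator_spec()].
#' @param grid_nm wavelength grid (must contain 222 nm).
#' @return a [spectrum()] of kind `ellipticity_mdeg`.
#' @export
make_cd <- function(gspec, grid_nm = seq(200, 250, by = 0.5)) {
  stopifnot(inherits(gspec, "generator_spec"))
  h <- gspec$cd_helix_percent
  target_mre_222 <- -(2340 + 303 * h)
  shape <- gaussian_band(grid_nm, 222, 6) + 0.9 * gaussian_band(grid_nm, 209, 5)
  i222 <- which.min(abs(grid_nm - 222))
  mre <- target_mre_222 * shape / shape[i222]
  theta <- mre * (10 * gspec$cd_path_cm * gspec$cd_conc_mg_ml) / gspec$cd_M0_Da
  spectrum(grid_nm, theta, kind = "ellipticity_mdeg",
           label = sprintf("synthetic CD, %.1f%% helix", h))
}

#' Write a complete simulated dataset to disk
#'
#' Generates and writes one titration file per temperature, the
#' donor/acceptor band pair, the EEM, and the CD spectrum, using the file
#' formats the readers in this package consume. Deterministic for a fixed
#' spec.
#'
#' @param gspec a [generator_spec()].
#' @param dir output directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
simulate_dataset <- function(gspec, dir) {
  stopifnot(inherits(gspec, "generator_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (tk in gspec$temperatures_K) {
    p <- file.path(dir, sprintf("titration_%gK.tsv", tk))
    write_titration(make_titration(gspec, tk), p)
    files[sprintf("titration_%g", tk)] <- p
  }
  pair <- make_fret_pair(gspec)
  files["donor"] <- file.path(dir, "donor_emission.tsv")
  write_spectrum(pair$donor, files["donor"])
  files["acceptor"] <- file.path(dir, "acceptor_extinction.tsv")
  write_spectrum(pair$acceptor, files["acceptor"])
  files["eem"] <- file.path(dir, "eem.tsv")
  write_eem(make_eem(gspec), files["eem"])
  files["cd"] <- file.path(dir, "cd.tsv")
  write_spectrum(make_cd(gspec), files["cd"])
  invisible(files)
}
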