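test_that("mean-residue ellipticity matches hand arithmetic and scales correctly", {
  grid <- seq(200, 250, by = 1)
  theta <- spectrum(grid, rep(-10, length(grid)), "ellipticity_mdeg")
  mre <- mean_residue_ellipticity(theta, conc_mg_ml = 0.264, path_cm = 0.1,
                                  M0_Da = 112.8)
  expect_equal(mre$kind, "mre_deg_cm2_dmol")
  # -10 * 112.8 / (10 * 0.1 * 0.264)
  expect_equal(mre$values, rep(-4272.727272727, length(grid)),
               tolerance = 1e-9)

  # zero in, zero out
  zero <- spectrum(grid, rep(0, length(grid)), "ellipticity_mdeg")
  expect_equal(mean_residue_ellipticity(zero, 0.264, 0.1)$values,
               rep(0, length(grid)))

  # linear in the input, inversely proportional to c and l
  set.seed(3)
  vals <- rnorm(length(grid), -10, 3)
  th2 <- spectrum(grid, vals, "ellipticity_mdeg")
  base <- mean_residue_ellipticity(th2, 0.264, 0.1)$values
  for (k in c(0.5, 2, 3.7)) {
    scaled_in <- spectrum(grid, vals * k, "ellipticity_mdeg")
    expect_equal(mean_residue_ellipticity(scaled_in, 0.264, 0.1)$values,
                 base * k, tolerance = 1e-12)
    expect_equal(mean_residue_ellipticity(th2, 0.264 * k, 0.1)$values,
                 base / k, tolerance = 1e-12)
    expect_equal(mean_residue_ellipticity(th2, 0.264, 0.1 * k)$values,
                 base / k, tolerance = 1e-12)
  }
  expect_error(mean_residue_ellipticity(th2, 0, 0.1), "> 0")
  expect_error(mean_residue_ellipticity(th2, 0.264, -1), "> 0")
})

test_that("helix percent formula hits its endpoints and is linear between them", {
  expect_equal(helix_percent(-32640), 100)
  expect_equal(helix_percent(-2340), 0)
  expect_equal(helix_percent(-17490), 50)
  # linearity between endpoints
  mre <- seq(-32640, -2340, length.out = 11)
  expect_equal(helix_percent(mre), seq(100, 0, length.out = 11),
               tolerance = 1e-12)
  # outside [0, 100]: unclamped, with a warning
  expect_warning(h <- helix_percent(-40000), "unclamped")
  expect_gt(h, 100)
})

test_that("molar absorptivity applies Beer-Lambert pointwise", {
  grid <- seq(240, 340, by = 1)
  a <- spectrum(grid, rep(0.365, length(grid)), "absorbance")
  eps <- molar_absorptivity(a, conc_M = 1e-5, path_cm = 1)
  # the reference extinction coefficient of the protein at 280 nm
  expect_equal(spectrum_at(eps, 280), 36500, tolerance = 1e-12)

  zero <- spectrum(grid, rep(0, length(grid)), "absorbance")
  expect_equal(molar_absorptivity(zero, 1e-5, 1)$values,
               rep(0, length(grid)))

  # halving the path doubles epsilon for fixed absorbance
  expect_equal(molar_absorptivity(a, 1e-5, 0.5)$values,
               molar_absorptivity(a, 1e-5, 1)$values * 2, tolerance = 1e-12)
  expect_error(molar_absorptivity(a, 0, 1), "> 0")
})

test_that("hyperchromicity reads programmed intensity changes at a wavelength", {
  grid <- seq(240, 340, by = 1)
  mk <- function(scale) spectrum(grid, scale * exp(-(grid - 278)^2 / 800),
                                 "absorbance")
  rise <- titration_series(298, 1e-5, c(0, 25e-6), list(mk(1), mk(1.35)))
  expect_equal(hyperchromicity(rise, 278), 35, tolerance = 1e-9)

  same <- titration_series(298, 1e-5, c(0, 25e-6), list(mk(1), mk(1)))
  expect_equal(hyperchromicity(same, 278), 0)

  fall <- titration_series(298, 1e-5, c(0, 25e-6), list(mk(1), mk(0.8)))
  expect_equal(hyperchromicity(fall, 278), -20, tolerance = 1e-9)

  zero_base <- titration_series(
    298, 1e-5, c(0, 25e-6),
    list(spectrum(grid, rep(0, length(grid)), "absorbance"), mk(1)))
  expect_error(hyperchromicity(zero_base, 278), "zero")
})

test_that("synchronous traces sample the em = ex + delta diagonal", {
  # constant surface: flat trace of 1
  flat <- eem(seq(240, 320, 5), seq(260, 420, 5),
              matrix(1, 17, 33))
  tr <- synchronous_trace(flat, 60)
  expect_true(all(abs(tr$values - 1) < 1e-12))

  # a ridge along em = ex + 60 appears in the delta = 60 trace only
  ex <- seq(240, 320, 2); em <- seq(260, 420, 2)
  ridge <- outer(ex, em, function(x, y)
    exp(-((y - x - 60)^2) / 20) * exp(-(x - 280)^2 / 400))
  x <- eem(ex, em, ridge)
  t60 <- synchronous_trace(x, 60)
  t15 <- synchronous_trace(x, 15)
  expect_equal(t60$values, exp(-(t60$wavelengths_nm - 280)^2 / 400),
               tolerance = 1e-9)
  expect_lt(max(t15$values), 1e-6)
  # ridge profile peaks at its programmed excitation centre
  expect_equal(peak_wavelength(t60), 280)

  expect_error(synchronous_trace(x, -15), "> 0")
  expect_error(synchronous_trace(x, 500), "intersect")
})

test_that("a stationary band shows no shift in its synchronous trace", {
  # tyrosine-like band fixed across a titration: delta = 15 trace of the
  # bound and free forms peaks at the same excitation wavelength
  ex <- seq(240, 320, 2); em <- seq(260, 420, 2)
  surf <- function(height) outer(ex, em, function(x, y)
    height * exp(-(x - 275)^2 / 200) * exp(-(y - 290)^2 / 300))
  tr_free <- synchronous_trace(eem(ex, em, surf(1)), 15)
  tr_bound <- synchronous_trace(eem(ex, em, surf(0.6)), 15)
  expect_equal(peak_wavelength(tr_free), peak_wavelength(tr_bound))
})

test_that("EEM peak extraction recovers programmed Gaussian maxima", {
  gs <- generator_spec()
  pk <- eem_peaks(make_eem(gs))
  expect_equal(nrow(pk$peaks), 2)
  # sorted by intensity, descending; positions exact on the grid
  expect_equal(pk$peaks$ex_nm, c(280, 230))
  expect_equal(pk$peaks$em_nm, c(335, 330))
  expect_equal(pk$peaks$intensity, c(3736, 1097), tolerance = 0.01)
  expect_true(all(diff(pk$peaks$intensity) < 0))

  # constant matrix: no strict local maxima
  flat <- eem(seq(240, 300, 5), seq(300, 400, 5), matrix(5, 13, 21))
  expect_equal(nrow(eem_peaks(flat)$peaks), 0)

  # a single Gaussian yields exactly one peak at its centre
  one <- generator_spec(eem_peak_list = list(
    list(ex_nm = 280, em_nm = 340, height = 100, sigma_nm = 15)))
  pk1 <- eem_peaks(make_eem(one))
  expect_equal(nrow(pk1$peaks), 1)
  expect_equal(pk1$peaks$ex_nm, 280)
  expect_equal(pk1$peaks$em_nm, 340)
})

test_that("minimum separation suppresses near-duplicate maxima only", {
  # two peaks close on both axes: the weaker one is dropped
  close_spec <- generator_spec(eem_peak_list = list(
    list(ex_nm = 280, em_nm = 340, height = 100, sigma_nm = 4),
    list(ex_nm = 287, em_nm = 346, height = 60, sigma_nm = 4)))
  pk <- eem_peaks(make_eem(close_spec), min_separation_nm = 10)
  expect_equal(nrow(pk$peaks), 1)
  expect_equal(pk$peaks$ex_nm, 280)
  # separated on one axis is enough to keep both
  pk2 <- eem_peaks(make_eem(generator_spec()), min_separation_nm = 10)
  expect_equal(nrow(pk2$peaks), 2)
})
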