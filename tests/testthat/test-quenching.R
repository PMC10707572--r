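test_that("inner-filter correction matches hand-computed values and is monotone", {
  expect_equal(correct_inner_filter(100, 0, 0), 100)
  expect_equal(correct_inner_filter(100, 1, 1), 100 * exp(1))
  expect_equal(correct_inner_filter(50, 0.2, 0.1), 50 * exp(0.15),
               tolerance = 1e-12)
  expect_error(correct_inner_filter(100, -0.1, 0), "absorbances")
  expect_error(correct_inner_filter(-1, 0.1, 0), "intensities")

  # monotone non-decreasing in A_ex + A_em
  a <- seq(0, 2, by = 0.05)
  expect_true(all(diff(correct_inner_filter(100, a, 0.3)) > 0))
})

test_that("intensity readout modes behave as defined", {
  s <- manual_series(c(0, 5e-6), c(100, 100))
  expect_equal(intensity_at_readout(s), c(100, 100))  # identical spectra

  # fixed mode reads every spectrum at the baseline peak wavelength
  grid <- seq(300, 400, by = 1)
  sp0 <- spectrum(grid, exp(-(grid - 340)^2 / 50) * 100, "emission_au")
  sp1 <- spectrum(grid, exp(-(grid - 350)^2 / 50) * 80, "emission_au")
  ser <- titration_series(298, 4e-6, c(0, 5e-6), list(sp0, sp1))
  fixed <- intensity_at_readout(ser, run_config())
  expect_equal(fixed[1], 100)
  expect_equal(fixed[2], spectrum_at(sp1, 340))
  permax <- intensity_at_readout(
    ser, run_config(intensity_readout = "per_spectrum_max"))
  expect_equal(permax, c(100, 80))

  # inner-filter correction applied first when absorbances are present
  ser_a <- titration_series(298, 4e-6, c(0, 5e-6), list(sp0, sp1),
                            excitation_absorbances = c(0, 0.2),
                            emission_absorbances = c(0, 0.1))
  corr <- intensity_at_readout(ser_a, run_config())
  expect_equal(corr[2], spectrum_at(sp1, 340) * exp(0.15))
})

test_that("Stern-Volmer fit recovers noiseless generating constants exactly", {
  for (ksv in c(3.82e4, 2.17e4)) {
    q <- seq(0, 25e-6, by = 5e-6)
    ser <- manual_series(q, 1000 / (1 + ksv * q))
    res <- stern_volmer_fit(ser)
    expect_equal(res$Ksv_M1, ksv, tolerance = 1e-9)
    expect_equal(res$intercept, 1, tolerance = 1e-9)
    expect_equal(res$r_squared, 1, tolerance = 1e-12)
    expect_equal(res$kq_M1s1, ksv / 1e-8, tolerance = 1e-9)
  }
})

test_that("Stern-Volmer fit handles degenerate and invalid inputs", {
  q <- seq(0, 25e-6, by = 5e-6)
  flat <- manual_series(q, rep(500, length(q)))
  res <- stern_volmer_fit(flat)
  expect_lt(abs(res$Ksv_M1), 1e-6)   # numerically zero slope in M^-1
  expect_equal(res$r_squared, 1)          # a constant is fit perfectly

  expect_error(stern_volmer_fit(manual_series(c(0, 5e-6), c(10, 9))),
               "at least 3")
  zero <- manual_series(c(0, 5e-6, 10e-6), c(10, 5, 0))
  expect_error(stern_volmer_fit(zero), "positive")
})

test_that("bimolecular rate is Ksv / tau0", {
  expect_equal(bimolecular_rate(3.82e4, 1e-8), 3.82e12)
  expect_equal(bimolecular_rate(0, 1e-8), 0)
  expect_equal(bimolecular_rate(2.17e4, 1e-8), 2.17e12)
  expect_error(bimolecular_rate(1e4, 0), "tau0")
})

test_that("double-log fit recovers Kb and n exactly on noiseless data", {
  q <- seq(0, 25e-6, by = 5e-6)
  cases <- list(c(kb = 1.89e4, n = 0.93), c(kb = 1e4, n = 1))
  for (cs in cases) {
    f <- 1000 / (1 + cs["kb"] * ifelse(q > 0, q^cs["n"], 0))
    res <- double_log_fit(manual_series(q, f))
    expect_equal(res$Kb_M1, unname(cs["kb"]), tolerance = 1e-9)
    expect_equal(res$n_sites, unname(cs["n"]), tolerance = 1e-9)
    expect_equal(res$r_squared, 1, tolerance = 1e-12)
    expect_equal(res$n_excluded, 0)
  }
  # n = 1, Kb = 1e4: slope 1, intercept 4 in log10 space
  f <- 1000 / (1 + 1e4 * q)
  res <- double_log_fit(manual_series(q, f))
  expect_equal(log10(res$Kb_M1), 4, tolerance = 1e-9)
})

test_that("double-log fit excludes unquenched points and counts them", {
  q <- seq(0, 25e-6, by = 5e-6)
  f <- 1000 / (1 + 1.89e4 * q)
  f[2] <- 1000                     # F = F0 at the smallest [Q]: excluded
  res <- double_log_fit(manual_series(q, f))
  expect_equal(res$n_excluded, 1)
  expect_equal(res$n_points, 4)
  expect_equal(res$Kb_M1, 1.89e4, tolerance = 1e-9)

  few <- manual_series(c(0, 5e-6, 10e-6, 15e-6),
                       c(1000, 1000, 1000, 900))
  expect_error(double_log_fit(few), "at least 3")
})

test_that("both fits recover random generating parameters across the working range", {
  set.seed(7)
  q <- seq(0, 25e-6, by = 5e-6)
  for (i in 1:20) {
    ksv <- 10^runif(1, 3, 7)
    n <- runif(1, 0.5, 2)
    f <- 1000 / (1 + ksv * ifelse(q > 0, q^n, 0))
    ser <- manual_series(q, f)
    dl <- double_log_fit(ser)
    expect_equal(dl$Kb_M1, ksv, tolerance = 1e-9)
    expect_equal(dl$n_sites, n, tolerance = 1e-9)
    if (abs(n - 1) < 1e-12) {
      expect_equal(stern_volmer_fit(ser)$Ksv_M1, ksv, tolerance = 1e-9)
    }
  }
  # linear law: Stern-Volmer slope across the same Ksv range
  for (ksv in 10^seq(3, 7, by = 1)) {
    ser <- manual_series(q, 1000 / (1 + ksv * q))
    expect_equal(stern_volmer_fit(ser)$Ksv_M1, ksv, tolerance = 1e-9)
  }
})

test_that("emission shift reports signed band movement with grid argmax", {
  # blue shift 339 -> 329 nm across a titration
  ser <- make_titration(generator_spec(), 298)
  sh <- emission_shift(ser)
  expect_equal(sh$shift_nm, -10)
  expect_equal(sh$lambda_max_start_nm, 339)
  expect_equal(sh$lambda_max_end_nm, 329)
  expect_false(sh$flat)

  # identical spectra: zero shift
  expect_equal(emission_shift(manual_series(c(0, 5e-6), c(10, 10)))$shift_nm, 0)

  # red shift 330 -> 338
  red <- make_titration(
    generator_spec(band_centre_start_nm = 330, band_centre_end_nm = 338), 298)
  expect_equal(emission_shift(red)$shift_nm, +8)

  # flat spectrum: tie broken toward shorter wavelength and flagged
  grid <- seq(300, 400, by = 1)
  flat_sp <- spectrum(grid, rep(1, length(grid)), "emission_au")
  flat <- titration_series(298, 4e-6, c(0, 5e-6), list(flat_sp, flat_sp))
  sh_flat <- emission_shift(flat)
  expect_true(sh_flat$flat)
  expect_equal(sh_flat$lambda_max_start_nm, 300)

  expect_error(emission_shift(manual_series(0, 10)), "at least 2")
})

test_that("parabolic refinement locates off-grid Gaussian band centres", {
  grid <- seq(300, 400, by = 1)
  centre <- 339.4                         # off-grid
  sp0 <- spectrum(grid, exp(-(grid - centre)^2 / (2 * 225)), "emission_au")
  sp1 <- spectrum(grid, exp(-(grid - (centre - 7.2))^2 / (2 * 225)),
                  "emission_au")
  ser <- titration_series(298, 4e-6, c(0, 25e-6), list(sp0, sp1))
  sh <- emission_shift(ser, refine = TRUE)
  expect_equal(sh$shift_nm, -7.2, tolerance = 1e-2)
})
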