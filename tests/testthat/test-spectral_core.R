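test_that("nm/eV conversion reproduces reported wavelength-energy pairs", {
  expect_equal(round_half_up(nm_to_ev(678), 2), 1.83)
  expect_equal(round_half_up(nm_to_ev(612), 2), 2.03)
  expect_equal(round_half_up(nm_to_ev(664), 2), 1.87)
  # roundtrip exact to 1e-10 relative over a wavelength sweep
  lam <- seq(200, 1200, by = 7.3)
  expect_equal(ev_to_nm(nm_to_ev(lam)), lam, tolerance = 1e-10)
  expect_error(nm_to_ev(0), "positive")
  expect_error(ev_to_nm(-1), "positive")
})

test_that("energy shifts between wavelengths match reported meV values", {
  expect_equal(round_half_up(energy_shift_mev(678, 664)), 39)
  expect_equal(round_half_up(energy_shift_mev(664, 658)), 17)
  expect_equal(energy_shift_mev(532, 532), 0)
  # blue shift positive, red shift negative
  expect_gt(energy_shift_mev(700, 650), 0)
  expect_lt(energy_shift_mev(650, 700), 0)
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(c(1, 2), c(1, 2, 3)), "length")
  expect_error(spectrum(c(2, 1, 3), c(0, 0, 0)), "increasing")
  expect_error(spectrum(c(1, 2, 2), c(0, 0, 0)), "increasing")
  expect_error(spectrum(c(1, NA, 3), c(0, 0, 0)), "finite")
  expect_error(spectrum(c(1, 2), c(0, Inf)), "finite")
  expect_error(spectrum(1, 1), "length")
})

test_that("baseline correction zeroes the minimum, preserves shape, idempotent", {
  sp <- spectrum(c(1, 2, 3), c(0.05, 0.25, 0.10))
  bc <- baseline_correct(sp)
  expect_equal(bc$values, c(0.00, 0.20, 0.05))
  expect_equal(min(bc$values), 0, tolerance = 1e-12)
  # all pairwise differences preserved
  expect_equal(outer(bc$values, bc$values, "-"),
               outer(sp$values, sp$values, "-"))
  expect_equal(baseline_correct(bc)$values, bc$values)
  flat <- baseline_correct(spectrum(1:5, rep(0.3, 5)))
  expect_equal(flat$values, rep(0, 5))
})

test_that("energy offset red-shifts for positive argument and round-trips", {
  g <- energy_grid(1.8, 2.5, 0.002)
  sp <- gaussian_spectrum(2.14, 0.022, g)
  red <- apply_energy_offset(sp, 0.056)
  expect_equal(red$energies[which.max(red$values)], 2.14 - 0.056,
               tolerance = 0.002)
  # reported shift arithmetic: 2.14 - 0.056 = 2.08, 2.25 - 0.32 = 1.93
  expect_equal(round_half_up(2.14 - 0.056, 2), 2.08)
  expect_equal(round_half_up(2.25 - 0.32, 2), 1.93)
  back <- apply_energy_offset(red, -0.056)
  expect_equal(back$energies, sp$energies)
  expect_identical(apply_energy_offset(sp, 0)$energies, sp$energies)
  st <- stick_spectrum(c(2.14, 2.2), c(1, 0.3))
  expect_equal(apply_energy_offset(st, 0.21)$lines$energy, c(1.93, 1.99))
})

test_that("Gaussian convolution conserves area and handles edge cases", {
  g <- energy_grid(1.5, 2.5, 0.002)
  one <- convolve_gaussian(stick_spectrum(2.0, 1), width = 0.022, grid = g)
  expect_equal(spectrum_area(one), 1, tolerance = 1e-3)
  expect_equal(one$energies[which.max(one$values)], 2.0, tolerance = 0.002)
  # intensity-weighted multi-stick area
  st <- stick_spectrum(c(1.9, 2.0, 2.2), c(0.5, 1.2, 0.3))
  sp <- convolve_gaussian(st, width = 0.022, grid = g)
  expect_equal(spectrum_area(sp), 2.0, tolerance = 2e-3)
  # empty stick list: flat zero
  z <- convolve_gaussian(stick_spectrum(), width = 0.022, grid = g)
  expect_true(all(z$values == 0))
  # fwhm convention is narrower in sigma, hence taller at the peak
  sp_f <- suppressWarnings(convolve_gaussian(st, width = 0.022, grid = g,
                                             width_type = "fwhm"))
  expect_gt(max(sp_f$values), max(sp$values))
  expect_warning(convolve_gaussian(st, width = 0.022,
                                   grid = energy_grid(1.5, 2.5, 0.01)),
                 "spacing")
  expect_warning(convolve_gaussian(st, width = 0.022,
                                   grid = energy_grid(1.95, 2.1, 0.002)),
                 "cover")
})

test_that("two-line doublet gives one peak near the 0-0 and one shoulder", {
  # strong line plus an unresolved satellite 56 meV above
  g <- energy_grid(1.9, 2.45, 0.002)
  st <- stick_spectrum(c(2.14, 2.196), c(1.0, 0.45))
  sp <- convolve_gaussian(st, width = 0.022, grid = g)
  ps <- detect_peaks(sp)
  expect_equal(nrow(ps$peaks), 1L)
  expect_equal(ps$peaks$energy, 2.14, tolerance = 2e-3)
  expect_equal(nrow(ps$shoulders), 1L)
  expect_gt(ps$shoulders$energy, 2.17)
  expect_lt(ps$shoulders$energy, 2.22)
})

test_that("peak detection resolves well-separated Gaussians at their centers", {
  g <- energy_grid(1.5, 3.0, 0.002)
  centers <- c(1.8, 2.1, 2.45, 2.8)  # separations > 6 sigma
  st <- stick_spectrum(centers, c(1, 0.8, 0.9, 0.7))
  ps <- detect_peaks(convolve_gaussian(st, width = 0.02, grid = g))
  expect_equal(nrow(ps$peaks), length(centers))
  expect_equal(ps$peaks$energy, centers, tolerance = 0.002)
  expect_equal(nrow(ps$shoulders), 0L)
  # single Gaussian: one peak, no shoulder
  ps1 <- detect_peaks(gaussian_spectrum(2.0, 0.03, g))
  expect_equal(nrow(ps1$peaks), 1L)
  expect_equal(nrow(ps1$shoulders), 0L)
})

test_that("peak detection rejects unusable inputs", {
  g <- energy_grid(1.5, 2.5, 0.02)
  sp <- gaussian_spectrum(2.0, 0.1, g)
  expect_error(detect_peaks(sp, smoothing = 0.01), "too coarse")
  short <- gaussian_spectrum(2.0, 0.1, energy_grid(1.99, 2.01, 0.002))
  expect_error(detect_peaks(short, smoothing = 0.05), "window")
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  g <- energy_grid(1.8, 2.4, 0.01)
  sp <- spectrum(g, 3 * g - 1)          # affine data: interpolation exact
  fine <- resample_spectrum(sp, energy_grid(1.85, 2.35, 0.003))
  expect_equal(fine$values, 3 * fine$energies - 1, tolerance = 1e-12)
  # identity on own grid
  self <- resample_spectrum(sp, g)
  expect_equal(self$values, sp$values)
  # area preserved on halved spacing
  gs <- gaussian_spectrum(2.1, 0.05, g)
  half <- resample_spectrum(gs, energy_grid(1.8, 2.4, 0.005))
  expect_equal(spectrum_area(half), spectrum_area(gs), tolerance = 1e-3)
  expect_error(resample_spectrum(sp, energy_grid(1.7, 2.3, 0.01)),
               "extrapolation")
})

test_that("peak sets serialize to the documented JSON schema", {
  g <- energy_grid(1.5, 2.5, 0.002)
  st <- stick_spectrum(c(1.9, 2.3), c(1, 0.8))
  ps <- detect_peaks(convolve_gaussian(st, width = 0.022, grid = g))
  txt <- peak_set_json(ps)
  parsed <- jsonlite::fromJSON(txt)
  expect_named(parsed, c("peaks", "shoulders"))
  expect_equal(parsed$peaks$energy_ev, ps$peaks$energy)
  expect_true(all(c("energy_ev", "height", "score") %in%
                    names(parsed$peaks)))
})
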