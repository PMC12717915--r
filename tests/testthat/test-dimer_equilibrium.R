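test_that("speciation solves the quadratic equilibrium exactly", {
  # k_d = 1000 M^-1, c_i = 5e-4 M: closed form (-1+sqrt(5))/4000
  sp <- speciate(1000, 5e-4)
  expect_equal(sp$monomer_conc, (-1 + sqrt(5)) / 4000, tolerance = 1e-12)
  expect_equal(sp$monomer_conc, 3.0902e-4, tolerance = 1e-4)
  expect_equal(sp$dimer_conc, 9.549e-5, tolerance = 1e-4)
  # substituting back recovers K_D
  expect_equal(sp$dimer_conc / sp$monomer_conc^2, 1000, tolerance = 1e-10)
  # no-dimerization limit
  sp0 <- speciate(0, 5e-4)
  expect_equal(sp0$monomer_conc, 5e-4)
  expect_equal(sp0$dimer_conc, 0)
  # dominant-balance limit at k_d c_i >> 1
  spl <- speciate(1e9, 1e-2)
  expect_equal(spl$monomer_conc, sqrt(1e-2 / 2e9), tolerance = 1e-3)
  expect_error(speciate(-1, 1e-4), ">= 0")
  expect_error(speciate(100, 0), "> 0")
})

test_that("mass balance holds to 1e-12 relative over 6 decades each", {
  for (kd in 10^seq(-2, 4)) for (ci in 10^seq(-7, -1)) {
    sp <- speciate(kd, ci)
    expect_equal(sp$monomer_conc + 2 * sp$dimer_conc, ci,
                 tolerance = 1e-12)
    expect_gte(sp$monomer_conc, 0)
    expect_gte(sp$dimer_conc, 0)
  }
})

test_that("speciation matches a brute-force root finder to 1e-10", {
  for (kd in 10^seq(-2, 4, by = 1.5)) for (ci in 10^seq(-7, -1, by = 1.5)) {
    expect_equal(speciate(kd, ci)$monomer_conc, speciate_root(kd, ci),
                 tolerance = 1e-10)
  }
})

test_that("series and closed-form branches agree across the switch", {
  ci <- 4e-4
  # k_d c_i crosses 1e-4 at k_d = 0.25; probe both sides of the switch
  for (kd in c(0.24, 0.24999, 0.25001, 0.26)) {
    expect_equal(speciate(kd, ci)$monomer_conc, speciate_root(kd, ci),
                 tolerance = 1e-10)
  }
  below <- speciate(0.25 * (1 - 1e-12), ci)$monomer_conc
  above <- speciate(0.25 * (1 + 1e-12), ci)$monomer_conc
  expect_equal(below, above, tolerance = 1e-10)
})

test_that("monomer fraction decreases in both k_d and c_i", {
  kds <- 10^seq(0, 5, by = 0.5)
  frac_kd <- vapply(kds, function(k) {
    speciate(k, 4e-4)$monomer_conc / 4e-4
  }, numeric(1L))
  expect_true(all(diff(frac_kd) < 0))
  cis <- 10^seq(-6, -2, by = 0.5)
  frac_ci <- vapply(cis, function(ci) {
    speciate(2e3, ci)$monomer_conc / ci
  }, numeric(1L))
  expect_true(all(diff(frac_ci) < 0))
})

test_that("composite spectrum implements the superposition verbatim", {
  g <- seq(1, 3, by = 0.5)
  rect <- spectrum(g, rep(1, length(g)))     # unit-height basis
  zero <- spectrum(g, rep(0, length(g)))
  model <- dimerization_model(1000, 5e-4, eps_m = 1, eps_d = 1)
  sp <- speciate(1000, 5e-4)
  # hand evaluation: eps_m [M] * 1 + eps_d [D] * 1 + eps_d [D] * 1
  comp <- composite_spectrum(model, rect, rect, rect)
  expect_equal(comp$values,
               rep(sp$monomer_conc + 2 * sp$dimer_conc, length(g)))
  # full [D] on EACH conformer term in verbatim mode
  comp_a <- composite_spectrum(model, zero, rect, zero)
  expect_equal(comp_a$values, rep(sp$dimer_conc, length(g)))
  # split mode halves each conformer factor
  comp_s <- composite_spectrum(model, zero, rect, zero,
                               conformer_weighting = "split")
  expect_equal(comp_s$values, rep(sp$dimer_conc / 2, length(g)))
  # zero dimer bases leave the monomer term
  comp_m <- composite_spectrum(model, rect, zero, zero)
  expect_equal(comp_m$values, rep(sp$monomer_conc, length(g)))
  # k_d = 0: proportional to eps_m C_i A_M
  comp0 <- composite_spectrum(dimerization_model(0, 5e-4, 2, 1),
                              rect, rect, rect)
  expect_equal(comp0$values, rep(2 * 5e-4, length(g)))
})

test_that("composite spectrum is linear in bases and homogeneous in eps", {
  g <- energy_grid(1.9, 2.4, 0.01)
  a_m <- gaussian_spectrum(2.14, 0.03, g)
  a_da <- gaussian_spectrum(2.25, 0.022, g)
  a_db <- gaussian_spectrum(2.23, 0.022, g)
  m1 <- dimerization_model(2e3, 4e-4, 3, 5)
  base <- composite_spectrum(m1, a_m, a_da, a_db)
  # doubling one basis adds exactly its weighted contribution
  a_m2 <- a_m; a_m2$values <- 2 * a_m$values
  doubled <- composite_spectrum(m1, a_m2, a_da, a_db)
  sp <- speciate(2e3, 4e-4)
  expect_equal(doubled$values - base$values,
               3 * sp$monomer_conc * a_m$values, tolerance = 1e-12)
  # scaling both eps scales the whole spectrum
  m2 <- dimerization_model(2e3, 4e-4, 6, 10)
  expect_equal(composite_spectrum(m2, a_m, a_da, a_db)$values,
               2 * base$values, tolerance = 1e-12)
  # grid mismatch is an error
  a_bad <- gaussian_spectrum(2.25, 0.022, energy_grid(1.9, 2.4, 0.02))
  expect_error(composite_spectrum(m1, a_m, a_bad, a_db), "common")
})

test_that("dimer shift probe moves bands rigidly and round-trips", {
  g <- energy_grid(1.7, 2.6, 0.002)
  a_da <- make_dimer_bands("parallel", grid = g)
  a_db <- make_dimer_bands("antiparallel", grid = g)
  sh <- dimer_shift_sensitivity(a_da, a_db, 0.02)
  expect_equal(sh$a_da$energies[which.max(sh$a_da$values)], 2.23,
               tolerance = 0.002)
  back <- dimer_shift_sensitivity(sh$a_da, sh$a_db, -0.02)
  expect_equal(back$a_da$energies, a_da$energies)
  expect_error(dimer_shift_sensitivity(a_da, a_db, 0.2), "force")
  forced <- dimer_shift_sensitivity(a_da, a_db, 0.2, force = TRUE)
  expect_equal(forced$a_da$energies, a_da$energies - 0.2)
})

test_that("dimer band share of the composite rises with concentration", {
  g <- energy_grid(1.85, 2.5, 0.004)
  ser <- make_dilution_series(seed = 3, noise_sigma_rel = 0)
  # integrate the dimer region (> 2.21 eV) relative to the whole band
  share <- vapply(ser, function(s) {
    sp <- s$spectrum
    hi <- sp$energies > 2.21
    sum(sp$values[hi]) / sum(sp$values)
  }, numeric(1L))
  cis <- vapply(ser, `[[`, numeric(1L), "concentration")
  expect_true(all(diff(share[order(cis)]) > 0))
})

test_that("dimerization fit recovers generating parameters without noise", {
  ser <- make_dilution_series(seed = 2, noise_sigma_rel = 0)
  b <- attr(ser, "basis")
  fit <- fit_dimerization(ser, b$a_m, b$a_da, b$a_db,
                          init = list(k_d = 300, eps_m = 1e4, eps_d = 1e4))
  expect_true(fit$converged)
  expect_equal(fit$k_d, 2e3, tolerance = 1e-6)
  expect_equal(fit$eps_m, 5e4, tolerance = 1e-6)
  expect_equal(fit$eps_d, 4e4, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-6)
})

test_that("a non-dimerizing series is fitted with a negligible k_d", {
  ser <- make_dilution_series(seed = 5, k_d = 0, noise_sigma_rel = 0.01)
  b <- attr(ser, "basis")
  fit <- fit_dimerization(ser, b$a_m, b$a_da, b$a_db,
                          init = list(k_d = 100, eps_m = 1e4, eps_d = 1e4))
  # fitted dimer contribution indistinguishable from zero: at the largest
  # concentration the implied dimer fraction stays below the noise floor
  frac <- 2 * speciate(fit$k_d, 400.5e-6)$dimer_conc / 400.5e-6
  expect_lt(frac, 0.02)
})

test_that("dimerization fit requires three distinct concentrations", {
  ser <- make_dilution_series(seed = 1, n_steps = 1L)
  b <- attr(ser, "basis")
  expect_error(fit_dimerization(ser, b$a_m, b$a_da, b$a_db), "3 distinct")
})
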