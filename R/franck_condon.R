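#' One-dimensional Franck-Condon overlap amplitudes
#'
#' Overlap \eqn{\langle \chi''_m | \chi'_n \rangle} between vibrational
#' eigenstates of two harmonic oscillators that differ in frequency
#' (`freq_ground` vs `freq_excited`, both in cm^-1) and in equilibrium
#' position (`displacement`, dimensionless in ground-state coordinates, so
#' the Huang-Rhys factor is \eqn{S = \Delta^2/2} at equal frequencies).
#'
#' Amplitudes are computed by a stable two-index recursion derived from
#' ladder-operator identities, seeded by the closed-form
#' \deqn{\langle 0|0 \rangle = \sqrt{2\sqrt{f}/(1+f)}\,
#'       \exp(-f\Delta^2 / (2(1+f))), \quad f = \omega'/\omega''.}
#' Sign convention: with equal frequencies,
#' \eqn{\langle 0|n\rangle \propto (-\Delta)^n} -- i.e. the excited-state
#' minimum sits at \eqn{+\Delta} in ground-state coordinates. Swapping
#' the two surfaces rescales the displacement (it is dimensionless in the
#' coordinates of whichever surface is called "ground"), so the exact
#' surface-swap symmetry reads \code{fc_overlap_1d(m, n, wg, we, d) ==
#' fc_overlap_1d(n, m, we, wg, -d * sqrt(we/wg))}.
#'
#' @param m,n Initial (ground-surface) and final (excited-surface)
#'   vibrational quanta, non-negative integers.
#' @param freq_ground,freq_excited Harmonic wavenumbers in cm^-1 (> 0).
#' @param displacement Dimensionless displacement between minima.
#' @param max_quanta Recursion cap; requesting quanta beyond it errors.
#' @return The overlap amplitude (a number in [-1, 1]).
#' @export
fc_overlap_1d <- function(m, n, freq_ground, freq_excited, displacement,
                          max_quanta = 200L) {
  if (m < 0 || n < 0 || m != floor(m) || n != floor(n)) {
    stop("quanta m, n must be non-negative integers", call. = FALSE)
  }
  if (m > max_quanta || n > max_quanta) {
    stop(sprintf("quanta exceed recursion cap %d", max_quanta), call. = FALSE)
  }
  tab <- fc_overlap_table(m, n, freq_ground, freq_excited, displacement)
  tab[m + 1L, n + 1L]
}

#' Table of Franck-Condon overlap amplitudes
#'
#' Computes all \eqn{\langle m|n \rangle} for `m = 0..m_max`,
#' `n = 0..n_max` in one recursion sweep. See [fc_overlap_1d()] for
#' conventions.
#'
#' @param m_max,n_max Maximum quanta per surface.
#' @inheritParams fc_overlap_1d
#' @return `(m_max+1) x (n_max+1)` matrix of amplitudes.
#' @export
fc_overlap_table <- function(m_max, n_max, freq_ground, freq_excited,
                             displacement) {
  if (freq_ground <= 0 || freq_excited <= 0) {
    stop("frequencies must be positive", call. = FALSE)
  }
  if (!is.finite(displacement)) {
    stop("displacement must be finite", call. = FALSE)
  }
  # work in ground-state dimensionless coordinates: alpha = 1, beta = f
  a <- 1
  b <- freq_excited / freq_ground
  D <- displacement
  M <- as.integer(m_max) + 1L
  N <- as.integer(n_max) + 1L
  S <- matrix(0, M, N)
  S[1L, 1L] <- sqrt(2 * sqrt(a * b) / (a + b)) *
    exp(-a * b * D^2 / (2 * (a + b)))
  sab <- sqrt(a * b)
  # first row: raise n
  if (N > 1L) {
    for (n in 1L:(N - 1L)) {
      s_prev2 <- if (n >= 2L) S[1L, n - 1L] else 0
      S[1L, n + 1L] <- (-sqrt(2) * a * sqrt(b) * D * S[1L, n] -
                          sqrt(n - 1) * (a - b) * s_prev2) /
        ((a + b) * sqrt(n))
    }
  }
  # subsequent rows: raise m
  if (M > 1L) {
    for (m in 1L:(M - 1L)) {
      for (n in 0L:(N - 1L)) {
        t1 <- if (n >= 1L) 2 * sqrt(n * a * b) * S[m, n] else 0
        t2 <- sqrt(2) * b * sqrt(a) * D * S[m, n + 1L]
        t3 <- if (m >= 2L) sqrt(m - 1) * (b - a) * S[m - 1L, n + 1L] else 0
        S[m + 1L, n + 1L] <- (t1 + t2 - t3) / ((a + b) * sqrt(m))
      }
    }
  }
  S
}

#' A single harmonic vibrational mode
#'
#' @param index Integer mode label (e.g. 25, 27).
#' @param freq_ground Ground-surface wavenumber, cm^-1 (> 0).
#' @param freq_excited Excited-surface wavenumber, cm^-1 (> 0); defaults to
#'   `freq_ground` (displaced, undistorted mode).
#' @param displacement Dimensionless displacement between minima.
#' @return Object of class `harmonic_mode`.
#' @export
harmonic_mode <- function(index, freq_ground, freq_excited = freq_ground,
                          displacement = 0) {
  if (freq_ground <= 0 || freq_excited <= 0) {
    stop("mode frequencies must be positive (cm^-1)", call. = FALSE)
  }
  if (!is.finite(displacement)) {
    stop("displacement must be finite", call. = FALSE)
  }
  structure(list(index = as.integer(index), freq_ground = freq_ground,
                 freq_excited = freq_excited, displacement = displacement),
            class = "harmonic_mode")
}

#' Harmonic vibronic model of one electronic transition
#'
#' Bundles the adiabatic (0-0) energy, a list of independent harmonic
#' modes, the temperature and an overall intensity scale. This is the
#' adiabatic-Hessian, independent-mode model: each ground mode pairs with
#' one excited mode (Duschinsky rotation fixed to identity).
#'
#' @param e_adiabatic 0-0 transition energy in eV (> 0).
#' @param modes List of [harmonic_mode()] objects (may be empty: pure 0-0).
#' @param temperature Temperature in K (>= 0).
#' @param intensity_scale Overall transition strength (arbitrary units).
#' @return Object of class `vibronic_system`.
#' @export
vibronic_system <- function(e_adiabatic, modes = list(), temperature = 300,
                            intensity_scale = 1) {
  if (e_adiabatic <= 0) stop("e_adiabatic must be positive (eV)",
                             call. = FALSE)
  if (temperature < 0) stop("temperature must be >= 0 (K)", call. = FALSE)
  if (!all(vapply(modes, inherits, logical(1L), "harmonic_mode"))) {
    stop("modes must be a list of harmonic_mode objects", call. = FALSE)
  }
  structure(list(e_adiabatic = e_adiabatic, modes = modes,
                 temperature = temperature,
                 intensity_scale = intensity_scale),
            class = "vibronic_system")
}

#' @export
print.vibronic_system <- function(x, ...) {
  cat(sprintf("<vibronic_system> e00 = %.4f eV, %d mode(s), T = %g K\n",
              x$e_adiabatic, length(x$modes), x$temperature))
  for (m in x$modes) {
    cat(sprintf("  mode %d: %g / %g cm^-1, displacement %g\n",
                m$index, m$freq_ground, m$freq_excited, m$displacement))
  }
  invisible(x)
}

#' Poisson vibronic progression (equal frequencies, 0 K)
#'
#' Stick spectrum of a single displaced mode at zero temperature with
#' equal ground/excited frequencies: lines at `e00 + n * freq` with
#' intensities \eqn{e^{-S} S^n / n!} (Poisson in the Huang-Rhys factor S).
#'
#' @param S Huang-Rhys factor (>= 0).
#' @param freq Mode wavenumber in cm^-1.
#' @param e00 0-0 energy in eV.
#' @param n_max Highest final quantum included.
#' @return A [stick_spectrum()].
#' @export
huang_rhys_progression <- function(S, freq, e00, n_max = 10L) {
  if (S < 0) stop("Huang-Rhys factor must be >= 0", call. = FALSE)
  if (n_max < 0) stop("n_max must be >= 0", call. = FALSE)
  n <- 0:n_max
  stick_spectrum(e00 + n * freq * cm1_to_ev, stats::dpois(n, S),
                 sprintf("0-%d", n))
}

# per-mode Boltzmann population of m quanta at temperature T (geometric
# normalisation over the full ladder; exactly {1, 0, 0, ...} at T = 0)
boltzmann_pop <- function(m, freq_cm1, temperature) {
  if (temperature <= 0) return(as.numeric(m == 0L))
  theta <- freq_cm1 * cm1_to_ev / (kb_ev_k * temperature)
  exp(-m * theta) * (1 - exp(-theta))
}

#' Finite-temperature Franck-Condon stick spectrum
#'
#' Time-independent enumeration of vibronic transitions for a
#' [vibronic_system()]. Initial states on the ground surface are
#' enumerated up to `max_initial_quanta` per mode and weighted by their
#' Boltzmann populations (from the ground-surface frequencies at the
#' system temperature); final states run to `max_quanta` per mode. Line
#' energy is \eqn{E_{ad} + \sum_j (n_j \omega'_j - m_j \omega''_j)} in eV;
#' line intensity is the Boltzmann weight times the product of squared
#' 1-D overlaps times `intensity_scale`. Lines weaker than
#' `intensity_floor` times the strongest line are dropped; the retained
#' fraction of the total generated intensity is stored in the
#' `"retained_fraction"` attribute.
#'
#' @param system A [vibronic_system()].
#' @param max_quanta Final-state cap per mode (>= 1). Default 8.
#' @param max_initial_quanta Initial-state cap per mode. Default 2 (modes
#'   above ~400 cm^-1 have small thermal populations beyond that at 300 K).
#' @param intensity_floor Relative floor (fraction of the largest line).
#'   Default 1e-6.
#' @return A [stick_spectrum()] with attribute `retained_fraction`.
#' @export
thermal_stick_spectrum <- function(system, max_quanta = 8L,
                                   max_initial_quanta = 2L,
                                   intensity_floor = 1e-6) {
  if (!inherits(system, "vibronic_system")) {
    stop("expected a vibronic_system", call. = FALSE)
  }
  if (max_quanta < 1L) stop("max_quanta must be >= 1", call. = FALSE)
  if (intensity_floor < 0) stop("intensity_floor must be >= 0", call. = FALSE)
  modes <- system$modes
  J <- length(modes)
  if (J == 0L) {
    out <- stick_spectrum(system$e_adiabatic, system$intensity_scale, "0-0")
    attr(out, "retained_fraction") <- 1
    return(out)
  }
  n_init <- (max_initial_quanta + 1L)^J
  n_fin <- (max_quanta + 1L)^J
  if (n_init * n_fin > 1e6) {
    stop(paste("more than 1e6 candidate lines; raise intensity_floor or",
               "lower the per-mode quanta caps"), call. = FALSE)
  }
  tabs <- lapply(modes, function(md) {
    fc_overlap_table(max_initial_quanta, max_quanta, md$freq_ground,
                     md$freq_excited, md$displacement)^2
  })
  init_grid <- as.matrix(expand.grid(rep(list(0:max_initial_quanta), J)))
  fin_grid <- as.matrix(expand.grid(rep(list(0:max_quanta), J)))
  wg <- vapply(modes, `[[`, numeric(1L), "freq_ground")
  we <- vapply(modes, `[[`, numeric(1L), "freq_excited")
  idx <- vapply(modes, `[[`, integer(1L), "index")

  energies <- numeric(0)
  intens <- numeric(0)
  assign <- character(0)
  for (i in seq_len(nrow(init_grid))) {
    mvec <- init_grid[i, ]
    w <- prod(vapply(seq_len(J), function(j) {
      boltzmann_pop(mvec[j], wg[j], system$temperature)
    }, numeric(1L)))
    if (w == 0) next
    fc2 <- rep(w, nrow(fin_grid))
    for (j in seq_len(J)) {
      fc2 <- fc2 * tabs[[j]][mvec[j] + 1L, fin_grid[, j] + 1L]
    }
    e <- system$e_adiabatic +
      (fin_grid %*% we - sum(mvec * wg))[, 1L] * cm1_to_ev
    a <- apply(fin_grid, 1L, function(nvec) {
      paste(sprintf("%d:%d-%d", idx, mvec, nvec), collapse = "|")
    })
    energies <- c(energies, e)
    intens <- c(intens, fc2 * system$intensity_scale)
    assign <- c(assign, a)
  }
  total <- sum(intens)
  keep <- intens >= intensity_floor * max(intens)
  out <- stick_spectrum(energies[keep], intens[keep], assign[keep])
  attr(out, "retained_fraction") <- sum(intens[keep]) / total
  out
}

#' Broadened monomer absorption spectrum
#'
#' Convenience composition: [thermal_stick_spectrum()] followed by
#' [convolve_gaussian()]. With the default methylene-blue-like parameters
#' (0-0 at 2.14 eV, displaced modes at 454 and 510 cm^-1, 300 K, 0.022 eV
#' width) the result shows one global peak at the 0-0 energy and a single
#' vibronic shoulder 40-70 meV above it.
#'
#' @param e00 0-0 energy in eV.
#' @param modes List of [harmonic_mode()] objects.
#' @param temperature Temperature in K.
#' @param width Gaussian broadening in eV (see [convolve_gaussian()]).
#' @param grid Energy grid; default covers the progression comfortably.
#' @param ... Passed to [thermal_stick_spectrum()].
#' @return A `spectrum`.
#' @export
meb_like_monomer_spectrum <- function(e00 = 2.14, modes = NULL,
                                      temperature = 300, width = 0.022,
                                      grid = NULL, ...) {
  if (is.null(modes)) {
    modes <- make_meb_monomer(e00 = e00, temperature = temperature)$modes
  }
  sys <- vibronic_system(e00, modes, temperature)
  sticks <- thermal_stick_spectrum(sys, ...)
  if (is.null(grid)) {
    grid <- energy_grid(min(sticks$lines$energy) - 6 * width,
                        max(sticks$lines$energy) + 6 * width, by = width / 8)
  }
  sp <- convolve_gaussian(sticks, width = width, grid = grid)
  sp$label <- "monomer vibronic spectrum"
  sp
}

#' Read / write a vibronic system as YAML or JSON
#'
#' Schema: `{e_adiabatic_ev, temperature_k, intensity_scale,
#' modes: [{index, freq_ground_cm1, freq_excited_cm1, displacement}]}`.
#' Format chosen by file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param system A [vibronic_system()].
#' @param path File path.
#' @return `write_vibronic_system` returns `path` invisibly;
#'   `read_vibronic_system` returns a `vibronic_system`.
#' @export
write_vibronic_system <- function(system, path) {
  obj <- list(
    e_adiabatic_ev = system$e_adiabatic,
    temperature_k = system$temperature,
    intensity_scale = system$intensity_scale,
    modes = lapply(system$modes, function(m) list(
      index = m$index, freq_ground_cm1 = m$freq_ground,
      freq_excited_cm1 = m$freq_excited, displacement = m$displacement)))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_vibronic_system
#' @export
read_vibronic_system <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  modes <- lapply(obj$modes, function(m) {
    harmonic_mode(m$index, m$freq_ground_cm1, m$freq_excited_cm1,
                  m$displacement)
  })
  vibronic_system(obj$e_adiabatic_ev, modes, obj$temperature_k,
                  if (is.null(obj$intensity_scale)) 1 else obj$intensity_scale)
}
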