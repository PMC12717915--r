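#' Molecular transition as a Lorentzian oscillator
#'
#' One molecular transition coupled to the cavity: energy `omega` (eV),
#' FULL linewidth `gamma` (eV; it enters the complex frequency as
#' `-i*gamma/2` -- half-width conventions are the main reproducibility
#' hazard in these models, so the full-width convention is stated here
#' prominently), and coupling strength `g` (eV).
#'
#' @param omega Transition energy, eV (> 0).
#' @param gamma Full linewidth, eV (> 0).
#' @param g Coupling strength, eV (>= 0).
#' @return Object of class `transition_oscillator`.
#' @export
transition_oscillator <- function(omega, gamma, g) {
  if (omega <= 0) stop("omega must be positive (eV)", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive (eV); zero linewidths put poles on the real axis", call. = FALSE)
  if (g < 0) stop("g must be >= 0 (eV)", call. = FALSE)
  structure(list(omega = omega, gamma = gamma, g = g),
            class = "transition_oscillator")
}

#' Nanocavity coupled-oscillator model
#'
#' Classical input/output model of a plasmonic nanocavity mode (energy
#' `omega_c`, FULL linewidth `kappa`) coupled to zero or more Lorentzian
#' molecular transitions.
#'
#' @param omega_c Cavity energy, eV (> 0).
#' @param kappa Cavity full linewidth, eV (> 0).
#' @param transitions List of [transition_oscillator()] objects.
#' @return Object of class `cavity_model`.
#' @export
cavity_model <- function(omega_c, kappa, transitions = list()) {
  if (omega_c <= 0) stop("omega_c must be positive (eV)", call. = FALSE)
  if (kappa <= 0) stop("kappa must be positive (eV)", call. = FALSE)
  if (!all(vapply(transitions, inherits, logical(1L),
                  "transition_oscillator"))) {
    stop("transitions must be transition_oscillator objects", call. = FALSE)
  }
  structure(list(omega_c = omega_c, kappa = kappa,
                 transitions = transitions), class = "cavity_model")
}

#' @export
print.cavity_model <- function(x, ...) {
  cat(sprintf("<cavity_model> omega_c = %.4f eV, kappa = %.4f eV, %d transition(s)\n",
              x$omega_c, x$kappa, length(x$transitions)))
  for (tr in x$transitions) {
    cat(sprintf("  omega = %.4f eV, gamma = %.4f eV, g = %.4f eV\n",
                tr$omega, tr$gamma, tr$g))
  }
  invisible(x)
}

#' Complex cavity susceptibility
#'
#' Driven response of the coupled system at photon energy E:
#' \deqn{\chi(E) = \left[\omega_c - E - i\kappa/2
#'   - \sum_j \frac{g_j^2}{\omega_j - E - i\gamma_j/2}\right]^{-1}.}
#' Finite for all real E because every linewidth is strictly positive.
#'
#' @param model A [cavity_model()].
#' @param energy Photon energies in eV (vectorized).
#' @return Complex vector of susceptibilities.
#' @export
cavity_susceptibility <- function(model, energy) {
  if (!inherits(model, "cavity_model")) {
    stop("expected a cavity_model", call. = FALSE)
  }
  den <- model$omega_c - energy - 1i * model$kappa / 2
  for (tr in model$transitions) {
    den <- den - tr$g^2 / (tr$omega - energy - 1i * tr$gamma / 2)
  }
  1 / den
}

#' Cavity extinction or scattering spectrum
#'
#' Extinction mode (default) evaluates the absorptive spectral function
#' \eqn{\mathrm{Im}\,\chi(E)} -- positive-definite with the sign
#' convention of [cavity_susceptibility()], and often written
#' \eqn{-\mathrm{Im}\,\chi} under the opposite time-phase convention --
#' which reduces to a Lorentzian absorption line of FWHM `kappa` in the
#' uncoupled limit. Scattering mode (dark-field-like) evaluates
#' \eqn{|\chi(E)|^2}. Normalized to unit maximum by default.
#'
#' @param model A [cavity_model()].
#' @param grid Energy grid in eV; should span all oscillators +- 5
#'   linewidths (a warning is issued otherwise).
#' @param mode `"extinction"` or `"scattering"`.
#' @param normalize Scale to unit maximum (default `TRUE`).
#' @return A `spectrum`.
#' @export
extinction_spectrum <- function(model, grid,
                                mode = c("extinction", "scattering"),
                                normalize = TRUE) {
  mode <- match.arg(mode)
  grid <- as.numeric(grid)
  centers <- c(model$omega_c,
               vapply(model$transitions, `[[`, numeric(1L), "omega"))
  widths <- c(model$kappa,
              vapply(model$transitions, `[[`, numeric(1L), "gamma"))
  if (min(grid) > min(centers - 5 * widths) ||
      max(grid) < max(centers + 5 * widths)) {
    warning("grid does not span all oscillators +- 5 linewidths",
            call. = FALSE)
  }
  chi <- cavity_susceptibility(model, grid)
  v <- if (mode == "extinction") Im(chi) else Mod(chi)^2
  if (normalize) v <- v / max(v)
  spectrum(grid, v, label = sprintf("cavity %s", mode),
           provenance = "computed")
}

#' Closed-form polariton eigenvalues (single transition)
#'
#' Complex eigenvalues of the 2x2 non-Hermitian coupling matrix
#' \deqn{\begin{pmatrix}\omega_c - i\kappa/2 & g\\
#'       g & \omega - i\gamma/2\end{pmatrix}.}
#' At resonance the real-part splitting is
#' \eqn{2\sqrt{g^2 - (\kappa-\gamma)^2/16}}, reducing to the textbook
#' \eqn{2g} in the lossless limit.
#'
#' @param model A [cavity_model()] with exactly one transition.
#' @return List: `eigenvalues` (complex pair, lower real part first) and
#'   `splitting` (difference of real parts, eV).
#' @export
polariton_eigenvalues <- function(model) {
  if (!inherits(model, "cavity_model")) {
    stop("expected a cavity_model", call. = FALSE)
  }
  if (length(model$transitions) != 1L) {
    stop("closed-form eigenvalues require exactly one transition",
         call. = FALSE)
  }
  tr <- model$transitions[[1L]]
  H <- matrix(c(model$omega_c - 1i * model$kappa / 2, tr$g,
                tr$g, tr$omega - 1i * tr$gamma / 2), 2L, 2L)
  ev <- eigen(H, symmetric = FALSE)$values
  ev <- ev[order(Re(ev))]
  list(eigenvalues = ev, splitting = Re(ev[2L]) - Re(ev[1L]))
}

#' Polariton peak analysis of a cavity spectrum
#'
#' Finds the resolved polariton branches with [detect_peaks()]: the
#' lowest- and highest-energy peaks are the lower (LP) and upper (UP)
#' polaritons. Reports their energies and heights, the Rabi splitting
#' (UP - LP) and the UP/LP height asymmetry, plus any shoulders detected
#' between the branches (a non-Lorentzian LP lineshape shows up there).
#'
#' @param spec A cavity `spectrum` (e.g. from [extinction_spectrum()]).
#' @param smoothing,shoulder_threshold Passed to [detect_peaks()].
#' @return Object of class `polariton_report`: `up_energy`, `lp_energy`,
#'   `splitting`, `up_height`, `lp_height`, `asymmetry`
#'   (`up_height/lp_height`), `n_peaks`, `shoulders` (data.frame).
#' @export
analyze_polaritons <- function(spec, smoothing = 0.01,
                               shoulder_threshold = 0.002) {
  ps <- detect_peaks(spec, smoothing = smoothing,
                     shoulder_threshold = shoulder_threshold)
  if (nrow(ps$peaks) < 2L) {
    stop("system not in resolved splitting regime (< 2 peaks)",
         call. = FALSE)
  }
  lp <- ps$peaks[1L, ]
  up <- ps$peaks[nrow(ps$peaks), ]
  structure(list(
    up_energy = up$energy, lp_energy = lp$energy,
    splitting = up$energy - lp$energy,
    up_height = up$height, lp_height = lp$height,
    asymmetry = up$height / lp$height,
    n_peaks = nrow(ps$peaks), shoulders = ps$shoulders),
    class = "polariton_report")
}

#' @export
print.polariton_report <- function(x, ...) {
  cat(sprintf("<polariton_report> LP %.4f eV (h %.3g), UP %.4f eV (h %.3g)\n",
              x$lp_energy, x$lp_height, x$up_energy, x$up_height))
  cat(sprintf("  splitting %.4f eV, UP/LP asymmetry %.3f, %d peak(s), %d shoulder(s)\n",
              x$splitting, x$asymmetry, x$n_peaks, nrow(x$shoulders)))
  invisible(x)
}

#' Read / write a cavity model as YAML or JSON
#'
#' Schema: `{omega_c_ev, kappa_ev, transitions: [{omega_ev, gamma_ev,
#' g_ev}]}`. Format chosen by file extension.
#'
#' @param model A [cavity_model()].
#' @param path File path.
#' @return `write_cavity_model` returns `path` invisibly;
#'   `read_cavity_model` returns a `cavity_model`.
#' @export
write_cavity_model <- function(model, path) {
  obj <- list(
    omega_c_ev = model$omega_c, kappa_ev = model$kappa,
    transitions = lapply(model$transitions, function(tr) list(
      omega_ev = tr$omega, gamma_ev = tr$gamma, g_ev = tr$g)))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cavity_model
#' @export
read_cavity_model <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  trs <- lapply(obj$transitions, function(tr) {
    transition_oscillator(tr$omega_ev, tr$gamma_ev, tr$g_ev)
  })
  cavity_model(obj$omega_c_ev, obj$kappa_ev, trs)
}
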