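#' Sampled absorption spectrum
#'
#' A `spectrum` holds a continuous lineshape sampled on a strictly
#' increasing photon-energy grid in eV, with values in arbitrary linear
#' units (absorbance or molar absorptivity). Every continuous lineshape in
#' the package -- computed vibronic spectra, synthetic dimer bands,
#' measured-style dilution series, cavity extinction -- is a `spectrum`.
#'
#' @param energies Photon energy grid in eV; strictly increasing, finite,
#'   length >= 2.
#' @param values Absorbance per grid point; finite, same length.
#' @param label Free-text label.
#' @param provenance One of `"computed"`, `"measured"`, `"synthetic"`.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(energies, values, label = "",
                     provenance = c("computed", "measured", "synthetic")) {
  provenance <- match.arg(provenance)
  energies <- as.numeric(energies)
  values <- as.numeric(values)
  if (length(energies) < 2L || length(energies) != length(values)) {
    stop("spectrum needs matching energy/value vectors of length >= 2",
         call. = FALSE)
  }
  if (any(!is.finite(energies)) || any(!is.finite(values))) {
    stop("spectrum energies and values must all be finite", call. = FALSE)
  }
  if (any(diff(energies) <= 0)) {
    stop("spectrum energy grid must be strictly increasing", call. = FALSE)
  }
  structure(list(energies = energies, values = values,
                 label = as.character(label)[1L], provenance = provenance),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s [%s]\n", x$label, x$provenance))
  cat(sprintf("  %d points, %.4f..%.4f eV, max value %.4g at %.4f eV\n",
              length(x$energies), min(x$energies), max(x$energies),
              max(x$values), x$energies[which.max(x$values)]))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ..., xlab = "energy (eV)", ylab = "absorbance",
                          type = "l") {
  graphics::plot(x$energies, x$values, type = type, xlab = xlab,
                 ylab = ylab, main = x$label, ...)
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

stopifnot_spectrum <- function(x, what = "spectrum") {
  if (!is_spectrum(x)) stop(sprintf("expected a %s object", what),
                            call. = FALSE)
  invisible(x)
}

#' Baseline-correct a spectrum
#'
#' Subtracts the minimum absorbance from every point, aligning the lowest
#' point to zero -- the linear baseline correction used to remove
#' cuvette-to-cuvette path-length offsets. Shape (all pairwise differences)
#' is preserved exactly, and the operation is idempotent.
#'
#' @param spec A [spectrum()].
#' @return A baseline-corrected `spectrum`.
#' @export
baseline_correct <- function(spec) {
  stopifnot_spectrum(spec)
  spec$values <- spec$values - min(spec$values)
  spec
}

#' Shift a spectrum or stick spectrum along the energy axis
#'
#' Sign convention (important): a positive `offset` shifts every feature to
#' LOWER energy -- i.e. `offset` is a red shift magnitude in eV. This
#' mirrors the usual use case of subtracting a constant from overestimated
#' computed excitation energies (a CIS(D)-style offset). A negative
#' `offset` blue-shifts. `apply_energy_offset(x, a)` followed by
#' `apply_energy_offset(., -a)` is the identity.
#'
#' @param x A [spectrum()] or [stick_spectrum()].
#' @param offset Red-shift magnitude in eV (finite; may be negative).
#' @return Object of the same class, shifted.
#' @export
apply_energy_offset <- function(x, offset) {
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset)) {
    stop("offset must be a single finite number (eV)", call. = FALSE)
  }
  if (is_spectrum(x)) {
    x$energies <- x$energies - offset
  } else if (inherits(x, "stick_spectrum")) {
    x$lines$energy <- x$lines$energy - offset
  } else {
    stop("expected a spectrum or stick_spectrum", call. = FALSE)
  }
  x
}

#' Resample a spectrum onto a new energy grid
#'
#' Linear interpolation onto `grid`. The target grid must lie inside the
#' source range: extrapolation is refused rather than filled, so no
#' baseline is ever fabricated. Values at grid points shared with the
#' source are reproduced exactly.
#'
#' @param spec A [spectrum()].
#' @param grid Strictly increasing target energies in eV.
#' @return A `spectrum` on `grid`.
#' @export
resample_spectrum <- function(spec, grid) {
  stopifnot_spectrum(spec)
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) {
    stop("target grid must be strictly increasing", call. = FALSE)
  }
  rng <- range(spec$energies)
  if (min(grid) < rng[1L] || max(grid) > rng[2L]) {
    stop(sprintf(
      "resampling grid [%.6g, %.6g] exceeds source range [%.6g, %.6g]; extrapolation is not allowed",
      min(grid), max(grid), rng[1L], rng[2L]), call. = FALSE)
  }
  v <- stats::approx(spec$energies, spec$values, xout = grid)$y
  spectrum(grid, v, label = spec$label, provenance = spec$provenance)
}

#' Trapezoidal integral of a spectrum
#'
#' @param spec A [spectrum()].
#' @return The trapezoid-rule integral of values over energies.
#' @export
spectrum_area <- function(spec) {
  stopifnot_spectrum(spec)
  e <- spec$energies
  v <- spec$values
  sum(diff(e) * (v[-1L] + v[-length(v)]) / 2)
}

#' Build a uniform energy grid
#'
#' @param from,to Grid limits in eV.
#' @param by Spacing in eV.
#' @return Numeric vector of energies.
#' @export
energy_grid <- function(from, to, by = 0.002) {
  if (to <= from || by <= 0) stop("need to > from and by > 0", call. = FALSE)
  seq(from, to, by = by)
}
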