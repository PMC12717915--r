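#' Peak and shoulder detection
#'
#' Locates local maxima (peaks) and unresolved flank features (shoulders)
#' of a sampled spectrum. The curve and its first two derivatives are
#' estimated with a Savitzky-Golay local-polynomial filter whose window is
#' five times the `smoothing` parameter. Peaks are strict local maxima of
#' the smoothed curve. Shoulders are regions of negative smoothed second
#' derivative that do not contain a peak and lie on a monotone flank
#' (first derivative of constant sign): the classic signature of a band
#' hiding under the tail of a stronger neighbour. Each shoulder is scored
#' by its curvature magnitude relative to the strongest curvature in the
#' spectrum; scores below `shoulder_threshold` are discarded.
#'
#' The default threshold is calibrated so that a methylene-blue-like
#' two-line doublet (strong 0-0 line plus an unresolved vibronic line
#' ~0.056 eV above, both 0.022 eV wide) yields exactly one shoulder.
#'
#' @param spec A [spectrum()], sampled at spacing <= `smoothing/3`.
#' @param smoothing Smoothing length scale in eV (the SG window is
#'   `5 * smoothing`). Default 0.01 eV.
#' @param shoulder_threshold Minimum relative curvature score in (0, 1].
#' @param peak_threshold Minimum peak height relative to the global
#'   maximum; suppresses numerical ripples on near-zero tails.
#' @return A `peak_set`: list with data.frames `peaks` (energy, height,
#'   score) and `shoulders` (energy, score), both sorted by energy.
#' @export
detect_peaks <- function(spec, smoothing = 0.01, shoulder_threshold = 0.02,
                         peak_threshold = 1e-3) {
  stopifnot_spectrum(spec)
  if (!is.numeric(smoothing) || smoothing <= 0) {
    stop("smoothing must be positive (eV)", call. = FALSE)
  }
  e <- spec$energies
  v <- spec$values
  de <- stats::median(diff(e))
  if (de > smoothing / 3) {
    stop(sprintf(
      "grid spacing %.4g eV too coarse for smoothing %.4g eV (need <= smoothing/3)",
      de, smoothing), call. = FALSE)
  }
  win <- ceiling(5 * smoothing / de)
  if (win %% 2L == 0L) win <- win + 1L
  win <- max(win, 7L)
  if (win >= length(e)) {
    stop("spectrum shorter than the smoothing window", call. = FALSE)
  }
  p <- min(4L, win - 2L)
  sm <- signal::sgolayfilt(v, p = p, n = win, m = 0)
  d1 <- signal::sgolayfilt(v, p = p, n = win, m = 1) / de
  d2 <- signal::sgolayfilt(v, p = p, n = win, m = 2) / de^2

  n <- length(sm)
  interior <- 2:(n - 1L)
  is_peak <- logical(n)
  is_peak[interior] <- sm[interior] > sm[interior - 1L] &
    sm[interior] > sm[interior + 1L]
  is_peak[sm < peak_threshold * max(sm)] <- FALSE
  peak_idx <- which(is_peak)

  d2max <- max(abs(d2))
  peaks <- data.frame(energy = e[peak_idx], height = sm[peak_idx],
                      score = if (length(peak_idx)) sm[peak_idx] / max(sm)
                              else numeric())

  # negative-curvature runs that hold no local maximum: shoulder candidates
  sh_energy <- numeric()
  sh_score <- numeric()
  neg <- d2 < 0
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  guard <- (win - 1L) / 2L   # SG edge transients are unreliable
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 <= guard || i1 > n - guard) next
    if (any(peak_idx >= i0 & peak_idx <= i1)) next
    s1 <- d1[i0:i1]
    if (!(all(s1 > 0) || all(s1 < 0))) next   # not a monotone flank
    j <- i0 - 1L + which.min(d2[i0:i1])
    score <- abs(d2[j]) / d2max
    if (score >= shoulder_threshold) {
      sh_energy <- c(sh_energy, e[j])
      sh_score <- c(sh_score, score)
    }
  }
  ord <- order(sh_energy)
  structure(list(
    peaks = peaks,
    shoulders = data.frame(energy = sh_energy[ord], score = sh_score[ord])),
    class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s), %d shoulder(s)\n",
              nrow(x$peaks), nrow(x$shoulders)))
  if (nrow(x$peaks)) {
    cat("peaks:\n"); print(x$peaks, row.names = FALSE)
  }
  if (nrow(x$shoulders)) {
    cat("shoulders:\n"); print(x$shoulders, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a peak set to JSON
#'
#' Writes `{"peaks":[{"energy_ev":..,"height":..,"score":..}],
#' "shoulders":[{"energy_ev":..,"score":..}]}`.
#'
#' @param ps A `peak_set` from [detect_peaks()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
peak_set_json <- function(ps, path = NULL) {
  if (!inherits(ps, "peak_set")) stop("expected a peak_set", call. = FALSE)
  obj <- list(
    peaks = if (nrow(ps$peaks)) data.frame(
      energy_ev = ps$peaks$energy, height = ps$peaks$height,
      score = ps$peaks$score) else list(),
    shoulders = if (nrow(ps$shoulders)) data.frame(
      energy_ev = ps$shoulders$energy, score = ps$shoulders$score) else list())
  txt <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                          digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
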