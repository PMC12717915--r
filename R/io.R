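#' Read a two-column spectrum file
#'
#' Reads delimited text (comma, tab or whitespace, auto-detected; decimal
#' point only) with column 1 = wavelength in nm or energy in eV and
#' column 2 = absorbance. Lines starting with `#` are comments. A header
#' row is optional; when present, a first-column name containing `nm` or
#' `ev` declares the units, otherwise pass `units`. Wavelength input is
#' converted to eV and the grid sorted ascending (with a warning if
#' reordering was needed beyond the nm-to-eV reversal).
#'
#' @param path File path.
#' @param units `"auto"` (from header), `"nm"` or `"ev"`.
#' @param label Label for the resulting spectrum.
#' @param provenance Provenance tag; default `"measured"`.
#' @return A [spectrum()] on an ascending eV grid.
#' @export
read_spectrum <- function(path, units = c("auto", "nm", "ev"),
                          label = basename(path), provenance = "measured") {
  units <- match.arg(units)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) < 2L) stop("spectrum file has fewer than 2 data rows",
                               call. = FALSE)
  delim <- if (grepl(",", lines[1L])) "," else if (grepl("\t", lines[1L]))
    "\t" else "[[:space:]]+"
  split1 <- strsplit(trimws(lines[1L]), delim)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(split1))))
  if (has_header) {
    if (units == "auto") {
      col1 <- tolower(split1[1L])
      units <- if (grepl("nm", col1)) "nm"
               else if (grepl("ev", col1)) "ev"
               else stop("cannot infer units from header; pass units=",
                         call. = FALSE)
    }
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  } else if (units == "auto") {
    stop("file has no header; declare units = \"nm\" or \"ev\"",
         call. = FALSE)
  }
  parts <- strsplit(trimws(lines), delim)
  x <- numeric(length(parts))
  y <- numeric(length(parts))
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]][1:2]))
    if (length(parts[[i]]) < 2L || any(is.na(v))) {
      stop(sprintf("malformed row at line %d of %s: '%s'", lineno[i], path,
                   lines[i]), call. = FALSE)
    }
    x[i] <- v[1L]; y[i] <- v[2L]
  }
  e <- if (units == "nm") nm_to_ev(x) else x
  ord <- order(e)
  e_sorted <- e[ord]
  # reversal is expected for nm files; anything else deserves a warning
  if (!identical(ord, seq_along(e)) && !identical(ord, rev(seq_along(e)))) {
    warning("energy grid not monotone after conversion; rows sorted",
            call. = FALSE)
  }
  if (any(diff(e_sorted) <= 0)) {
    stop("duplicate energies in spectrum file", call. = FALSE)
  }
  spectrum(e_sorted, y[ord], label = label, provenance = provenance)
}

#' Write a spectrum as two-column CSV
#'
#' Always writes a `#` provenance comment line (package version, label,
#' provenance) followed by an `energy_ev,absorbance` header. Values are
#' written with enough digits that a write/read round trip preserves them
#' to better than 1e-9 relative.
#'
#' @param spec A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot_spectrum(spec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vibromix %s | %s | provenance: %s",
                     as.character(utils::packageVersion("vibromix")),
                     spec$label, spec$provenance), con)
  writeLines("energy_ev,absorbance", con)
  writeLines(sprintf("%.12g,%.12g", spec$energies, spec$values), con)
  invisible(path)
}
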