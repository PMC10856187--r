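# ECD spectrum synthesis from TDDFT rotatory strengths: Gaussian band
# broadening on the energy axis, Boltzmann weighting over conformers,
# wavelength (UV) correction, and cosine similarity scanning.

#' Construct a transition set
#'
#' One conformer's electronic transitions: excitation energies (eV) and
#' rotatory strengths (10^-40 cgs), plus the conformer's relative energy
#' used for Boltzmann weighting.
#'
#' @param conformer_id Label.
#' @param energy_ev Excitation energies in eV (all `> 0`; may be empty).
#' @param rotatory_strength Signed strengths in 10^-40 cgs, same length.
#' @param rel_energy Conformer relative energy in kcal/mol.
#' @return An object of class `transition_set`.
#' @export
transition_set <- function(conformer_id, energy_ev, rotatory_strength,
                           rel_energy = 0) {
  stopifnot(length(energy_ev) == length(rotatory_strength))
  if (length(energy_ev) > 0L) {
    stopifnot(all(energy_ev > 0), all(is.finite(rotatory_strength)))
  }
  structure(
    list(conformer_id = conformer_id, energy_ev = as.numeric(energy_ev),
         rotatory_strength = as.numeric(rotatory_strength),
         rel_energy = rel_energy),
    class = "transition_set"
  )
}

#' Read per-conformer transition tables
#'
#' Expected columns: `conformer_id, rel_energy_kcal`, one or both of
#' `energy_ev` / `wavelength_nm` (converted via
#' `E[eV] = 1239.84193 / lambda[nm]`; if both are present they must agree
#' to 1e-6 relative), and `rotatory_strength`. Each conformer must have a
#' single relative energy.
#'
#' @param path CSV/TSV path.
#' @return A named list of `transition_set` objects.
#' @export
read_transitions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, progress = FALSE,
                           show_col_types = FALSE, na = c("", "NA"))
  req <- c("conformer_id", "rel_energy_kcal", "rotatory_strength")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0L) {
    stop("transition table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_ev <- "energy_ev" %in% names(tab)
  has_nm <- "wavelength_nm" %in% names(tab)
  if (!has_ev && !has_nm) {
    stop("transition table needs energy_ev or wavelength_nm", call. = FALSE)
  }
  ev <- if (has_ev) tab$energy_ev else EV_NM / tab$wavelength_nm
  if (has_ev && has_nm) {
    ev_from_nm <- EV_NM / tab$wavelength_nm
    rel <- abs(ev_from_nm - tab$energy_ev) / tab$energy_ev
    if (any(rel > 1e-6, na.rm = TRUE)) {
      stop("inconsistent energy_ev and wavelength_nm at row ",
           which(rel > 1e-6)[1], call. = FALSE)
    }
  }
  out <- list()
  for (cid in unique(tab$conformer_id)) {
    sub <- tab[tab$conformer_id == cid, ]
    e <- unique(sub$rel_energy_kcal)
    if (length(e) != 1L) {
      stop("duplicate conformer_id ", cid, " with conflicting energies",
           call. = FALSE)
    }
    keep <- !is.na(sub$rotatory_strength)
    out[[as.character(cid)]] <- transition_set(
      cid, ev[tab$conformer_id == cid][keep], sub$rotatory_strength[keep], e)
  }
  out
}

#' Read an experimental ECD trace
#'
#' Two-column whitespace- or comma-delimited text (wavelength nm, delta
#' epsilon); `#` starts a comment line. The trace is sorted ascending in
#' wavelength.
#'
#' @param path Text file path.
#' @return An `ecd_spectrum`.
#' @export
read_ecd_trace <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) stop("malformed line ", bad[1], " in ", path, call. = FALSE)
  wl <- as.numeric(vapply(parts, `[[`, "", 1L))
  de <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(wl) || anyNA(de)) stop("non-numeric value in ", path, call. = FALSE)
  ord <- order(wl)
  ecd_spectrum(wl[ord], de[ord])
}

#' Construct an ECD spectrum
#'
#' @param wavelength_nm Ascending wavelength grid (nm).
#' @param d_eps Delta-epsilon values (M^-1 cm^-1), same length; `NA` marks
#'   points outside the supported window (excluded from comparisons).
#' @param sigma_ev Band width used to synthesize the curve, if any.
#' @param shift_nm Cumulative wavelength correction applied, if any.
#' @return An object of class `ecd_spectrum`.
#' @export
ecd_spectrum <- function(wavelength_nm, d_eps, sigma_ev = NA_real_,
                         shift_nm = 0) {
  stopifnot(length(wavelength_nm) == length(d_eps),
            !is.unsorted(wavelength_nm, strictly = TRUE))
  structure(
    list(wavelength_nm = as.numeric(wavelength_nm),
         d_eps = as.numeric(d_eps), sigma_ev = sigma_ev,
         shift_nm = shift_nm),
    class = "ecd_spectrum"
  )
}

#' @export
print.ecd_spectrum <- function(x, ...) {
  rng <- range(x$wavelength_nm)
  cat(sprintf("ECD spectrum: %d points, %.0f-%.0f nm", length(x$d_eps),
              rng[1], rng[2]))
  if (!is.na(x$sigma_ev)) cat(sprintf(", sigma %.2f eV", x$sigma_ev))
  if (x$shift_nm != 0) cat(sprintf(", shifted %+.1f nm", x$shift_nm))
  cat("\n")
  invisible(x)
}

#' Gaussian band broadening of a transition set
#'
#' On the energy axis,
#' `d_eps(E) = sum_i E_i * R_i / (gamma * sigma * sqrt(pi)) *
#' exp(-((E - E_i) / sigma)^2)` with `R` in 10^-40 cgs and `E`, `sigma` in
#' eV; `sigma` is the half-width at `d_eps_max / e`. The curve is evaluated
#' at the wavelength grid via the eV/nm conversion. The prefactor constant
#' `gamma = 22.97` is the cgs convention for rotatory strengths in 10^-40
#' esu^2 cm^2 and is exposed for other conventions.
#'
#' @param ts A `transition_set`.
#' @param sigma_ev Band width in eV (default 0.23).
#' @param grid_nm Wavelength grid (default 180-400 nm at 1 nm).
#' @param gamma_const Prefactor constant (default 22.97).
#' @return An `ecd_spectrum`.
#' @export
broaden_spectrum <- function(ts, sigma_ev = 0.23,
                             grid_nm = seq(180, 400, by = 1),
                             gamma_const = 22.97) {
  stopifnot(inherits(ts, "transition_set"), length(grid_nm) > 0L)
  if (!is.finite(sigma_ev) || sigma_ev <= 0) {
    stop("sigma_ev must be > 0", call. = FALSE)
  }
  grid_e <- EV_NM / grid_nm
  vals <- numeric(length(grid_nm))
  for (i in seq_along(ts$energy_ev)) {
    ei <- ts$energy_ev[i]
    ri <- ts$rotatory_strength[i]
    vals <- vals + ei * ri / (gamma_const * sigma_ev * sqrt(pi)) *
      exp(-((grid_e - ei) / sigma_ev)^2)
  }
  ecd_spectrum(grid_nm, vals, sigma_ev = sigma_ev)
}

#' Boltzmann-weighted average of per-conformer ECD spectra
#'
#' Weights come from [boltzmann_weights()] on the sets' relative energies;
#' the averaged curve is the pointwise weighted sum of the per-conformer
#' broadened spectra on a shared grid.
#'
#' @param sets List of `transition_set` objects.
#' @param temperature Kelvin (default 298.15).
#' @param sigma_ev,grid_nm,gamma_const Passed to [broaden_spectrum()].
#' @return An `ecd_spectrum`.
#' @export
boltzmann_average_spectra <- function(sets, temperature = 298.15,
                                      sigma_ev = 0.23,
                                      grid_nm = seq(180, 400, by = 1),
                                      gamma_const = 22.97) {
  stopifnot(length(sets) >= 1L)
  w <- boltzmann_weights(vapply(sets, function(s) s$rel_energy, numeric(1)),
                         temperature)
  vals <- numeric(length(grid_nm))
  for (i in seq_along(sets)) {
    sp <- broaden_spectrum(sets[[i]], sigma_ev = sigma_ev, grid_nm = grid_nm,
                           gamma_const = gamma_const)
    vals <- vals + w[i] * sp$d_eps
  }
  ecd_spectrum(grid_nm, vals, sigma_ev = sigma_ev)
}

#' Apply a wavelength (UV) correction to a spectrum
#'
#' Translates the spectrum by `delta_nm` (a feature at `lambda` moves to
#' `lambda + delta_nm`) and resamples onto the original grid by linear
#' interpolation. Grid points that fall outside the translated support are
#' `NA` and excluded from comparisons.
#'
#' @param s An `ecd_spectrum`.
#' @param delta_nm Shift in nm; must be smaller than the grid span.
#' @return The shifted `ecd_spectrum`.
#' @export
shift_spectrum <- function(s, delta_nm) {
  stopifnot(inherits(s, "ecd_spectrum"))
  span <- diff(range(s$wavelength_nm))
  if (abs(delta_nm) >= span) {
    stop("shift of ", delta_nm, " nm exceeds the grid span (", span, " nm)",
         call. = FALSE)
  }
  if (delta_nm == 0) return(s)
  ok <- !is.na(s$d_eps)
  res <- stats::approx(s$wavelength_nm[ok] + delta_nm, s$d_eps[ok],
                       xout = s$wavelength_nm, method = "linear",
                       rule = 1)
  ecd_spectrum(s$wavelength_nm, res$y, sigma_ev = s$sigma_ev,
               shift_nm = s$shift_nm + delta_nm)
}

# Cosine overlap of two spectra on their common non-NA window
# (trapezoidal integration). Returns NA when the overlap is degenerate.
spectrum_cosine <- function(calc, exp) {
  lo <- max(min(calc$wavelength_nm), min(exp$wavelength_nm))
  hi <- min(max(calc$wavelength_nm), max(exp$wavelength_nm))
  if (lo >= hi) return(list(similarity = NA_real_, window = c(NA, NA)))
  wl <- calc$wavelength_nm[calc$wavelength_nm >= lo & calc$wavelength_nm <= hi]
  f <- stats::approx(calc$wavelength_nm, calc$d_eps, xout = wl)$y
  g <- stats::approx(exp$wavelength_nm, exp$d_eps, xout = wl)$y
  ok <- !is.na(f) & !is.na(g)
  if (sum(ok) < 2L) return(list(similarity = NA_real_, window = c(NA, NA)))
  wl <- wl[ok]; f <- f[ok]; g <- g[ok]
  ff <- pracma::trapz(wl, f * f)
  gg <- pracma::trapz(wl, g * g)
  fg <- pracma::trapz(wl, f * g)
  if (ff == 0 || gg == 0) return(list(similarity = NA_real_, window = range(wl)))
  list(similarity = fg / sqrt(ff * gg), window = range(wl))
}

#' Best-shift cosine similarity between calculated and experimental ECD
#'
#' Scans wavelength corrections of the calculated spectrum over
#' `[-scan, +scan]` nm in steps of `step`, computing the normalized overlap
#' (cosine) `int f g / sqrt(int f^2 int g^2)` on the common window by
#' trapezoidal integration. Returns the maximizing shift; ties break to
#' the smallest `|shift|`.
#'
#' @param calc,exp `ecd_spectrum` objects with overlapping support.
#' @param scan Half-width of the shift scan in nm (default 15).
#' @param step Scan step in nm (default 1).
#' @return A `spectrum_comparison` list: `similarity` in `[-1, 1]`,
#'   `shift_nm`, `window` (nm), and the full `scan` tibble.
#' @export
similarity_with_shift <- function(calc, exp, scan = 15, step = 1) {
  stopifnot(inherits(calc, "ecd_spectrum"), inherits(exp, "ecd_spectrum"),
            scan >= 0, step > 0)
  shifts <- seq(-scan, scan, by = step)
  rows <- lapply(shifts, function(dl) {
    sc <- spectrum_cosine(shift_spectrum(calc, dl), exp)
    tibble::tibble(shift_nm = dl, similarity = sc$similarity,
                   window_lo = sc$window[1], window_hi = sc$window[2])
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$similarity))) {
    stop("no overlapping wavelength support between the spectra", call. = FALSE)
  }
  ord <- order(-tab$similarity, abs(tab$shift_nm))
  best <- tab[ord[1], ]
  structure(
    list(similarity = best$similarity, shift_nm = best$shift_nm,
         window = c(best$window_lo, best$window_hi), scan = tab),
    class = "spectrum_comparison"
  )
}

#' @export
print.spectrum_comparison <- function(x, ...) {
  cat(sprintf("ECD similarity %.4f at shift %+.1f nm (window %.0f-%.0f nm)\n",
              x$similarity, x$shift_nm, x$window[1], x$window[2]))
  invisible(x)
}

#' Write a spectrum as two-column text
#'
#' @param s An `ecd_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecd_trace <- function(s, path) {
  ok <- !is.na(s$d_eps)
  writeLines(c("# wavelength_nm d_eps",
               sprintf("%.6g %.10g", s$wavelength_nm[ok], s$d_eps[ok])),
             path)
  invisible(path)
}
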