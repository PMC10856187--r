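# Conformer-ensemble post-processing: energy-window filtering, Boltzmann
# weighting, shielding averaging, and shielding -> chemical shift
# conversion (empirical linear scaling and reference-based unscaled shifts).

#' Construct a conformer ensemble
#'
#' One candidate structure's DFT output: per-conformer relative energies
#' plus per-nucleus isotropic shieldings. Energies are re-based so the
#' minimum is 0. Every conformer must report every nucleus.
#'
#' @param candidate_id Candidate structure label.
#' @param energies Numeric vector of conformer energies (kcal/mol; any
#'   common offset is removed).
#' @param shieldings Numeric matrix, conformers x nuclei, columns named by
#'   `nucleus_id`.
#' @param nuclei Tibble `nucleus_id, element, hybridization,
#'   equivalence_group` (`element` "C" or "H"; `equivalence_group` `NA` for
#'   ungrouped nuclei).
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(candidate_id, energies, shieldings, nuclei) {
  stopifnot(length(energies) >= 1L, is.matrix(shieldings),
            nrow(shieldings) == length(energies))
  if (anyNA(energies) || any(!is.finite(energies))) {
    stop("non-finite conformer energies", call. = FALSE)
  }
  nuclei <- tibble::as_tibble(nuclei)
  req <- c("nucleus_id", "element", "hybridization", "equivalence_group")
  stopifnot(all(req %in% names(nuclei)))
  if (anyDuplicated(nuclei$nucleus_id)) {
    stop("duplicate nucleus_id in candidate ", candidate_id, call. = FALSE)
  }
  if (!setequal(colnames(shieldings), nuclei$nucleus_id)) {
    stop("shielding columns do not match the nucleus table for candidate ",
         candidate_id, call. = FALSE)
  }
  shieldings <- shieldings[, nuclei$nucleus_id, drop = FALSE]
  if (anyNA(shieldings)) {
    idx <- which(is.na(shieldings), arr.ind = TRUE)[1, ]
    stop("missing shielding for conformer ", idx[1], ", nucleus ",
         nuclei$nucleus_id[idx[2]], " (candidate ", candidate_id, ")",
         call. = FALSE)
  }
  grp <- nuclei$equivalence_group
  for (g in unique(grp[!is.na(grp)])) {
    el <- unique(nuclei$element[!is.na(grp) & grp == g])
    if (length(el) > 1L) {
      stop("equivalence group ", g, " mixes elements ",
           paste(el, collapse = "/"), call. = FALSE)
    }
  }
  structure(
    list(candidate_id = candidate_id,
         energies = energies - min(energies),
         shieldings = shieldings, nuclei = nuclei),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("Conformer ensemble", dQuote(x$candidate_id), "-",
      length(x$energies), "conformers,", nrow(x$nuclei), "nuclei\n")
  cat(sprintf("  relative energies: %.2f .. %.2f kcal/mol\n",
              min(x$energies), max(x$energies)))
  invisible(x)
}

#' Read conformer ensembles from a long-format table
#'
#' Expected columns: `candidate_id, conformer_id, rel_energy_kcal,
#' nucleus_id, element, hybridization, shielding_ppm`, and optionally
#' `equivalence_group`. With `energy_unit = "kJ"` the energy column is
#' named `rel_energy_kj` and converted at 4.184 kJ/kcal.
#'
#' @param path CSV/TSV path (delimiter sniffed from the header).
#' @param energy_unit `"kcal"` (default) or `"kJ"`.
#' @return A named list of `conformer_ensemble` objects, one per candidate.
#' @export
read_ensemble_table <- function(path, energy_unit = c("kcal", "kJ")) {
  energy_unit <- match.arg(energy_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, progress = FALSE,
                           show_col_types = FALSE, na = c("", "NA"))
  ecol <- if (energy_unit == "kcal") "rel_energy_kcal" else "rel_energy_kj"
  req <- c("candidate_id", "conformer_id", ecol, "nucleus_id", "element",
           "hybridization", "shielding_ppm")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0L) {
    stop("ensemble table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"equivalence_group" %in% names(tab)) tab$equivalence_group <- NA_character_
  energy <- tab[[ecol]]
  if (energy_unit == "kJ") energy <- energy / 4.184
  tab$.energy <- energy
  out <- list()
  for (cand in unique(tab$candidate_id)) {
    sub <- tab[tab$candidate_id == cand, ]
    conf_ids <- unique(sub$conformer_id)
    nuc_ids <- unique(sub$nucleus_id)
    for (cid in conf_ids) {
      have <- sub$nucleus_id[sub$conformer_id == cid]
      lack <- setdiff(nuc_ids, have)
      if (length(lack) > 0L) {
        stop("conformer ", cid, " of candidate ", cand,
             " lacks nucleus ", paste(lack, collapse = ", "),
             " reported by other conformers", call. = FALSE)
      }
    }
    bad <- which(is.na(sub$shielding_ppm))
    if (length(bad) > 0L) {
      stop("missing shielding for conformer ", sub$conformer_id[bad[1]],
           ", nucleus ", sub$nucleus_id[bad[1]], call. = FALSE)
    }
    m <- matrix(NA_real_, length(conf_ids), length(nuc_ids),
                dimnames = list(conf_ids, nuc_ids))
    for (i in seq_len(nrow(sub))) {
      m[as.character(sub$conformer_id[i]), sub$nucleus_id[i]] <- sub$shielding_ppm[i]
    }
    energies <- vapply(conf_ids, function(cid) {
      e <- unique(sub$.energy[sub$conformer_id == cid])
      if (length(e) != 1L) {
        stop("conformer ", cid, " of candidate ", cand,
             " has conflicting energies", call. = FALSE)
      }
      e
    }, numeric(1))
    nuclei <- unique(sub[c("nucleus_id", "element", "hybridization",
                           "equivalence_group")])
    if (anyDuplicated(nuclei$nucleus_id)) {
      stop("nucleus metadata inconsistent across rows for candidate ",
           cand, call. = FALSE)
    }
    out[[as.character(cand)]] <-
      conformer_ensemble(cand, unname(energies), m, nuclei)
  }
  out
}

#' Drop conformers above an energy window
#'
#' Retains conformers with relative energy `<= window` (boundary
#' inclusive); the energy minimum (0) is always retained. Order preserved.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param window Window in kcal/mol above the minimum (default 3.0).
#' @return The filtered `conformer_ensemble`.
#' @export
filter_energy_window <- function(ensemble, window = 3.0) {
  stopifnot(inherits(ensemble, "conformer_ensemble"), window > 0)
  keep <- ensemble$energies <= window
  conformer_ensemble(ensemble$candidate_id, ensemble$energies[keep],
                     ensemble$shieldings[keep, , drop = FALSE],
                     ensemble$nuclei)
}

#' Boltzmann population weights
#'
#' `w_i = exp(-E_i / RT) / sum_j exp(-E_j / RT)` with
#' `R = 1.9872041e-3 kcal mol^-1 K^-1`, computed with max-subtraction for
#' numerical stability. Invariant to adding a constant to all energies.
#'
#' @param energies Conformer energies in kcal/mol.
#' @param temperature Temperature in kelvin (default 298.15).
#' @return Weights summing to 1.
#' @export
boltzmann_weights <- function(energies, temperature = 298.15) {
  if (length(energies) == 0L) stop("empty energy list", call. = FALSE)
  stopifnot(temperature > 0, all(is.finite(energies)))
  softmax_log(-energies / (R_KCAL_MOL_K * temperature))
}

#' Boltzmann-average shieldings and collapse equivalence groups
#'
#' Per nucleus, the population-weighted mean shielding across conformers.
#' Equivalence groups (e.g. the three protons of a methyl) are then
#' replaced by their unweighted mean across group members, yielding one
#' value per experimental assignment; the group label becomes the
#' `nucleus_id` of the collapsed entry.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param weights Weights aligned with the conformers, summing to 1 (see
#'   [boltzmann_weights()]).
#' @return A tibble `nucleus_id, element, hybridization, shielding_ppm`.
#' @export
average_shieldings <- function(ensemble, weights) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (length(weights) != length(ensemble$energies)) {
    stop("weight vector length (", length(weights),
         ") does not match conformer count (", length(ensemble$energies), ")",
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("weights must sum to 1", call. = FALSE)
  }
  avg <- drop(crossprod(ensemble$shieldings, weights))
  nuc <- ensemble$nuclei
  grp <- nuc$equivalence_group
  key <- ifelse(is.na(grp), nuc$nucleus_id, grp)
  out <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    tibble::tibble(
      nucleus_id = k,
      element = nuc$element[idx[1]],
      hybridization = nuc$hybridization[idx[1]],
      shielding_ppm = mean(avg[nuc$nucleus_id[idx]])
    )
  })
  do.call(rbind, out)
}

#' Read empirical shielding-to-shift scaling factors
#'
#' JSON keyed by element, each entry `slope` (dimensionless, negative by
#' convention) and `intercept` (ppm), plus a top-level `provenance` string.
#'
#' @param path JSON path. Defaults to the factors bundled with the package.
#' @return A list with `C`, `H`, and `provenance`.
#' @export
read_scaling_factors <- function(path = system.file("extdata", "scaling_factors.json",
                                                    package = "fpcrevise")) {
  f <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (el in setdiff(names(f), "provenance")) {
    if (is.null(f[[el]]$slope) || is.null(f[[el]]$intercept) ||
        f[[el]]$slope == 0) {
      stop("invalid scaling factors for element ", el, call. = FALSE)
    }
  }
  f
}

#' Convert shieldings to shifts with global empirical scaling
#'
#' `delta = (intercept - sigma_iso) / (-slope)`, the standard convention
#' for regression factors fitted as `sigma = intercept + slope * delta`
#' (slope negative).
#'
#' @param shieldings Tibble from [average_shieldings()].
#' @param factors Per-element factors from [read_scaling_factors()].
#' @return The tibble with a `shift_ppm` column replacing `shielding_ppm`.
#' @export
scale_shifts_global <- function(shieldings, factors) {
  els <- unique(shieldings$element)
  lack <- setdiff(els, names(factors))
  if (length(lack) > 0L) {
    stop("no scaling factors for element(s): ", paste(lack, collapse = ", "),
         call. = FALSE)
  }
  slope <- vapply(shieldings$element, function(el) factors[[el]]$slope,
                  numeric(1), USE.NAMES = FALSE)
  intercept <- vapply(shieldings$element, function(el) factors[[el]]$intercept,
                      numeric(1), USE.NAMES = FALSE)
  out <- shieldings
  out$shift_ppm <- (intercept - shieldings$shielding_ppm) / (-slope)
  out$shielding_ppm <- NULL
  out
}

#' Unscaled shifts from a reference-standard shielding
#'
#' `delta_u = sigma_ref(element) - sigma_iso`, i.e. the shift relative to a
#' reference compound (TMS) computed at the same level of theory. Used by
#' the unscaled branch of DP4+.
#'
#' @param shieldings Tibble from [average_shieldings()].
#' @param sigma_ref Named numeric vector (or list) of reference shieldings
#'   per element, in ppm.
#' @return The tibble with a `shift_ppm` column replacing `shielding_ppm`.
#' @export
unscaled_shifts <- function(shieldings, sigma_ref) {
  sigma_ref <- unlist(sigma_ref)
  lack <- setdiff(unique(shieldings$element), names(sigma_ref))
  if (length(lack) > 0L) {
    stop("no reference shielding for element(s): ",
         paste(lack, collapse = ", "), call. = FALSE)
  }
  out <- shieldings
  out$shift_ppm <- unname(sigma_ref[shieldings$element]) - shieldings$shielding_ppm
  out$shielding_ppm <- NULL
  out
}

#' Per-candidate regression rescaling of calculated shifts
#'
#' For each element, least-squares fit of `calc = m * exp + b` over paired
#' nuclei; the scaled value is `(calc - b) / m`. This is the per-candidate
#' scaled branch used by DP4+ (distinct from the global empirical scaling).
#'
#' @param calc,exp Shift tibbles (`nucleus_id, element, ..., shift_ppm`)
#'   sharing at least 3 nuclei per element.
#' @return A list: `scaled` (tibble like `calc`), `fits` (tibble
#'   `element, slope, intercept, n`).
#' @export
regression_scale <- function(calc, exp) {
  j <- merge(calc[c("nucleus_id", "element", "shift_ppm")],
             exp[c("nucleus_id", "shift_ppm")],
             by = "nucleus_id", suffixes = c("_calc", "_exp"))
  out <- calc
  fits <- list()
  for (el in unique(j$element)) {
    sub <- j[j$element == el, ]
    if (nrow(sub) < 3L) {
      stop("need >= 3 paired nuclei for element ", el,
           " to fit the scaling regression (have ", nrow(sub), ")",
           call. = FALSE)
    }
    fit <- stats::lm(shift_ppm_calc ~ shift_ppm_exp, data = sub)
    m <- unname(stats::coef(fit)[2])
    b <- unname(stats::coef(fit)[1])
    if (!is.finite(m) || m == 0) {
      stop("degenerate regression (slope 0) for element ", el, call. = FALSE)
    }
    sel <- out$element == el
    out$shift_ppm[sel] <- (out$shift_ppm[sel] - b) / m
    fits[[el]] <- tibble::tibble(element = el, slope = m, intercept = b,
                                 n = nrow(sub))
  }
  list(scaled = out, fits = do.call(rbind, fits))
}

#' Shift-error statistics (MAE / RMSD)
#'
#' Errors are `calc - exp` over the shared nuclei of the requested element.
#' MAE = mean |error|; RMSD = sqrt(mean error^2); per-nucleus errors are
#' retained for absolute-error bar reports.
#'
#' @param calc,exp Shift tibbles with `nucleus_id, element, shift_ppm`.
#' @param element `"C"`, `"H"`, or `"all"`.
#' @param candidate_id Optional label carried into the result.
#' @return A `shift_comparison` list: `candidate_id`, `element`, `errors`
#'   (tibble `nucleus_id, element, calc_ppm, exp_ppm, error_ppm`), `mae`,
#'   `rmsd`, `n`.
#' @export
error_stats <- function(calc, exp, element = c("all", "C", "H"),
                        candidate_id = NULL) {
  element <- match.arg(element)
  j <- merge(calc[c("nucleus_id", "element", "shift_ppm")],
             exp[c("nucleus_id", "shift_ppm")],
             by = "nucleus_id", suffixes = c("_calc", "_exp"))
  if (element != "all") j <- j[j$element == element, ]
  if (nrow(j) == 0L) {
    miss <- setdiff(exp$nucleus_id, calc$nucleus_id)
    stop("no shared ", if (element == "all") "" else paste0(element, " "),
         "nuclei between calculated and experimental shifts",
         if (length(miss) > 0L) paste0("; unmatched experimental: ",
                                       paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  err <- j$shift_ppm_calc - j$shift_ppm_exp
  structure(
    list(candidate_id = candidate_id, element = element,
         errors = tibble::tibble(nucleus_id = j$nucleus_id,
                                 element = j$element,
                                 calc_ppm = j$shift_ppm_calc,
                                 exp_ppm = j$shift_ppm_exp,
                                 error_ppm = err),
         mae = mean(abs(err)), rmsd = sqrt(mean(err^2)), n = length(err)),
    class = "shift_comparison"
  )
}

#' @export
print.shift_comparison <- function(x, ...) {
  cat("Shift comparison", if (!is.null(x$candidate_id)) dQuote(x$candidate_id),
      "-", x$n, if (x$element == "all") "nuclei" else paste0(x$element, " nuclei"),
      "\n")
  cat(sprintf("  MAE %.3f ppm, RMSD %.3f ppm\n", x$mae, x$rmsd))
  invisible(x)
}

#' Read an experimental shift-assignment table
#'
#' Expected columns: `nucleus_id, element, hybridization, shift_ppm`;
#' `equivalence_group` is optional (experimental assignments are usually
#' already one value per group, keyed by the group label).
#'
#' @param path CSV/TSV path.
#' @return A shift tibble.
#' @export
read_shift_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, progress = FALSE,
                           show_col_types = FALSE, na = c("", "NA"))
  req <- c("nucleus_id", "element", "hybridization", "shift_ppm")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0L) {
    stop("assignment table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$nucleus_id)) {
    stop("duplicate nucleus_id in assignment table", call. = FALSE)
  }
  tibble::as_tibble(tab)
}
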