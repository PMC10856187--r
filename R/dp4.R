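# DP4+ candidate discrimination: Student-t likelihoods of scaled and
# unscaled shift errors, normalized over candidates in log space.

#' Student-t likelihood of a shift error
#'
#' `f(e) = t_nu((e - mu) / sigma) / sigma`, the density of a location-scale
#' Student-t at the standardized error.
#'
#' @param error Error(s) in ppm (vectorized).
#' @param mu Location (ppm).
#' @param sigma Scale (ppm), `> 0`.
#' @param nu Degrees of freedom, `> 0`.
#' @return Density value(s), strictly positive.
#' @export
t_likelihood <- function(error, mu, sigma, nu) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!is.finite(nu) || nu <= 0) stop("nu must be > 0", call. = FALSE)
  stats::dt((error - mu) / sigma, df = nu) / sigma
}

#' Read a DP4+ parameter table
#'
#' JSON keyed by level of theory. Each entry carries a `provenance` string
#' plus `scaled` parameters keyed by element (`C`, `H`) and `unscaled`
#' parameters keyed by element and, for carbon, hybridization (`C_sp2`,
#' `C_sp3`, `H`); every parameter set is `(mu, sigma, nu)`. Key
#' completeness is validated here, not at scoring time.
#'
#' @param path JSON path. Defaults to the table bundled with the package.
#' @param level Level-of-theory key (default the bundled
#'   mPW1PW91/6-311+G(d,p) entry).
#' @return A validated parameter list with elements `scaled`, `unscaled`,
#'   `provenance`.
#' @export
read_dp4_parameters <- function(path = system.file("extdata", "dp4_parameters.json",
                                                   package = "fpcrevise"),
                                level = "mPW1PW91/6-311+G(d,p)") {
  all <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!level %in% names(all)) {
    stop("level ", dQuote(level), " not in parameter file; available: ",
         paste(names(all), collapse = ", "), call. = FALSE)
  }
  p <- all[[level]]
  check <- function(branch, key) {
    ps <- p[[branch]][[key]]
    if (is.null(ps) || is.null(ps$mu) || is.null(ps$sigma) || is.null(ps$nu) ||
        ps$sigma <= 0 || ps$nu <= 0) {
      stop("DP4+ parameter table incomplete: need (mu, sigma, nu) for ",
           branch, "/", key, call. = FALSE)
    }
  }
  for (key in c("C", "H")) check("scaled", key)
  for (key in c("C_sp2", "C_sp3", "H")) check("unscaled", key)
  p
}

dp4_param_for <- function(params, branch, element, hybridization) {
  key <- if (branch == "unscaled" && element == "C") {
    paste0("C_", hybridization)
  } else {
    element
  }
  ps <- params[[branch]][[key]]
  if (is.null(ps)) {
    stop("missing DP4+ parameters for (", element, ", ", branch,
         if (element == "C" && branch == "unscaled")
           paste0(", ", hybridization), ")", call. = FALSE)
  }
  ps
}

#' DP4+ probability analysis over candidate structures
#'
#' For each candidate, the log-likelihood is the sum over nuclei of the log
#' Student-t likelihoods of the scaled errors (parameters keyed by element)
#' and of the unscaled errors (parameters keyed by element and, for
#' carbon, hybridization). Candidate probabilities are the softmax of the
#' log-likelihoods; component probabilities (scaled-only, unscaled-only,
#' carbon-only, proton-only) are softmaxes of the corresponding partial
#' sums. All accumulation is in log space with max-subtraction.
#'
#' @param candidates Named list (>= 2 entries); each entry a list with
#'   `scaled` and `unscaled` shift tibbles (`nucleus_id, element,
#'   hybridization, shift_ppm`) covering an identical nucleus set.
#' @param exp Experimental shift tibble.
#' @param params Parameter list from [read_dp4_parameters()].
#' @return A `dp4_result`: tibble `candidate_id, total, scaled, unscaled,
#'   carbon, proton` (each column summing to 1), with the per-candidate
#'   log-likelihood table in the `"loglik"` attribute.
#' @export
dp4_plus <- function(candidates, exp, params) {
  if (length(candidates) < 2L) stop("need at least 2 candidates", call. = FALSE)
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    stop("candidates must be a named list", call. = FALSE)
  }
  ref_ids <- sort(candidates[[1]]$scaled$nucleus_id)
  for (nm in names(candidates)) {
    for (branch in c("scaled", "unscaled")) {
      ids <- sort(candidates[[nm]][[branch]]$nucleus_id)
      if (!identical(ids, ref_ids)) {
        stop("nucleus coverage mismatch: candidate ", nm, " (", branch,
             " branch) does not match the first candidate", call. = FALSE)
      }
    }
  }
  shared <- intersect(ref_ids, exp$nucleus_id)
  if (length(shared) == 0L) {
    stop("no nuclei shared with the experimental assignments", call. = FALSE)
  }
  ll <- lapply(candidates, function(cand) {
    parts <- c(scaled_C = 0, scaled_H = 0, unscaled_C = 0, unscaled_H = 0)
    for (branch in c("scaled", "unscaled")) {
      tbl <- cand[[branch]]
      tbl <- tbl[match(shared, tbl$nucleus_id), ]
      e <- exp[match(shared, exp$nucleus_id), ]
      err <- tbl$shift_ppm - e$shift_ppm
      for (i in seq_along(shared)) {
        ps <- dp4_param_for(params, branch, tbl$element[i], tbl$hybridization[i])
        key <- paste0(branch, "_", tbl$element[i])
        parts[key] <- parts[key] +
          log(t_likelihood(err[i], ps$mu, ps$sigma, ps$nu))
      }
    }
    parts
  })
  ll <- do.call(rbind, ll)
  comp <- function(cols) unname(softmax_log(rowSums(ll[, cols, drop = FALSE])))
  res <- tibble::tibble(
    candidate_id = names(candidates),
    total = comp(colnames(ll)),
    scaled = comp(c("scaled_C", "scaled_H")),
    unscaled = comp(c("unscaled_C", "unscaled_H")),
    carbon = comp(c("scaled_C", "unscaled_C")),
    proton = comp(c("scaled_H", "unscaled_H"))
  )
  attr(res, "loglik") <- ll
  class(res) <- c("dp4_result", class(res))
  res
}

#' @export
print.dp4_result <- function(x, ...) {
  cat("DP4+ candidate probabilities:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s total %3.0f%%  (scaled %3.0f%%, unscaled %3.0f%%, C %3.0f%%, H %3.0f%%)\n",
                x$candidate_id[i], 100 * x$total[i], 100 * x$scaled[i],
                100 * x$unscaled[i], 100 * x$carbon[i], 100 * x$proton[i]))
  }
  invisible(x)
}

#' Full DFT-NMR scoring of candidate ensembles against experiment
#'
#' Convenience pipeline: energy-window filter, Boltzmann weighting,
#' shielding averaging, global empirical scaling (for MAE/RMSD reporting),
#' reference-based unscaled shifts plus per-candidate regression rescaling
#' (for DP4+), then [dp4_plus()].
#'
#' @param ensembles Named list of `conformer_ensemble` objects.
#' @param exp Experimental shift tibble (see [read_shift_table()]).
#' @param factors Scaling factors ([read_scaling_factors()]).
#' @param sigma_ref Named per-element reference shieldings (ppm).
#' @param params DP4+ parameters ([read_dp4_parameters()]).
#' @param window Energy window in kcal/mol (default 3.0).
#' @param temperature Kelvin (default 298.15).
#' @return A list: `comparisons` (per candidate, list of `shift_comparison`
#'   for `"C"`, `"H"`, `"all"` on globally scaled shifts), `dp4`
#'   (`dp4_result`), `shifts` (per candidate: `global`, `scaled`,
#'   `unscaled` tibbles and regression `fits`).
#' @export
score_candidates <- function(ensembles, exp, factors, sigma_ref, params,
                             window = 3.0, temperature = 298.15) {
  stopifnot(length(ensembles) >= 2L)
  shifts <- list()
  comparisons <- list()
  cands <- list()
  for (nm in names(ensembles)) {
    ens <- filter_energy_window(ensembles[[nm]], window)
    w <- boltzmann_weights(ens$energies, temperature)
    avg <- average_shieldings(ens, w)
    glob <- scale_shifts_global(avg, factors)
    unsc <- unscaled_shifts(avg, sigma_ref)
    reg <- regression_scale(unsc, exp)
    shifts[[nm]] <- list(global = glob, scaled = reg$scaled, unscaled = unsc,
                         fits = reg$fits)
    comparisons[[nm]] <- list(
      C = error_stats(glob, exp, "C", candidate_id = nm),
      H = error_stats(glob, exp, "H", candidate_id = nm),
      all = error_stats(glob, exp, "all", candidate_id = nm)
    )
    cands[[nm]] <- list(scaled = reg$scaled, unscaled = unsc)
  }
  list(comparisons = comparisons,
       dp4 = dp4_plus(cands, exp, params),
       shifts = shifts)
}
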