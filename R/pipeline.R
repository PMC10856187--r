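# Pipeline orchestration: run the fingerprint, DFT-NMR and ECD arms on
# whatever inputs are supplied and assemble a single revision report.

#' Run the structure-revision pipeline on one compound
#'
#' Executes the arms for which inputs are supplied, in order: fingerprint
#' classification, DFT-NMR candidate scoring (MAE/RMSD + DP4+), and ECD
#' comparison. Absent arms are skipped with a message and reported as
#' `NULL` in the result. The verdict is the candidate with the highest
#' DP4+ total probability (ties broken by lexicographic candidate id,
#' with a warning); the concordance flag is true iff every arm that
#' expresses a preference agrees with the verdict.
#'
#' @param fingerprint `NULL`, or a list with `dataset`
#'   (`fpc_fingerprints`) and `fp` (one-row record to assess); optional
#'   `threshold`, `k`, `autoscale` passed to [flag_misassignment()].
#' @param nmr `NULL`, or a list with `ensembles` (named list of
#'   `conformer_ensemble`), `exp` (shift tibble); optional `factors`,
#'   `sigma_ref`, `params`, `window`, `temperature` (defaults: bundled
#'   factors/parameters, [default_sigma_ref()], 3.0 kcal/mol, 298.15 K).
#' @param ecd `NULL`, or a list with `transitions` (named list, per
#'   candidate, of lists of `transition_set`) and `exp_spectrum`
#'   (`ecd_spectrum`); optional `sigma_ev`, `grid_nm`, `scan`, `step`,
#'   `temperature`.
#' @param candidate_classes Optional named character vector mapping
#'   candidate ids to fingerprint class labels, letting the fingerprint
#'   arm participate in the concordance check.
#' @param compound_id Label for the report (defaults to the fingerprint
#'   record's id, else `"compound"`).
#' @return A `revision_report` list: `compound_id`, `misassignment`,
#'   `comparisons`, `dp4`, `ecd`, `verdict` (`candidate_id`,
#'   `concordant`), `arms_run`.
#' @export
run_revision <- function(fingerprint = NULL, nmr = NULL, ecd = NULL,
                         candidate_classes = NULL, compound_id = NULL) {
  if (is.null(fingerprint) && is.null(nmr)) {
    stop("supply at least the fingerprint arm or the NMR arm", call. = FALSE)
  }
  if (!is.null(nmr) && !is.null(ecd)) {
    nmr_ids <- sort(names(nmr$ensembles))
    ecd_ids <- sort(names(ecd$transitions))
    if (!identical(nmr_ids, ecd_ids)) {
      stop("candidate ids differ between the NMR arm (",
           paste(nmr_ids, collapse = ", "), ") and the ECD arm (",
           paste(ecd_ids, collapse = ", "), ")", call. = FALSE)
    }
  }

  mis <- NULL
  if (!is.null(fingerprint)) {
    mis <- flag_misassignment(
      fingerprint$dataset, fingerprint$fp,
      threshold = fingerprint$threshold %||% 1.0,
      k = fingerprint$k %||% 2,
      autoscale = fingerprint$autoscale %||% TRUE)
  } else {
    message("fingerprint arm skipped: no inputs supplied")
  }

  comparisons <- NULL
  dp4 <- NULL
  if (!is.null(nmr)) {
    scored <- score_candidates(
      nmr$ensembles, nmr$exp,
      factors = nmr$factors %||% read_scaling_factors(),
      sigma_ref = nmr$sigma_ref %||% default_sigma_ref(),
      params = nmr$params %||% read_dp4_parameters(),
      window = nmr$window %||% 3.0,
      temperature = nmr$temperature %||% 298.15)
    comparisons <- scored$comparisons
    dp4 <- scored$dp4
  } else {
    message("NMR arm skipped: no inputs supplied")
  }

  ecd_results <- NULL
  if (!is.null(ecd)) {
    grid_nm <- ecd$grid_nm %||% seq(180, 400, by = 1)
    ecd_results <- lapply(ecd$transitions, function(sets) {
      calc <- boltzmann_average_spectra(
        sets, temperature = ecd$temperature %||% 298.15,
        sigma_ev = ecd$sigma_ev %||% 0.23, grid_nm = grid_nm)
      similarity_with_shift(calc, ecd$exp_spectrum,
                            scan = ecd$scan %||% 15, step = ecd$step %||% 1)
    })
  } else {
    message("ECD arm skipped: no inputs supplied")
  }

  verdict <- list(candidate_id = NULL, concordant = NA)
  if (!is.null(dp4)) {
    ord <- order(-dp4$total, dp4$candidate_id)
    top <- dp4$candidate_id[ord[1]]
    if (nrow(dp4) > 1L && dp4$total[ord[1]] - dp4$total[ord[2]] < 1e-12) {
      warning("DP4+ tie between candidates; resolved to ", top,
              " by lexicographic order", call. = FALSE)
    }
    agree <- logical(0)
    if (!is.null(ecd_results)) {
      sims <- vapply(ecd_results, function(x) x$similarity, numeric(1))
      best_ecd <- names(sims)[order(-sims, names(sims))[1]]
      agree <- c(agree, ecd = identical(best_ecd, top))
    }
    if (!is.null(mis) && !is.null(candidate_classes)) {
      agree <- c(agree,
                 fingerprint = identical(unname(candidate_classes[top]),
                                         mis$pca_nearest_class))
    }
    verdict <- list(candidate_id = top,
                    concordant = if (length(agree) > 0L) all(agree) else NA)
  }

  structure(
    list(compound_id = compound_id %||% (if (!is.null(mis)) mis$compound_id else "compound"),
         misassignment = mis, comparisons = comparisons, dp4 = dp4,
         ecd = ecd_results, verdict = verdict,
         arms_run = c(fingerprint = !is.null(mis), nmr = !is.null(dp4),
                      ecd = !is.null(ecd_results))),
    class = "revision_report"
  )
}

#' @export
print.revision_report <- function(x, ...) {
  cat("Revision report for", x$compound_id, "\n")
  if (!is.null(x$misassignment)) {
    cat(sprintf("  fingerprint: assigned %s, PCA nearest %s, flagged %s\n",
                dQuote(x$misassignment$assigned_class),
                dQuote(x$misassignment$pca_nearest_class),
                x$misassignment$flagged))
  }
  if (!is.null(x$dp4)) {
    for (i in seq_len(nrow(x$dp4))) {
      cmp <- x$comparisons[[x$dp4$candidate_id[i]]]
      cat(sprintf("  %-10s 13C MAE %.2f RMSD %.2f | 1H MAE %.3f | DP4+ %.1f%%\n",
                  x$dp4$candidate_id[i], cmp$C$mae, cmp$C$rmsd, cmp$H$mae,
                  100 * x$dp4$total[i]))
    }
  }
  if (!is.null(x$ecd)) {
    for (nm in names(x$ecd)) {
      cat(sprintf("  ECD %-10s similarity %.3f at %+.0f nm\n", nm,
                  x$ecd[[nm]]$similarity, x$ecd[[nm]]$shift_nm))
    }
  }
  if (!is.null(x$verdict$candidate_id)) {
    cat("  verdict:", x$verdict$candidate_id,
        if (isTRUE(x$verdict$concordant)) "(concordant)"
        else if (isFALSE(x$verdict$concordant)) "(arms disagree)"
        else "", "\n")
  }
  invisible(x)
}

report_to_list <- function(report) {
  num_tbl <- function(x) if (is.null(x)) NULL else as.list(tibble::as_tibble(x))
  mis <- report$misassignment
  list(
    version = as.character(utils::packageVersion("fpcrevise")),
    compound_id = report$compound_id,
    misassignment = if (is.null(mis)) NULL else list(
      compound_id = mis$compound_id, assigned_class = mis$assigned_class,
      pca_nearest_class = mis$pca_nearest_class,
      distances = num_tbl(mis$distances),
      deviations = num_tbl(mis$deviations),
      unevaluated = as.list(mis$unevaluated),
      max_deviation = mis$max_deviation, threshold = mis$threshold,
      flagged = mis$flagged),
    comparisons = if (is.null(report$comparisons)) NULL else lapply(
      report$comparisons, function(cands) lapply(cands, function(cmp) list(
        element = cmp$element, mae = cmp$mae, rmsd = cmp$rmsd, n = cmp$n,
        errors = num_tbl(cmp$errors)))),
    dp4 = num_tbl(report$dp4),
    ecd = if (is.null(report$ecd)) NULL else lapply(report$ecd, function(sc)
      list(similarity = sc$similarity, shift_nm = sc$shift_nm,
           window = as.list(sc$window))),
    verdict = list(candidate_id = report$verdict$candidate_id,
                   concordant = report$verdict$concordant)
  )
}

#' Write a revision report to disk
#'
#' Emits `report.json` (machine-readable, full precision, explicit nulls
#' for skipped arms, stable key order, package version and config hash
#' embedded) and `report.md` (human-readable summary). Identical reports
#' serialize byte-identically.
#'
#' @param report A `revision_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "revision_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  lst <- report_to_list(report)
  lst$config_hash <- rlang::hash(lst)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(lst, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, always_decimal = FALSE)
  md_path <- file.path(dir, "report.md")
  md <- c(paste("# Revision report:", report$compound_id), "")
  if (!is.null(report$misassignment)) {
    m <- report$misassignment
    md <- c(md, "## Fingerprint",
            sprintf("- assigned class: %s", m$assigned_class),
            sprintf("- PCA nearest class: %s", m$pca_nearest_class),
            sprintf("- max range deviation: %.3f ppm (threshold %.2f)",
                    m$max_deviation, m$threshold),
            sprintf("- flagged: %s", m$flagged), "")
  }
  if (!is.null(report$dp4)) {
    md <- c(md, "## DFT-NMR",
            "| candidate | 13C MAE | 13C RMSD | 1H MAE | DP4+ total |",
            "|---|---|---|---|---|")
    for (i in seq_len(nrow(report$dp4))) {
      nm <- report$dp4$candidate_id[i]
      cmp <- report$comparisons[[nm]]
      md <- c(md, sprintf("| %s | %.2f | %.2f | %.3f | %.0f%% |", nm,
                          cmp$C$mae, cmp$C$rmsd, cmp$H$mae,
                          100 * report$dp4$total[i]))
    }
    md <- c(md, "")
  }
  if (!is.null(report$ecd)) {
    md <- c(md, "## ECD")
    for (nm in names(report$ecd)) {
      md <- c(md, sprintf("- %s: similarity %.4f at %+.1f nm", nm,
                          report$ecd[[nm]]$similarity,
                          report$ecd[[nm]]$shift_nm))
    }
    md <- c(md, "")
  }
  if (!is.null(report$verdict$candidate_id)) {
    md <- c(md, "## Verdict",
            sprintf("- candidate: %s", report$verdict$candidate_id),
            sprintf("- concordant: %s", report$verdict$concordant))
  }
  writeLines(md, md_path)
  invisible(c(json = json_path, md = md_path))
}
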