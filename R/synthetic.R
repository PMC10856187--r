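# Seeded synthetic-data generators. These emulate the statistical
# structure of each pipeline input -- class-structured fingerprint
# vectors, conformer ensembles whose averaged scaled shifts deviate from
# experiment at a controlled scale, and sparse rotatory-strength tables --
# so every stage is testable without quantum-chemistry runs. Shieldings
# are statistical stand-ins, not computed observables.

#' Build class templates for the fingerprint generator
#'
#' Each template holds per-slot mean and sd (ppm) plus a per-slot missing
#' probability. Base means sit in chemically plausible ranges for this
#' compound family (core/olefinic carbons 90-170 ppm, carbonyls 185-200
#' ppm, aldehydic protons 9.5-10.5 ppm, phenolic protons 11-14 ppm).
#' Classes are separated by adding multiples of `separation` ppm to two
#' groups of co-moving diagnostic slots -- the ring-system axis (C2, C4,
#' C6) and the carbonyl-substitution axis (C1, C7, C9) -- mirroring how a
#' change of ring system or acyl substitution moves several core
#' positions together. Any two classes differ by at least `separation`
#' ppm on at least one slot, and the between-class structure spans a
#' two-dimensional subspace with balanced (uncorrelated) axes, so it is
#' recoverable from the first two principal components.
#'
#' @param n_classes Number of classes (2-8).
#' @param separation Diagnostic-slot mean separation in ppm (default 4).
#' @param sd Within-class sd in ppm for every slot (default 1).
#' @param missing_prob Named per-slot missing probabilities; defaults to
#'   0.25 for the second aldehydic and second phenolic proton slots.
#' @return A list of class templates.
#' @export
make_class_templates <- function(n_classes = 6, separation = 4, sd = 1,
                                 missing_prob = NULL) {
  stopifnot(n_classes >= 2L, n_classes <= 8L, separation > 0, sd > 0)
  base <- c(C1 = 160, C2 = 105, C3 = 163, C4 = 106, C5 = 161, C6 = 110,
            C7 = 192, C9 = 191, H_CHO_1 = 10.15, H_CHO_2 = 10.05,
            H_OH_1 = 12.6, H_OH_2 = 13.3)
  labels <- c("pyrano-diformyl", "oxepine-diformyl",
              "pyrano-3-acyl-1-formyl", "oxepine-1-formyl-3-acyl",
              "open-chain-diformyl", "triformyl",
              "dimeric-diformyl", "euglobal-type")[seq_len(n_classes)]
  mp <- c(C1 = 0, C2 = 0, C3 = 0, C4 = 0, C5 = 0, C6 = 0, C7 = 0, C9 = 0,
          H_CHO_1 = 0, H_CHO_2 = 0.25, H_OH_1 = 0, H_OH_2 = 0.25)
  if (!is.null(missing_prob)) mp[names(missing_prob)] <- missing_prob
  if (any(mp >= 1)) {
    stop("degenerate template: slot(s) always missing", call. = FALSE)
  }
  # class centroids on a balanced 2D grid: ring axis x, carbonyl axis y
  nx <- ceiling(n_classes / 2)
  grid <- list(x = (seq_len(n_classes) - 1L) %% nx,
               y = (seq_len(n_classes) - 1L) %/% nx)
  lapply(seq_len(n_classes), function(i) {
    mean <- base
    mean[c("C2", "C4", "C6")] <- mean[c("C2", "C4", "C6")] +
      separation * grid$x[i]
    mean[c("C1", "C7", "C9")] <- mean[c("C1", "C7", "C9")] +
      separation * grid$y[i]
    list(class = labels[i], mean = mean,
         sd = stats::setNames(rep(sd, 12), FP_SLOTS), missing_prob = mp)
  })
}

#' Generate a class-structured synthetic fingerprint dataset
#'
#' Per compound, each slot is drawn Normal(template mean, template sd) and
#' dropped with the template's missing probability. Deterministic for a
#' fixed seed (purpose-specific sub-stream, see [substream_seed()]).
#'
#' @param templates Templates from [make_class_templates()].
#' @param n_per_class Compounds per class (default 30).
#' @param seed Master seed.
#' @return A `fpc_fingerprints` tibble of `n_per_class * length(templates)`
#'   records.
#' @export
gen_fingerprint_dataset <- function(templates, n_per_class = 30, seed = 1) {
  stopifnot(length(templates) >= 2L, n_per_class >= 1L)
  set.seed(substream_seed(seed, "fingerprints"))
  rows <- list()
  for (ti in seq_along(templates)) {
    tp <- templates[[ti]]
    if (any(tp$missing_prob >= 1)) {
      stop("degenerate template for class ", tp$class, call. = FALSE)
    }
    for (i in seq_len(n_per_class)) {
      vals <- stats::rnorm(12, tp$mean[FP_SLOTS], tp$sd[FP_SLOTS])
      drop <- stats::runif(12) < tp$missing_prob[FP_SLOTS]
      vals[drop] <- NA_real_
      row <- tibble::as_tibble(as.list(stats::setNames(vals, FP_SLOTS)))
      row <- cbind(tibble::tibble(
        compound_id = sprintf("syn-%02d-%03d", ti, i),
        class = tp$class, solvent = "CDCl3"), row)
      rows[[length(rows) + 1L]] <- row
    }
  }
  fingerprint_dataset(do.call(rbind, rows))
}

#' Default reference shieldings for unscaled shifts
#'
#' Package-default per-element reference (TMS-like) shieldings in ppm,
#' configurable by the user for their own level of theory.
#'
#' @return Named numeric vector with elements `C` and `H`.
#' @export
default_sigma_ref <- function() c(C = 189.7, H = 31.9)

#' Scenario configuration for the DP4+ / ECD generators
#'
#' Defaults encode the error regimes the workflow is designed to resolve:
#' correct-candidate averaged-shift errors Normal(0, 1.9 ppm) for carbon
#' and Normal(0, 0.13 ppm) for proton, versus an incorrect candidate that
#' additionally carries 6 positions offset by Uniform(5, 12) ppm with
#' random sign -- the scale of localized deviations diagnostic of a wrong
#' ring system.
#'
#' @param seed Master seed.
#' @param n_carbons,n_protons Nuclei counts (defaults 25 / 15).
#' @param sd_c,sd_h Correct-candidate error sd in ppm (defaults 1.9 / 0.13).
#' @param n_offsets Offset positions in the incorrect candidate (default 6).
#' @param offset_min,offset_max Offset magnitude range in ppm (default
#'   5-12; must lie within \[0, 30\]).
#' @param n_conformers Conformers per candidate (default 5).
#' @param energy_mean Mean of the Exponential conformer-energy spread in
#'   kcal/mol (default 1).
#' @param jitter_sd Conformer-level shielding jitter sd in ppm (default
#'   0.3).
#' @param n_transitions Electronic transitions per conformer (default 8).
#' @param strength_scale Rotatory-strength sd in 10^-40 cgs (default 20).
#' @param ecd_shift_nm Planted wavelength displacement of the
#'   "experimental" ECD trace in nm (default 7).
#' @param ecd_noise Sd of additive noise on the experimental trace in
#'   delta-epsilon units (default 0.05).
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(seed = 1, n_carbons = 25, n_protons = 15,
                            sd_c = 1.9, sd_h = 0.13, n_offsets = 6,
                            offset_min = 5, offset_max = 12,
                            n_conformers = 5, energy_mean = 1,
                            jitter_sd = 0.3, n_transitions = 8,
                            strength_scale = 20, ecd_shift_nm = 7,
                            ecd_noise = 0.05) {
  stopifnot(n_carbons >= 1L, n_protons >= 1L, n_conformers >= 1L,
            n_transitions >= 1L, sd_c >= 0, sd_h >= 0, n_offsets >= 0L,
            offset_min >= 0, offset_max >= offset_min, offset_max <= 30,
            energy_mean > 0, jitter_sd >= 0)
  if (n_offsets > n_carbons) {
    stop("offset count (", n_offsets, ") exceeds carbon count (",
         n_carbons, ")", call. = FALSE)
  }
  structure(as.list(environment()), class = "scenario_config")
}

# Draw chemically plausible "true" shifts for a synthetic compound.
draw_true_shifts <- function(n_carbons, n_protons) {
  n_carbonyl <- min(2L, n_carbons)
  n_aromatic <- min(10L, n_carbons - n_carbonyl)
  n_aliph <- n_carbons - n_carbonyl - n_aromatic
  c_shift <- c(stats::runif(n_carbonyl, 185, 200),
               stats::runif(n_aromatic, 90, 170),
               stats::runif(n_aliph, 15, 85))
  c_hyb <- c(rep("sp2", n_carbonyl + n_aromatic), rep("sp3", n_aliph))
  n_ald <- min(2L, n_protons)
  n_phen <- min(2L, max(0L, n_protons - n_ald))
  n_rest <- n_protons - n_ald - n_phen
  h_shift <- c(stats::runif(n_ald, 9.5, 10.5), stats::runif(n_phen, 11, 14),
               stats::runif(n_rest, 0.8, 8.0))
  tibble::tibble(
    nucleus_id = c(sprintf("C-%d", seq_len(n_carbons)),
                   sprintf("H-%d", seq_len(n_protons))),
    element = c(rep("C", n_carbons), rep("H", n_protons)),
    hybridization = c(c_hyb, rep("sp3", n_protons)),
    shift_ppm = c(c_shift, h_shift)
  )
}

# Build a conformer ensemble whose Boltzmann-averaged, globally scaled
# shifts equal `target` exactly: shieldings are the inverse-scaled targets
# plus weight-centered conformer jitter.
build_ensemble_for_targets <- function(candidate_id, target, factors, cfg) {
  energies <- stats::rexp(cfg$n_conformers, rate = 1 / cfg$energy_mean)
  energies <- energies - min(energies)
  w <- boltzmann_weights(energies)
  slope <- vapply(target$element, function(el) factors[[el]]$slope,
                  numeric(1), USE.NAMES = FALSE)
  intercept <- vapply(target$element, function(el) factors[[el]]$intercept,
                      numeric(1), USE.NAMES = FALSE)
  n_nuc <- nrow(target)
  jit <- matrix(stats::rnorm(cfg$n_conformers * n_nuc, 0, cfg$jitter_sd),
                cfg$n_conformers, n_nuc)
  jit <- sweep(jit, 2L, drop(crossprod(jit, w)))
  sig <- matrix(rep(intercept + slope * target$shift_ppm,
                    each = cfg$n_conformers),
                cfg$n_conformers, n_nuc) + sweep(jit, 2L, slope, "*")
  colnames(sig) <- target$nucleus_id
  nuclei <- tibble::tibble(
    nucleus_id = target$nucleus_id, element = target$element,
    hybridization = target$hybridization,
    equivalence_group = NA_character_)
  conformer_ensemble(candidate_id, energies, sig, nuclei)
}

#' Generate a two-candidate DP4+ discrimination scenario
#'
#' Draws "true" experimental shifts, then builds two conformer ensembles:
#' the correct candidate, whose Boltzmann-averaged scaled shifts deviate
#' from experiment by Normal(0, `sd_c` / `sd_h`), and an incorrect
#' candidate carrying in addition `n_offsets` carbon positions displaced
#' by Uniform(`offset_min`, `offset_max`) ppm with random sign. Conformer
#' energies are Exponential(mean `energy_mean`) re-based to zero.
#' Shieldings are constructed by inverse application of the scaling
#' factors, so the analysis pipeline run with the same factors recovers
#' the planted shifts.
#'
#' @param cfg A [scenario_config()].
#' @param factors Scaling factors (default the bundled ones).
#' @param sigma_ref Reference shieldings (default [default_sigma_ref()]).
#' @return A list: `exp` (shift tibble), `ensembles` (named list `correct`,
#'   `incorrect`), `factors`, `sigma_ref`, `offset_nuclei`.
#' @export
gen_dp4_scenario <- function(cfg = scenario_config(),
                             factors = read_scaling_factors(),
                             sigma_ref = default_sigma_ref()) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(substream_seed(cfg$seed, "dp4"))
  exp <- draw_true_shifts(cfg$n_carbons, cfg$n_protons)
  sd_vec <- ifelse(exp$element == "C", cfg$sd_c, cfg$sd_h)
  correct_target <- exp
  correct_target$shift_ppm <- exp$shift_ppm + stats::rnorm(nrow(exp), 0, sd_vec)
  incorrect_target <- exp
  incorrect_target$shift_ppm <- exp$shift_ppm + stats::rnorm(nrow(exp), 0, sd_vec)
  carbon_idx <- which(exp$element == "C")
  off_idx <- sample(carbon_idx, cfg$n_offsets)
  if (cfg$n_offsets > 0L) {
    mag <- stats::runif(cfg$n_offsets, cfg$offset_min, cfg$offset_max)
    sgn <- sample(c(-1, 1), cfg$n_offsets, replace = TRUE)
    incorrect_target$shift_ppm[off_idx] <-
      incorrect_target$shift_ppm[off_idx] + sgn * mag
  }
  list(
    exp = exp,
    ensembles = list(
      correct = build_ensemble_for_targets("correct", correct_target, factors, cfg),
      incorrect = build_ensemble_for_targets("incorrect", incorrect_target, factors, cfg)
    ),
    factors = factors, sigma_ref = sigma_ref,
    offset_nuclei = exp$nucleus_id[off_idx]
  )
}

#' Generate an ECD recovery scenario
#'
#' Random sparse transition sets (wavelengths Uniform(200, 380) nm, signed
#' strengths Normal(0, `strength_scale`)) for `n_conformers` conformers;
#' the "experimental" trace is the broadened, Boltzmann-weighted spectrum
#' displaced by the planted `ecd_shift_nm` plus additive Normal noise. The
#' planted shift is returned: applying it to the calculated spectrum
#' re-aligns the two, so [similarity_with_shift()] should recover it.
#'
#' @param cfg A [scenario_config()].
#' @param sigma_ev,grid_nm Passed to the broadening step.
#' @return A list: `sets` (transition sets), `exp_spectrum`, `calc_spectrum`
#'   (unshifted Boltzmann average), `true_shift_nm`.
#' @export
gen_ecd_scenario <- function(cfg = scenario_config(), sigma_ev = 0.23,
                             grid_nm = seq(180, 400, by = 1)) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(substream_seed(cfg$seed, "ecd"))
  sets <- lapply(seq_len(cfg$n_conformers), function(i) {
    wl <- stats::runif(cfg$n_transitions, 200, 380)
    transition_set(sprintf("conf-%d", i), EV_NM / wl,
                   stats::rnorm(cfg$n_transitions, 0, cfg$strength_scale),
                   rel_energy = stats::rexp(1, 1 / cfg$energy_mean))
  })
  names(sets) <- vapply(sets, function(s) s$conformer_id, "")
  calc <- boltzmann_average_spectra(sets, sigma_ev = sigma_ev,
                                    grid_nm = grid_nm)
  exp_sp <- shift_spectrum(calc, cfg$ecd_shift_nm)
  if (cfg$ecd_noise > 0) {
    exp_sp$d_eps <- exp_sp$d_eps +
      stats::rnorm(length(exp_sp$d_eps), 0, cfg$ecd_noise)
  }
  list(sets = sets, exp_spectrum = exp_sp, calc_spectrum = calc,
       true_shift_nm = cfg$ecd_shift_nm)
}

#' Write a generated scenario to the on-disk schemas
#'
#' Emits the exact CSV schemas consumed by [read_ensemble_table()],
#' [read_shift_table()], [read_transitions()] and [read_ecd_trace()], so a
#' generated scenario can exercise the file-based entry points.
#'
#' @param scenario Output of [gen_dp4_scenario()] and/or
#'   [gen_ecd_scenario()] (a list; recognized elements are written).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (!is.null(scenario$exp)) {
    p <- file.path(dir, "experimental_shifts.csv")
    readr::write_csv(scenario$exp, p, progress = FALSE)
    files["exp"] <- p
  }
  if (!is.null(scenario$ensembles)) {
    rows <- list()
    for (nm in names(scenario$ensembles)) {
      ens <- scenario$ensembles[[nm]]
      for (i in seq_along(ens$energies)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          candidate_id = nm, conformer_id = sprintf("%s-c%d", nm, i),
          rel_energy_kcal = ens$energies[i],
          nucleus_id = ens$nuclei$nucleus_id,
          element = ens$nuclei$element,
          hybridization = ens$nuclei$hybridization,
          equivalence_group = ens$nuclei$equivalence_group,
          shielding_ppm = ens$shieldings[i, ])
      }
    }
    p <- file.path(dir, "ensembles.csv")
    readr::write_csv(do.call(rbind, rows), p, progress = FALSE)
    files["ensembles"] <- p
  }
  if (!is.null(scenario$sets)) {
    rows <- lapply(scenario$sets, function(s) {
      tibble::tibble(conformer_id = s$conformer_id,
                     rel_energy_kcal = s$rel_energy,
                     energy_ev = s$energy_ev,
                     rotatory_strength = s$rotatory_strength)
    })
    p <- file.path(dir, "transitions.csv")
    readr::write_csv(do.call(rbind, rows), p, progress = FALSE)
    files["transitions"] <- p
  }
  if (!is.null(scenario$exp_spectrum)) {
    p <- file.path(dir, "experimental_ecd.txt")
    write_ecd_trace(scenario$exp_spectrum, p)
    files["ecd"] <- p
  }
  invisible(files)
}
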