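# Small in-code fixtures shared across test files.

slot_names <- c("C1", "C2", "C3", "C4", "C5", "C6", "C7", "C9",
                "H_CHO_1", "H_CHO_2", "H_OH_1", "H_OH_2")

toy_fp_df <- function() {
  tibble::tibble(
    compound_id = c("a", "b", "c"),
    class = c("pyrano-diformyl", "pyrano-diformyl", "oxepine-diformyl"),
    solvent = "CDCl3",
    C1 = c(159.8, 160.1, 159.9), C2 = c(104.2, 104.6, 110.9),
    C3 = c(163.1, 162.8, 163.0), C4 = c(105.4, 105.1, 105.6),
    C5 = c(161.2, 161.0, 161.3), C6 = c(110.6, 110.2, 104.2),
    C7 = c(191.8, 192.0, 196.1), C9 = c(190.9, 191.2, NA),
    H_CHO_1 = c(10.12, 10.08, 10.11), H_CHO_2 = c(10.04, NA, 10.02),
    H_OH_1 = c(12.55, 12.63, 12.52), H_OH_2 = c(13.21, 13.35, 13.24)
  )
}

# Ensemble with two conformers and three nuclei; shieldings chosen so
# hand arithmetic is easy.
toy_ensemble <- function(candidate_id = "cand") {
  nuclei <- tibble::tibble(
    nucleus_id = c("C-1", "C-2", "H-1"),
    element = c("C", "C", "H"),
    hybridization = c("sp2", "sp3", "sp3"),
    equivalence_group = NA_character_)
  sh <- matrix(c(60, 100, 26, 64, 104, 28), nrow = 2, byrow = TRUE,
               dimnames = list(NULL, nuclei$nucleus_id))
  conformer_ensemble(candidate_id, c(0, 0.5), sh, nuclei)
}

random_ensemble <- function(n_conf, n_nuc, seed) {
  set.seed(seed)
  nuclei <- tibble::tibble(
    nucleus_id = sprintf("C-%d", seq_len(n_nuc)),
    element = "C", hybridization = "sp2",
    equivalence_group = NA_character_)
  sh <- matrix(runif(n_conf * n_nuc, 20, 180), n_conf, n_nuc,
               dimnames = list(NULL, nuclei$nucleus_id))
  conformer_ensemble("rand", runif(n_conf, 0, 6), sh, nuclei)
}

# Shift tibble helper.
shift_tbl <- function(ids, element, shift, hyb = NULL) {
  if (is.null(hyb)) hyb <- ifelse(element == "H", "sp3", "sp2")
  tibble::tibble(nucleus_id = ids, element = element,
                 hybridization = hyb, shift_ppm = shift)
}

default_params <- read_dp4_parameters()
default_factors <- read_scaling_factors()
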