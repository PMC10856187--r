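# Physical constants and shared helpers.

# Gas constant in kcal mol^-1 K^-1 (CODATA, conventional NMR usage).
R_KCAL_MOL_K <- 1.9872041e-3

# eV <-> nm conversion: E[eV] = EV_NM / lambda[nm]
EV_NM <- 1239.84193

# The 12 fingerprint feature slots: phloroglucinol core carbons C-1..C-6,
# formyl/acyl carbonyl carbons C-7 and C-9, then aldehydic and phenolic
# proton slots (up to two each).
FP_SLOTS <- c("C1", "C2", "C3", "C4", "C5", "C6", "C7", "C9",
              "H_CHO_1", "H_CHO_2", "H_OH_1", "H_OH_2")

fp_slot_is_carbon <- function(slot) startsWith(slot, "C")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-stream seed
#'
#' Generators draw from purpose-specific sub-streams so that adding a new
#' generator call does not perturb fixtures produced by existing ones. The
#' sub-seed is a deterministic 31-bit hash of the master seed and a purpose
#' label.
#'
#' @param seed Integer master seed.
#' @param purpose Character label naming the consumer of the stream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(purpose))
  codes <- utf8ToInt(purpose)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483647)
}

softmax_log <- function(loglik) {
  m <- max(loglik)
  w <- exp(loglik - m)
  w / sum(w)
}
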