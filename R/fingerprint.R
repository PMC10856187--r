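# Phloroglucinol NMR fingerprint container and I/O.
#
# A fingerprint is a 12-slot vector of diagnostic chemical shifts: the six
# phloroglucinol core carbons C-1..C-6, the carbonyl carbons C-7 and C-9,
# and up to two aldehydic plus two phenolic proton shifts. Slots may be
# missing (not every compound has two aldehyde protons); missingness is
# handled by column-mean imputation before any multivariate analysis.

#' Construct a fingerprint dataset
#'
#' Validates and classes a data frame of per-compound diagnostic NMR shifts.
#' Required columns: `compound_id`, `class`, `solvent`, and the 12 shift
#' slots `C1..C7, C9, H_CHO_1, H_CHO_2, H_OH_1, H_OH_2` (ppm, `NA` for
#' missing).
#'
#' Invariants enforced: unique compound ids; carbon shifts in \[0, 230\] ppm
#' and proton shifts in \[0, 20\] ppm where present; at least 6 of the 12
#' slots present per compound.
#'
#' @param df Data frame or tibble with the columns above.
#' @return A tibble of class `fpc_fingerprints`.
#' @export
fingerprint_dataset <- function(df) {
  required <- c("compound_id", "class", "solvent", FP_SLOTS)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("fingerprint table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[required]
  dup <- df$compound_id[duplicated(df$compound_id)]
  if (length(dup) > 0L) {
    stop("duplicate compound_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  for (slot in FP_SLOTS) {
    x <- df[[slot]]
    if (!is.numeric(x)) {
      stop("slot ", slot, " is not numeric", call. = FALSE)
    }
    lim <- if (fp_slot_is_carbon(slot)) c(0, 230) else c(0, 20)
    bad <- which(!is.na(x) & (x < lim[1] | x > lim[2]))
    if (length(bad) > 0L) {
      stop("slot ", slot, " outside [", lim[1], ", ", lim[2], "] ppm for ",
           paste(df$compound_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  n_present <- rowSums(!is.na(as.matrix(df[FP_SLOTS])))
  if (any(n_present < 6L)) {
    stop("compound(s) with fewer than 6 of 12 slots present: ",
         paste(df$compound_id[n_present < 6L], collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("fpc_fingerprints", class(df))
  df
}

#' Read a fingerprint table from CSV/TSV
#'
#' The delimiter is sniffed from the header line (tab if present, otherwise
#' comma). Empty cells denote missing slots; decimal separator is always
#' `"."` regardless of locale.
#'
#' @param path Path to a delimited text file.
#' @return A `fpc_fingerprints` tibble.
#' @export
read_fingerprint_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = "."), progress = FALSE,
    show_col_types = FALSE, na = c("", "NA")
  )
  required <- c("compound_id", "class", "solvent", FP_SLOTS)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("fingerprint table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (slot in FP_SLOTS) {
    cell <- raw[[slot]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad) > 0L) {
      stop("non-numeric shift value ", dQuote(cell[bad[1]]), " at row ",
           bad[1], ", column ", slot, call. = FALSE)
    }
    raw[[slot]] <- num
  }
  fingerprint_dataset(raw)
}

#' Write a fingerprint table to CSV
#'
#' Inverse of [read_fingerprint_table()]; round-trips all values exactly
#' (full double precision).
#'
#' @param dataset A `fpc_fingerprints` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_table <- function(dataset, path) {
  # readr emits the shortest decimal representation that round-trips the
  # double, so write -> read reproduces every shift bit-exactly
  readr::write_csv(tibble::as_tibble(dataset), path, na = "",
                   progress = FALSE)
  invisible(path)
}

fp_slot_matrix <- function(dataset) {
  m <- as.matrix(tibble::as_tibble(dataset)[FP_SLOTS])
  rownames(m) <- dataset$compound_id
  m
}

#' Impute missing fingerprint slots by column means
#'
#' Each missing cell is replaced by the mean of the observed values in its
#' slot; observed cells are unchanged. The logical imputation mask is kept
#' in the `"imputed"` attribute for reporting.
#'
#' @param dataset A `fpc_fingerprints` tibble.
#' @return The dataset with no missing slots and an `"imputed"` attribute.
#' @export
impute_missing <- function(dataset) {
  m <- fp_slot_matrix(dataset)
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0L)) {
    stop("slot(s) with no observed values: ",
         paste(FP_SLOTS[n_obs == 0L], collapse = ", "), call. = FALSE)
  }
  mask <- is.na(m)
  mu <- colMeans(m, na.rm = TRUE)
  for (j in seq_along(FP_SLOTS)) m[mask[, j], j] <- mu[j]
  out <- dataset
  for (j in seq_along(FP_SLOTS)) out[[FP_SLOTS[j]]] <- unname(m[, j])
  attr(out, "imputed") <- mask
  out
}

# Fill a single fingerprint record's missing slots with reference column
# means (typically those of the training dataset).
impute_record <- function(fp, means) {
  for (slot in FP_SLOTS) {
    if (is.na(fp[[slot]])) fp[[slot]] <- unname(means[slot])
  }
  fp
}
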