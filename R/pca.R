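# PCA of fingerprint matrices, nearest-centroid class assignment, and
# diagnostic-range misassignment flagging.
#
# The PCA is an eigendecomposition of the covariance of the processed
# (centered, optionally autoscaled) data matrix, population convention
# (divide by n). Autoscaling defaults to TRUE: proton slots live on a 0-20
# ppm scale and carbon slots on 0-230 ppm, so without unit variance the
# carbons would dominate every component.

#' Fit a principal component model
#'
#' @param x A numeric matrix (rows = observations) or a `fpc_fingerprints`
#'   dataset with no missing slots (see [impute_missing()]).
#' @param k Number of components to retain (`k <= ncol(x)`).
#' @param autoscale Scale columns to unit population variance after
#'   centering. Population convention: sd = sqrt(mean((x - mean)^2)).
#' @param ... Passed between methods.
#' @return An object of class `fpc_pca` with elements `center`, `scale`,
#'   `loadings` (p x k, columns orthonormal, sign fixed so each column's
#'   largest-magnitude element is positive), `explained_variance`
#'   (non-increasing), `total_variance`, `k`, `autoscale`.
#' @export
fit_pca <- function(x, k = 2, autoscale = TRUE, ...) UseMethod("fit_pca")

#' @rdname fit_pca
#' @export
fit_pca.matrix <- function(x, k = 2, autoscale = TRUE, ...) {
  p <- ncol(x)
  n <- nrow(x)
  stopifnot(k >= 1L, k <= p)
  if (n <= k) stop("need more observations than components", call. = FALSE)
  if (anyNA(x)) stop("matrix contains missing values; impute first", call. = FALSE)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  if (autoscale) {
    scl <- sqrt(colMeans(xc^2))
    if (any(scl == 0)) {
      stop("zero-variance column(s) with autoscale = TRUE: ",
           paste(colnames(x)[scl == 0] %||% which(scl == 0), collapse = ", "),
           call. = FALSE)
    }
  } else {
    scl <- rep(1, p)
  }
  names(scl) <- colnames(x)
  z <- sweep(xc, 2L, scl, "/")
  cv <- crossprod(z) / n
  e <- eigen(cv, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  load <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(x)
  structure(
    list(center = ctr, scale = scl, loadings = load,
         explained_variance = ev[seq_len(k)], total_variance = sum(ev),
         k = k, autoscale = autoscale, slot_names = colnames(x)),
    class = "fpc_pca"
  )
}

#' @rdname fit_pca
#' @export
fit_pca.fpc_fingerprints <- function(x, k = 2, autoscale = TRUE, ...) {
  fit_pca(fp_slot_matrix(x), k = k, autoscale = autoscale)
}

#' @export
print.fpc_pca <- function(x, ...) {
  cat("PCA model:", length(x$center), "features,", x$k, "components",
      if (x$autoscale) "(autoscaled)" else "(centered only)", "\n")
  pct <- 100 * x$explained_variance / x$total_variance
  cat("explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(x$k), pct), collapse = ", "), "\n")
  invisible(x)
}

#' Project observations into PC space
#'
#' Scores are `t(loadings) %*% ((x - center) / scale)`, so a record equal to
#' the training mean maps to the origin.
#'
#' @param model A `fpc_pca` model.
#' @param x A numeric vector (one record), matrix, or `fpc_fingerprints`
#'   dataset with no missing slots.
#' @return A numeric matrix of scores (observations x k).
#' @export
project <- function(model, x) {
  stopifnot(inherits(model, "fpc_pca"))
  if (inherits(x, "fpc_fingerprints")) x <- fp_slot_matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  if (anyNA(x)) stop("record has missing slots; impute before projecting", call. = FALSE)
  z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  z %*% model$loadings
}

fp_class_centroids <- function(model, dataset) {
  scores <- project(model, dataset)
  cls <- sort(unique(dataset$class))
  cent <- t(vapply(cls, function(cl) colMeans(scores[dataset$class == cl, , drop = FALSE]),
                   numeric(model$k)))
  n <- vapply(cls, function(cl) sum(dataset$class == cl), integer(1))
  list(classes = cls, centroids = cent, n = n)
}

#' Assign a fingerprint to its nearest class centroid in PC space
#'
#' Per-class centroids are computed from the training scores in the first
#' `k` components; the record is assigned to the class whose centroid is
#' nearest by Euclidean distance. Ties break to the lexicographically
#' smallest class label.
#'
#' @param model `fpc_pca` fitted on `dataset`.
#' @param dataset Imputed `fpc_fingerprints` training data (at least 2
#'   distinct classes).
#' @param fp A single fingerprint record (one-row tibble or named vector)
#'   with no missing slots.
#' @return A list with `nearest_class` and a `distances` tibble
#'   (`class`, `n`, `distance`, `note`); classes with fewer than 2 members
#'   carry a warning note but remain usable.
#' @export
assign_class <- function(model, dataset, fp) {
  if (length(unique(dataset$class)) < 2L) {
    stop("classification requires at least 2 distinct class labels", call. = FALSE)
  }
  cc <- fp_class_centroids(model, dataset)
  if (is.data.frame(fp)) fp <- unlist(fp[1, FP_SLOTS])
  s <- drop(project(model, fp[FP_SLOTS]))
  d <- sqrt(rowSums(sweep(cc$centroids, 2L, s)^2))
  tab <- tibble::tibble(
    class = cc$classes, n = cc$n, distance = unname(d),
    note = ifelse(cc$n < 2L, "fewer than 2 members; centroid unreliable", "")
  )
  ord <- order(tab$distance, tab$class)
  list(nearest_class = tab$class[ord[1]], distances = tab[ord, ])
}

#' Diagnostic chemical-shift ranges per class and slot
#'
#' For each (class, slot) with at least 3 observed values, records the
#' min/max shift and the observation count. Slots with fewer observations
#' are omitted (no reliable range).
#'
#' @param dataset A `fpc_fingerprints` tibble (missing values allowed).
#' @return A tibble `class, slot, min_ppm, max_ppm, n`.
#' @export
class_range_table <- function(dataset) {
  m <- fp_slot_matrix(dataset)
  rows <- list()
  for (cl in sort(unique(dataset$class))) {
    sub <- m[dataset$class == cl, , drop = FALSE]
    for (slot in FP_SLOTS) {
      x <- sub[, slot]
      x <- x[!is.na(x)]
      if (length(x) >= 3L) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          class = cl, slot = slot, min_ppm = min(x), max_ppm = max(x),
          n = length(x))
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-slot deviation of a fingerprint from a class's diagnostic ranges
#'
#' deviation = max(0, min_range - x, x - max_range); a value inside the
#' range deviates by 0. Slots missing in the record, or without a derivable
#' range for the class, contribute 0 and are listed as unevaluated.
#'
#' @param dataset Training `fpc_fingerprints` (missing values allowed).
#' @param fp One fingerprint record (one-row tibble or named vector;
#'   missing slots allowed).
#' @param class_label Class whose ranges to score against.
#' @return A list with `deviations` (tibble `slot, value_ppm, min_ppm,
#'   max_ppm, deviation_ppm`), `unevaluated` (slot names), and
#'   `max_deviation`.
#' @export
range_deviation <- function(dataset, fp, class_label) {
  ranges <- class_range_table(dataset)
  avail <- unique(ranges$class)
  if (!class_label %in% avail) {
    stop("unknown class ", dQuote(class_label), "; available: ",
         paste(avail, collapse = ", "), call. = FALSE)
  }
  ranges <- ranges[ranges$class == class_label, ]
  if (is.data.frame(fp)) fp <- unlist(fp[1, FP_SLOTS])
  rows <- list()
  unevaluated <- character()
  for (slot in FP_SLOTS) {
    x <- unname(fp[slot])
    r <- ranges[ranges$slot == slot, ]
    if (is.na(x) || nrow(r) == 0L) {
      unevaluated <- c(unevaluated, slot)
      next
    }
    dev <- max(0, r$min_ppm - x, x - r$max_ppm)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      slot = slot, value_ppm = x, min_ppm = r$min_ppm, max_ppm = r$max_ppm,
      deviation_ppm = dev)
  }
  devs <- do.call(rbind, rows)
  list(deviations = devs, unevaluated = unevaluated,
       max_deviation = if (is.null(devs)) 0 else max(devs$deviation_ppm))
}

#' Flag a compound whose class label is inconsistent with its shifts
#'
#' Combines PCA nearest-centroid assignment with diagnostic-range
#' deviations: the compound is flagged iff the nearest PCA class differs
#' from its assigned class, or the largest range deviation exceeds
#' `threshold`. The 1.0 ppm default is the smallest carbon-shift deviation
#' treated as diagnostic of misassignment in this compound family.
#'
#' @param dataset Training `fpc_fingerprints` (the record itself may or may
#'   not be a member).
#' @param fp One fingerprint record (one-row tibble with `compound_id`,
#'   `class`, and the 12 slots).
#' @param threshold Deviation threshold in ppm (default 1.0).
#' @param k Components for the PCA arm (default 2).
#' @param autoscale Passed to [fit_pca()].
#' @return A `misassignment_report` list: `compound_id`, `assigned_class`,
#'   `pca_nearest_class`, `distances`, `deviations`, `unevaluated`,
#'   `max_deviation`, `threshold`, `flagged`.
#' @export
flag_misassignment <- function(dataset, fp, threshold = 1.0, k = 2,
                               autoscale = TRUE) {
  stopifnot(is.data.frame(fp), nrow(fp) == 1L)
  imp <- impute_missing(dataset)
  model <- fit_pca(imp, k = k, autoscale = autoscale)
  means <- colMeans(fp_slot_matrix(imp))
  fp_filled <- impute_record(fp, means)
  ac <- assign_class(model, imp, fp_filled)
  rd <- range_deviation(dataset, fp, fp$class)
  flagged <- (ac$nearest_class != fp$class) || (rd$max_deviation > threshold)
  structure(
    list(compound_id = fp$compound_id, assigned_class = fp$class,
         pca_nearest_class = ac$nearest_class, distances = ac$distances,
         deviations = rd$deviations, unevaluated = rd$unevaluated,
         max_deviation = rd$max_deviation, threshold = threshold,
         flagged = flagged),
    class = "misassignment_report"
  )
}

#' @export
print.misassignment_report <- function(x, ...) {
  cat("Compound", x$compound_id, "assigned", dQuote(x$assigned_class), "\n")
  cat("  PCA nearest class:", x$pca_nearest_class, "\n")
  cat(sprintf("  max range deviation: %.2f ppm (threshold %.2f)\n",
              x$max_deviation, x$threshold))
  cat("  flagged:", x$flagged, "\n")
  invisible(x)
}

#' Leave-one-out nearest-centroid accuracy
#'
#' The PCA basis is fitted once on the full (imputed) dataset; for each
#' record, class centroids are recomputed with that record held out and the
#' record is assigned to the nearest centroid.
#'
#' @param dataset A `fpc_fingerprints` tibble.
#' @param k,autoscale Passed to [fit_pca()].
#' @return Fraction of records whose held-out assignment matches their
#'   label.
#' @export
loo_centroid_accuracy <- function(dataset, k = 2, autoscale = TRUE) {
  imp <- impute_missing(dataset)
  model <- fit_pca(imp, k = k, autoscale = autoscale)
  scores <- project(model, imp)
  cls <- dataset$class
  labels <- sort(unique(cls))
  correct <- logical(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    d <- vapply(labels, function(cl) {
      idx <- which(cls == cl)
      idx <- setdiff(idx, i)
      if (length(idx) == 0L) return(Inf)
      cen <- colMeans(scores[idx, , drop = FALSE])
      sqrt(sum((scores[i, ] - cen)^2))
    }, numeric(1))
    correct[i] <- labels[order(d, labels)[1]] == cls[i]
  }
  mean(correct)
}
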