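# Optional ggplot2 figures: PC score maps, per-nucleus absolute-error
# bars, and calculated/experimental ECD overlays.

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}

#' PC1/PC2 score scatter colored by class
#'
#' @param model A `fpc_pca` with `k >= 2`.
#' @param dataset Imputed `fpc_fingerprints` training data.
#' @param highlight Optional compound ids to label.
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(model, dataset, highlight = NULL) {
  require_ggplot()
  stopifnot(model$k >= 2L)
  s <- project(model, dataset)
  df <- data.frame(PC1 = s[, 1], PC2 = s[, 2], class = dataset$class,
                   compound_id = dataset$compound_id)
  pct <- 100 * model$explained_variance / model$total_variance
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                        color = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2]), color = "class") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    sel <- df[df$compound_id %in% highlight, ]
    p <- p + ggplot2::geom_text(data = sel,
                                ggplot2::aes(label = .data$compound_id),
                                color = "black", vjust = -0.8, size = 3)
  }
  p
}

#' Per-nucleus absolute-error bars for candidate structures
#'
#' @param comparisons Named list of `shift_comparison` objects (one per
#'   candidate, same element selection).
#' @return A ggplot object.
#' @export
plot_error_bars <- function(comparisons) {
  require_ggplot()
  df <- do.call(rbind, lapply(names(comparisons), function(nm) {
    e <- comparisons[[nm]]$errors
    data.frame(candidate = nm, nucleus_id = e$nucleus_id,
               abs_error = abs(e$error_ppm))
  }))
  df$nucleus_id <- factor(df$nucleus_id, levels = unique(df$nucleus_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$nucleus_id, .data$abs_error,
                                   fill = .data$candidate)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "|calc - exp| (ppm)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Overlay calculated and experimental ECD spectra
#'
#' @param calc,exp `ecd_spectrum` objects.
#' @param shift_nm Optional wavelength correction applied to `calc` before
#'   plotting.
#' @return A ggplot object.
#' @export
plot_ecd_overlay <- function(calc, exp, shift_nm = 0) {
  require_ggplot()
  if (shift_nm != 0) calc <- shift_spectrum(calc, shift_nm)
  df <- rbind(
    data.frame(wavelength_nm = calc$wavelength_nm, d_eps = calc$d_eps,
               trace = "calculated"),
    data.frame(wavelength_nm = exp$wavelength_nm, d_eps = exp$d_eps,
               trace = "experimental"))
  ggplot2::ggplot(df[!is.na(df$d_eps), ],
                  ggplot2::aes(.data$wavelength_nm, .data$d_eps,
                               color = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression(Delta * epsilon ~ (M^-1 ~ cm^-1)),
                  color = NULL) +
    ggplot2::theme_minimal()
}
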