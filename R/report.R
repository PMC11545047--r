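metrics_table <- function(agg) {
  data.frame(
    `True Class` = names(agg$sensitivity$mean),
    `Sensitivity (%)` = fmt_pm(agg$sensitivity$mean, agg$sensitivity$sd),
    `Specificity (%)` = fmt_pm(agg$specificity$mean, agg$specificity$sd),
    `Accuracy (%)` = c(fmt_pm(agg$accuracy$mean, agg$accuracy$sd),
                       rep("", length(agg$sensitivity$mean) - 1)),
    `Error (%)` = c(fmt_pm(agg$error$mean, agg$error$sd),
                    rep("", length(agg$sensitivity$mean) - 1)),
    check.names = FALSE)
}

#' Write the performance report of an rDCV result
#'
#' Emits plain-text tables and figures: the per-class
#' sensitivity/specificity table with overall accuracy and mean class
#' error (mean over runs, +/- standard deviation), the row-percent
#' confusion matrix, the per-sample mean canonical scores with 95%
#' confidence intervals, and -- when variable selection was active --
#' the selection-frequency table and a frequency plot with the stable
#' wavelengths marked. If `spectra` is supplied, a PCA score plot of
#' the pre-processed spectra is added.
#'
#' @param result An [run_rdcv()] result.
#' @param dir Output directory (created if missing).
#' @param spectra Optional [spectra_set()] used for the PCA score plot.
#' @return Invisibly, the paths written.
#' @export
report <- function(result, dir, spectra = NULL) {
  stopifnot(inherits(result, "rdcv_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name, rn = FALSE) {
    p <- file.path(dir, name)
    write_atomic(p, function(f)
      utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = rn))
    paths <<- c(paths, p)
  }

  wt(metrics_table(result$aggregate), "metrics.tsv")

  cmp <- rdcv_confusion(result)
  cm_df <- matrix(fmt_pm(cmp$mean, cmp$sd), nrow(cmp$mean),
                  dimnames = list(result$classes, result$classes))
  wt(as.data.frame(cm_df), "confusion_rowpct.tsv", rn = TRUE)

  sc <- score_summary(result)
  wt(sc, "scores.tsv")

  grDevices::png(file.path(dir, "scores.png"), 800, 500)
  ord <- order(sc$class, sc$mean)
  graphics::plot(seq_along(ord), sc$mean[ord], col = as.integer(sc$class[ord]),
                 pch = 16, cex = 0.6, xlab = "sample (grouped by class)",
                 ylab = "canonical score (LV1)",
                 main = "Mean outer-loop canonical scores (95% CI)")
  graphics::segments(seq_along(ord), sc$lower[ord], seq_along(ord), sc$upper[ord],
                     col = as.integer(sc$class[ord]))
  graphics::legend("topleft", legend = levels(sc$class), col = seq_along(levels(sc$class)),
                   pch = 16, bty = "n")
  grDevices::dev.off()
  paths <- c(paths, file.path(dir, "scores.png"))

  if (!is.null(result$selected) && is.null(result$fixed_subset)) {
    freq <- selection_frequency(result)
    stable <- stable_subset(freq, result$config$stability_threshold)
    wt(data.frame(wavelength_nm = result$variable_wavelengths,
                  frequency = freq,
                  stable = seq_along(freq) %in% stable),
       "selection_frequency.tsv")
    grDevices::png(file.path(dir, "selection_frequency.png"), 800, 500)
    graphics::plot(result$variable_wavelengths, freq, type = "h",
                   xlab = "wavelength (nm)", ylab = "selection frequency",
                   ylim = c(0, 1), main = "CovSel selection frequency")
    graphics::abline(h = result$config$stability_threshold, lty = 2)
    if (length(stable))
      graphics::abline(v = result$variable_wavelengths[stable], col = "red")
    grDevices::dev.off()
    paths <- c(paths, file.path(dir, "selection_frequency.png"))
  }

  if (!is.null(spectra)) {
    pp <- fit_apply_pipeline(result$config$pipelines[[1]],
                             spectra$reflectance,
                             spacing = stats::median(diff(spectra$wavelengths)))
    pc <- pca(mean_center(pp$train), n_components = 2)
    grDevices::png(file.path(dir, "pca_scores.png"), 650, 600)
    graphics::plot(pc$scores, col = as.integer(spectra$labels), pch = 16,
                   xlab = sprintf("PC1 (%.1f%%)", 100 * pc$explained[1]),
                   ylab = sprintf("PC2 (%.1f%%)", 100 * pc$explained[2]),
                   main = "PCA scores of pre-processed spectra")
    graphics::legend("topright", legend = levels(droplevels(spectra$labels)),
                     col = seq_len(nlevels(droplevels(spectra$labels))),
                     pch = 16, bty = "n")
    grDevices::dev.off()
    paths <- c(paths, file.path(dir, "pca_scores.png"))
  }
  invisible(paths)
}
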