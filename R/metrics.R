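#' Confusion matrix
#'
#' Counts of true class (rows) against predicted class (columns), with
#' class order fixed by severity rank.
#'
#' @param true,predicted Factors (or values coercible to factors with
#'   the same levels).
#' @param classes Class levels; default: levels of `true`.
#' @return Integer matrix of class `confusion`.
#' @export
confusion <- function(true, predicted, classes = NULL) {
  if (is.null(classes))
    classes <- if (is.factor(true)) levels(true) else sort(unique(c(true, predicted)))
  true <- factor(true, levels = classes)
  predicted <- factor(predicted, levels = classes)
  if (length(true) != length(predicted)) stop("label vectors differ in length")
  if (anyNA(true) || anyNA(predicted)) stop("labels outside the class set")
  cm <- table(true = true, predicted = predicted)
  structure(unclass(cm), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) { print(unclass(x)); invisible(x) }

#' Per-class sensitivity (true-positive rate)
#'
#' `100 * TP / (TP + FN)` for class `k`: the percentage of class-`k`
#' samples predicted as class `k`.
#'
#' @param cm A [confusion()] matrix.
#' @param k Class index or name.
#' @return Percentage in \[0, 100\].
#' @export
sensitivity <- function(cm, k) {
  if (is.character(k)) k <- match(k, rownames(cm))
  n_k <- sum(cm[k, ])
  if (n_k == 0) stop("class has no true samples")
  100 * cm[k, k] / n_k
}

#' Per-class specificity (true-negative rate)
#'
#' `100 * TN / (TN + FP)` for class `k`: the percentage of non-`k`
#' samples not predicted as class `k`. In a two-class problem
#' specificity of one class equals sensitivity of the other.
#'
#' @inheritParams sensitivity
#' @export
specificity <- function(cm, k) {
  if (is.character(k)) k <- match(k, rownames(cm))
  neg <- sum(cm[-k, , drop = FALSE])
  if (neg == 0) stop("no true samples outside the class")
  fp <- sum(cm[-k, k])
  100 * (neg - fp) / neg
}

#' Overall classification accuracy
#'
#' `100 * trace / total`, algebraically identical to the
#' class-count-weighted mean of the per-class sensitivities.
#'
#' @param cm A [confusion()] matrix.
#' @export
overall_accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  100 * sum(diag(as.matrix(unclass(cm)))) / tot
}

#' Overall accuracy from per-class sensitivities and class sizes
#'
#' The algebraic identity behind [overall_accuracy()]: trace/total
#' equals the class-count-weighted mean of the per-class
#' sensitivities. Lets the overall figure be recomputed from a
#' published per-class table without the underlying confusion matrix.
#'
#' @param sens Per-class sensitivities (percent).
#' @param counts Per-class sample counts.
#' @export
accuracy_from_sensitivities <- function(sens, counts) {
  if (length(sens) != length(counts)) stop("length mismatch")
  if (sum(counts) <= 0) stop("total count must be positive")
  sum(counts * sens) / sum(counts)
}

#' Mean class error
#'
#' Macro-average over classes of `100 - sensitivity`: the error figure
#' reported alongside accuracy in classification tables. Unlike
#' `100 - accuracy` it weights every class equally, so it is not
#' dominated by the largest class.
#'
#' @param sens Vector of per-class sensitivities (percent), or a
#'   [confusion()] matrix.
#' @export
mean_class_error <- function(sens) {
  if (inherits(sens, "confusion") || is.matrix(sens))
    sens <- vapply(seq_len(nrow(sens)), function(k) sensitivity(sens, k), 0)
  if (!length(sens)) stop("need at least one class")
  mean(100 - sens)
}

#' All performance statistics from one confusion matrix
#'
#' @param cm A [confusion()] matrix.
#' @return Object of class `class_metrics`: per-class `sensitivity` and
#'   `specificity` (percent), `accuracy`, `error` (mean class error).
#' @export
class_metrics <- function(cm) {
  ks <- seq_len(nrow(cm))
  sens <- vapply(ks, function(k) sensitivity(cm, k), 0)
  spec <- vapply(ks, function(k) specificity(cm, k), 0)
  names(sens) <- names(spec) <- rownames(cm)
  structure(list(sensitivity = sens, specificity = spec,
                 accuracy = overall_accuracy(cm),
                 error = mean_class_error(sens)),
            class = "class_metrics")
}

#' Aggregate metrics over repeated cross-validation runs
#'
#' Element-wise mean and sample standard deviation of per-run metrics;
#' with a single run all standard deviations are 0.
#'
#' @param runs List of [class_metrics()] objects, one per run.
#' @return Object of class `class_metrics_agg`: each statistic as a
#'   `mean` / `sd` pair.
#' @export
aggregate_metrics <- function(runs) {
  if (!length(runs)) stop("need at least one run")
  nm <- names(runs[[1]]$sensitivity)
  for (r in runs)
    if (!identical(names(r$sensitivity), nm))
      stop("inconsistent class sets across runs")
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  col_stat <- function(field) {
    M <- do.call(rbind, lapply(runs, `[[`, field))
    list(mean = colMeans(M), sd = apply(M, 2, sd0))
  }
  num_stat <- function(field) {
    v <- vapply(runs, `[[`, 0, field)
    list(mean = mean(v), sd = sd0(v))
  }
  structure(list(sensitivity = col_stat("sensitivity"),
                 specificity = col_stat("specificity"),
                 accuracy = num_stat("accuracy"),
                 error = num_stat("error"),
                 n_runs = length(runs)),
            class = "class_metrics_agg")
}

round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

fmt_pm <- function(m, s, digits = 1)
  sprintf("%.*f ± %.*f", digits, round_half_up(m, digits),
          digits, round_half_up(s, digits))

#' @export
print.class_metrics <- function(x, ...) {
  df <- data.frame(Class = names(x$sensitivity),
                   `Sensitivity (%)` = round_half_up(x$sensitivity),
                   `Specificity (%)` = round_half_up(x$specificity),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  cat(sprintf("Accuracy (%%): %.1f   Error (%%): %.1f\n",
              round_half_up(x$accuracy), round_half_up(x$error)))
  invisible(x)
}

#' @export
print.class_metrics_agg <- function(x, ...) {
  df <- data.frame(Class = names(x$sensitivity$mean),
    `Sensitivity (%)` = fmt_pm(x$sensitivity$mean, x$sensitivity$sd),
    `Specificity (%)` = fmt_pm(x$specificity$mean, x$specificity$sd),
    check.names = FALSE)
  print(df, row.names = FALSE)
  cat("Accuracy (%):", fmt_pm(x$accuracy$mean, x$accuracy$sd),
      "  Error (%):", fmt_pm(x$error$mean, x$error$sd),
      sprintf("  [%d runs]\n", x$n_runs))
  invisible(x)
}

#' Row-percent confusion matrix
#'
#' Each row rescaled to percentages of its true-class total (the layout
#' used to report multi-class confusion in grading studies).
#'
#' @param cm A [confusion()] matrix (or an averaged numeric matrix).
#' @export
confusion_row_percent <- function(cm) {
  m <- as.matrix(unclass(cm))
  sweep(m, 1, rowSums(m), `/`) * 100
}
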