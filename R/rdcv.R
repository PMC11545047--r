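#' Configuration of the repeated double cross-validation engine
#'
#' The engine wraps an outer loop (unbiased performance estimation)
#' around an inner loop (model selection: pre-treatment, number of
#' latent variables and, optionally, number of CovSel variables),
#' repeated over many random partitions. Defaults follow the grading
#' study design: 10 outer segments, 9 inner segments, 50 runs.
#'
#' @param n_outer Outer segments (>= 2).
#' @param n_inner Inner segments (>= 2).
#' @param n_runs Number of repeated runs (>= 1).
#' @param stratified Stratify segment assignment by class (recommended:
#'   the class counts are strongly unbalanced).
#' @param selection `"none"` or `"covsel"` (greedy covariance-based
#'   variable selection fitted inside each training set).
#' @param n_lv_grid Candidate numbers of latent variables.
#' @param n_select_grid Candidate numbers of CovSel variables (used
#'   only when `selection = "covsel"`).
#' @param pipelines List of candidate [pipeline_spec()]s searched in
#'   the inner loop. With `selection = "covsel"` exactly one pipeline
#'   is allowed, so that variable indices are comparable across all
#'   fitted models.
#' @param stability_threshold Selection-frequency threshold defining
#'   the stable variable subset (fraction of models, default 0.8).
#' @return Object of class `rdcv_config`.
#' @export
rdcv_config <- function(n_outer = 10, n_inner = 9, n_runs = 50,
                        stratified = TRUE,
                        selection = c("none", "covsel"),
                        n_lv_grid = 1:10,
                        n_select_grid = c(10, 20, 30, 40, 50),
                        pipelines = list(default_pipeline()),
                        stability_threshold = 0.8) {
  selection <- match.arg(selection)
  if (n_outer < 2 || n_inner < 2 || n_runs < 1)
    stop("need n_outer >= 2, n_inner >= 2, n_runs >= 1")
  if (stability_threshold <= 0 || stability_threshold > 1)
    stop("stability_threshold must be in (0, 1]")
  if (!length(n_lv_grid)) stop("empty n_lv_grid")
  n_lv_grid <- sort(unique(as.integer(n_lv_grid)))
  if (any(n_lv_grid < 1)) stop("n_lv_grid entries must be >= 1")
  if (selection == "covsel") {
    if (!length(n_select_grid)) stop("empty n_select_grid")
    n_select_grid <- sort(unique(as.integer(n_select_grid)))
    if (any(n_select_grid < 1)) stop("n_select_grid entries must be >= 1")
    if (length(pipelines) != 1)
      stop("variable selection requires a single candidate pipeline")
  }
  for (p in pipelines) if (!inherits(p, "pipeline_spec"))
    stop("pipelines must be pipeline_spec objects")
  structure(list(n_outer = n_outer, n_inner = n_inner, n_runs = n_runs,
                 stratified = stratified, selection = selection,
                 n_lv_grid = n_lv_grid, n_select_grid = n_select_grid,
                 pipelines = pipelines,
                 stability_threshold = stability_threshold),
            class = "rdcv_config")
}

stratified_folds <- function(y, k, stratified = TRUE) {
  n <- length(y)
  f <- integer(n)
  if (stratified) {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      f[idx] <- rep_len(sample.int(k), length(idx))
    }
  } else {
    f <- sample(rep_len(seq_len(k), n))
  }
  f
}

macro_error <- function(y_int, pred_int, n_classes) {
  errs <- vapply(seq_len(n_classes), function(k) {
    in_k <- y_int == k
    if (!any(in_k)) return(NA_real_)
    mean(pred_int[in_k] != k)
  }, 0)
  mean(errs, na.rm = TRUE) * 100
}

# inner-loop model selection for one outer training set; returns the
# winning (pipeline index, n_lv, n_select) by minimal pooled macro error,
# ties towards fewer latent variables, then fewer variables, then the
# earlier pipeline in the candidate list
inner_select <- function(X_tr, y_tr, config, spacing, fixed_subset = NULL) {
  n_cand <- length(config$pipelines) * length(config$n_lv_grid) *
    (if (config$selection == "covsel") length(config$n_select_grid) else 1L)
  if (n_cand == 1L)
    return(list(pipeline = 1L, n_lv = config$n_lv_grid[1],
                n_select = if (config$selection == "covsel")
                  config$n_select_grid[1] else NA_integer_,
                inner_error = NA_real_))
  n_classes <- nlevels(y_tr)
  y_int <- as.integer(y_tr)
  folds <- stratified_folds(y_tr, config$n_inner, config$stratified)
  lv_grid <- config$n_lv_grid
  ns_grid <- if (config$selection == "covsel") config$n_select_grid else NA_integer_
  # predictions[sample, lv, ns, pipeline]
  pred <- array(NA_integer_,
                c(length(y_tr), length(lv_grid), length(ns_grid),
                  length(config$pipelines)))
  for (pi in seq_along(config$pipelines)) {
    for (i in seq_len(config$n_inner)) {
      tr <- folds != i; te <- !tr
      if (!any(te)) next
      pp <- fit_apply_pipeline(config$pipelines[[pi]],
                               X_tr[tr, , drop = FALSE],
                               X_tr[te, , drop = FALSE], spacing)
      if (!is.null(fixed_subset)) {
        pp$train <- pp$train[, fixed_subset, drop = FALSE]
        pp$test <- pp$test[, fixed_subset, drop = FALSE]
      }
      max_lv <- min(max(lv_grid), sum(tr) - 1, ncol(pp$train))
      if (config$selection == "covsel") {
        cs <- covsel(pp$train, dummy_matrix(y_tr[tr]),
                     min(max(ns_grid), ncol(pp$train)))
        for (si in seq_along(ns_grid)) {
          sub <- cs$selected[seq_len(min(ns_grid[si], length(cs$selected)))]
          m <- fit_plsda(pp$train[, sub, drop = FALSE], y_tr[tr],
                         min(max_lv, length(sub)))
          pred[te, , si, pi] <- plsda_predict_grid(m, pp$test[, sub, drop = FALSE],
                                                   lv_grid)
        }
      } else {
        m <- fit_plsda(pp$train, y_tr[tr], max_lv)
        pred[te, , 1, pi] <- plsda_predict_grid(m, pp$test, lv_grid)
      }
    }
  }
  cand <- expand.grid(lv = seq_along(lv_grid), ns = seq_along(ns_grid),
                      pi = seq_along(config$pipelines))
  cand$err <- vapply(seq_len(nrow(cand)), function(r)
    macro_error(y_int, pred[, cand$lv[r], cand$ns[r], cand$pi[r]], n_classes), 0)
  ord <- order(cand$err, lv_grid[cand$lv],
               if (config$selection == "covsel") ns_grid[cand$ns] else cand$ns,
               cand$pi)
  best <- cand[ord[1], ]
  list(pipeline = best$pi, n_lv = lv_grid[best$lv],
       n_select = if (config$selection == "covsel") ns_grid[best$ns] else NA_integer_,
       inner_error = best$err)
}

#' Run repeated double cross-validation
#'
#' For each of `n_runs` seeded repetitions: samples are partitioned
#' into `n_outer` (stratified) segments; for every outer segment the
#' remaining samples are used to select the model -- candidate
#' pre-treatment, number of latent variables, and (optionally) number
#' of CovSel variables -- by `n_inner`-fold inner cross-validation
#' minimizing the mean per-class error; the winning model is refitted
#' on all training samples and the held-out segment is predicted. All
#' pre-processing statistics and variable selections are computed from
#' training rows only, so outer predictions are genuine external
#' validation. Every sample is predicted exactly once per run, and
#' `n_runs * n_outer` models are fitted in total.
#'
#' @param x A [spectra_set()] (labels with >= 2 classes present).
#' @param config An [rdcv_config()].
#' @param seed Master seed; per-run sub-seeds are derived from it, so
#'   results depend only on (data, config, seed).
#' @param fixed_subset Optional integer indices into the pre-processed
#'   variable grid; when given, every model uses exactly these
#'   variables and `config$selection` is ignored (used by
#'   [rdcv_on_subset()]).
#' @return Object of class `rdcv_result`; see Details.
#' @details The result contains: `predictions` (n x n_runs integer
#'   matrix of predicted class ranks), `scores` (n x n_runs matrix of
#'   first-latent-variable canonical scores), `models` (data frame of
#'   per-model choices and inner errors), `selected` (list of selected
#'   variable index vectors, when selection is active), per-run
#'   `metrics` and their aggregate, per-run `confusions`, `classes`,
#'   `variable_wavelengths` (wavelengths of the pre-processed variable
#'   grid), `config`, `seed`.
#' @export
run_rdcv <- function(x, config = rdcv_config(), seed = 1,
                     fixed_subset = NULL) {
  stopifnot(inherits(x, "spectra_set"), inherits(config, "rdcv_config"))
  X <- x$reflectance
  y <- droplevels(as.factor(x$labels))
  if (nlevels(y) < 2) stop("need at least two classes present")
  n <- nrow(X)
  classes <- levels(y)
  spacing <- stats::median(diff(x$wavelengths))
  if (config$stratified && min(table(y)) < config$n_outer)
    stop("smallest class (", min(table(y)),
         ") has fewer members than n_outer; cannot stratify")

  selection <- if (is.null(fixed_subset)) config$selection else "none"
  # wavelengths of the pre-processed variable grid (band subset survives
  # deterministically from the pipeline structure, not the data)
  probe <- fit_pipeline(config$pipelines[[1]], X[seq_len(min(n, 20)), , drop = FALSE],
                        spacing)
  var_wl <- x$wavelengths[probe$kept]
  if (!is.null(fixed_subset)) {
    fixed_subset <- as.integer(fixed_subset)
    if (any(fixed_subset < 1 | fixed_subset > length(var_wl)))
      stop("subset indices out of range of the pre-processed variable grid")
    if (length(config$pipelines) != 1)
      stop("a fixed variable subset requires a single pipeline")
  }

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1, config$n_runs)

  n_models <- config$n_runs * config$n_outer
  predictions <- matrix(NA_integer_, n, config$n_runs)
  scores <- matrix(NA_real_, n, config$n_runs)
  selected <- if (selection == "covsel" || !is.null(fixed_subset))
    vector("list", n_models) else NULL
  models <- data.frame(run = integer(n_models), outer = integer(n_models),
                       pipeline = integer(n_models), n_lv = integer(n_models),
                       n_select = integer(n_models),
                       inner_error = numeric(n_models))
  confusions <- vector("list", config$n_runs)
  metrics <- vector("list", config$n_runs)

  cfg_inner <- config
  cfg_inner$selection <- selection

  mi <- 0L
  for (r in seq_len(config$n_runs)) {
    set.seed(run_seeds[r])
    outer <- stratified_folds(y, config$n_outer, config$stratified)
    for (o in seq_len(config$n_outer)) {
      tr <- which(outer != o); te <- which(outer == o)
      mi <- mi + 1L
      choice <- inner_select(X[tr, , drop = FALSE], droplevels(y[tr]),
                             cfg_inner, spacing, fixed_subset)
      pp <- fit_apply_pipeline(config$pipelines[[choice$pipeline]],
                               X[tr, , drop = FALSE], X[te, , drop = FALSE],
                               spacing)
      Xtr <- pp$train; Xte <- pp$test
      if (!is.null(fixed_subset)) {
        Xtr <- Xtr[, fixed_subset, drop = FALSE]
        Xte <- Xte[, fixed_subset, drop = FALSE]
        selected[[mi]] <- fixed_subset
      } else if (selection == "covsel") {
        cs <- covsel(Xtr, dummy_matrix(droplevels(y[tr])),
                     min(choice$n_select, ncol(Xtr)))
        selected[[mi]] <- sort(cs$selected)
        Xtr <- Xtr[, cs$selected, drop = FALSE]
        Xte <- Xte[, cs$selected, drop = FALSE]
      }
      n_lv <- min(choice$n_lv, length(tr) - 1, ncol(Xtr))
      m <- fit_plsda(Xtr, droplevels(y[tr]), n_lv)
      pr <- predict(m, Xte)
      predictions[te, r] <- match(as.character(pr$class), classes)
      scores[te, r] <- pr$scores[, 1]
      models$run[mi] <- r; models$outer[mi] <- o
      models$pipeline[mi] <- choice$pipeline; models$n_lv[mi] <- n_lv
      models$n_select[mi] <- if (is.na(choice$n_select)) ncol(Xtr) else choice$n_select
      models$inner_error[mi] <- choice$inner_error
    }
    cm <- confusion(y, factor(classes[predictions[, r]], levels = classes))
    confusions[[r]] <- cm
    metrics[[r]] <- class_metrics(cm)
  }

  structure(list(predictions = predictions, scores = scores,
                 models = models, selected = selected,
                 metrics = metrics, aggregate = aggregate_metrics(metrics),
                 confusions = confusions, truth = y, classes = classes,
                 variable_wavelengths = var_wl, config = config,
                 seed = seed, fixed_subset = fixed_subset),
            class = "rdcv_result")
}

#' @export
print.rdcv_result <- function(x, ...) {
  cat("rDCV:", length(x$truth), "samples,", x$config$n_runs, "runs x",
      x$config$n_outer, "outer segments =", nrow(x$models), "models\n")
  print(x$aggregate)
  invisible(x)
}

#' Per-variable selection frequency
#'
#' Fraction of fitted outer-loop models (over all runs and outer
#' segments) in which each pre-processed variable was selected.
#'
#' @param result An [run_rdcv()] result with variable selection active.
#' @return Named numeric vector (names = wavelengths in nm), values in
#'   \[0, 1\].
#' @export
selection_frequency <- function(result) {
  stopifnot(inherits(result, "rdcv_result"))
  if (is.null(result$selected))
    stop("variable selection was not active in this rDCV run")
  p <- length(result$variable_wavelengths)
  counts <- tabulate(unlist(result$selected), nbins = p)
  stats::setNames(counts / length(result$selected),
                  format(result$variable_wavelengths, trim = TRUE))
}

#' Stability-based variable subset
#'
#' Variables selected in at least `threshold` of all fitted models
#' (e.g. 0.8 = at least 400 of 500 models under the default design),
#' ordered by wavelength.
#'
#' @param frequencies Output of [selection_frequency()], or an
#'   `rdcv_result`.
#' @param threshold Fraction in (0, 1].
#' @return Integer indices into the pre-processed variable grid, named
#'   by wavelength. May be empty.
#' @export
stable_subset <- function(frequencies, threshold = 0.8) {
  if (inherits(frequencies, "rdcv_result"))
    frequencies <- selection_frequency(frequencies)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  idx <- which(frequencies >= threshold)
  stats::setNames(as.integer(idx), names(frequencies)[idx])
}

#' Re-validate a fixed variable subset by rDCV
#'
#' Runs the identical engine with the spectra restricted (after
#' pre-processing) to the given variables and selection disabled --
#' the confirmation step applied to the stable subset.
#'
#' @param x A [spectra_set()].
#' @param subset Non-empty indices into the pre-processed variable
#'   grid (e.g. from [stable_subset()]).
#' @param config An [rdcv_config()].
#' @param seed Master seed.
#' @return An `rdcv_result`.
#' @export
rdcv_on_subset <- function(x, subset, config = rdcv_config(), seed = 1) {
  if (!length(subset)) stop("subset must be non-empty")
  run_rdcv(x, config, seed, fixed_subset = subset)
}

#' Aggregated row-percent confusion matrix
#'
#' Mean (and standard deviation) over runs of the per-run row-percent
#' confusion matrices.
#'
#' @param result An [run_rdcv()] result.
#' @return List with matrices `mean` and `sd`.
#' @export
rdcv_confusion <- function(result) {
  stopifnot(inherits(result, "rdcv_result"))
  mats <- lapply(result$confusions, confusion_row_percent)
  arr <- simplify2array(mats)
  sd0 <- if (length(mats) > 1) apply(arr, c(1, 2), stats::sd) else arr[, , 1] * 0
  list(mean = apply(arr, c(1, 2), mean), sd = sd0)
}

#' Per-sample mean canonical scores with confidence intervals
#'
#' Each sample is scored once per run on the first latent variable of
#' the model that held it out; the mean over runs is reported with a
#' normal-approximation 95% confidence interval
#' (mean +/- 1.96 sd / sqrt(n_runs)).
#'
#' @param result An [run_rdcv()] result.
#' @return Data frame: `sample`, `class`, `mean`, `lower`, `upper`.
#' @export
score_summary <- function(result) {
  stopifnot(inherits(result, "rdcv_result"))
  m <- rowMeans(result$scores)
  s <- apply(result$scores, 1, stats::sd)
  s[is.na(s)] <- 0
  half <- 1.96 * s / sqrt(ncol(result$scores))
  data.frame(sample = seq_along(m), class = result$truth,
             mean = m, lower = m - half, upper = m + half)
}
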