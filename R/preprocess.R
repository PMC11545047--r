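#' Standard normal variate (SNV)
#'
#' Standardizes each spectrum (row) to mean 0 and sample standard
#' deviation 1 (denominator n - 1). Removes multiplicative gain and
#' additive offset per spectrum without a reference.
#'
#' @param X Spectra matrix (samples x bands).
#' @return Matrix of the same shape.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (ncol(X) - 1))
  bad <- which(s < .Machine$double.eps * 100)
  if (length(bad))
    stop("zero-variance (constant) spectrum in row(s): ",
         paste(bad, collapse = ", "))
  (X - m) / s
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum,
#' `x = a * reference + b + e`, and returns `(x - b) / a`. With
#' `reference = "training-mean"` the reference is the column mean of
#' `X` (the conventional choice; inside a fitted pipeline it is the
#' training-set mean).
#'
#' @param X Spectra matrix.
#' @param reference Numeric reference spectrum, or `"training-mean"`.
#' @return Corrected matrix; the reference used is attached as
#'   attribute `"reference"`.
#' @export
msc <- function(X, reference = "training-mean") {
  X <- as.matrix(X)
  if (is.character(reference)) reference <- colMeans(X)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(X)) stop("reference length must equal n_bands")
  vr <- stats::var(reference)
  if (vr < .Machine$double.eps * 100) stop("reference spectrum has zero variance")
  rc <- reference - mean(reference)
  # slope of the least-squares fit x ~ a*ref + b via centred cross-products
  a <- as.numeric((X - rowMeans(X)) %*% rc) / sum(rc^2)
  if (any(abs(a) < 1e-10))
    stop("degenerate MSC fit (slope ~ 0) in row(s): ",
         paste(which(abs(a) < 1e-10), collapse = ", "))
  b <- rowMeans(X) - a * mean(reference)
  out <- (X - b) / a
  attr(out, "reference") <- reference
  out
}

#' Savitzky-Golay convolution weights
#'
#' Least-squares polynomial filter weights for a window of `window`
#' points: fit a polynomial of order `polyorder` to the window and
#' evaluate its `derivative`-th derivative at offset `at` from the
#' window centre (`at = 0` is the usual centred filter; non-zero
#' offsets give edge filters).
#'
#' @param window Odd window length > polyorder.
#' @param polyorder Polynomial order.
#' @param derivative Derivative order (<= polyorder).
#' @param at Evaluation offset from the window centre, in points.
#' @return Numeric weight vector of length `window`.
#' @export
savgol_weights <- function(window, polyorder, derivative = 0, at = 0) {
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (derivative > polyorder) stop("derivative must be <= polyorder")
  h <- (window - 1) / 2
  M <- outer(-h:h, 0:polyorder, `^`)                 # window x (p+1)
  G <- solve(crossprod(M), t(M))                     # (p+1) x window
  # d-th derivative of sum_j a_j t^j at t = `at`
  j <- derivative:polyorder
  dcoef <- factorial(j) / factorial(j - derivative) * at^(j - derivative)
  as.numeric(dcoef %*% G[j + 1, , drop = FALSE])
}

#' Savitzky-Golay smoothing / derivative of spectra
#'
#' Row-wise local polynomial least-squares filter. The derivative is
#' scaled by `1 / spacing^derivative` so that output units are
#' reflectance per nm^derivative. Two edge policies are available:
#' `"truncate"` (default) drops `(window - 1) / 2` bands at each end so
#' every output band comes from a full centred window; `"refit"` keeps
#' all bands by evaluating the first/last window's polynomial at the
#' off-centre positions.
#'
#' @param X Spectra matrix (samples x bands).
#' @param window Odd window length (default 15).
#' @param polyorder Polynomial order (default 3).
#' @param derivative Derivative order (default 2).
#' @param spacing Band spacing in nm (default 5).
#' @param edges `"truncate"` or `"refit"`.
#' @return Filtered matrix; attribute `"kept"` holds the indices of the
#'   input bands represented in the output columns.
#' @export
savgol <- function(X, window = 15, polyorder = 3, derivative = 2,
                   spacing = 5, edges = c("truncate", "refit")) {
  edges <- match.arg(edges)
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < window) stop("need at least `window` bands (have ", p, ")")
  h <- (window - 1) / 2
  w0 <- savgol_weights(window, polyorder, derivative, at = 0) / spacing^derivative
  # centred part via banded matrix product: out[, i] = sum_k w0[k] X[, i-h-1+k]
  n_mid <- p - window + 1
  mid <- matrix(0, nrow(X), n_mid)
  for (k in seq_len(window))
    mid <- mid + w0[k] * X[, (k - 1) + seq_len(n_mid), drop = FALSE]
  if (edges == "truncate") {
    out <- mid
    kept <- (h + 1):(p - h)
  } else {
    left <- sapply(-h:-1, function(at)
      X[, seq_len(window), drop = FALSE] %*%
        (savgol_weights(window, polyorder, derivative, at) / spacing^derivative))
    right <- sapply(1:h, function(at)
      X[, p - window + seq_len(window), drop = FALSE] %*%
        (savgol_weights(window, polyorder, derivative, at) / spacing^derivative))
    out <- cbind(matrix(left, nrow(X)), mid, matrix(right, nrow(X)))
    kept <- seq_len(p)
  }
  if (!is.null(colnames(X))) colnames(out) <- colnames(X)[kept]
  attr(out, "kept") <- kept
  out
}

#' Mean centering
#'
#' Subtracts per-band means. With `means = "fit"` the means are
#' computed from `X` and attached as attribute `"means"`; a supplied
#' numeric vector (e.g. training means) is applied as-is.
#'
#' @param X Spectra matrix.
#' @param means `"fit"` or numeric vector of length `ncol(X)`.
#' @export
mean_center <- function(X, means = "fit") {
  X <- as.matrix(X)
  if (is.character(means)) means <- colMeans(X)
  if (length(means) != ncol(X)) stop("means length must equal n_bands")
  out <- sweep(X, 2, means)
  attr(out, "means") <- as.numeric(means)
  out
}

## ---- pipeline -------------------------------------------------------------

#' @rdname pipeline_spec
#' @export
step_snv <- function() structure(list(kind = "snv"), class = "pp_step")

#' @rdname pipeline_spec
#' @export
step_msc <- function() structure(list(kind = "msc"), class = "pp_step")

#' @rdname pipeline_spec
#' @param window,polyorder,derivative,edges See [savgol()].
#' @export
step_savgol <- function(window = 15, polyorder = 3, derivative = 2,
                        edges = "truncate") {
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (derivative > polyorder) stop("derivative must be <= polyorder")
  structure(list(kind = "savgol", window = window, polyorder = polyorder,
                 derivative = derivative, edges = edges), class = "pp_step")
}

#' @rdname pipeline_spec
#' @export
step_mean_center <- function() structure(list(kind = "mean_center"),
                                         class = "pp_step")

#' Pre-processing pipeline specification
#'
#' An ordered list of spectral pre-treatments applied before modelling.
#' Learned statistics (MSC reference, column means) are always
#' estimated on training rows only; see [fit_pipeline()]. Mean
#' centering, if present, must be the final step.
#'
#' @param ... `pp_step` objects in application order, e.g.
#'   `pipeline_spec(step_msc(), step_savgol(), step_mean_center())`.
#' @return Object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(...) {
  steps <- list(...)
  if (length(steps) == 1 && is.list(steps[[1]]) && !inherits(steps[[1]], "pp_step"))
    steps <- steps[[1]]
  for (s in steps) if (!inherits(s, "pp_step")) stop("all steps must be pp_step objects")
  kinds <- vapply(steps, `[[`, "", "kind")
  if ("mean_center" %in% kinds && match("mean_center", kinds) != length(steps))
    stop("mean centering must be the last step")
  structure(list(steps = steps), class = "pipeline_spec")
}

#' The default pre-treatment chain
#'
#' Multiplicative scatter correction, second-derivative Savitzky-Golay
#' filter (15-point window, third-order polynomial), then mean
#' centering -- the chain selected for the defect-grading models.
#'
#' @param edges Savitzky-Golay edge policy.
#' @export
default_pipeline <- function(edges = "truncate") {
  pipeline_spec(step_msc(), step_savgol(15, 3, 2, edges), step_mean_center())
}

#' @export
print.pipeline_spec <- function(x, ...) {
  if (!length(x$steps)) { cat("pipeline_spec: <identity>\n"); return(invisible(x)) }
  cat("pipeline_spec:",
      paste(vapply(x$steps, function(s) {
        if (s$kind == "savgol")
          sprintf("savgol(%d,%d,d%d)", s$window, s$polyorder, s$derivative)
        else s$kind
      }, ""), collapse = " -> "), "\n")
  invisible(x)
}

#' Fit a pre-processing pipeline on training spectra
#'
#' Estimates every learned statistic (MSC reference spectrum, column
#' means) from `X_train` only and freezes it, so test spectra are
#' transformed without touching training state.
#'
#' @param spec A [pipeline_spec()].
#' @param X_train Training spectra matrix.
#' @param spacing Band spacing in nm for derivative scaling.
#' @return Object of class `fitted_pipeline` with the frozen statistics
#'   and the indices (`kept`) of input bands surviving the chain.
#' @export
fit_pipeline <- function(spec, X_train, spacing = 5) {
  stopifnot(inherits(spec, "pipeline_spec"))
  X <- as.matrix(X_train)
  kept <- seq_len(ncol(X))
  fitted <- vector("list", length(spec$steps))
  for (i in seq_along(spec$steps)) {
    s <- spec$steps[[i]]
    if (s$kind == "snv") {
      X <- snv(X)
    } else if (s$kind == "msc") {
      X <- msc(X, "training-mean")
      s$reference <- attr(X, "reference")
    } else if (s$kind == "savgol") {
      X <- savgol(X, s$window, s$polyorder, s$derivative, spacing, s$edges)
      kept <- kept[attr(X, "kept")]
      s$spacing <- spacing
    } else if (s$kind == "mean_center") {
      X <- mean_center(X, "fit")
      s$means <- attr(X, "means")
    }
    fitted[[i]] <- s
  }
  structure(list(steps = fitted, kept = kept, n_bands_in = ncol(as.matrix(X_train))),
            class = "fitted_pipeline")
}

#' Apply a fitted pipeline to new spectra
#'
#' @param fp A [fit_pipeline()] result.
#' @param X Spectra matrix with the same bands as the training matrix.
#' @return Transformed matrix.
#' @export
apply_pipeline <- function(fp, X) {
  stopifnot(inherits(fp, "fitted_pipeline"))
  X <- as.matrix(X)
  if (ncol(X) != fp$n_bands_in)
    stop("band count mismatch: pipeline fitted on ", fp$n_bands_in,
         " bands, data has ", ncol(X))
  for (s in fp$steps) {
    X <- switch(s$kind,
      snv = snv(X),
      msc = msc(X, s$reference),
      savgol = savgol(X, s$window, s$polyorder, s$derivative, s$spacing, s$edges),
      mean_center = mean_center(X, s$means))
  }
  attributes(X) <- attributes(X)[c("dim", "dimnames")]
  X
}

#' Fit on training rows, transform both sets
#'
#' @param spec A [pipeline_spec()].
#' @param X_train,X_test Spectra matrices on the same band grid.
#' @param spacing Band spacing in nm.
#' @return List with `pipeline` (fitted), `train`, `test`.
#' @export
fit_apply_pipeline <- function(spec, X_train, X_test = NULL, spacing = 5) {
  fp <- fit_pipeline(spec, X_train, spacing)
  list(pipeline = fp,
       train = apply_pipeline(fp, X_train),
       test = if (!is.null(X_test)) apply_pipeline(fp, X_test))
}
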