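#' Class-indicator (dummy) response matrix
#'
#' One column per class in severity-rank order, a single 1 per row
#' marking the sample's class. This is the response regressed on the
#' spectra in PLS-DA.
#'
#' @param labels Factor of class labels; levels fix the column order.
#' @return 0/1 matrix, samples x classes.
#' @export
dummy_matrix <- function(labels) {
  labels <- droplevels(as.factor(labels))
  Y <- stats::model.matrix(~ labels - 1)
  colnames(Y) <- levels(labels)
  attributes(Y)$assign <- NULL
  attributes(Y)$contrasts <- NULL
  Y
}

#' Principal component analysis of spectra
#'
#' Singular-value-decomposition PCA of a column-centred matrix:
#' orthonormal loadings, scores = X loadings, and the fraction of total
#' variance captured by each component.
#'
#' @param X Numeric matrix, assumed column-centred (a warning is issued
#'   if column means are visibly non-zero).
#' @param n_components Number of components (<= min(n - 1, p)).
#' @return Object of class `pca_result`: `scores`, `loadings`,
#'   `explained` (variance fractions).
#' @export
pca <- function(X, n_components = 2) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1, p))
    stop("n_components must be <= min(n - 1, p) = ", min(n - 1, p))
  if (max(abs(colMeans(X))) > 1e-6 * max(1, max(abs(X))))
    warning("X does not look column-centred; PCA assumes centred input")
  sv <- svd(X, nu = n_components, nv = n_components)
  # sign convention: largest-magnitude loading element positive
  for (k in seq_len(n_components)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) { sv$v[, k] <- -sv$v[, k]; sv$u[, k] <- -sv$u[, k] }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  structure(list(scores = scores, loadings = sv$v,
                 explained = sv$d[seq_len(n_components)]^2 / sum(sv$d^2)),
            class = "pca_result")
}

pls_fit_core <- function(Xc, Yc, n_lv, tol = 1e-12) {
  p <- ncol(Xc); K <- ncol(Yc)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, K, n_lv); Tm <- matrix(0, nrow(Xc), n_lv)
  a <- 0
  for (k in seq_len(n_lv)) {
    S <- crossprod(Xc, Yc)                       # p x K covariance core
    if (sum(S^2) < tol) break                    # nothing left to model
    sv <- svd(S, nu = 1, nv = 0)
    w <- sv$u[, 1]
    j <- which.max(abs(w)); if (w[j] < 0) w <- -w   # deterministic sign
    t <- as.numeric(Xc %*% w); tt <- sum(t^2)
    if (tt < tol) break
    pvec <- as.numeric(crossprod(Xc, t)) / tt
    qvec <- as.numeric(crossprod(Yc, t)) / tt
    Xc <- Xc - tcrossprod(t, pvec)
    Yc <- Yc - tcrossprod(t, qvec)
    a <- k
    W[, k] <- w; P[, k] <- pvec; Q[, k] <- qvec; Tm[, k] <- t
  }
  if (a == 0) stop("zero-variance X (or X uncorrelated with Y): cannot fit PLS")
  list(W = W[, 1:a, drop = FALSE], P = P[, 1:a, drop = FALSE],
       Q = Q[, 1:a, drop = FALSE], T = Tm[, 1:a, drop = FALSE], n_lv = a)
}

#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis: a bilinear PLS2
#' regression of the class-indicator matrix on the spectra, fitted by
#' iterative score deflation. At each component the X-weight vector is
#' the dominant direction of the X-Y covariance (leading left singular
#' vector of X'Y on the deflated data), scores are orthogonal by
#' construction, and the regression coefficients reproduce the
#' training fit with `n_lv` components. Class assignment at prediction
#' time is by largest predicted indicator value (ties broken towards
#' the lower severity rank).
#'
#' @param X Pre-processed spectra matrix (samples x variables).
#' @param labels Factor of class labels (>= 2 classes present) or a
#'   dummy matrix.
#' @param n_lv Number of latent variables, `1 <= n_lv <=
#'   min(n - 1, n_vars)`. If deflation exhausts X earlier the model
#'   stops at the achieved rank.
#' @param pipeline Optional frozen [fit_pipeline()] used to produce
#'   `X`; stored so that raw spectra can be classified later.
#' @param subset Optional indices of the variables of the pre-processed
#'   grid used in `X` (bookkeeping for variable-selection models).
#' @return Object of class `plsda` with weights `W`, loadings `P`,
#'   Y-loadings `Q`, projection matrix `R = W (P'W)^-1`, coefficients
#'   `B`, training column means, class levels.
#' @export
fit_plsda <- function(X, labels, n_lv, pipeline = NULL, subset = NULL) {
  X <- as.matrix(X)
  if (is.matrix(labels)) {
    Y <- labels
    classes <- colnames(Y)
  } else {
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) < 2) stop("need at least 2 classes present in training")
    Y <- dummy_matrix(labels)
    classes <- levels(labels)
  }
  if (any(colSums(Y) == 0)) stop("a class is absent from the training set")
  n <- nrow(X)
  if (n_lv < 1 || n_lv > min(n - 1, ncol(X)))
    stop("n_lv must be in 1..min(n-1, n_vars) = ", min(n - 1, ncol(X)))
  xm <- colMeans(X); ym <- colMeans(Y)
  core <- pls_fit_core(sweep(X, 2, xm), sweep(Y, 2, ym), n_lv)
  R <- core$W %*% solve(crossprod(core$P, core$W))
  structure(list(W = core$W, P = core$P, Q = core$Q, R = R,
                 scores = core$T, B = tcrossprod(R, core$Q),
                 x_means = xm, y_means = ym, n_lv = core$n_lv,
                 classes = classes, pipeline = pipeline, subset = subset),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA model:", x$n_lv, "latent variable(s),",
      length(x$x_means), "variables, classes:",
      paste(x$classes, collapse = " < "), "\n")
  invisible(x)
}

#' Predict class membership from a PLS-DA model
#'
#' Computes predicted indicator values
#' `Yhat = (X - x_means) B + y_means`, assigns each sample to the class
#' with the largest value (ties go to the lower severity rank), and
#' returns the latent-variable scores of the new samples (canonical
#' scores used in discrimination plots).
#'
#' @param object A [fit_plsda()] model.
#' @param newdata Matrix on the variable grid the model was fitted on.
#'   If the model stores a pipeline and `raw = TRUE`, raw spectra are
#'   pre-processed (and restricted to the model's variable subset)
#'   first.
#' @param n_lv Use only the first `n_lv` components (default: all).
#' @param raw Treat `newdata` as raw spectra to be pre-processed.
#' @param ... Unused.
#' @return List with `Yhat`, `class` (factor), `scores`.
#' @export
predict.plsda <- function(object, newdata, n_lv = object$n_lv, raw = FALSE, ...) {
  X <- as.matrix(newdata)
  if (raw) {
    if (is.null(object$pipeline)) stop("model stores no pipeline; cannot take raw spectra")
    X <- apply_pipeline(object$pipeline, X)
    if (!is.null(object$subset)) X <- X[, object$subset, drop = FALSE]
  }
  if (ncol(X) != length(object$x_means))
    stop("variable count mismatch: model has ", length(object$x_means),
         ", data has ", ncol(X))
  if (n_lv < 1 || n_lv > object$n_lv) stop("n_lv out of range")
  Xc <- sweep(X, 2, object$x_means)
  Tn <- Xc %*% object$R[, seq_len(n_lv), drop = FALSE]
  Yhat <- tcrossprod(Tn, object$Q[, seq_len(n_lv), drop = FALSE])
  Yhat <- sweep(Yhat, 2, object$y_means, `+`)
  colnames(Yhat) <- object$classes
  cls <- factor(object$classes[max.col(Yhat, ties.method = "first")],
                levels = object$classes)
  list(Yhat = Yhat, class = cls, scores = Tn)
}

# class predictions for every candidate number of latent variables at once
# (one model fit, nested truncations) -- workhorse of the inner CV loop
plsda_predict_grid <- function(object, X, lv_grid) {
  Xc <- sweep(as.matrix(X), 2, object$x_means)
  Tn <- Xc %*% object$R
  out <- matrix(NA_integer_, nrow(Xc), length(lv_grid))
  for (i in seq_along(lv_grid)) {
    a <- min(lv_grid[i], object$n_lv)
    Yhat <- tcrossprod(Tn[, seq_len(a), drop = FALSE],
                       object$Q[, seq_len(a), drop = FALSE])
    Yhat <- sweep(Yhat, 2, object$y_means, `+`)
    out[, i] <- max.col(Yhat, ties.method = "first")
  }
  out
}

#' CovSel greedy variable selection
#'
#' Covariance selection: repeatedly picks the variable with the largest
#' summed squared covariance with the response columns, then projects
#' all remaining X columns and the response orthogonally to the picked
#' column. Selection on the deflated data makes the chosen set
#' complementary rather than redundant.
#'
#' @param X Predictor matrix; centred internally.
#' @param Y Response matrix (e.g. [dummy_matrix()]); centred internally.
#' @param n_select Number of variables to select (1..n_vars).
#' @return Object of class `covsel_result`: `selected` (ordered
#'   indices) and `criterion` (summed squared covariance at each pick).
#'   If deflation exhausts X early, a shorter list is returned with a
#'   warning.
#' @export
covsel <- function(X, Y, n_select) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (n_select < 1 || n_select > ncol(X)) stop("n_select must be in 1..n_vars")
  n <- nrow(X)
  Xd <- sweep(X, 2, colMeans(X))
  Yd <- sweep(Y, 2, colMeans(Y))
  sel <- integer(0); crit <- numeric(0)
  for (k in seq_len(n_select)) {
    cn <- colSums(Xd^2)
    score <- rowSums(crossprod(Xd, Yd)^2) / (n - 1)^2   # sum_k cov(x_j, y_k)^2, up to scale
    score[cn < 1e-12 * max(cn, 1)] <- -Inf
    if (!any(is.finite(score)) || max(score) <= 0) {
      warning("X numerically exhausted after ", k - 1,
              " selections; returning a shorter list")
      break
    }
    j <- which.max(score)
    sel <- c(sel, j); crit <- c(crit, score[j])
    v <- Xd[, j]
    vv <- sum(v^2)
    Xd <- Xd - v %*% (crossprod(v, Xd) / vv)
    Yd <- Yd - v %*% (crossprod(v, Yd) / vv)
  }
  structure(list(selected = sel, criterion = crit), class = "covsel_result")
}

#' @export
print.covsel_result <- function(x, ...) {
  cat("covsel:", length(x$selected), "variables:",
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
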