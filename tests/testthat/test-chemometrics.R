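test_that("dummy matrix has one unit entry per row in rank order", {
  y <- as_defect_class(c(1, 3, 2, 4, 1))
  Y <- dummy_matrix(y)
  expect_equal(colnames(Y), defect_classes())
  expect_equal(unname(rowSums(Y)), rep(1, 5))
  expect_equal(unname(Y[, "moderate"]), c(0, 1, 0, 0, 0))
})

test_that("pca matches the eigen-decomposition of the covariance", {
  set.seed(10)
  X <- scale(matrix(rnorm(12), 4, 3), scale = FALSE)
  res <- pca(X, n_components = 3)
  ev <- eigen(cov(X))
  for (k in 1:3) {
    # loadings agree up to sign
    expect_equal(abs(sum(res$loadings[, k] * ev$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(res$explained, ev$values / sum(ev$values), tolerance = 1e-8)
  expect_equal(unname(res$scores), unname(X %*% res$loadings),
               tolerance = 1e-8)
  expect_lt(max(abs(colMeans(res$scores))), 1e-10)
})

test_that("pca of collinear rows puts all variance on PC1", {
  v <- c(1, -2, 0.5)
  X <- scale(outer(c(1, 2, 3, 4), v), scale = FALSE)
  res <- pca(X, 2)
  expect_equal(res$explained[1], 1, tolerance = 1e-12)
  expect_error(pca(X, 4), "n_components")
})

test_that("plsda separates a one-informative-variable problem with 1 LV", {
  set.seed(11)
  y <- as_defect_class(rep(c(1, 2), each = 10))
  X <- cbind(ifelse(as.integer(y) == 1, 0, 1), matrix(0, 20, 5))
  X[, 1] <- X[, 1] + rnorm(20, 0, 0.01)
  m <- fit_plsda(X, y, n_lv = 1)
  expect_equal(as.character(predict(m, X)$class), as.character(droplevels(y)))
})

test_that("plsda at full rank equals least-squares dummy regression", {
  set.seed(12)
  X <- matrix(rnorm(40), 10, 4)
  y <- factor(rep(c("sound", "defective"), 5), c("sound", "defective"))
  Y <- dummy_matrix(y)
  m <- fit_plsda(X, y, n_lv = 4)
  Xc <- scale(X, scale = FALSE)
  B_ls <- solve(crossprod(Xc), crossprod(Xc, scale(Y, scale = FALSE)))
  Yhat_ls <- Xc %*% B_ls + matrix(colMeans(Y), 10, 2, byrow = TRUE)
  expect_lt(max(abs(predict(m, X)$Yhat - Yhat_ls)), 1e-8)
})

test_that("plsda scores are mutually orthogonal and fit is duplication-invariant", {
  set.seed(13)
  X <- matrix(rnorm(200), 20, 10)
  y <- as_defect_class(rep(1:4, 5))
  m <- fit_plsda(X, y, n_lv = 5)
  G <- crossprod(m$scores)
  offdiag <- max(abs(G[upper.tri(G)])) / max(diag(G))
  expect_lt(offdiag, 1e-8)
  # duplicating every training row leaves coefficients unchanged
  m2 <- fit_plsda(X[rep(1:20, 2), ], y[rep(1:20, 2)], n_lv = 5)
  expect_equal(m$B, m2$B, tolerance = 1e-8)
})

test_that("prediction uses argmax with ties to the lower severity rank", {
  set.seed(14)
  X <- matrix(rnorm(40), 10, 4)
  y <- as_defect_class(rep(1:2, 5))
  m <- fit_plsda(X, y, n_lv = 2)
  # hand-crafted response rows routed through the same assignment rule
  fake <- m
  fake$y_means <- c(0, 0)
  cls <- function(yhat) {
    lv <- m$classes
    factor(lv[max.col(rbind(yhat), ties.method = "first")], levels = lv)
  }
  expect_equal(as.character(cls(c(0.9, 0.1))), "sound")
  expect_equal(as.character(cls(c(0.1, 0.9))), "mild")
  expect_equal(as.character(cls(c(0.5, 0.5))), "sound")
  # a perfectly fit training sample is assigned its own class
  Xs <- cbind(as.integer(y), matrix(0, 10, 3))
  ms <- fit_plsda(Xs, y, n_lv = 1)
  expect_equal(as.character(predict(ms, Xs)$class), as.character(droplevels(y)))
  # prediction is invariant to duplication of prediction rows
  pr <- predict(m, X[c(3, 3, 7), ])
  expect_equal(pr$Yhat[1, ], pr$Yhat[2, ])
  # and to a consistent band permutation of model-and-data
  prm <- sample(4)
  mp <- fit_plsda(X[, prm], y, n_lv = 2)
  expect_equal(predict(mp, X[c(1, 5), prm])$Yhat, predict(m, X[c(1, 5), ])$Yhat,
               tolerance = 1e-10)
})

test_that("plsda rejects degenerate inputs", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_plsda(X, as_defect_class(rep(1, 10)), 2), "2 classes")
  expect_error(fit_plsda(X, as_defect_class(rep(1:2, 5)), 20), "n_lv")
  expect_error(fit_plsda(matrix(0, 10, 4), as_defect_class(rep(1:2, 5)), 2),
               "zero-variance")
})

test_that("covsel picks an exact response column first and zeroes the residual", {
  set.seed(15)
  Y <- dummy_matrix(factor(rep(c("a", "b"), 8)))
  X <- cbind(matrix(rnorm(16 * 4, sd = 0.2), 16, 4), Y[, 1])
  res <- covsel(X, Y, 1)
  expect_equal(res$selected[1], 5)
  # once the response is fully explained the greedy search stops early
  expect_warning(r2 <- covsel(X, Y, 3), "shorter")
  expect_equal(r2$selected, 5L)
  # after deflating by that column the response is fully explained
  Xd <- scale(X, scale = FALSE); Yd <- scale(Y, scale = FALSE)
  v <- Xd[, 5]
  Yres <- Yd - outer(v, as.numeric(crossprod(v, Yd))) / sum(v^2)
  expect_lt(max(abs(Yres)), 1e-10)
})

test_that("covsel first pick matches the exhaustive covariance scan", {
  for (s in 1:25) {
    d <- toy_xy(s)
    Xc <- scale(d$X, scale = FALSE); Yc <- scale(d$Y, scale = FALSE)
    brute <- which.max(sapply(seq_len(ncol(Xc)), function(j)
      sum(as.numeric(crossprod(Xc[, j], Yc))^2)))
    expect_equal(covsel(d$X, d$Y, 1)$selected, brute)
  }
})

test_that("covsel full greedy sequence equals the naive deflation oracle", {
  for (s in 1:10) {
    set.seed(100 + s)
    X <- matrix(rnorm(72), 12, 6)
    Y <- matrix(rnorm(24), 12, 2)
    expect_equal(covsel(X, Y, 6)$selected, covsel_oracle(X, Y, 6))
  }
})

test_that("covsel selections are nested and criterion values recorded", {
  d <- toy_xy(77)
  r3 <- covsel(d$X, d$Y, 3)
  r6 <- covsel(d$X, d$Y, 6)
  expect_equal(r6$selected[1:3], r3$selected)
  expect_true(all(r6$criterion >= 0))
  expect_equal(length(r6$criterion), 6)
  expect_equal(anyDuplicated(r6$selected), 0)
  expect_error(covsel(d$X, d$Y, 0), "n_select")
})
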