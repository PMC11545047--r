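# small fixtures shared across test files; everything is generated in code

# a compact, well-separated two-class population (80 sound / 120 defective)
small_two_class <- function(seed = 11, noise_sd = 0.004) {
  cfg <- sim_config(class_counts = c(80, 120, 0, 0), noise_sd = noise_sd)
  x <- generate_spectra(cfg, seed = seed)
  spectra_set(x$reflectance, x$wavelengths, two_class_labels(x$labels))
}

# tiny random matrix problems for oracle comparisons
toy_xy <- function(seed, n = 20, p = 8, k = 2) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p), Y = matrix(rnorm(n * k), n, k))
}

# brute-force per-window polynomial refit: the independent Savitzky-Golay
# oracle (fits lm() in every window, evaluates the derivative at the centre)
savgol_oracle <- function(x, window, polyorder, derivative, spacing = 1) {
  h <- (window - 1) / 2
  p <- length(x)
  out <- numeric(p - window + 1)
  for (i in (h + 1):(p - h)) {
    t <- (-h:h)
    fit <- lm(x[(i - h):(i + h)] ~ poly(t, polyorder, raw = TRUE))
    a <- coef(fit)[derivative + 1]
    out[i - h] <- factorial(derivative) * a / spacing^derivative
  }
  unname(out)
}

# naive CovSel oracle: explicit greedy scan + Gram-Schmidt deflation
covsel_oracle <- function(X, Y, n_select) {
  Xd <- scale(X, scale = FALSE); Yd <- scale(Y, scale = FALSE)
  n <- nrow(X)
  sel <- integer(0)
  for (step in seq_len(n_select)) {
    score <- sapply(seq_len(ncol(Xd)), function(j)
      sum(sapply(seq_len(ncol(Yd)), function(k)
        (sum(Xd[, j] * Yd[, k]) / (n - 1))^2)))
    score[sel] <- -Inf
    j <- which.max(score)
    sel <- c(sel, j)
    v <- Xd[, j]
    proj <- function(M) M - outer(v, as.numeric(crossprod(v, M))) / sum(v^2)
    Xd <- proj(Xd); Yd <- proj(Yd)
  }
  sel
}
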