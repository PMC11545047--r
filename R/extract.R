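cube_flat <- function(cube) {
  d <- dim(cube$cube)
  matrix(cube$cube, nrow = d[1] * d[2], ncol = d[3])
}

new_fruit_mask <- function(all, dim, retained = all,
                           excluded_glare = integer(0),
                           excluded_defect_edge = integer(0),
                           oversized = FALSE) {
  structure(list(all = sort(all), retained = sort(retained),
                 excluded_glare = sort(excluded_glare),
                 excluded_defect_edge = sort(excluded_defect_edge),
                 dim = dim, oversized = oversized),
            class = "fruit_mask")
}

#' @export
print.fruit_mask <- function(x, ...) {
  cat("fruit_mask:", length(x$all), "pixels (", length(x$retained),
      "retained,", length(x$excluded_glare), "glare,",
      length(x$excluded_defect_edge), "defect-edge )",
      if (x$oversized) "[oversized]" else "", "\n")
  invisible(x)
}

#' Segment fruit in a hyperspectral cube
#'
#' Thresholds the image at a single reference band where fruit /
#' background contrast is high (default 800 nm, on the NIR plateau) and
#' labels connected components. One mask per component of at least
#' `min_area` pixels, ordered row-major by centroid. A component
#' covering more than 90% of the frame is flagged `oversized` (a
#' threshold of 0 selects the whole frame).
#'
#' @param cube A `hypercube`.
#' @param background_threshold Reflectance fraction separating
#'   background from fruit at the reference band.
#' @param reference_band Wavelength in nm; must lie on the cube's grid.
#' @param min_area Minimum component size in pixels.
#' @return List of `fruit_mask` objects (linear, column-major 1-based
#'   pixel indices).
#' @export
segment_fruit <- function(cube, background_threshold = 0.15,
                          reference_band = 800, min_area = 20) {
  stopifnot(inherits(cube, "hypercube"))
  b <- match(reference_band, cube$wavelengths)
  if (is.na(b)) stop("reference_band ", reference_band, " nm is not on the grid")
  img <- cube$cube[, , b]
  bw <- img > background_threshold
  if (!any(bw)) stop("no component found above the background threshold")
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (!length(keep)) stop("no component found of at least min_area pixels")
  d <- dim(img)
  masks <- lapply(keep, function(k) {
    px <- which(lab == k)
    new_fruit_mask(px, d, oversized = length(px) > 0.9 * prod(d))
  })
  cent <- t(vapply(masks, function(m) {
    c(mean((m$all - 1) %% d[1] + 1), mean((m$all - 1) %/% d[1] + 1))
  }, c(0, 0)))
  masks[order(round(cent[, 1]), cent[, 2])]
}

#' Exclude saturated (glare) pixels from a fruit mask
#'
#' Specular highlights saturate the reflectance measurement and
#' distort the mean spectrum. Any retained pixel whose reflectance
#' reaches `saturation_level` in at least one band is moved to the
#' `excluded_glare` set.
#'
#' @param cube A `hypercube`.
#' @param mask A `fruit_mask`.
#' @param saturation_level Reflectance fraction in (0, 1.05].
#' @return Updated `fruit_mask`.
#' @export
exclude_glare <- function(cube, mask, saturation_level = 0.98) {
  stopifnot(inherits(cube, "hypercube"), inherits(mask, "fruit_mask"))
  if (saturation_level <= 0 || saturation_level > 1.05)
    stop("saturation_level must be in (0, 1.05]")
  X <- cube_flat(cube)[mask$retained, , drop = FALSE]
  hit <- mask$retained[apply(X >= saturation_level, 1, any)]
  retained <- setdiff(mask$retained, hit)
  if (!length(retained))
    stop("invalid fruit: all pixels excluded as glare")
  new_fruit_mask(mask$all, mask$dim, retained,
                 excluded_glare = union(mask$excluded_glare, hit),
                 excluded_defect_edge = mask$excluded_defect_edge,
                 oversized = mask$oversized)
}

# mean-over-bands spatial gradient magnitude, central differences
gradient_image <- function(cube) {
  a <- cube$cube
  d <- dim(a)
  gr <- array(0, d); gc <- array(0, d)
  gr[2:(d[1] - 1), , ] <- (a[3:d[1], , ] - a[1:(d[1] - 2), , ]) / 2
  gc[, 2:(d[2] - 1), ] <- (a[, 3:d[2], ] - a[, 1:(d[2] - 2), ]) / 2
  g <- sqrt(gr^2 + gc^2)
  apply(g, c(1, 2), mean)
}

#' Exclude defect-edge pixels with rapid spatial reflectance change
#'
#' Defective regions show sharp local changes in reflectance; pixels
#' whose spatial gradient magnitude (mean over bands) exceeds the
#' threshold are moved to `excluded_defect_edge`, retaining the sound
#' tissue around defects. Off by default in the extraction pipeline.
#'
#' @param cube A `hypercube`.
#' @param mask A `fruit_mask`.
#' @param gradient_threshold Reflectance change per pixel (> 0);
#'   `Inf` leaves the mask unchanged.
#' @return Updated `fruit_mask`.
#' @export
exclude_defect_edges <- function(cube, mask, gradient_threshold) {
  stopifnot(inherits(cube, "hypercube"), inherits(mask, "fruit_mask"))
  if (gradient_threshold <= 0) stop("gradient_threshold must be > 0")
  if (is.infinite(gradient_threshold)) return(mask)
  g <- gradient_image(cube)
  hit <- mask$retained[g[mask$retained] > gradient_threshold]
  retained <- setdiff(mask$retained, hit)
  if (!length(retained))
    stop("invalid fruit: all pixels excluded as defect edges")
  new_fruit_mask(mask$all, mask$dim, retained,
                 excluded_glare = mask$excluded_glare,
                 excluded_defect_edge = union(mask$excluded_defect_edge, hit),
                 oversized = mask$oversized)
}

#' Mean spectrum of the retained pixels of one fruit
#'
#' Band-wise arithmetic mean over the retained pixel set: the single
#' spectrum representing the fruit in all downstream modelling.
#'
#' @param cube A `hypercube`.
#' @param mask A `fruit_mask` with non-empty retained set.
#' @return Numeric vector over the cube's wavelength grid.
#' @export
mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"), inherits(mask, "fruit_mask"))
  if (!length(mask$retained)) stop("empty retained pixel set")
  colMeans(cube_flat(cube)[mask$retained, , drop = FALSE])
}

#' Extract one mean spectrum per fruit from a cube
#'
#' Convenience wrapper: segmentation, glare exclusion, optional
#' defect-edge exclusion, then per-fruit mean spectra.
#'
#' @param cube A `hypercube`.
#' @param background_threshold,reference_band,min_area See
#'   [segment_fruit()].
#' @param saturation_level See [exclude_glare()].
#' @param gradient_threshold `NULL` (default: defect pixels are kept in
#'   the average) or a positive threshold for [exclude_defect_edges()].
#' @param labels Optional per-fruit labels (e.g. the simulator truth).
#' @return A [spectra_set()] (labels default to `sound` placeholders
#'   when unknown) with the masks attached as attribute `"masks"`.
#' @export
extract_spectra <- function(cube, background_threshold = 0.15,
                            reference_band = 800, min_area = 20,
                            saturation_level = 0.98,
                            gradient_threshold = NULL, labels = NULL) {
  masks <- segment_fruit(cube, background_threshold, reference_band, min_area)
  masks <- lapply(masks, function(m) exclude_glare(cube, m, saturation_level))
  if (!is.null(gradient_threshold))
    masks <- lapply(masks, function(m)
      exclude_defect_edges(cube, m, gradient_threshold))
  X <- t(vapply(masks, function(m) mean_spectrum(cube, m),
                numeric(length(cube$wavelengths))))
  if (is.null(labels)) labels <- rep("sound", length(masks))
  out <- spectra_set(X, cube$wavelengths, labels)
  attr(out, "masks") <- masks
  out
}

#' Pixel-by-pixel classification map
#'
#' Applies a trained PLS-DA model (with its frozen pre-processing
#' pipeline) to every retained pixel spectrum; background and excluded
#' pixels receive `NA`.
#'
#' @param cube A `hypercube` on the model's training grid.
#' @param model A [fit_plsda()] model that stores a fitted pipeline.
#' @param masks List of `fruit_mask` objects (default: segment with
#'   default settings and exclude glare).
#' @return Integer matrix (rows x cols) of class ranks, `NA` where no
#'   prediction is made, with the class levels as attribute
#'   `"classes"`.
#' @export
pixelwise_classify <- function(cube, model, masks = NULL) {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "plsda"))
  if (is.null(model$pipeline))
    stop("model must store a fitted pre-processing pipeline")
  if (length(cube$wavelengths) != model$pipeline$n_bands_in)
    stop("cube band count does not match the model's training grid")
  if (is.null(masks)) {
    masks <- segment_fruit(cube)
    masks <- lapply(masks, function(m) exclude_glare(cube, m))
  }
  d <- dim(cube$cube)
  out <- matrix(NA_integer_, d[1], d[2])
  X <- cube_flat(cube)
  for (m in masks) {
    pr <- predict(model, X[m$retained, , drop = FALSE], raw = TRUE)
    out[m$retained] <- as.integer(pr$class)
  }
  attr(out, "classes") <- model$classes
  out
}
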