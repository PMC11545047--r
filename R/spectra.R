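#' Default Vis-NIR wavelength grid
#'
#' The working spectral axis: 400 to 1000 nm sampled every 5 nm
#' (121 bands), the grid of a line-scan Vis-NIR imaging spectrograph.
#'
#' @param from,to Range limits in nm.
#' @param by Spectral sampling interval in nm.
#' @return Numeric vector of strictly increasing wavelengths (nm).
#' @export
#' @examples
#' length(wavelength_grid())  # 121
wavelength_grid <- function(from = 400, to = 1000, by = 5) {
  stopifnot(by > 0, to > from)
  seq(from, to, by = by)
}

#' Severity class labels
#'
#' Fruit are graded into four ordinal severity classes. Rank order is
#' fixed: sound (1) < mild (2) < moderate (3) < severe (4).
#'
#' @export
defect_classes <- function() c("sound", "mild", "moderate", "severe")

#' Coerce labels to the ordinal defect-class factor
#'
#' Accepts integer ranks 1-4, class names, or an existing factor whose
#' levels are a subset of the four classes.
#'
#' @param x Integer ranks, character names, or factor.
#' @return Factor with levels `sound < mild < moderate < severe`.
#' @export
as_defect_class <- function(x) {
  cls <- defect_classes()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (any(is.na(x)) || any(x < 1 | x > 4 | x != round(x)))
      stop("integer class ranks must be in 1..4")
    x <- cls[x]
  }
  if (!all(x %in% cls)) stop("unknown class label(s): ",
                             paste(setdiff(unique(x), cls), collapse = ", "))
  factor(x, levels = cls)
}

#' Collapse four severity classes to sound vs defective
#'
#' @param labels Factor as returned by [as_defect_class()].
#' @return Factor with levels `sound < defective`.
#' @export
two_class_labels <- function(labels) {
  labels <- as_defect_class(labels)
  factor(ifelse(labels == "sound", "sound", "defective"),
         levels = c("sound", "defective"))
}

#' Construct a spectra set
#'
#' Bundles a matrix of reflectance spectra on a shared wavelength grid
#' with per-sample class labels. This is the `X` / `y` container every
#' downstream stage consumes.
#'
#' @param reflectance Numeric matrix, samples in rows, bands in columns.
#' @param wavelengths Strictly increasing numeric vector (nm), one entry
#'   per column of `reflectance`.
#' @param labels Per-sample class labels (see [as_defect_class()]), or a
#'   factor with arbitrary class levels for non-standard problems.
#' @return Object of class `spectra_set`: a list with elements
#'   `reflectance`, `wavelengths`, `labels`.
#' @export
spectra_set <- function(reflectance, wavelengths, labels) {
  reflectance <- as.matrix(reflectance)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(reflectance) != length(wavelengths))
    stop("number of bands (", ncol(reflectance),
         ") does not match wavelength grid length (", length(wavelengths), ")")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(reflectance)) stop("reflectance contains missing values")
  if (!is.factor(labels)) labels <- as_defect_class(labels)
  if (length(labels) != nrow(reflectance))
    stop("length of labels does not match number of samples")
  colnames(reflectance) <- format(wavelengths, trim = TRUE)
  structure(list(reflectance = reflectance,
                 wavelengths = wavelengths,
                 labels = labels),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set:", nrow(x$reflectance), "samples x",
      length(x$wavelengths), "bands (",
      min(x$wavelengths), "-", max(x$wavelengths), "nm )\n")
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

#' Subset a spectra set by sample and/or band
#'
#' @param x A `spectra_set`.
#' @param i Sample (row) indices.
#' @param j Band (column) indices.
#' @export
subset_spectra <- function(x, i = NULL, j = NULL) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.null(i)) i <- seq_len(nrow(x$reflectance))
  if (is.null(j)) j <- seq_along(x$wavelengths)
  spectra_set(x$reflectance[i, j, drop = FALSE], x$wavelengths[j],
              droplevels(x$labels[i]))
}
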