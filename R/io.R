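# write-temp-then-rename so readers never see a partial file
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

#' Write a spectra set to a tabular text file
#'
#' Tab-separated, one header row of wavelengths in nm, one row per
#' sample, final column `class` holding the label rank (1-4, or the
#' level index for non-standard label sets).
#'
#' @param x A [spectra_set()].
#' @param path Output file.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  df <- as.data.frame(x$reflectance)
  names(df) <- format(x$wavelengths, trim = TRUE)
  df$class <- as.integer(x$labels)
  write_atomic(path, function(p)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE))
}

#' Read a spectra set from a tabular text file
#'
#' Expects the dialect of [write_spectra()]: numeric wavelength header
#' (strictly increasing), optional trailing `class` column with labels
#' 1-4.
#'
#' @param path Input file.
#' @param sep Field separator (default tab; `","` for CSV).
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  has_class <- "class" %in% names(df)
  wl_names <- setdiff(names(df), "class")
  wl <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(wl)) stop("non-numeric wavelength column name(s): ",
                      paste(wl_names[is.na(wl)], collapse = ", "))
  if (any(diff(wl) <= 0)) stop("wavelength header is not strictly increasing")
  X <- as.matrix(df[, wl_names, drop = FALSE])
  if (anyNA(X)) stop("missing or non-numeric reflectance values")
  labels <- if (has_class) as_defect_class(df$class)
            else as_defect_class(rep(1L, nrow(X)))
  spectra_set(X, wl, labels)
}

#' Write a hyperspectral cube in ENVI format
#'
#' ASCII `.hdr` header plus a raw binary file (4-byte little-endian
#' IEEE floats). `interleave` controls the binary layout: `bsq` (band
#' sequential), `bil` (band interleaved by line) or `bip` (by pixel).
#'
#' @param cube A `hypercube`.
#' @param path Binary file path; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param interleave One of `"bsq"`, `"bil"`, `"bip"`.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$cube)   # rows (lines) x cols (samples) x bands
  a <- cube$cube
  # ENVI stores pixels sample-fastest within a line
  vals <- switch(interleave,
    bsq = as.numeric(aperm(a, c(2, 1, 3))),   # sample, line, band
    bil = as.numeric(aperm(a, c(2, 3, 1))),   # sample, band, line
    bip = as.numeric(aperm(a, c(3, 2, 1))))   # band, sample, line
  write_atomic(path, function(p)
    writeBin(vals, p, size = 4, endian = "little"))
  hdr <- c("ENVI",
           "description = { synthetic reflectance cube }",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           paste0("interleave = ", interleave),
           "byte order = 0",
           "wavelength units = Nanometers",
           paste0("wavelength = { ",
                  paste(format(cube$wavelengths, trim = TRUE), collapse = ", "),
                  " }"))
  write_atomic(paste0(path, ".hdr"), function(p) writeLines(hdr, p))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_field <- function(name, required = TRUE) {
    m <- regmatches(txt, regexpr(paste0("(?mi)^", name,
                                        "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"),
                                 txt, perl = TRUE))
    if (!length(m)) {
      if (required) stop("ENVI header missing field: ", name)
      return(NULL)
    }
    v <- sub(paste0("(?i)^", name, "\\s*=\\s*"), "", m, perl = TRUE)
    gsub("^\\{\\s*|\\s*\\}$", "", v)
  }
  list(samples = as.integer(get_field("samples")),
       lines = as.integer(get_field("lines")),
       bands = as.integer(get_field("bands")),
       dtype = as.integer(get_field("data type")),
       interleave = tolower(trimws(get_field("interleave"))),
       byte_order = as.integer(get_field("byte order")),
       offset = {
         v <- get_field("header offset", required = FALSE)
         if (is.null(v)) 0L else as.integer(v)
       },
       wavelength = {
         v <- get_field("wavelength", required = FALSE)
         if (is.null(v)) NULL else as.numeric(strsplit(v, ",")[[1]])
       },
       scale = {
         v <- get_field("reflectance scale factor", required = FALSE)
         if (is.null(v)) 1 else as.numeric(v)
       })
}

#' Read an ENVI hyperspectral cube
#'
#' Supports data types 4 (float32) and 5 (float64), interleaves bsq /
#' bil / bip, and applies the header's reflectance scale factor when
#' present so values are reflectance fractions.
#'
#' @param path Binary file; the header is looked up at
#'   `paste0(path, ".hdr")` (or `path` with extension `.hdr`).
#' @return A `hypercube` (without truth masks).
#' @export
read_envi <- function(path) {
  hdr_path <- if (file.exists(paste0(path, ".hdr"))) paste0(path, ".hdr")
              else sub("\\.[^.]*$", ".hdr", path)
  if (!file.exists(hdr_path)) stop("ENVI header not found for ", path)
  h <- parse_envi_header(hdr_path)
  if (is.null(h$wavelength)) stop("ENVI header has no wavelength list")
  if (length(h$wavelength) != h$bands)
    stop("wavelength list length does not match band count")
  if (!h$dtype %in% c(4L, 5L)) stop("unsupported ENVI data type ", h$dtype)
  size <- if (h$dtype == 4L) 4L else 8L
  n_vals <- h$samples * h$lines * h$bands
  expected <- h$offset + n_vals * size
  if (file.info(path)$size < expected)
    stop("binary file smaller than header implies (", file.info(path)$size,
         " < ", expected, " bytes): size mismatch")
  con <- file(path, "rb"); on.exit(close(con))
  if (h$offset > 0) readBin(con, "raw", h$offset)
  endian <- if (h$byte_order == 0) "little" else "big"
  vals <- readBin(con, "numeric", n_vals, size = size, endian = endian)
  a <- switch(h$interleave,
    bsq = aperm(array(vals, c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    bil = aperm(array(vals, c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bip = aperm(array(vals, c(h$bands, h$samples, h$lines)), c(3, 2, 1)),
    stop("unknown interleave: ", h$interleave))
  structure(list(cube = a / h$scale, wavelengths = h$wavelength, truth = NULL),
            class = "hypercube")
}

#' Write an integer label image as a portable graymap (PGM, ASCII)
#'
#' Used for truth masks and pixel-wise classification maps; `NA`
#' becomes 0. A sidecar `<path>.legend.txt` lists the value-label
#' correspondence when `legend` is given.
#'
#' @param img Integer matrix.
#' @param path Output `.pgm` path.
#' @param legend Optional character vector: `legend[k]` is the meaning
#'   of pixel value `k`.
#' @export
write_pgm <- function(img, path, legend = NULL) {
  img <- as.matrix(img)
  img[is.na(img)] <- 0L
  maxv <- max(1L, max(img))
  write_atomic(path, function(p) {
    con <- file(p, "w"); on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxv)), con)
    utils::write.table(img, con, row.names = FALSE, col.names = FALSE)
  })
  if (!is.null(legend))
    write_atomic(paste0(path, ".legend.txt"), function(p)
      writeLines(sprintf("%d\t%s", seq_along(legend), legend), p))
  invisible(path)
}
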