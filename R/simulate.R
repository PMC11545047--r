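#' Spectral effect regions tied to fruit chemistry
#'
#' Default wavelength regions through which defect severity acts on the
#' simulated reflectance, following the band--chemistry associations
#' reported for goji berries: pigment (carotenoid) absorption over
#' 400--680 nm, water-related features over 715--750 nm, and
#' sugar-related features at 820, 930 and 970 nm. Each effect is a sum
#' of Gaussian bumps scaled by `delta` (reflectance units; positive =
#' brighter with damage, as pigments degrade; negative = darker) and a
#' monotone response shape in the latent severity score `s`:
#' `"linear"` (`g(s) = s`), `"saturating"` (`g(s) = min(s, param)`,
#' early change that levels off) or `"late"` (`g(s) = max(s - param,
#' 0)`, change only at advanced damage). The three default regions
#' follow different trajectories -- pigment degradation saturates
#' early, water status drifts steadily, sugar loss appears late -- so
#' the four class mean spectra are not collinear, as in real defect
#' spectra where bruising, pitting and mould each dominate a different
#' spectral region.
#'
#' @return Named list of effects, each a list with `centers` (nm),
#'   `width` (Gaussian sigma, nm), `delta` (reflectance per unit
#'   response), `response` and `param`.
#' @export
default_effects <- function() {
  list(
    carotenoid = list(centers = c(460, 530, 600, 660), width = 35,
                      delta = 0.045, response = "saturating", param = 1.2),
    water      = list(centers = c(730), width = 14,
                      delta = -0.040, response = "linear", param = NA),
    sugar      = list(centers = c(820, 930, 970), width = 12,
                      delta = -0.035, response = "late", param = 1.5)
  )
}

#' Narrow-band effect specification
#'
#' Concentrates the severity effect at a small set of isolated
#' wavelengths (one bump per band, sigma narrower than the band
#' spacing), used in variable-recovery experiments where the identity of
#' the informative bands must be unambiguous. Each band expresses the
#' severity score with independent fruit-to-fruit `jitter`, as distinct
#' chemical markers do; without it the planted bands would be exactly
#' collinear and any one of them would carry all the usable signal.
#'
#' @param wavelengths Centres of the informative bands (nm).
#' @param delta Reflectance change per severity step at each band.
#' @param width Gaussian sigma in nm (default 2, i.e. sub-band).
#' @param jitter Standard deviation of the per-fruit, per-band
#'   variation of the expressed severity (severity-score units).
#' @export
narrowband_effects <- function(wavelengths, delta = 0.04, width = 2,
                               jitter = 0.5) {
  list(planted = list(centers = wavelengths, width = width, delta = delta,
                      response = "linear", param = NA, jitter = jitter))
}

#' Simulation configuration
#'
#' Defines the statistical structure of the synthetic population:
#' per-class fruit counts, how severity perturbs the reflectance
#' spectrum, and the magnitudes of the measurement artifacts. The
#' default class counts 51/182/285/107 (625 fruit total) reproduce the
#' composition of a stored goji-berry population graded by a sensory
#' panel.
#'
#' Severity acts through a one-dimensional latent score: a fruit of
#' class rank r draws `s ~ N(r - 1, severity_sd^2)`, and its clean
#' spectrum is `base(w) + sum_e g_e(s) * profile_e(w)` over the effect
#' regions (see [default_effects()] for the response shapes `g_e`).
#' Neighbouring classes overlap in s, so misclassifications
#' concentrate on adjacent severity grades.
#' Measurement artifacts are applied per spectrum as
#' `gain * clean + offset + noise` with `gain ~ N(1, scatter_sd^2)`
#' (multiplicative scatter), `offset ~ N(0, baseline_sd^2)` (additive
#' baseline) and i.i.d. per-band noise `N(0, noise_sd^2)`.
#'
#' @param class_counts Four non-negative integers
#'   (sound, mild, moderate, severe).
#' @param effects Effect list as [default_effects()] or
#'   [narrowband_effects()].
#' @param severity_sd Within-class spread of the latent severity score.
#' @param scatter_sd,baseline_sd,noise_sd Artifact magnitudes (all >= 0).
#'   `noise_sd` is the independent per-band noise of a per-fruit mean
#'   spectrum; averaging hundreds of pixels leaves this small, which
#'   matters because derivative pre-treatments amplify white noise.
#'   Simulated cube pixels carry `4 * noise_sd` (single-pixel spectra
#'   are noisier than fruit means).
#' @param wavelengths Wavelength grid (nm).
#' @param glare_ceiling Saturated-reflectance level used for glare
#'   pixels in simulated cubes.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(class_counts = c(51, 182, 285, 107),
                       effects = default_effects(),
                       severity_sd = 0.40,
                       scatter_sd = 0.08,
                       baseline_sd = 0.02,
                       noise_sd = 0.0015,
                       wavelengths = wavelength_grid(),
                       glare_ceiling = 1.05) {
  class_counts <- as.integer(class_counts)
  if (length(class_counts) != 4 || any(is.na(class_counts)) || any(class_counts < 0))
    stop("class_counts must be four non-negative integers")
  if (sum(class_counts) <= 0) stop("total class count must be positive")
  for (v in c(severity_sd, scatter_sd, baseline_sd, noise_sd))
    if (v < 0) stop("spread parameters must be non-negative")
  structure(list(class_counts = class_counts, effects = effects,
                 severity_sd = severity_sd, scatter_sd = scatter_sd,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 wavelengths = as.numeric(wavelengths),
                 glare_ceiling = glare_ceiling),
            class = "sim_config")
}

gaussian_bump <- function(wl, center, width) exp(-0.5 * ((wl - center) / width)^2)

#' Base reflectance template
#'
#' A smooth fixed curve emulating the reflectance of red fruit tissue:
#' a logistic red edge near 690 nm rising to a NIR plateau, with
#' absorption dips for pigments (480, 675 nm) and water/sugar overtones
#' (930, 970 nm). Purely synthetic; only its qualitative shape matters.
#'
#' @param wavelengths Wavelength grid (nm).
#' @return Reflectance fractions in (0, 1).
#' @export
base_reflectance <- function(wavelengths = wavelength_grid()) {
  wl <- wavelengths
  r <- 0.16 + 0.42 * stats::plogis((wl - 690) / 18)
  r <- r - 0.06 * gaussian_bump(wl, 480, 35)
  r <- r - 0.05 * gaussian_bump(wl, 675, 12)
  r <- r - 0.02 * gaussian_bump(wl, 930, 18)
  r <- r - 0.04 * gaussian_bump(wl, 970, 22)
  r
}

effect_profile <- function(effect, wavelengths) {
  prof <- numeric(length(wavelengths))
  for (cc in effect$centers)
    prof <- prof + effect$delta * gaussian_bump(wavelengths, cc, effect$width)
  prof
}

effect_response <- function(effect, s) {
  resp <- if (is.null(effect$response)) "linear" else effect$response
  switch(resp,
         linear = s,
         saturating = pmin(s, effect$param),
         late = pmax(s - effect$param, 0),
         stop("unknown effect response: ", resp))
}

# artifact-free spectra for latent severity scores `s`; effects with
# per-band jitter draw from the active RNG stream (callers seed it)
clean_spectra <- function(s, effects, wavelengths) {
  out <- matrix(base_reflectance(wavelengths), length(s), length(wavelengths),
                byrow = TRUE)
  for (e in effects) {
    g <- effect_response(e, s)
    if (!is.null(e$jitter) && e$jitter > 0) {
      for (cc in e$centers) {
        amp <- g + e$jitter * stats::rnorm(length(s))
        out <- out + outer(amp, e$delta * gaussian_bump(wavelengths, cc, e$width))
      }
    } else {
      out <- out + outer(g, effect_profile(e, wavelengths))
    }
  }
  out
}

#' Generate a synthetic spectra set
#'
#' Draws `sum(class_counts)` per-fruit mean spectra from the latent
#' severity model of [sim_config()]. Identical `seed` gives bitwise
#' identical output. The artifact-free spectra and the latent severity
#' scores are attached as attributes `"clean"` and `"severity"` for use
#' in recovery experiments.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for the random draws.
#' @return A [spectra_set()].
#' @export
#' @examples
#' x <- generate_spectra(sim_config(), seed = 1)
#' dim(x)         # 625 x 121
#' table(x$labels)
generate_spectra <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  wl <- config$wavelengths
  n <- sum(config$class_counts)
  ranks <- rep(1:4, times = config$class_counts)

  set.seed(seed)
  sev <- stats::rnorm(n, mean = ranks - 1, sd = config$severity_sd)
  clean <- clean_spectra(sev, config$effects, wl)
  gain <- stats::rnorm(n, 1, config$scatter_sd)
  offset <- stats::rnorm(n, 0, config$baseline_sd)
  noise <- matrix(stats::rnorm(n * length(wl), 0, config$noise_sd), n, length(wl))
  x <- clean * gain + offset + noise

  out <- spectra_set(x, wl, as_defect_class(ranks))
  attr(out, "clean") <- clean
  attr(out, "severity") <- sev
  out
}

#' Scene layout for a simulated hyperspectral cube
#'
#' Describes a line-scan frame containing several fruit rendered as
#' ellipses on a dark background, matching a scanner tray holding 5-10
#' berries.
#'
#' @param n_fruit Number of fruit in the frame (>= 1).
#' @param rows,cols Frame size in pixels.
#' @param radius Mean fruit semi-axis in pixels; each axis is jittered
#'   by +/- 20%.
#' @param defect_fraction Target fraction of a damaged fruit's pixels
#'   covered by the defect patch.
#' @param glare_fraction Fraction of fruit pixels replaced by saturated
#'   glare.
#' @param labels Optional explicit per-fruit class labels; default
#'   samples them from the config's class proportions.
#' @export
cube_layout <- function(n_fruit = 5, rows = 80, cols = 120, radius = 12,
                        defect_fraction = 0.25, glare_fraction = 0.02,
                        labels = NULL) {
  if (n_fruit < 1) stop("n_fruit must be >= 1")
  if (defect_fraction < 0 || defect_fraction > 1 ||
      glare_fraction < 0 || glare_fraction > 1)
    stop("fractions must be in [0, 1]")
  structure(list(n_fruit = n_fruit, rows = rows, cols = cols, radius = radius,
                 defect_fraction = defect_fraction,
                 glare_fraction = glare_fraction, labels = labels),
            class = "cube_layout")
}

#' Generate a synthetic hyperspectral cube
#'
#' Renders `layout$n_fruit` elliptical fruit on a dark background.
#' Every fruit pixel carries the fruit's clean spectrum (latent severity
#' model of [generate_spectra()]) plus per-pixel noise; fruit of class
#' mild or worse receive one spatially contiguous defect patch whose
#' pixels have elevated severity, producing a sharp reflectance edge at
#' the patch boundary. A fraction of fruit pixels is replaced by
#' saturated glare at `config$glare_ceiling`. Ground truth is returned
#' in `truth`.
#'
#' @param config A [sim_config()].
#' @param layout A [cube_layout()].
#' @param seed Integer seed.
#' @return Object of class `hypercube`: list with `cube`
#'   (rows x cols x bands array), `wavelengths`, and `truth` containing
#'   `mask` (0 background, 1 sound tissue, 2 defect tissue, 3 glare),
#'   `fruit_id` (0 = background), `labels` (per-fruit class factor) and
#'   `severity` (per-fruit latent score).
#' @export
generate_hypercube <- function(config = sim_config(), layout = cube_layout(),
                               seed = 1) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "cube_layout"))
  wl <- config$wavelengths
  nb <- length(wl)
  R <- layout$rows; C <- layout$cols

  set.seed(seed)
  # place fruit centres on a jittered grid so ellipses never overlap
  ng <- ceiling(sqrt(layout$n_fruit))
  cell_r <- R / ceiling(layout$n_fruit / ng); cell_c <- C / ng
  rad_max <- layout$radius * 1.2
  if (cell_r / 2 <= rad_max + 1 || cell_c / 2 <= rad_max + 1)
    stop("fruit do not fit the frame: enlarge rows/cols or shrink radius")
  centers <- cbind(
    rep(seq_len(ceiling(layout$n_fruit / ng)), each = ng)[seq_len(layout$n_fruit)] * cell_r - cell_r / 2,
    rep(seq_len(ng), times = ceiling(layout$n_fruit / ng))[seq_len(layout$n_fruit)] * cell_c - cell_c / 2
  )
  centers <- centers + matrix(stats::runif(2 * layout$n_fruit, -1, 1), ncol = 2)

  if (is.null(layout$labels)) {
    pr <- config$class_counts / sum(config$class_counts)
    labels <- as_defect_class(sample.int(4, layout$n_fruit, replace = TRUE, prob = pr))
  } else {
    labels <- as_defect_class(layout$labels)
    if (length(labels) != layout$n_fruit) stop("labels length must equal n_fruit")
  }
  sev <- stats::rnorm(layout$n_fruit, as.integer(labels) - 1, config$severity_sd)

  mask <- matrix(0L, R, C)       # 0 bg, 1 sound, 2 defect, 3 glare
  fruit_id <- matrix(0L, R, C)
  rr <- row(mask); cc <- col(mask)
  sev_pix <- matrix(0, R, C)

  for (k in seq_len(layout$n_fruit)) {
    a <- layout$radius * stats::runif(1, 0.8, 1.2)
    b <- layout$radius * stats::runif(1, 0.8, 1.2)
    inside <- ((rr - centers[k, 1]) / a)^2 + ((cc - centers[k, 2]) / b)^2 <= 1
    mask[inside] <- 1L
    fruit_id[inside] <- k
    sev_pix[inside] <- sev[k]
    if (labels[k] != "sound" && layout$defect_fraction > 0) {
      idx <- which(inside)
      target <- max(1L, round(layout$defect_fraction * length(idx)))
      # grow a disk around an interior seed until the patch is large enough
      seed_px <- idx[which.min((rr[idx] - centers[k, 1])^2 +
                               (cc[idx] - centers[k, 2])^2 +
                               stats::runif(length(idx), 0, (a * b) / 4))]
      sr <- rr[seed_px]; sc <- cc[seed_px]
      d2 <- (rr[idx] - sr)^2 + (cc[idx] - sc)^2
      patch <- idx[order(d2)[seq_len(target)]]
      mask[patch] <- 2L
      sev_pix[patch] <- sev[k] + 1.5   # defect tissue is markedly worse
    }
  }

  fruit_px <- which(mask > 0L)
  glare <- integer(0)
  if (layout$glare_fraction > 0 && length(fruit_px) > 0) {
    n_glare <- round(layout$glare_fraction * length(fruit_px))
    if (n_glare > 0) {
      glare <- sample(fruit_px, n_glare)
      mask[glare] <- 3L
    }
  }

  # assemble spectra: background dark and flat, fruit from the latent model
  npix <- R * C
  px_noise <- 4 * config$noise_sd
  X <- matrix(0.03, npix, nb) +
    matrix(stats::rnorm(npix * nb, 0, px_noise / 2), npix, nb)
  if (length(fruit_px) > 0) {
    gain <- stats::rnorm(length(fruit_px), 1, config$scatter_sd / 2)
    clean <- clean_spectra(sev_pix[fruit_px], config$effects, wl)
    X[fruit_px, ] <- clean * gain +
      matrix(stats::rnorm(length(fruit_px) * nb, 0, px_noise),
             length(fruit_px), nb)
  }
  if (length(glare) > 0) X[glare, ] <- config$glare_ceiling
  X[X < 0] <- 0

  structure(list(cube = array(X, dim = c(R, C, nb)), wavelengths = wl,
                 truth = list(mask = mask, fruit_id = fruit_id,
                              labels = labels, severity = sev)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$cube)
  cat("hypercube:", d[1], "x", d[2], "pixels x", d[3], "bands\n")
  if (!is.null(x$truth))
    cat("  fruit:", length(x$truth$labels), "(",
        paste(as.character(x$truth$labels), collapse = ", "), ")\n")
  invisible(x)
}
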