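cube5 <- generate_hypercube(sim_config(), cube_layout(n_fruit = 5,
                                                      glare_fraction = 0.02),
                            seed = 21)

test_that("segmentation recovers the rendered fruit regions", {
  masks <- segment_fruit(cube5)
  expect_length(masks, 5)
  # match each mask to the truth component it overlaps and check Jaccard
  for (m in masks) {
    k <- as.integer(names(which.max(table(cube5$truth$fruit_id[m$all]))))
    truth_px <- which(cube5$truth$fruit_id == k)
    jacc <- length(intersect(m$all, truth_px)) /
      length(union(m$all, truth_px))
    expect_gte(jacc, 0.95)
  }
  # masks come back in row-major centroid order
  cent_row <- sapply(masks, function(m) mean((m$all - 1) %% m$dim[1] + 1))
  cent_col <- sapply(masks, function(m) mean((m$all - 1) %/% m$dim[1] + 1))
  ord <- order(round(cent_row), cent_col)
  expect_equal(ord, seq_along(masks))
})

test_that("segmentation edge cases: empty scene and zero threshold", {
  dark <- structure(list(cube = array(0.01, c(10, 10, 3)),
                         wavelengths = c(500, 800, 900), truth = NULL),
                    class = "hypercube")
  expect_error(segment_fruit(dark, reference_band = 800), "no component")
  bright <- dark; bright$cube[] <- 0.5
  m <- segment_fruit(bright, background_threshold = 0, reference_band = 800,
                     min_area = 1)
  expect_length(m, 1)
  expect_length(m[[1]]$all, 100)
  expect_true(m[[1]]$oversized)
})

test_that("glare exclusion matches the simulator's glare truth exactly", {
  masks <- segment_fruit(cube5)
  all_glare <- integer(0)
  for (m in masks) {
    m2 <- exclude_glare(cube5, m, saturation_level = 0.98)
    all_glare <- c(all_glare, m2$excluded_glare)
    # partition property: retained + excluded = all, pairwise disjoint
    expect_setequal(c(m2$retained, m2$excluded_glare,
                      m2$excluded_defect_edge), m2$all)
    expect_length(intersect(m2$retained, m2$excluded_glare), 0)
  }
  truth_glare <- which(cube5$truth$mask == 3L)
  # glare pixels inside segmented fruit regions are found exactly
  in_masks <- intersect(truth_glare, unlist(lapply(masks, `[[`, "all")))
  expect_setequal(all_glare, in_masks)
  # a glare-free cube yields no exclusions at the ceiling
  clean <- generate_hypercube(sim_config(), cube_layout(glare_fraction = 0),
                              seed = 22)
  mc <- segment_fruit(clean)[[1]]
  expect_length(exclude_glare(clean, mc, 1.05)$excluded_glare, 0)
  # a level below fruit reflectance excludes everything -> invalid fruit
  expect_error(exclude_glare(clean, mc, 0.01), "invalid fruit")
})

test_that("defect-edge exclusion removes patch boundary pixels", {
  # scatter off: per-pixel gain variation would otherwise blur the
  # patch edge into the speckle floor
  cube <- generate_hypercube(sim_config(scatter_sd = 0),
                             cube_layout(n_fruit = 1, rows = 60, cols = 60,
                                         radius = 16, defect_fraction = 0.25,
                                         glare_fraction = 0,
                                         labels = "severe"), seed = 23)
  m <- segment_fruit(cube)[[1]]
  m2 <- exclude_defect_edges(cube, m, gradient_threshold = 0.006)
  # truth boundary: defect pixels adjacent to sound tissue (and vice versa)
  msk <- cube$truth$mask
  d <- dim(msk)
  boundary <- integer(0)
  for (px in which(msk == 2L)) {
    r <- (px - 1) %% d[1] + 1; cc <- (px - 1) %/% d[1] + 1
    nb <- c(if (r > 1) px - 1, if (r < d[1]) px + 1,
            if (cc > 1) px - d[1], if (cc < d[2]) px + d[1])
    if (any(msk[nb] == 1L)) boundary <- c(boundary, px)
  }
  hit <- mean(boundary %in% m2$excluded_defect_edge)
  expect_gte(hit, 0.9)
  # infinite threshold is the identity
  expect_equal(exclude_defect_edges(cube, m, Inf)$retained, m$retained)
  # a spatially constant fruit has no exclusions
  flat <- cube
  flat$cube[] <- rep(0.5, prod(dim(flat$cube)))
  expect_length(exclude_defect_edges(flat, m, 0.02)$excluded_defect_edge, 0)
})

test_that("mean_spectrum is the band-wise average of retained pixels", {
  a <- array(0, c(2, 2, 3))
  a[1, 1, ] <- 0.2; a[2, 1, ] <- 0.4; a[1, 2, ] <- 9; a[2, 2, ] <- 9
  cube <- structure(list(cube = a, wavelengths = c(1, 2, 3), truth = NULL),
                    class = "hypercube")
  m <- structure(list(all = 1:2, retained = 1:2, excluded_glare = integer(0),
                      excluded_defect_edge = integer(0), dim = c(2, 2),
                      oversized = FALSE), class = "fruit_mask")
  expect_equal(unname(mean_spectrum(cube, m)), c(0.3, 0.3, 0.3))
  # brute-force oracle on a random cube, permutation invariance, linearity
  set.seed(24)
  b <- array(runif(5 * 4 * 3), c(5, 4, 3))
  cb <- structure(list(cube = b, wavelengths = 1:3, truth = NULL),
                  class = "hypercube")
  px <- sample(20, 7)
  mk <- function(p) structure(list(all = p, retained = p,
                                   excluded_glare = integer(0),
                                   excluded_defect_edge = integer(0),
                                   dim = c(5, 4), oversized = FALSE),
                              class = "fruit_mask")
  brute <- sapply(1:3, function(k) mean(b[, , k][px]))
  expect_equal(unname(mean_spectrum(cb, mk(px))), brute)
  expect_equal(mean_spectrum(cb, mk(rev(px))), mean_spectrum(cb, mk(px)))
  cb2 <- cb; cb2$cube <- 2 * cb$cube
  expect_equal(mean_spectrum(cb2, mk(px)), 2 * mean_spectrum(cb, mk(px)))
  m0 <- mk(px); m0$retained <- integer(0)
  expect_error(mean_spectrum(cb, m0), "empty")
})

test_that("pixel-wise classification maps sound fruit to sound", {
  # well-separated conditions: strong effects, tight within-class spread,
  # balanced sound/defective training, non-derivative pipeline (a second
  # derivative amplifies single-pixel noise)
  eff <- default_effects()
  for (i in seq_along(eff)) eff[[i]]$delta <- 2 * eff[[i]]$delta
  cfg <- sim_config(effects = eff, severity_sd = 0.2)
  train <- generate_spectra(sim_config(effects = eff,
                                       class_counts = c(120, 40, 40, 40)),
                            seed = 25)
  train <- spectra_set(train$reflectance, train$wavelengths,
                       two_class_labels(train$labels))
  pp <- fit_apply_pipeline(pipeline_spec(step_msc(), step_mean_center()),
                           train$reflectance, spacing = 5)
  model <- fit_plsda(pp$train, train$labels, n_lv = 4, pipeline = pp$pipeline)
  cube <- generate_hypercube(cfg, cube_layout(n_fruit = 2, glare_fraction = 0,
                                              labels = c("sound", "severe")),
                             seed = 26)
  masks <- segment_fruit(cube)
  img <- pixelwise_classify(cube, model, masks)
  # background is never assigned a class
  expect_true(all(is.na(img[cube$truth$fruit_id == 0L])))
  # the sound fruit's pixels are overwhelmingly labelled sound
  sound_id <- which(cube$truth$labels == "sound")
  sound_px <- masks[[1]]$retained
  if (!sound_id %in% cube$truth$fruit_id[sound_px])
    sound_px <- masks[[2]]$retained
  expect_gte(mean(img[sound_px] == 1L, na.rm = TRUE), 0.9)
  # single-pixel mask agrees with predict() on that pixel's spectrum
  px <- masks[[1]]$retained[1]
  spec1 <- matrix(cube$cube, ncol = length(cube$wavelengths))[px, , drop = FALSE]
  one <- predict(model, spec1, raw = TRUE)$class
  expect_equal(img[px], as.integer(one))
})
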