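test_that("checkerboard geometry matches the visual-angle conversion", {
  geom <- viewing_geometry()
  spec <- checkerboard_spec()
  f <- make_checkerboard(geom, spec)
  ppd <- pixels_per_degree(geom)

  # two levels symmetric about the mean
  lev <- sort(unique(as.vector(f$luminance)))
  expect_length(lev, 2)
  expect_equal(mean(lev), geom$mean_luminance_norm)
  expect_equal(diff(lev), 2 * geom$mean_luminance_norm * spec$contrast)

  # radial period along a horizontal ray from centre = ppd / cpd, measured
  # by run lengths of the alternating polarity (one run = half period)
  row <- f$luminance[geom$screen_height_px / 2, (geom$screen_width_px / 2 + 1):
                       geom$screen_width_px]
  runs <- rle(sign(row - geom$mean_luminance_norm))$lengths
  runs <- runs[-length(runs)]  # last run is clipped by the frame edge
  expect_lt(abs(stats::median(runs) - ppd / (2 * spec$spatial_freq_cpd)), 1)
})

test_that("zero contrast yields the uniform mock frame", {
  geom <- viewing_geometry()
  f <- make_checkerboard(geom, checkerboard_spec(contrast = 0))
  expect_true(all(f$luminance == geom$mean_luminance_norm))
  expect_error(checkerboard_spec(spatial_freq_cpd = 0), "positive")
})

test_that("phase inversion is an involution and sums to twice the mean", {
  geom <- viewing_geometry(screen_width_px = 160, screen_height_px = 120)
  f0 <- make_checkerboard(geom, checkerboard_spec(phase = 0))
  f1 <- make_checkerboard(geom, checkerboard_spec(phase = 1))
  expect_true(all(abs(f0$luminance + f1$luminance - 2 * 0.5) < 1e-12))
  # inverting twice returns the original
  f2 <- make_checkerboard(geom, checkerboard_spec(phase = 0))
  expect_identical(f0$luminance, f2$luminance)
})

test_that("reversal timestamps follow the pattern-reversal rate", {
  expect_length(reversal_times(checkerboard_spec(reversal_rate_hz = 4), 5), 20)
  expect_equal(reversal_times(checkerboard_spec(reversal_rate_hz = 4), 0.25),
               0.25)
  expect_length(reversal_times(checkerboard_spec(reversal_rate_hz = 0), 5), 0)
  tt <- reversal_times(checkerboard_spec(reversal_rate_hz = 4), 5)
  expect_true(all(abs(diff(tt) - 0.25) < 1e-12))
})

test_that("isoluminant grey conversion normalizes the mean and is
           gain-invariant", {
  geom <- viewing_geometry()
  set.seed(2)
  rgb <- array(runif(40 * 30 * 3, 0, 0.9), c(40, 30, 3))
  g1 <- to_isoluminant_gray(rgb, geom)
  expect_lt(abs(mean(g1$luminance) - geom$mean_luminance_norm), 1e-9)
  # global gain invariance
  g2 <- to_isoluminant_gray(rgb * 0.37, geom)
  expect_equal(g1$luminance, g2$luminance, tolerance = 1e-12)
  # uniform white -> uniform mean-level frame
  gw <- to_isoluminant_gray(array(1, c(5, 5, 3)), geom)
  expect_true(all(abs(gw$luminance - geom$mean_luminance_norm) < 1e-12))
  expect_error(to_isoluminant_gray(array(0, c(5, 5, 3)), geom), "all-black")
})

test_that("contrast scaling is linear in RMS and multiplicative", {
  set.seed(3)
  vals <- runif(1250, 0.2, 0.8)
  lum <- matrix(c(vals, 1 - vals), 50, 50)  # symmetric about the mean level
  fr <- stim_frame(lum, 0.5)
  expect_equal(mean(fr$luminance), 0.5, tolerance = 1e-12)
  rms0 <- sqrt(mean((fr$luminance - 0.5)^2))
  for (c in c(0.2, 0.4, 0.8)) {
    sc <- scale_contrast(fr, c)
    expect_equal(sqrt(mean((sc$luminance - 0.5)^2)) / rms0, c,
                 tolerance = 1e-12)
    expect_equal(mean(sc$luminance), mean(fr$luminance), tolerance = 1e-12)
  }
  # c = 0 uniform, c = 1 identity
  expect_true(all(scale_contrast(fr, 0)$luminance == 0.5))
  expect_equal(scale_contrast(fr, 1)$luminance, fr$luminance)
  # multiplicativity
  ab <- scale_contrast(scale_contrast(fr, 0.5), 0.4)
  expect_equal(ab$luminance, scale_contrast(fr, 0.2)$luminance,
               tolerance = 1e-12)
  expect_error(scale_contrast(fr, 1.2), "contrast")
})

test_that("auto-Canny finds step edges and nothing on uniform frames", {
  expect_true(all(auto_canny_mask(stim_frame(matrix(0.5, 30, 30), 0.5)) == 0L))
  step <- stim_frame(cbind(matrix(0.2, 60, 30), matrix(0.8, 60, 30)), 0.5)
  mk <- auto_canny_mask(step)
  expect_true(all(mk %in% c(0L, 1L)))
  cols <- which(colSums(mk) > 0)
  expect_true(length(cols) > 0)
  expect_true(all(abs(cols - 30.5) <= 2))  # within 2 px of the boundary
})

test_that("blending inverts check polarity on cartoon edges only", {
  geom <- viewing_geometry(screen_width_px = 200, screen_height_px = 150)
  checker <- make_checkerboard(geom, checkerboard_spec())
  # uniform cartoon -> output identical to checkerboard
  uni <- stim_frame(matrix(0.5, 150, 200), 0.5)
  expect_equal(blend_frame(uni, checker)$luminance, checker$luminance)

  set.seed(4)
  cart <- to_isoluminant_gray(matrix(runif(150 * 200), 150, 200), geom)
  bl <- blend_frame(cart, checker)
  mask <- auto_canny_mask(cart) == 1L
  lev <- sort(unique(as.vector(checker$luminance)))
  # never leaves the two checkerboard levels (up to float rounding of the
  # polarity inversion)
  dist_to_levels <- pmin(abs(bl$luminance - lev[1]), abs(bl$luminance - lev[2]))
  expect_lt(max(dist_to_levels), 1e-12)
  # edge pixels carry the full check excursion relative to the local level
  excursion <- abs(bl$luminance[mask] - checker$luminance[mask])
  expect_true(all(abs(excursion - 2 * 0.5 * 0.9) < 1e-12))
  # non-edge fraction equals 1 - mask density
  expect_equal(mean(bl$luminance == checker$luminance), 1 - mean(mask))
  expect_error(blend_frame(stim_frame(matrix(0.5, 10, 10), 0.5), checker),
               "dimensions")
})

test_that("block schedules are reproducible, uniform and well-formed", {
  sch <- build_block_schedule(20, 20, 5, 10, seed = 1)
  expect_equal(sch$total_duration_s, 600)
  expect_equal(nrow(sch$trials), 40)
  expect_equal(sum(sch$trials$condition == "S"), 20)
  # determinism
  expect_identical(build_block_schedule(20, 20, 5, 10, seed = 9)$trials,
                   build_block_schedule(20, 20, 5, 10, seed = 9)$trials)
  # single trial at onset 0
  one <- build_block_schedule(1, 0, 5, 10, seed = 3)
  expect_equal(one$trials$onset_s, 0)
  expect_equal(one$trials$condition, "S")
  # invariants over 100 seeds
  for (s in 1:100) {
    sc <- build_block_schedule(4, 4, 5, 10, seed = s)
    expect_true(all(diff(sc$trials$onset_s) == 15))
    expect_equal(sc$total_duration_s, 8 * 15)
    expect_equal(sum(sc$trials$condition == "B"), 4)
  }
})

test_that("stimulus positions are uniformly distributed across seeds", {
  # chi-square on the distribution of S positions over 1000 seeded draws
  n_draw <- 1000
  counts <- numeric(8)
  for (s in seq_len(n_draw)) {
    sch <- build_block_schedule(4, 4, 5, 10, seed = 10000 + s)
    counts <- counts + (sch$trials$condition == "S")
  }
  expected <- n_draw * 0.5
  chisq <- sum((counts - expected)^2 / (expected * 0.5))
  # 8 cells, alpha = 0.01
  expect_lt(chisq, qchisq(0.99, df = 7))
})

test_that("schedules and frames round-trip through their file formats", {
  sch <- build_block_schedule(6, 6, 5, 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(sch, path)
  back <- read_events(path)
  expect_equal(back$trials, sch$trials)
  expect_equal(back$on_duration_s, 5)
  expect_equal(back$off_duration_s, 10)

  # shuffled row order on disk -> identical schedule after onset sort
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  set.seed(1)
  utils::write.table(df[sample(nrow(df)), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_equal(read_events(path)$trials, sch$trials)

  # empty file -> empty schedule
  writeLines("onset_s\tduration_s\tcondition", path)
  expect_equal(nrow(read_events(path)$trials), 0)

  # overlapping trials rejected
  writeLines(c("onset_s\tduration_s\tcondition", "0\t5\tS", "3\t5\tB"), path)
  expect_error(read_events(path), "overlap")

  dir <- withr::local_tempdir()
  geom <- viewing_geometry(screen_width_px = 64, screen_height_px = 48)
  fr <- make_checkerboard(geom, checkerboard_spec())
  paths <- write_frames_png(list(fr, fr), dir)
  expect_true(all(file.exists(file.path(dir, c("frame_0001.png",
                                               "frame_0002.png")))))
  expect_equal(png::readPNG(file.path(dir, "frame_0001.png")),
               fr$luminance, tolerance = 1 / 255)
})
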