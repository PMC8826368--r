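test_that("optical density is the negative log relative to the mean", {
  m <- default_montage("adult", n_channels = 1)
  # constant intensity -> zero OD
  I <- list(`760` = matrix(0.05, 50, 1), `850` = matrix(0.02, 50, 1))
  rec <- nirs_recording(I, montage = m)
  expect_true(all(abs(intensity_to_od(rec)$od[[1]]) < 1e-15))

  # I = I0 * exp(-x) -> od = x up to the additive constant fixed by the
  # empirical mean; compare both centred
  set.seed(1)
  x <- rnorm(500, 0, 0.1)
  I2 <- list(`760` = matrix(0.05 * exp(-x), ncol = 1),
             `850` = matrix(0.05 * exp(-x), ncol = 1))
  od <- intensity_to_od(nirs_recording(I2, montage = m))
  got <- as.numeric(od$od[[1]])
  expect_equal(got - mean(got), x - mean(x), tolerance = 1e-12)

  # doubling intensities leaves OD unchanged
  I3 <- lapply(I2, function(v) v * 2)
  od3 <- intensity_to_od(nirs_recording(I3, montage = m))
  expect_equal(od3$od[[1]], od$od[[1]], tolerance = 1e-12)
})

test_that("channel pruning applies range, SNR and separation rules", {
  m <- default_montage("adult", n_channels = 4)
  set.seed(2)
  n <- 400
  base <- matrix(0.05 * exp(rnorm(n * 4, 0, 0.005)), n, 4)
  I <- list(`760` = base, `850` = base * 1.1)
  I[["760"]][, 2] <- 2.0                            # exceeds d_range max
  I[["850"]][, 3] <- abs(rnorm(n, 0.1, 0.1)) + 1e-6 # SNR ~ 1
  rec <- nirs_recording(I, montage = m)
  keep <- prune_channels(rec)
  expect_identical(keep, c(TRUE, FALSE, FALSE, TRUE))

  # separation rule: shrink the admissible range (here it empties the
  # keep-set, which is allowed but warned about)
  cfg <- pipeline_config(sd_range_mm = c(0, 25))
  keep2 <- suppressWarnings(prune_channels(rec, cfg))
  expect_true(all(!keep2[m$separation_mm > 25]))
})

test_that("motion detection flags steps and spikes but not physiology", {
  cfg <- pipeline_config()
  fs <- fs_default
  # sub-threshold slow sinusoid -> empty mask
  t <- (0:(600 * fs)) / fs
  quiet <- make_od(0.01 * sin(2 * pi * 0.1 * t))
  expect_false(any(detect_motion(quiet, cfg)))

  # injected step: mask covers the step instant dilated by t_mask
  set.seed(3)
  x <- rnorm(length(t), 0, 0.005)
  s0 <- 3000
  x[s0:length(x)] <- x[s0:length(x)] + 1.0
  mask <- detect_motion(make_od(x), cfg)[, 1]
  expect_true(all(mask[(s0 - round(cfg$t_mask_s * fs)):
                         (s0 + round(cfg$t_mask_s * fs))]))
  # flagged extent is bounded by window + dilation on each side
  ext <- range(which(mask))
  expect_lt(diff(ext) / fs,
            2 * (cfg$t_mask_s + cfg$t_motion_s) + cfg$t_motion_s)

  # 100 spikes of 0.5 OD in noise SD 0.005: >= 95% detected, <= 5% false
  set.seed(4)
  n <- round(2400 * fs)
  y <- rnorm(n, 0, 0.005)
  spikes <- sort(sample(seq(2000, n - 2000), 100))
  y[spikes] <- y[spikes] + 0.5
  mk <- detect_motion(make_od(y), cfg)[, 1]
  expect_gte(mean(mk[spikes]), 0.95)
  truth <- logical(n); truth[spikes] <- TRUE
  legit <- visnirs:::dilate_mask(truth,
                                 round((cfg$t_mask_s + cfg$t_motion_s) * fs))
  expect_lte(mean(mk & !legit), 0.05)
})

test_that("spline correction removes baseline shifts and keeps the signal", {
  cfg <- pipeline_config()
  fs <- fs_default
  t <- (0:5999) / fs

  # empty mask -> identity
  x <- sin(2 * pi * 0.1 * t) * 0.01
  od <- make_od(x)
  same <- spline_correct(od, matrix(FALSE, length(x), 1), cfg)
  expect_identical(same$od[[1]], od$od[[1]])

  # 0.5 OD baseline shift flagged exactly: residual discontinuity < 5%
  y <- x; y[3000:6000] <- y[3000:6000] + 0.5
  mask <- matrix(FALSE, 6000, 1); mask[2990:3010, 1] <- TRUE
  yc <- spline_correct(make_od(y), mask, cfg)$od[[1]][, 1]
  jump <- max(abs(diff(yc[2950:3060])))
  native <- max(abs(diff(x)))  # the signal's own sample-to-sample change
  expect_lt(jump - native, 0.05 * 0.5)
  # unflagged samples unchanged up to a constant offset per side
  expect_lt(diff(range((yc - y)[1:2989])), 1e-12)
  expect_lt(diff(range((yc - y)[3011:6000])), 1e-9)

  # HRF amplitude outside flagged segments preserved within 1%
  k <- trial_kernel()
  h <- numeric(3000); h[500:(499 + length(k))] <- k * 0.01
  msk <- matrix(FALSE, 3000, 1); msk[2000:2050, 1] <- TRUE
  hc <- spline_correct(make_od(h + rnorm(3000, 0, 1e-5)), msk, cfg)$od[[1]][, 1]
  expect_lt(abs(max(hc[1:1900]) - 0.01) / 0.01, 0.01)

  # segments shorter than the spline minimum fall back to mean-shift
  short_mask <- matrix(FALSE, 6000, 1); short_mask[3000:3001, 1] <- TRUE
  expect_silent(spline_correct(make_od(y), short_mask, cfg))
})

test_that("the Daubechies-2 transform reconstructs perfectly and preserves
           energy", {
  set.seed(5)
  X <- matrix(rnorm(1024 * 2), 1024, 2)
  dec <- visnirs:::dwt_full(X)
  # perfect reconstruction
  expect_equal(visnirs:::idwt_full(dec), X, tolerance = 1e-12)
  # orthonormality: coefficient energy equals signal energy
  energy <- sum(dec$approx^2) + sum(vapply(dec$details,
                                           function(d) sum(d^2), numeric(1)))
  expect_equal(energy, sum(X^2), tolerance = 1e-9)
})

test_that("wavelet correction crushes spikes and spares slow signals", {
  cfg <- pipeline_config()
  fs <- fs_default
  n <- 4096
  # constant series unchanged
  const <- make_od(rep(0.3, n))
  expect_equal(wavelet_correct(const, cfg)$od[[1]], const$od[[1]],
               tolerance = 1e-12)

  # single 1.0 OD spike on a flat series: peak reduced >= 80%
  sp <- numeric(n); sp[2000] <- 1.0
  w <- wavelet_correct(make_od(sp), cfg)$od[[1]][, 1]
  expect_lt(max(abs(w)), 0.2)

  # slow 0.05 Hz tone without outliers: RMS change < 5%
  t <- (0:(n - 1)) / fs
  tone <- sin(2 * pi * 0.05 * t)
  wt <- wavelet_correct(make_od(tone), cfg)$od[[1]][, 1]
  mid <- 500:(n - 500)
  expect_lt(abs(sqrt(mean(wt[mid]^2)) / sqrt(mean(tone[mid]^2)) - 1), 0.05)

  # too-short series skipped with a warning
  expect_warning(wavelet_correct(make_od(rep(0.1, 4)), cfg), "short")
})

test_that("the zero-phase band-pass matches its analytic response", {
  cfg <- pipeline_config()
  fs <- fs_default
  n <- round(600 * fs)
  t <- (0:(n - 1)) / fs

  # DC rejection: output mean below 1e-6 of the input offset (the residual
  # filter transient lives at the series edges)
  flat <- bandpass(make_od(rep(0.7, n)), cfg)$od[[1]][, 1]
  expect_lt(abs(mean(flat)), 0.7 * 1e-6)
  expect_lt(max(abs(flat[1000:(n - 1000)])), 0.7 * 1e-6)

  # measured tone gains vs the analytic zero-phase Butterworth response
  gains <- vapply(c(0.01, 0.1, 0.5, 1.0), function(f) {
    y <- bandpass(make_od(sin(2 * pi * f * t)), cfg)$od[[1]][, 1]
    mid <- 1000:(n - 1000)
    co <- coef(lm(y[mid] ~ sin(2 * pi * f * t[mid]) + cos(2 * pi * f * t[mid])))
    sqrt(sum(co[2:3]^2))
  }, numeric(1))
  analytic <- bandpass_gain(c(0.01, 0.1, 0.5, 1.0), cfg)
  expect_true(all(abs(gains / analytic - 1) < 0.05))
  # spec bounds: passband ~1, cardiac heavily attenuated
  expect_true(gains[2] > 0.95 && gains[2] < 1.05)
  expect_lt(gains[4], 0.2)

  expect_error(bandpass(make_od(rep(0, 10), fs = 0.9), cfg), "Nyquist")
})

test_that("Beer-Lambert inversion is exact and linear", {
  m <- default_montage("adult")
  cfg <- pipeline_config()
  # zero OD -> zero concentrations
  z <- structure(list(od = list(`760` = matrix(0, 5, 22),
                                `850` = matrix(0, 5, 22)),
                      fs = fs_default, montage = m, steps = "t"),
                 class = "optical_density")
  hb0 <- mbll(z, m, cfg)
  expect_true(all(hb0$ohb == 0) && all(hb0$dhb == 0) && all(hb0$thb == 0))

  # forward-generate from known pair and invert
  ohb <- matrix(2e-4, 8, 22); dhb <- matrix(-1e-4, 8, 22)
  odf <- structure(list(od = hb_to_od(ohb, dhb, m, cfg), fs = fs_default,
                        montage = m, steps = "t"), class = "optical_density")
  hb <- mbll(odf, m, cfg)
  expect_lt(max(abs(hb$ohb - ohb)), 1e-10)
  expect_lt(max(abs(hb$dhb - dhb)), 1e-10)

  # THb identity on any converted recording
  rec <- make_recording(n = 100, n_ch = 3)
  hb2 <- mbll(intensity_to_od(rec), rec$montage, cfg)
  expect_lt(max(abs(hb2$thb - hb2$ohb - hb2$dhb)), 1e-12)

  # singular extinction matrix rejected
  bad <- pipeline_config(extinction = data.frame(
    wavelength = c(760, 850), e_hbo = c(1, 1), e_hbr = c(1, 1)))
  expect_error(mbll(odf, m, bad), "singular")
})

test_that("the full stream records its stage order", {
  rec <- make_recording(n = 700, n_ch = 2)
  pp <- preprocess_recording(rec)
  expect_identical(pp$log$steps,
                   c("intensity_to_od", "spline_correct", "wavelet_correct",
                     "bandpass", "mbll"))
  expect_equal(dim(pp$motion_mask), dim(pp$residual_mask))
  expect_equal(pp$log$n_channels, 2)
})
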