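#' Stimulus frame container
#'
#' A frame of normalized luminance values in \[0, 1\] together with the mean
#' level the frame is contrast-scaled around.
#'
#' @param luminance numeric matrix (rows x cols) of values in \[0, 1\].
#' @param mean_level normalized luminance the frame is centred on.
#' @return An object of class `stim_frame`.
#' @export
stim_frame <- function(luminance, mean_level) {
  if (!is.matrix(luminance) || !is.numeric(luminance))
    stop("luminance must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(luminance)) || min(luminance) < -1e-12 ||
      max(luminance) > 1 + 1e-12)
    stop("luminance values must lie in [0, 1]", call. = FALSE)
  luminance <- pmin(pmax(luminance, 0), 1)
  structure(list(luminance = luminance, mean_level = mean_level),
            class = "stim_frame")
}

#' Render the radial checkerboard
#'
#' Builds one frame of the full-field, square-wave, radial checkerboard:
#' concentric rings of constant radial width (half a spatial period) crossed
#' with wedges whose tangential width at half-maximal eccentricity
#' approximately equals the radial check width. The two luminance levels are
#' `mean * (1 +/- contrast)`; `phase = 1` returns the polarity-swapped frame.
#' At zero contrast the frame is uniform at the mean level (the mock
#' stimulus).
#'
#' @param geom a [viewing_geometry()].
#' @param spec a [checkerboard_spec()].
#' @return A [stim_frame()].
#' @examples
#' f <- make_checkerboard(viewing_geometry(), checkerboard_spec())
#' range(f$luminance)
#' @export
make_checkerboard <- function(geom, spec) {
  stopifnot(inherits(geom, "viewing_geometry"),
            inherits(spec, "checkerboard_spec"))
  ppd <- pixels_per_degree(geom)
  half_period_px <- ppd / (2 * spec$spatial_freq_cpd)

  w <- geom$screen_width_px; h <- geom$screen_height_px
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  x <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  y <- matrix(seq_len(h), h, w) - cy
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)

  ring <- floor(r / half_period_px)
  # wedge count: tangential arc length at half-max eccentricity ~ radial width
  r_half <- sqrt((w / 2)^2 + (h / 2)^2) / 2
  n_wedge <- max(2, 2 * round(pi * r_half / half_period_px))
  wedge <- floor((theta + pi) / (2 * pi) * n_wedge)

  pol <- (ring + wedge + spec$phase) %% 2
  mean_level <- geom$mean_luminance_norm
  lum <- mean_level * (1 + spec$contrast * (2 * pol - 1))
  stim_frame(lum, mean_level)
}

#' Pattern-reversal timestamps within one stimulus presentation
#'
#' Phase inversions occur at a fixed rate (the pattern-reversal convention:
#' a 4 Hz temporal frequency means four abrupt polarity swaps per second).
#'
#' @param spec a [checkerboard_spec()].
#' @param on_duration_s stimulus-on duration in seconds (> 0).
#' @return Numeric vector of inversion times in seconds (possibly empty for a
#'   static pattern).
#' @export
reversal_times <- function(spec, on_duration_s) {
  stopifnot(inherits(spec, "checkerboard_spec"))
  if (!is.finite(on_duration_s) || on_duration_s <= 0)
    stop("on_duration_s must be positive", call. = FALSE)
  rate <- spec$reversal_rate_hz
  if (rate == 0) return(numeric(0))
  n <- floor(on_duration_s * rate + 1e-9)
  seq_len(n) / rate
}

#' Convert an RGB frame to an isoluminant grey frame
#'
#' Collapses an RGB frame to luma and rescales it multiplicatively so its
#' spatial mean equals the display's normalized mean luminance. Frames that
#' differ only by a global gain therefore map to identical outputs.
#'
#' @param rgb_frame numeric array `h x w x 3` (or an `h x w` matrix already
#'   grey) with values in \[0, 1\].
#' @param geom a [viewing_geometry()]; supplies the target mean luminance.
#' @return A [stim_frame()] whose spatial mean equals
#'   `geom$mean_luminance_norm`.
#' @export
to_isoluminant_gray <- function(rgb_frame, geom) {
  stopifnot(inherits(geom, "viewing_geometry"))
  if (is.matrix(rgb_frame)) {
    gray <- rgb_frame
  } else if (is.array(rgb_frame) && length(dim(rgb_frame)) == 3 &&
             dim(rgb_frame)[3] >= 3) {
    gray <- 0.2126 * rgb_frame[, , 1] + 0.7152 * rgb_frame[, , 2] +
      0.0722 * rgb_frame[, , 3]
  } else {
    stop("rgb_frame must be an h x w matrix or h x w x 3 array", call. = FALSE)
  }
  if (min(gray) < -1e-12 || max(gray) > 1 + 1e-12)
    stop("RGB values must lie in [0, 1]", call. = FALSE)
  m <- mean(gray)
  if (m <= 0)
    stop("degenerate input: all-black frame cannot be rescaled", call. = FALSE)
  out <- gray * (geom$mean_luminance_norm / m)
  stim_frame(pmin(out, 1), geom$mean_luminance_norm)
}

#' Scale the Michelson contrast of a frame about its mean level
#'
#' `pixel' = mean_level + c * (pixel - mean_level)`; the frame mean is
#' unchanged. Used to present the baseline cartoon at 20, 40 or 80% contrast.
#'
#' @param frame a [stim_frame()].
#' @param c contrast scale in \[0, 1\].
#' @return A [stim_frame()].
#' @export
scale_contrast <- function(frame, c) {
  stopifnot(inherits(frame, "stim_frame"))
  if (!is.finite(c) || c < 0 || c > 1)
    stop("contrast scale must lie in [0, 1]", call. = FALSE)
  lum <- frame$mean_level + c * (frame$luminance - frame$mean_level)
  stim_frame(lum, frame$mean_level)
}

# 2D shift helper: moves a matrix by (di, dj), replicating the border row/col.
shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + di, 1), nr)
  ci <- pmin(pmax(seq_len(nc) + dj, 1), nc)
  m[ri, ci, drop = FALSE]
}

#' Median-based automatic Canny edge mask
#'
#' Zero-parameter Canny recipe: a Gaussian blur, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, then hysteresis with
#' thresholds derived from the frame median `m` as
#' `[max(0, (1 - sigma) m), min(1, (1 + sigma) m)]`, `sigma = 0.33`.
#'
#' @param frame a [stim_frame()] (grey-scale).
#' @param sigma relative threshold half-width (default 0.33).
#' @return A binary (0/1) integer matrix of the frame's dimensions.
#' @export
auto_canny_mask <- function(frame, sigma = 0.33) {
  stopifnot(inherits(frame, "stim_frame"))
  img <- frame$luminance
  med <- stats::median(img)
  lo <- max(0, (1 - sigma) * med)
  hi <- min(1, (1 + sigma) * med)

  # separable 5-tap Gaussian blur (sd ~ 1.1 px)
  g <- c(1, 4, 6, 4, 1) / 16
  blur <- img
  for (k in -2:2) if (k != 0) blur <- blur + 0  # keep shape
  blur <- g[1] * shift_mat(img, -2, 0) + g[2] * shift_mat(img, -1, 0) +
    g[3] * img + g[4] * shift_mat(img, 1, 0) + g[5] * shift_mat(img, 2, 0)
  blur <- g[1] * shift_mat(blur, 0, -2) + g[2] * shift_mat(blur, 0, -1) +
    g[3] * blur + g[4] * shift_mat(blur, 0, 1) + g[5] * shift_mat(blur, 0, 2)

  # Sobel gradients
  sx <- function(m) shift_mat(m, 0, -1) - shift_mat(m, 0, 1)
  sy <- function(m) shift_mat(m, -1, 0) - shift_mat(m, 1, 0)
  gx <- sx(shift_mat(blur, -1, 0) + 2 * blur + shift_mat(blur, 1, 0))
  gy <- sy(shift_mat(blur, 0, -1) + 2 * blur + shift_mat(blur, 0, 1))
  mag <- sqrt(gx^2 + gy^2)

  if (max(mag) == 0) return(matrix(0L, nrow(img), ncol(img)))

  # non-maximum suppression over 4 quantized directions
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4
  n1 <- mag; n2 <- mag
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    d <- offs[[as.character(s)]]
    sel <- sector == s
    n1[sel] <- shift_mat(mag, d[1], d[2])[sel]
    n2[sel] <- shift_mat(mag, -d[1], -d[2])[sel]
  }
  ridge <- mag >= n1 & mag >= n2

  strong <- ridge & mag >= hi
  weak <- ridge & mag >= lo
  # hysteresis: grow strong edges through weak pixels (8-connected)
  repeat {
    grown <- strong
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      grown <- grown | shift_mat(strong, di, dj)
    }
    grown <- grown & weak
    if (all(grown == strong)) break
    strong <- grown
  }
  matrix(as.integer(strong), nrow(img), ncol(img))
}

#' Blend a cartoon frame into a checkerboard frame
#'
#' Non-edge pixels take the checkerboard value; pixels on the cartoon's
#' Canny edge mask are drawn in the checkerboard level opposite to the local
#' check polarity (`2 * mean_level - check`), so every cartoon edge stays
#' visible against either check level. The output never leaves the two
#' checkerboard levels.
#'
#' @param cartoon a [stim_frame()] (typically the contrast-scaled grey
#'   cartoon baseline).
#' @param checker a [stim_frame()] with exactly two luminance levels.
#' @param sigma auto-Canny threshold width passed to [auto_canny_mask()].
#' @return A [stim_frame()].
#' @export
blend_frame <- function(cartoon, checker, sigma = 0.33) {
  stopifnot(inherits(cartoon, "stim_frame"), inherits(checker, "stim_frame"))
  if (!all(dim(cartoon$luminance) == dim(checker$luminance)))
    stop("cartoon and checkerboard dimensions differ", call. = FALSE)
  lev <- sort(unique(as.vector(checker$luminance)))
  if (length(lev) > 2)
    stop("checkerboard frame must have exactly two levels", call. = FALSE)
  mask <- auto_canny_mask(cartoon, sigma = sigma) == 1L
  out <- checker$luminance
  out[mask] <- 2 * checker$mean_level - out[mask]
  stim_frame(out, checker$mean_level)
}

#' Trial schedule for the event-related block design
#'
#' Ordered trials of stimulus (`"S"`, reversing checkerboard) and mock
#' (`"B"`, zero-contrast) presentations, laid out back-to-back: each trial is
#' `on_duration_s` of stimulation followed by `off_duration_s` of baseline.
#'
#' @param onsets numeric vector of trial onsets (s), strictly increasing.
#' @param conditions character vector of `"S"`/`"B"`, same length as onsets.
#' @param on_duration_s,off_duration_s trial on/off durations (s).
#' @return An object of class `trial_schedule` with fields `trials` (a tibble
#'   with `onset_s`, `condition`), `on_duration_s`, `off_duration_s` and
#'   `total_duration_s`.
#' @export
trial_schedule <- function(onsets, conditions, on_duration_s, off_duration_s) {
  if (length(onsets) != length(conditions))
    stop("onsets and conditions lengths differ", call. = FALSE)
  if (!all(conditions %in% c("S", "B")))
    stop("conditions must be 'S' or 'B'", call. = FALSE)
  if (on_duration_s <= 0 || off_duration_s <= 0)
    stop("durations must be positive", call. = FALSE)
  n <- length(onsets)
  period <- on_duration_s + off_duration_s
  if (n >= 1) {
    if (any(diff(onsets) <= 0))
      stop("onsets must be strictly increasing", call. = FALSE)
    if (n >= 2 && any(abs(diff(onsets) - period) > 1e-9))
      stop("consecutive onsets must differ by exactly on + off", call. = FALSE)
  }
  structure(
    list(trials = tibble::tibble(onset_s = as.numeric(onsets),
                                 condition = as.character(conditions)),
         on_duration_s = on_duration_s, off_duration_s = off_duration_s,
         total_duration_s = n * period),
    class = "trial_schedule")
}

#' Build a pseudo-randomized block schedule
#'
#' Interleaves `n_stim` stimulus trials and `n_mock` mock trials in a seeded
#' pseudo-random order, back-to-back. The study protocol uses 20 + 20 trials
#' of 5 s on / 10 s off, i.e. a 10-minute block.
#'
#' @param n_stim,n_mock trial counts (>= 0).
#' @param on_s,off_s on/off durations in seconds.
#' @param seed integer seed; the same seed reproduces the same ordering.
#' @return A [trial_schedule()].
#' @examples
#' sch <- build_block_schedule(20, 20, 5, 10, seed = 1)
#' sch$total_duration_s  # 600
#' @export
build_block_schedule <- function(n_stim = 20, n_mock = 20, on_s = 5,
                                 off_s = 10, seed = 1) {
  if (n_stim < 0 || n_mock < 0) stop("trial counts must be >= 0", call. = FALSE)
  conds <- c(rep("S", n_stim), rep("B", n_mock))
  conds <- with_seed(seed, sample(conds))
  n <- length(conds)
  onsets <- (seq_len(n) - 1) * (on_s + off_s)
  trial_schedule(onsets, conds, on_s, off_s)
}

#' Write a trial schedule as a tab-separated events file
#'
#' Columns: `onset_s`, `duration_s` (the on duration), `condition`.
#'
#' @param schedule a [trial_schedule()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "trial_schedule"))
  df <- data.frame(onset_s = schedule$trials$onset_s,
                   duration_s = schedule$on_duration_s,
                   condition = schedule$trials$condition)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trial schedule from a tab-separated events file
#'
#' Rows are sorted by onset before validation, so on-disk row order is
#' irrelevant. Overlapping trials (an onset before the previous trial's
#' offset) raise a validation error.
#'
#' @param path events file with columns `onset_s`, `duration_s`, `condition`.
#' @param off_duration_s off duration; if `NULL`, inferred from the onset
#'   spacing (spacing minus on duration).
#' @return A [trial_schedule()]; an empty file yields an empty schedule.
#' @export
read_events <- function(path, off_duration_s = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    return(structure(
      list(trials = tibble::tibble(onset_s = numeric(0),
                                   condition = character(0)),
           on_duration_s = NA_real_, off_duration_s = NA_real_,
           total_duration_s = 0),
      class = "trial_schedule"))
  }
  need <- c("onset_s", "duration_s", "condition")
  if (!all(need %in% names(df)))
    stop("events file must have columns onset_s, duration_s, condition",
         call. = FALSE)
  df <- df[order(df$onset_s), , drop = FALSE]
  on_s <- unique(df$duration_s)
  if (length(on_s) != 1)
    stop("events file mixes trial durations", call. = FALSE)
  if (nrow(df) >= 2) {
    gap <- diff(df$onset_s)
    if (any(gap < on_s - 1e-9))
      stop("overlapping trials in events file", call. = FALSE)
    off <- if (is.null(off_duration_s)) gap[1] - on_s else off_duration_s
  } else {
    off <- if (is.null(off_duration_s)) 10 else off_duration_s
  }
  trial_schedule(df$onset_s, df$condition, on_s, off)
}

#' Write stimulus frames as a numbered PNG sequence
#'
#' @param frames a list of [stim_frame()]s.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_frames_png <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    stopifnot(inherits(frames[[i]], "stim_frame"))
    paths[i] <- file.path(dir, sprintf("%s_%04d.png", prefix, i))
    png::writePNG(frames[[i]]$luminance, paths[i])
  }
  invisible(paths)
}
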