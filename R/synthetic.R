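#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities, normalized to unit peak: a positive
#' lobe peaking at `peak_s` (6 s by default) and an undershoot peaking at
#' `undershoot_s` whose depth is `undershoot_ratio` (1/6) of the main peak.
#' `hrf(0) = 0`.
#'
#' @param peak_s time-to-peak of the positive lobe (s).
#' @param undershoot_s time-to-peak of the undershoot (s).
#' @param undershoot_ratio undershoot depth relative to the main peak.
#' @param rate gamma rate parameter (1/s); shapes are
#'   `peak * rate + 1` so the mode lands at the requested peak times.
#' @return `hrf_shape` returns a parameter object; `hrf` evaluates the
#'   response at times `t >= 0` (zero for `t < 0`).
#' @export
hrf_shape <- function(peak_s = 6, undershoot_s = 15, undershoot_ratio = 1 / 6,
                      rate = 1) {
  a1 <- peak_s * rate + 1
  a2 <- undershoot_s * rate + 1
  tg <- seq(0, undershoot_s + 20, by = 0.01)
  raw <- stats::dgamma(tg, a1, rate) -
    undershoot_ratio * stats::dgamma(tg, a2, rate)
  structure(list(a1 = a1, a2 = a2, rate = rate,
                 undershoot_ratio = undershoot_ratio,
                 peak_value = max(raw)),
            class = "hrf_shape")
}

#' @rdname hrf_shape
#' @param t evaluation times (s).
#' @param shape an [hrf_shape()].
#' @export
hrf <- function(t, shape = hrf_shape()) {
  stopifnot(inherits(shape, "hrf_shape"))
  out <- (stats::dgamma(t, shape$a1, shape$rate) -
            shape$undershoot_ratio * stats::dgamma(t, shape$a2, shape$rate)) /
    shape$peak_value
  out[t < 0] <- 0
  out
}

#' Single-trial response kernel: HRF convolved with the 5 s stimulus boxcar
#'
#' The kernel is the double-gamma HRF convolved with the stimulus-on boxcar,
#' normalized to unit peak, then smoothly tapered to zero with a raised
#' cosine over `taper_s` (10-13 s post onset by default). The compact
#' support mirrors the return-to-baseline seen in block-averaged responses
#' within the 15 s trial spacing, so one trial's response does not leak into
#' the next trial's baseline window.
#'
#' @param fs sampling rate (Hz).
#' @param on_s stimulus-on duration (s).
#' @param shape an [hrf_shape()].
#' @param taper_s two times (s): taper start and end.
#' @return Numeric vector sampled at `fs`, starting at onset, unit peak.
#' @export
trial_kernel <- function(fs = 10.2, on_s = 5, shape = hrf_shape(),
                         taper_s = c(10, 13)) {
  t <- seq(0, taper_s[2], by = 1 / fs)
  h <- hrf(t, shape)
  box_n <- max(1L, round(on_s * fs))
  conv <- stats::convolve(h, rev(rep(1, box_n)), type = "open")[seq_along(t)]
  conv <- conv / max(conv)
  w <- rep(1, length(t))
  ramp <- t >= taper_s[1] & t <= taper_s[2]
  w[ramp] <- 0.5 * (1 + cos(pi * (t[ramp] - taper_s[1]) /
                              (taper_s[2] - taper_s[1])))
  w[t > taper_s[2]] <- 0
  conv * w
}

#' Physiological-noise and artifact presets
#'
#' Amplitudes are in optical-density units per wavelength. The default
#' preset combines cardiac (~1.1 Hz), respiratory (~0.25 Hz) and Mayer-wave
#' (~0.1 Hz) oscillations, white sensor noise, a slow drift, and a motion
#' schedule of spikes and baseline shifts. `"off"` disables everything.
#'
#' @param preset `"default"` or `"off"`.
#' @return A list of noise parameters.
#' @export
noise_preset <- function(preset = c("default", "off")) {
  preset <- match.arg(preset)
  if (preset == "off") {
    return(list(cardiac_hz = 1.1, cardiac_amp = 0, resp_hz = 0.25,
                resp_amp = 0, mayer_hz = 0.1, mayer_amp = 0, white_sd = 0,
                pink_sd = 0, drift_hz = 0.005, drift_amp = 0, n_spikes = 0,
                spike_amp = c(0, 0), spike_width_s = c(0.2, 0.8),
                n_shifts = 0, shift_amp = c(0, 0)))
  }
  list(cardiac_hz = 1.1, cardiac_amp = 2e-3,
       resp_hz = 0.25, resp_amp = 1e-3,
       mayer_hz = 0.1, mayer_amp = 5e-4,
       white_sd = 5e-4,
       pink_sd = 1e-3,
       drift_hz = 0.005, drift_amp = 5e-3,
       n_spikes = 4, spike_amp = c(0.08, 0.40), spike_width_s = c(0.2, 0.8),
       n_shifts = 2, shift_amp = c(0.05, 0.20))
}

#' Synthetic-recording configuration
#'
#' @param dhb_ratio planted deoxy/oxy amplitude ratio (negative: the deoxy
#'   trace is a scaled, inverted copy of the oxy trace; default -1/3, a
#'   smaller depletion of deoxy-hemoglobin than the oxy increase).
#' @param lead_in_s,tail_s recording padding before the first onset and
#'   after the last trial (s), so every averaging window lies inside the
#'   recording.
#' @param gain_width spatial spread (in channel index units) of the evoked
#'   response around the best channel.
#' @param i0_range raw-intensity baseline range (detector units).
#' @param noise a [noise_preset()] list.
#' @param shape an [hrf_shape()].
#' @param taper_s trial-kernel taper, passed to [trial_kernel()].
#' @return A list of generator settings.
#' @export
sim_config <- function(dhb_ratio = -1 / 3, lead_in_s = 15, tail_s = 25,
                       gain_width = 3, i0_range = c(0.02, 0.08),
                       noise = noise_preset("default"),
                       shape = hrf_shape(), taper_s = c(10, 13)) {
  list(dhb_ratio = dhb_ratio, lead_in_s = lead_in_s, tail_s = tail_s,
       gain_width = gain_width, i0_range = i0_range, noise = noise,
       shape = shape, taper_s = taper_s)
}

#' Simulate one subject's two-wavelength recording
#'
#' Composes per-channel oxy-hemoglobin responses (`A_ohb x trial kernel` at
#' every stimulus onset, zero for mock trials), a proportional inverted
#' deoxy trace (`dhb_ratio`), forward Beer-Lambert conversion to OD at 760
#' and 850 nm, additive physiological noise and scheduled motion artifacts,
#' and exponentiation to raw intensities at 10.2 Hz. The evoked amplitude is
#' maximal at `best_channel` and falls off over neighbouring channels.
#'
#' @param thb_amplitude planted total-hemoglobin peak amplitude (molar).
#' @param schedule a [trial_schedule()] (onsets are shifted by the
#'   configured lead-in inside the recording).
#' @param montage a [probe_montage()].
#' @param best_channel channel carrying the full planted amplitude.
#' @param scfg a [sim_config()].
#' @param seed integer seed; the same seed reproduces the recording
#'   bit-for-bit.
#' @param fs sampling rate (Hz).
#' @param subject_id,cohort recording metadata.
#' @return List with `recording` (a [nirs_recording()]), `schedule` (the
#'   shifted [trial_schedule()]) and `truth` (planted amplitudes, best
#'   channel, channel gains, artifact table).
#' @export
simulate_subject <- function(thb_amplitude, schedule, montage,
                             best_channel = 1, scfg = sim_config(), seed = 1,
                             fs = 10.2, subject_id = "S01",
                             cohort = c("adult", "child")) {
  cohort <- match.arg(cohort)
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(montage, "probe_montage"))
  n_ch <- nrow(montage$channels)
  stopifnot(best_channel >= 1, best_channel <= n_ch)
  dur <- scfg$lead_in_s + schedule$total_duration_s + scfg$tail_s
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs

  onsets <- schedule$trials$onset_s + scfg$lead_in_s
  shifted <- trial_schedule(onsets, schedule$trials$condition,
                            schedule$on_duration_s, schedule$off_duration_s)
  if (max(onsets) + scfg$taper_s[2] > dur)
    stop("schedule longer than the requested recording duration",
         call. = FALSE)

  with_seed(seed, {
    kern <- trial_kernel(fs, schedule$on_duration_s, scfg$shape, scfg$taper_s)
    a_ohb <- thb_amplitude / (1 + scfg$dhb_ratio)
    resp <- numeric(n)
    s_onsets <- onsets[shifted$trials$condition == "S"]
    for (o in s_onsets) {
      i0 <- round(o * fs) + 1L
      ii <- i0:min(n, i0 + length(kern) - 1L)
      resp[ii] <- resp[ii] + kern[seq_along(ii)]
    }
    gains <- 0.3 + 0.7 * exp(-((seq_len(n_ch) - best_channel)^2) /
                               (2 * scfg$gain_width^2))
    gains[best_channel] <- 1
    ohb <- outer(resp * a_ohb, gains)
    dhb <- scfg$dhb_ratio * ohb
    od <- hb_to_od(ohb, dhb, montage)

    nz <- scfg$noise
    # broadband 1/f (pink) noise via spectral shaping, one column per channel
    pink_noise <- function(sd_target) {
      if (sd_target == 0) return(matrix(0, n, n_ch))
      nf <- floor(n / 2)
      shape <- seq_len(nf)^(-0.5)
      out <- matrix(0, n, n_ch)
      for (ch in seq_len(n_ch)) {
        amp <- stats::rnorm(nf) * shape
        phs <- stats::runif(nf, 0, 2 * pi)
        spec <- complex(modulus = c(0, amp, rep(0, n - nf - 1)),
                        argument = c(0, phs, rep(0, n - nf - 1)))
        x <- Re(stats::fft(spec, inverse = TRUE))
        out[, ch] <- x / stats::sd(x) * sd_target
      }
      out
    }
    sin_noise <- function(hz, amp) {
      if (amp == 0) return(matrix(0, n, n_ch))
      f <- hz * stats::runif(n_ch, 0.95, 1.05)
      ph <- stats::runif(n_ch, 0, 2 * pi)
      amp * sin(outer(tt, 2 * pi * f) +
                  matrix(ph, n, n_ch, byrow = TRUE))
    }
    # artifact schedule shared across channels/wavelengths (head motion)
    spikes <- if (nz$n_spikes > 0)
      tibble::tibble(type = "spike",
                     time_s = stats::runif(nz$n_spikes, 5, dur - 5),
                     amplitude = sample(c(-1, 1), nz$n_spikes, TRUE) *
                       stats::runif(nz$n_spikes, nz$spike_amp[1],
                                    nz$spike_amp[2]),
                     width_s = stats::runif(nz$n_spikes, nz$spike_width_s[1],
                                            nz$spike_width_s[2]))
    else NULL
    shifts <- if (nz$n_shifts > 0)
      tibble::tibble(type = "shift",
                     time_s = stats::runif(nz$n_shifts, 5, dur - 5),
                     amplitude = sample(c(-1, 1), nz$n_shifts, TRUE) *
                       stats::runif(nz$n_shifts, nz$shift_amp[1],
                                    nz$shift_amp[2]),
                     width_s = NA_real_)
    else NULL
    artifacts <- dplyr::bind_rows(spikes, shifts)

    artifact_series <- numeric(n)
    if (!is.null(spikes)) for (i in seq_len(nrow(spikes))) {
      c0 <- spikes$time_s[i]; w <- spikes$width_s[i]
      sel <- abs(tt - c0) <= w
      artifact_series[sel] <- artifact_series[sel] +
        spikes$amplitude[i] * (1 - abs(tt[sel] - c0) / w)
    }
    if (!is.null(shifts)) for (i in seq_len(nrow(shifts))) {
      artifact_series[tt >= shifts$time_s[i]] <-
        artifact_series[tt >= shifts$time_s[i]] + shifts$amplitude[i]
    }

    intensity <- list()
    for (w in names(od)) {
      noise <- sin_noise(nz$cardiac_hz, nz$cardiac_amp) +
        sin_noise(nz$resp_hz, nz$resp_amp) +
        sin_noise(nz$mayer_hz, nz$mayer_amp) +
        sin_noise(nz$drift_hz, nz$drift_amp) +
        pink_noise(nz$pink_sd)
      if (nz$white_sd > 0)
        noise <- noise + matrix(stats::rnorm(n * n_ch, 0, nz$white_sd),
                                n, n_ch)
      ch_scale <- stats::runif(n_ch, 0.8, 1.2)
      od_w <- od[[w]] + noise + outer(artifact_series, ch_scale)
      i0 <- stats::runif(n_ch, scfg$i0_range[1], scfg$i0_range[2])
      intensity[[w]] <- sweep(exp(-od_w), 2, i0, "*")
    }
    rec <- nirs_recording(intensity, fs = fs, montage = montage,
                          subject_id = subject_id, cohort = cohort)
    list(recording = rec, schedule = shifted,
         truth = list(thb_amplitude = thb_amplitude,
                      ohb_amplitude = a_ohb, dhb_ratio = scfg$dhb_ratio,
                      best_channel = best_channel, gains = gains,
                      artifacts = artifacts))
  })
}

#' Cohort link parameters: amplitude-trait coupling and AQ marginals
#'
#' The planted total-hemoglobin amplitude of subject i is
#' `A_i = cohort_scale * a_base - b * AQ_i + eps`, `eps ~ N(0, sd)`,
#' truncated to stay positive. Defaults plant no coupling and a unit scale
#' for adults, and a negative coupling with a larger response scale for
#' children (the developmental amplitude increase). AQ totals are drawn from
#' a truncated normal matching the cohort's published mean/SD/range.
#'
#' @param cohort `"adult"` or `"child"`.
#' @return A list of link parameters: `a_base`, `cohort_scale`, `b`, `sd`,
#'   `aq_mean`, `aq_sd`, `aq_range`, `subscale_max`.
#' @export
link_params <- function(cohort = c("adult", "child")) {
  cohort <- match.arg(cohort)
  if (cohort == "adult") {
    list(a_base = 1.6e-6, cohort_scale = 1.0, b = 0, sd = 0.3e-6,
         aq_mean = 15.1, aq_sd = 6.5, aq_range = c(0, 50), subscale_max = 10)
  } else {
    list(a_base = 1.6e-6, cohort_scale = 2.5, b = 0.05e-6, sd = 0.3e-6,
         aq_mean = 32.1, aq_sd = 10.7, aq_range = c(0, 150),
         subscale_max = 30)
  }
}

# Truncated-normal draws by rejection; errors out if the marginals are
# infeasible (acceptance below ~1%).
rtruncnorm <- function(n, mean, sd, range) {
  if (sd > 2 * diff(range))
    stop("infeasible marginals: SD too large for range", call. = FALSE)
  out <- numeric(0)
  tries <- 0
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
    tries <- tries + 1
    if (tries > 200) stop("infeasible marginals", call. = FALSE)
  }
  out[seq_len(n)]
}

# Split an integer total into 5 subscale scores <= cap (Dirichlet-weighted
# multinomial, resampled until the cap holds).
split_subscales <- function(total, cap) {
  repeat {
    w <- stats::rgamma(5, shape = 2)
    s <- stats::rmultinom(1, total, w / sum(w))[, 1]
    if (all(s <= cap)) return(s)
  }
}

#' Simulate a cohort of recordings, events and AQ scores
#'
#' Draws AQ totals from the cohort's truncated-normal marginal, decomposes
#' them into the five subscales, plants per-subject total-hemoglobin
#' amplitudes through the (negative) amplitude-trait link, and simulates one
#' recording per subject and condition with per-subject pseudo-random trial
#' schedules. All randomness flows from `seed` via derived per-subject
#' streams.
#'
#' @param n number of subjects (>= 3).
#' @param cohort `"adult"` or `"child"`.
#' @param link a [link_params()] list.
#' @param seed integer master seed.
#' @param montage a [probe_montage()].
#' @param scfg a [sim_config()].
#' @param n_stim,n_mock,on_s,off_s schedule parameters (defaults: the
#'   20 + 20 trial, 5 s on / 10 s off protocol).
#' @param conditions names of stimulation conditions; each gets its own
#'   recording per subject with the same planted amplitude.
#' @return List with `subjects` (list of per-subject lists: `recordings` and
#'   `schedules` by condition, plus ids), `aq` (AQ score tibble), `truth`
#'   (tibble of planted amplitudes, AQ, best channel), and `montage`.
#' @export
simulate_cohort <- function(n, cohort = c("adult", "child"),
                            link = link_params(cohort), seed = 1,
                            montage = default_montage(cohort),
                            scfg = sim_config(),
                            n_stim = 20, n_mock = 20, on_s = 5, off_s = 10,
                            conditions = "C1") {
  cohort <- match.arg(cohort)
  if (n < 3) stop("cohort needs n >= 3", call. = FALSE)
  seeds <- derive_seeds(seed, 2L * n * length(conditions) + 1L)
  draws <- with_seed(seeds[1], {
    aq <- round(rtruncnorm(n, link$aq_mean, link$aq_sd, link$aq_range))
    amp <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        a <- link$cohort_scale * link$a_base - link$b * aq[i] +
          stats::rnorm(1, 0, link$sd)
        if (a > 0.05 * link$a_base) break
      }
      amp[i] <- a
    }
    best <- sample.int(nrow(montage$channels), n, replace = TRUE)
    subs <- t(vapply(aq, split_subscales, integer(5),
                     cap = link$subscale_max))
    list(aq = aq, amp = amp, best = best, subs = subs)
  })
  ids <- sprintf("%s%02d", if (cohort == "adult") "A" else "B", seq_len(n))
  aq_tab <- tibble::tibble(subject_id = ids, version = cohort,
                           AQ = as.integer(draws$aq),
                           AQ_S = draws$subs[, 1], AQ_C = draws$subs[, 2],
                           AQ_A = draws$subs[, 3], AQ_D = draws$subs[, 4],
                           AQ_I = draws$subs[, 5])
  subjects <- vector("list", n)
  si <- 1L
  for (i in seq_len(n)) {
    recs <- list(); scheds <- list()
    for (cond in conditions) {
      sch <- build_block_schedule(n_stim, n_mock, on_s, off_s,
                                  seed = seeds[1L + si])
      sim <- simulate_subject(draws$amp[i], sch, montage,
                              best_channel = draws$best[i], scfg = scfg,
                              seed = seeds[1L + n * length(conditions) + si],
                              subject_id = ids[i], cohort = cohort)
      recs[[cond]] <- sim$recording
      scheds[[cond]] <- sim$schedule
      si <- si + 1L
    }
    subjects[[i]] <- list(subject_id = ids[i], recordings = recs,
                          schedules = scheds)
  }
  truth <- tibble::tibble(subject_id = ids, aq = as.integer(draws$aq),
                          thb_amplitude = draws$amp,
                          best_channel = draws$best)
  list(subjects = subjects, aq = aq_tab, truth = truth, montage = montage,
       cohort = cohort, conditions = conditions)
}

#' Write a simulated cohort to disk in the package formats
#'
#' Recordings in the plain-text dialect, per-subject events TSVs, the AQ
#' table as CSV, the montage as JSON and the ground truth as JSON.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (subj in sim$subjects) {
    for (cond in names(subj$recordings)) {
      base <- file.path(dir, paste0(subj$subject_id, "_", cond))
      write_recording(subj$recordings[[cond]], paste0(base, ".tsv"))
      write_events(subj$schedules[[cond]], paste0(base, "_events.tsv"))
    }
  }
  write_aq_table(sim$aq, file.path(dir, "aq_scores.csv"))
  write_montage(sim$montage, file.path(dir, "montage.json"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
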