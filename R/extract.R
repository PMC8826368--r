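#' Block-average hemoglobin epochs by condition
#'
#' Epochs every trial over `trange_s` (default -2 to 20 s around onset),
#' subtracts the per-trial baseline (mean over \[-2, 0)) and averages trials
#' per condition and channel. Trials whose window intersects residual
#' artifacts (second detection pass) are dropped for the affected channel.
#'
#' @param hb an `hb_series` from [mbll()] / [preprocess_recording()].
#' @param schedule a [trial_schedule()].
#' @param residual_mask optional logical `samples x channels` mask of
#'   uncorrected artifacts.
#' @param cfg a [pipeline_config()].
#' @return An object of class `block_average`: `time_s`, per-condition lists
#'   of `time x channels` matrices for `ohb`, `dhb`, `thb`, and
#'   `n_trials_used` (condition x channel matrix).
#' @export
block_average <- function(hb, schedule, residual_mask = NULL,
                          cfg = pipeline_config()) {
  stopifnot(inherits(hb, "hb_series"), inherits(schedule, "trial_schedule"))
  fs <- hb$fs
  n <- nrow(hb$thb); n_ch <- ncol(hb$thb)
  offs <- round(cfg$trange_s[1] * fs):round(cfg$trange_s[2] * fs)
  time_s <- offs / fs
  base <- which(time_s < 0)
  onset_idx <- round(schedule$trials$onset_s * fs) + 1L
  if (any(onset_idx + offs[1] < 1) || any(onset_idx + offs[length(offs)] > n))
    stop("a trial's averaging window lies outside the recording",
         call. = FALSE)
  conds <- unique(schedule$trials$condition)
  if (is.null(residual_mask)) residual_mask <- matrix(FALSE, n, n_ch)

  out <- list()
  n_used <- matrix(0L, length(conds), n_ch,
                   dimnames = list(conds, NULL))
  n_off <- length(offs)
  for (cond in conds) {
    onsets <- onset_idx[schedule$trials$condition == cond]
    n_tr <- length(onsets)
    rows <- outer(offs, onsets, "+")            # n_off x n_tr sample indices
    # per-channel trial weights: drop trials whose window hits residual flags
    W <- matrix(1, n_tr, n_ch)
    hits <- array(residual_mask[as.vector(rows), , drop = FALSE],
                  c(n_off, n_tr, n_ch))
    W[colSums(hits) > 0] <- 0
    cnt <- as.integer(colSums(W))
    if (all(cnt == 0))
      stop("no usable trials for condition ", cond, call. = FALSE)
    w_exp <- array(rep(W, each = n_off), c(n_off, n_tr, n_ch))
    acc <- list()
    for (chrom in c("ohb", "dhb", "thb")) {
      ep <- array(hb[[chrom]][as.vector(rows), , drop = FALSE],
                  c(n_off, n_tr, n_ch))
      bl <- colMeans(ep[base, , , drop = FALSE])  # n_tr x n_ch baselines
      ep <- ep - array(rep(bl, each = n_off), c(n_off, n_tr, n_ch))
      summed <- colSums(aperm(ep * w_exp, c(2, 1, 3)))
      acc[[chrom]] <- sweep(summed, 2, pmax(cnt, 1L), "/")
    }
    out[[cond]] <- acc
    n_used[cond, ] <- cnt
  }
  structure(list(time_s = time_s, cond = out, n_trials_used = n_used,
                 fs = fs, blank_subtracted = FALSE),
            class = "block_average")
}

#' Peak amplitude and latency of a block-averaged response
#'
#' The peak is the maximal post-onset value for total and oxy-hemoglobin and
#' the minimal value for deoxy-hemoglobin; latency is the time of that
#' extremum relative to onset. The search window is (0, 20\] s; ties are
#' broken by the earliest time.
#'
#' @param block a [block_average()] (or the output of [blank_subtract()]).
#' @param chromophore `"thb"`, `"ohb"` or `"dhb"`.
#' @param condition which condition's average to use (default `"S"`; for
#'   blank-subtracted blocks the single stored course is used).
#' @return A tibble with one row per channel: `channel`, `amplitude`,
#'   `latency_s`.
#' @export
extract_peak <- function(block, chromophore = c("thb", "ohb", "dhb"),
                         condition = "S") {
  chromophore <- match.arg(chromophore)
  stopifnot(inherits(block, "block_average"))
  traces <- block$cond[[condition]][[chromophore]]
  if (is.null(traces)) stop("condition not present in block", call. = FALSE)
  post <- which(block$time_s > 0)
  if (!length(post) || all(is.na(traces[post, ])))
    stop("no post-onset data to extract a peak from", call. = FALSE)
  y <- traces[post, , drop = FALSE]
  pick <- if (chromophore == "dhb") apply(y, 2, which.min)
          else apply(y, 2, which.max)
  tibble::tibble(
    channel = seq_len(ncol(y)),
    amplitude = y[cbind(pick, seq_len(ncol(y)))],
    latency_s = block$time_s[post][pick])
}

#' Subtract the blank-evoked response from the stimulus response
#'
#' Normalizes the stimulus condition against the mock condition. In
#' `"timecourse"` mode (default) the blank average is subtracted sample-wise
#' from the stimulus average and peaks are extracted afterwards; in `"peak"`
#' mode peaks are extracted per condition and subtracted.
#'
#' @param block a [block_average()] containing both `S` and `B`.
#' @param cfg a [pipeline_config()] (supplies `blank_mode`).
#' @return In timecourse mode, a `block_average` with a single condition
#'   `"S"` holding the difference courses and `blank_subtracted = TRUE`; in
#'   peak mode, a tibble of per-channel, per-chromophore subtracted peaks.
#' @export
blank_subtract <- function(block, cfg = pipeline_config()) {
  stopifnot(inherits(block, "block_average"))
  if (is.null(block$cond$S) || is.null(block$cond$B))
    stop("blank subtraction needs both S and B conditions", call. = FALSE)
  if (ncol(block$cond$S$thb) != ncol(block$cond$B$thb))
    stop("S and B block averages come from different channel sets",
         call. = FALSE)
  if (cfg$blank_mode == "timecourse") {
    diffc <- lapply(c(ohb = "ohb", dhb = "dhb", thb = "thb"), function(ch)
      block$cond$S[[ch]] - block$cond$B[[ch]])
    structure(list(time_s = block$time_s, cond = list(S = diffc),
                   n_trials_used = block$n_trials_used, fs = block$fs,
                   blank_subtracted = TRUE),
              class = "block_average")
  } else {
    do.call(rbind, lapply(c("thb", "ohb", "dhb"), function(ch) {
      s <- extract_peak(block, ch, "S")
      b <- extract_peak(block, ch, "B")
      tibble::tibble(channel = s$channel, chrom = ch,
                     amplitude = s$amplitude - b$amplitude,
                     latency_s = s$latency_s)
    }))
  }
}

#' Select the analysis channel
#'
#' The channel with the highest blank-subtracted total-hemoglobin response
#' amplitude; ties are broken by the lowest channel index.
#'
#' @param amplitudes numeric vector of per-channel THb amplitudes.
#' @param keep optional logical mask of admissible (unpruned) channels.
#' @return The selected channel index.
#' @export
select_best_channel <- function(amplitudes, keep = NULL) {
  if (!is.null(keep)) amplitudes[!keep] <- -Inf
  if (!length(amplitudes) || all(!is.finite(amplitudes)))
    stop("no admissible channels to select from", call. = FALSE)
  which.max(amplitudes)  # which.max already takes the first (lowest) index
}

#' Per-subject response metrics from a preprocessed recording
#'
#' Block-averages by condition, subtracts the blank response, selects the
#' best channel on blank-subtracted THb amplitude, and returns peak
#' amplitude/latency for all three chromophores on that channel. Latency is
#' reported both after blank subtraction (`latency_s`) and from the raw
#' stimulus average (`latency_raw_s`).
#'
#' @param pp output of [preprocess_recording()].
#' @param schedule the recording's [trial_schedule()].
#' @param cfg a [pipeline_config()].
#' @param subject_id carried into the output.
#' @return A tibble with one row per chromophore: `subject_id`, `channel`,
#'   `chrom`, `amplitude`, `latency_s`, `latency_raw_s`, `condition`,
#'   `n_trials`, `blank_subtracted`.
#' @export
extract_metrics <- function(pp, schedule, cfg = pipeline_config(),
                            subject_id = "S01") {
  block <- block_average(pp$hb, schedule, pp$residual_mask, cfg)
  bs <- blank_subtract(block, cfg)
  if (cfg$blank_mode == "peak")
    stop("extract_metrics requires blank_mode = 'timecourse'", call. = FALSE)
  thb_amp <- extract_peak(bs, "thb")$amplitude
  best <- select_best_channel(thb_amp, keep = pp$keep)
  rows <- lapply(c("thb", "ohb", "dhb"), function(ch) {
    pk <- extract_peak(bs, ch)[best, ]
    raw_s <- extract_peak(block, ch, "S")[best, ]
    raw_b <- extract_peak(block, ch, "B")[best, ]
    tibble::tibble(subject_id = subject_id, channel = best, chrom = ch,
                   amplitude = pk$amplitude, latency_s = pk$latency_s,
                   latency_raw_s = raw_s$latency_s,
                   amplitude_s_raw = raw_s$amplitude,
                   amplitude_b_raw = raw_b$amplitude, condition = "S-B",
                   n_trials = min(block$n_trials_used[, best]),
                   blank_subtracted = TRUE)
  })
  dplyr::bind_rows(rows)
}
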