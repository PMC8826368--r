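# Shared helpers for building small synthetic inputs in tests.

fs_default <- 10.2

# Wrap a vector (or matrix) as an optical_density object on a tiny montage.
make_od <- function(x, n_ch = NULL, fs = fs_default, cohort = "adult") {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (is.null(n_ch)) n_ch <- ncol(x)
  m <- default_montage(cohort, n_channels = n_ch)
  structure(list(od = list(`760` = x, `850` = x), fs = fs, montage = m,
                 steps = "test"),
            class = "optical_density")
}

# A small clean recording: constant intensity with a touch of noise.
make_recording <- function(n = 200, n_ch = 2, seed = 1, cohort = "adult") {
  m <- default_montage(cohort, n_channels = n_ch)
  withr_seed <- function(expr) {
    set.seed(seed); expr
  }
  I <- withr_seed(lapply(1:2, function(i)
    matrix(0.05 * exp(stats::rnorm(n * n_ch, 0, 0.01)), n, n_ch)))
  names(I) <- c("760", "850")
  nirs_recording(I, fs = fs_default, montage = m, cohort = cohort)
}

# Peristimulus time grid matching the default averaging window.
trange_time <- function(cfg = pipeline_config(), fs = fs_default) {
  offs <- round(cfg$trange_s[1] * fs):round(cfg$trange_s[2] * fs)
  offs / fs
}
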