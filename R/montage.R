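#' Probe montage (sources, detectors, channels)
#'
#' Describes the optode array: source and detector positions (cm, flattened
#' scalp plane), the source-detector pairs forming channels, and the
#' per-channel separations used by the modified Beer-Lambert conversion and
#' by channel pruning. The default montage has 22 channels; separations must
#' lie in 20-44 mm for the adult cap and 22-30 mm for the child cap.
#'
#' @param channels data frame with columns `channel`, `source`, `detector`.
#' @param source_pos,detector_pos matrices of optode positions (cm), one row
#'   per optode, columns x/y; row names are 10-20-style labels.
#' @param cohort `"adult"` or `"child"`.
#' @return An object of class `probe_montage` with a `separation_mm` field.
#' @export
probe_montage <- function(channels, source_pos, detector_pos, cohort) {
  cohort <- match.arg(cohort, c("adult", "child"))
  stopifnot(is.data.frame(channels),
            all(c("channel", "source", "detector") %in% names(channels)))
  d <- source_pos[channels$source, , drop = FALSE] -
    detector_pos[channels$detector, , drop = FALSE]
  sep_mm <- 10 * sqrt(rowSums(d^2))
  rng <- if (cohort == "adult") c(20, 44) else c(22, 30)
  if (any(sep_mm < rng[1] - 1e-6) || any(sep_mm > rng[2] + 1e-6))
    stop(sprintf("%s montage separations must lie in [%g, %g] mm",
                 cohort, rng[1], rng[2]), call. = FALSE)
  structure(
    list(channels = tibble::as_tibble(channels),
         source_pos = source_pos, detector_pos = detector_pos,
         separation_mm = as.numeric(sep_mm), cohort = cohort),
    class = "probe_montage")
}

#' Default 22-channel occipital montage
#'
#' A synthetic two-row occipital layout standing in for the study's
#' 8-source / 7-detector array: sources on a parietal row, detectors on an
#' occipital row, 14 short and 8 long source-detector pairs (22 channels).
#' Child positions are the adult layout scaled by 0.70, keeping separations
#' within the cap-specific ranges (adult 20-44 mm, child 22-30 mm). Optode
#' labels follow 10-20 naming but the coordinates are synthetic.
#'
#' @param cohort `"adult"` or `"child"`.
#' @param n_channels optionally keep only the first `n_channels` channels
#'   (used to run reduced problem sizes; default all 22).
#' @return A [probe_montage()].
#' @export
default_montage <- function(cohort = c("adult", "child"), n_channels = 22) {
  cohort <- match.arg(cohort)
  scale <- if (cohort == "adult") 1 else 0.70
  sx <- seq(-7, 7, by = 2)                      # 8 sources, y = 0
  dx <- seq(-6, 6, by = 2)                      # 7 detectors, y = 3
  source_pos <- cbind(x = sx, y = rep(0, 8)) * scale
  detector_pos <- cbind(x = dx, y = rep(3, 7)) * scale
  rownames(source_pos) <- c("P7", "P5", "P3", "P1", "P2", "P4", "P6", "P8")
  rownames(detector_pos) <- c("PO7", "PO3", "POz", "PO4", "PO8", "O1", "O2")
  short <- do.call(rbind, lapply(1:7, function(j) {
    rbind(c(j, j), c(j + 1, j))                 # each detector with 2 sources
  }))
  long <- rbind(cbind(1:6, 2:7), c(1, 2), c(8, 6))
  pairs <- rbind(short, long)
  channels <- data.frame(channel = seq_len(nrow(pairs)),
                         source = pairs[, 1], detector = pairs[, 2])
  if (n_channels < 1 || n_channels > nrow(channels))
    stop("n_channels must be between 1 and 22", call. = FALSE)
  channels <- channels[seq_len(n_channels), , drop = FALSE]
  probe_montage(channels, source_pos, detector_pos, cohort)
}

#' Write / read a montage as JSON
#'
#' @param montage a [probe_montage()].
#' @param path JSON file path.
#' @return `write_montage` returns `path` invisibly; `read_montage` returns a
#'   [probe_montage()].
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "probe_montage"))
  obj <- list(
    cohort = montage$cohort,
    sources = data.frame(label = rownames(montage$source_pos),
                         x_cm = montage$source_pos[, 1],
                         y_cm = montage$source_pos[, 2]),
    detectors = data.frame(label = rownames(montage$detector_pos),
                           x_cm = montage$detector_pos[, 1],
                           y_cm = montage$detector_pos[, 2]),
    channels = as.data.frame(montage$channels))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- cbind(x = obj$sources$x_cm, y = obj$sources$y_cm)
  rownames(sp) <- obj$sources$label
  dp <- cbind(x = obj$detectors$x_cm, y = obj$detectors$y_cm)
  rownames(dp) <- obj$detectors$label
  probe_montage(obj$channels, sp, dp, obj$cohort)
}
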