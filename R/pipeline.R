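#' Validate and normalize a study configuration
#'
#' Fills every omitted field with the study defaults (the printed processing
#' parameters: 0.01-0.50 Hz band, -2 to 20 s averaging window, 20 + 20 trial
#' 5 s / 10 s schedule, and so on), rejects unknown keys with their key path,
#' and checks cross-field consistency (band edges against the Nyquist
#' frequency). Normalization is idempotent.
#'
#' @param config named list; recognized top-level keys are `seed`, `fs`,
#'   `cohorts`, `n_subjects`, `conditions`, `n_stim`, `n_mock`, `on_s`,
#'   `off_s`, `noise`, `input_dir`, `out_dir`, and `pipeline` (a named list
#'   of [pipeline_config()] arguments).
#' @return A normalized list of class `study_config`.
#' @export
validate_config <- function(config = list()) {
  if (inherits(config, "study_config")) config <- unclass(config)
  defaults <- list(seed = 1L, fs = 10.2, cohorts = "child",
                   n_subjects = 19L, conditions = "C1",
                   n_stim = 20L, n_mock = 20L, on_s = 5, off_s = 10,
                   noise = "default", input_dir = NULL, out_dir = NULL,
                   pipeline = list())
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  pc_args <- cfg$pipeline
  known_pc <- names(formals(pipeline_config))
  bad <- setdiff(names(pc_args), known_pc)
  if (length(bad))
    stop("unknown configuration key(s): ",
         paste0("pipeline.", bad, collapse = ", "), call. = FALSE)
  pc <- do.call(pipeline_config, pc_args)
  if (pc$lpf_hz >= cfg$fs / 2)
    stop("pipeline.lpf_hz must be below the Nyquist frequency fs/2",
         call. = FALSE)
  if (!all(cfg$cohorts %in% c("adult", "child")))
    stop("cohorts must be 'adult' and/or 'child'", call. = FALSE)
  if (cfg$n_subjects < 3) stop("n_subjects must be >= 3", call. = FALSE)
  cfg$pipeline <- pc_args  # keep user args; full config built at run time
  structure(cfg, class = "study_config")
}

#' Analyze a set of recordings into per-subject response metrics
#'
#' Runs the preprocessing stream and metric extraction over every subject
#' and condition of a simulated (or loaded) cohort.
#'
#' @param sim output of [simulate_cohort()] (or the same structure built from
#'   files).
#' @param cfg a [pipeline_config()].
#' @return List with `metrics` (tibble over subject x condition x
#'   chromophore) and `grand` (per-condition grand-average blank-subtracted
#'   best-channel time courses).
#' @export
analyze_cohort <- function(sim, cfg = pipeline_config()) {
  rows <- list()
  grand <- list()
  for (subj in sim$subjects) {
    for (cond in names(subj$recordings)) {
      pp <- preprocess_recording(subj$recordings[[cond]], cfg)
      met <- extract_metrics(pp, subj$schedules[[cond]], cfg,
                             subject_id = subj$subject_id)
      met$condition_name <- cond
      met$cohort <- sim$cohort
      rows[[length(rows) + 1]] <- met
      block <- block_average(pp$hb, subj$schedules[[cond]],
                             pp$residual_mask, cfg)
      bs <- blank_subtract(block, cfg)
      best <- met$channel[1]
      tc <- cbind(thb = bs$cond$S$thb[, best], ohb = bs$cond$S$ohb[, best],
                  dhb = bs$cond$S$dhb[, best])
      grand[[cond]] <- if (is.null(grand[[cond]])) list(sum = tc, n = 1L,
                                                        time_s = bs$time_s)
      else list(sum = grand[[cond]]$sum + tc, n = grand[[cond]]$n + 1L,
                time_s = bs$time_s)
    }
  }
  grand <- lapply(grand, function(g)
    list(time_s = g$time_s, mean = g$sum / g$n, n = g$n))
  list(metrics = dplyr::bind_rows(rows), grand = grand)
}

#' Grand-average response plot
#'
#' @param grand one element of `analyze_cohort()$grand`.
#' @param title plot title.
#' @return A ggplot object: THb (green), OHb (red), DHb (blue) versus
#'   peristimulus time.
#' @export
plot_block_average <- function(grand, title = "Grand-average response") {
  df <- tibble::tibble(
    time_s = rep(grand$time_s, 3),
    chrom = rep(c("THb", "OHb", "DHb"), each = length(grand$time_s)),
    value = c(grand$mean[, "thb"], grand$mean[, "ohb"], grand$mean[, "dhb"]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                   colour = .data$chrom)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(THb = "#2ca02c", OHb = "#d62728",
                                            DHb = "#1f77b4")) +
    ggplot2::labs(x = "time from onset (s)",
                  y = "concentration change (M)",
                  colour = NULL, title = title) +
    ggplot2::theme_minimal()
}

# Group statistics over a metrics table + AQ scores: S-vs-B paired t per
# chromophore/condition, RM-ANOVA across conditions, adult-vs-child
# comparison, Spearman/BH trait correlations.
study_statistics <- function(metrics, aq_tables) {
  stats_rows <- list()
  add <- function(df, family, cohort, detail) {
    df$family <- family; df$cohort <- cohort; df$detail <- detail
    stats_rows[[length(stats_rows) + 1]] <<- df
  }
  for (coh in unique(metrics$cohort)) {
    m <- metrics[metrics$cohort == coh, ]
    for (cond in unique(m$condition_name)) {
      mc <- m[m$condition_name == cond, ]
      for (ch in unique(mc$chrom)) {
        sub <- mc[mc$chrom == ch, ]
        add(paired_t(sub$amplitude_s_raw, sub$amplitude_b_raw),
            "stim_vs_blank", coh, paste(cond, ch))
      }
    }
    conds <- unique(m$condition_name)
    if (length(conds) >= 2) {
      for (ch in unique(m$chrom)) {
        sub <- m[m$chrom == ch, ]
        add(rm_anova(data.frame(subject = sub$subject_id,
                                condition = sub$condition_name,
                                value = sub$amplitude)),
            "condition_anova", coh, ch)
      }
    }
    # trait correlations: family = chromophores x (AQ + subscales) x conds
    aq <- aq_tables[[coh]]
    if (!is.null(aq)) {
      fam <- list()
      for (cond in conds) {
        mc <- m[m$condition_name == cond, ]
        wide <- stats::reshape(
          as.data.frame(mc[, c("subject_id", "chrom", "amplitude")]),
          idvar = "subject_id", timevar = "chrom", direction = "wide")
        names(wide) <- sub("^amplitude\\.", "", names(wide))
        merged <- merge(wide, aq, by = "subject_id")
        sp <- spearman_bh(
          stats::setNames(merged[, c("thb", "ohb", "dhb")],
                          paste0(cond, ".", c("thb", "ohb", "dhb"))),
          merged[, c("AQ", "AQ_S", "AQ_C", "AQ_A", "AQ_D", "AQ_I")])
        fam[[cond]] <- sp[, c("metric", "trait", "n", "rho", "p_value")]
      }
      fam <- dplyr::bind_rows(fam)
      fam$adj_p <- stats::p.adjust(fam$p_value, method = "BH")
      fam$test <- "spearman"
      add(dplyr::rename(fam, statistic = "rho"), "aq_correlation", coh,
          paste(fam$metric, fam$trait))
    }
  }
  if (length(unique(metrics$cohort)) == 2) {
    for (ch in unique(metrics$chrom)) {
      a <- metrics$amplitude[metrics$cohort == "adult" &
                               metrics$chrom == ch]
      b <- metrics$amplitude[metrics$cohort == "child" &
                               metrics$chrom == ch]
      tt <- stats::t.test(b, a)
      add(tibble::tibble(test = "welch_t", statistic = unname(tt$statistic),
                         df = unname(tt$parameter), p_value = tt$p.value,
                         mean_child = mean(b), mean_adult = mean(a)),
          "cohort_comparison", "both", ch)
    }
  }
  dplyr::bind_rows(stats_rows)
}

#' Run a complete simulated study end to end
#'
#' Simulates (or loads) the configured cohorts, runs the preprocessing
#' stream and response extraction for every subject and condition, computes
#' the four statistical families (stimulus vs blank, condition comparison,
#' cohort comparison when two cohorts are configured, AQ correlations with
#' BH correction), and returns a results bundle with a reproducibility
#' manifest. With `out_dir` set, the metrics and statistics are written as
#' CSV, grand-average plots as PNG, and the manifest as JSON.
#'
#' @param config a [validate_config()] input or result.
#' @return List with `metrics`, `stats`, `grand`, `aq`, `truth`, `manifest`.
#' @export
run_study <- function(config = list()) {
  cfg <- validate_config(config)
  pc <- do.call(pipeline_config, cfg$pipeline)
  seeds <- derive_seeds(cfg$seed, length(cfg$cohorts))
  metrics <- list(); grand <- list(); aq_tables <- list()
  truth <- list()
  for (i in seq_along(cfg$cohorts)) {
    coh <- cfg$cohorts[i]
    sim <- simulate_cohort(
      cfg$n_subjects, coh, seed = seeds[i],
      scfg = sim_config(noise = noise_preset(cfg$noise)),
      n_stim = cfg$n_stim, n_mock = cfg$n_mock, on_s = cfg$on_s,
      off_s = cfg$off_s, conditions = cfg$conditions)
    an <- analyze_cohort(sim, pc)
    metrics[[coh]] <- an$metrics
    grand[[coh]] <- an$grand
    aq_tables[[coh]] <- sim$aq
    tr <- sim$truth; tr$cohort <- coh
    truth[[coh]] <- tr
  }
  metrics <- dplyr::bind_rows(metrics)
  stats_tab <- study_statistics(metrics, aq_tables)
  manifest <- list(
    package = "visnirs",
    version = as.character(utils::packageVersion("visnirs")),
    seed = cfg$seed, cohort_seeds = seeds,
    config = unclass(cfg)[setdiff(names(cfg), c("input_dir", "out_dir"))],
    counts = list(
      subjects_analyzed = length(unique(metrics$subject_id)),
      cohorts = cfg$cohorts,
      conditions = cfg$conditions,
      metric_rows = nrow(metrics)))
  bundle <- list(metrics = metrics, stats = stats_tab, grand = grand,
                 aq = dplyr::bind_rows(aq_tables), truth =
                   dplyr::bind_rows(truth), manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_tab, file.path(cfg$out_dir, "stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    for (coh in names(grand)) {
      for (cond in names(grand[[coh]])) {
        p <- plot_block_average(grand[[coh]][[cond]],
                                sprintf("%s / %s", coh, cond))
        ggplot2::ggsave(
          file.path(cfg$out_dir, sprintf("grand_%s_%s.png", coh, cond)),
          p, width = 6, height = 4, dpi = 120)
      }
    }
  }
  bundle
}
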