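#' End-to-end analysis configuration
#'
#' @param cohort a [cohort_spec()] (or a list of recordings plus subject
#'   table supplied directly to the run functions).
#' @param preprocess a [preprocess_config()], or `NULL` to skip
#'   preprocessing (e.g. for artifact-free simulations).
#' @param welch a [welch_config()].
#' @param bands a [band_scheme()].
#' @param n_permutations permutation count for group tests.
#' @param level FDR level.
#' @param seed seed for the permutation schedule.
#' @param fdr_family `"joint"` or `"per_feature"`.
#' @export
analysis_config <- function(cohort = cohort_spec(),
                            preprocess = preprocess_config(),
                            welch = welch_config(),
                            bands = band_scheme(),
                            n_permutations = 10000, level = 0.05,
                            seed = 1L,
                            fdr_family = "joint") {
  structure(list(cohort = cohort, preprocess = preprocess, welch = welch,
                 bands = bands, n_permutations = n_permutations,
                 level = level, seed = as.integer(seed),
                 fdr_family = fdr_family),
            class = "analysis_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(errorCondition(sprintf("stage '%s' failed: %s", name,
                                conditionMessage(e)),
                        class = c("megalpha_stage_error",
                                  class(e)[1], "error"))))
}

#' Per-subject feature extraction
#'
#' Preprocess (optional), estimate the Welch PSD over the good segments,
#' and extract the seven spectral features.
#'
#' @param rec a [meg_recording()] or [region_timeseries()].
#' @param preprocess_cfg a [preprocess_config()] or `NULL`.
#' @param welch_cfg a [welch_config()].
#' @param scheme a [band_scheme()].
#' @return list: `features` (`spectral_features`), `psd_mean`
#'   (signal-average PSD vector), `freqs`, `log`.
#' @export
subject_features <- function(rec, preprocess_cfg = NULL,
                             welch_cfg = welch_config(),
                             scheme = band_scheme()) {
  log <- NULL
  if (!is.null(preprocess_cfg) && inherits(rec, "meg_recording")) {
    pp <- preprocess(rec, preprocess_cfg)
    segments <- pp$segments
    log <- pp$log
  } else segments <- list(rec)
  psd <- welch_psd(segments, welch_cfg)
  list(features = extract_features(psd, scheme),
       psd_mean = colMeans(psd$power), freqs = psd$freqs, log = log)
}

group_mean_table <- function(subject_avg) {
  stats_for <- function(v) c(mean = mean(v, na.rm = TRUE),
                             sd = stats::sd(v, na.rm = TRUE))
  out <- do.call(rbind, lapply(split(subject_avg, subject_avg$group),
    function(df) {
      vals <- lapply(feature_names(), function(fn) stats_for(df[[fn]]))
      data.frame(group = df$group[1],
                 feature = feature_names(),
                 mean = vapply(vals, `[[`, 0, "mean"),
                 sd = vapply(vals, `[[`, 0, "sd"))
    }))
  rownames(out) <- NULL
  out
}

# whole-head average PSD per group: mean and standard error over subjects
psd_summary_table <- function(freqs, psd_rows, groups) {
  do.call(rbind, lapply(unique(groups), function(g) {
    m <- psd_rows[groups == g, , drop = FALSE]
    data.frame(group = g, freq = freqs,
               mean = colMeans(m),
               se = apply(m, 2, stats::sd) / sqrt(nrow(m)))
  }))
}

#' Sensor-level group analysis
#'
#' Simulates (or accepts) a cohort, preprocesses every recording, extracts
#' the seven spectral features per sensor, tests group differences with
#' permutation t tests (shared schedule) under FDR correction, tests the
#' whole-head (sensor-average) alpha power ratio, and correlates the
#' sensor-average ratio with the pain/depression covariates within the
#' patient group.
#'
#' @param cfg an [analysis_config()].
#' @param recordings,subjects optionally, precomputed recordings and an
#'   aligned subject table (bypasses simulation).
#' @return An `analysis_report` list: `level`, `subject_avg`,
#'   `group_means`, `tests` (a `perm_test_result`), `avg_ratio_test`,
#'   `correlations`, `psd_summary`, `provenance`.
#' @export
run_sensor_analysis <- function(cfg = analysis_config(), recordings = NULL,
                                subjects = NULL) {
  if (is.null(recordings)) {
    sim <- run_stage("simulate", simulate_cohort(cfg$cohort))
    recordings <- sim$recordings
    subjects <- sim$subjects
  }
  per <- run_stage("features", lapply(recordings, subject_features,
                                      preprocess_cfg = cfg$preprocess,
                                      welch_cfg = cfg$welch,
                                      scheme = cfg$bands))
  fm <- run_stage("features", stack_features(
    lapply(per, `[[`, "features"), subjects,
    signal_meta = recordings[[1]]$channel_meta))
  tests <- run_stage("compare", group_compare(
    fm, n_perm = cfg$n_permutations, seed = cfg$seed, level = cfg$level,
    fdr_family = cfg$fdr_family))
  subject_avg <- run_stage("summarise", {
    avg <- t(vapply(per, function(p) sensor_average(p$features), numeric(7)))
    cbind(subjects, as.data.frame(avg))
  })
  is_pat <- subject_avg$group == "patient"
  avg_ratio_test <- run_stage("compare", permutation_ttest(
    subject_avg$alpha_power_ratio[is_pat],
    subject_avg$alpha_power_ratio[!is_pat],
    n_perm = cfg$n_permutations, seed = cfg$seed))
  correlations <- run_stage("correlate", {
    covs <- intersect(c("pain_vas_24h", "pain_vas_now", "depression_score"),
                      names(subject_avg))
    do.call(rbind, lapply(covs, function(cv) {
      ct <- pearson_correlation(subject_avg$alpha_power_ratio[is_pat],
                                subject_avg[[cv]][is_pat])
      data.frame(covariate = cv, r = ct$r, p = ct$p, n = ct$n)
    }))
  })
  psd_rows <- do.call(rbind, lapply(per, `[[`, "psd_mean"))
  structure(list(level = "sensor",
                 subject_avg = subject_avg,
                 group_means = group_mean_table(subject_avg),
                 tests = tests,
                 avg_ratio_test = avg_ratio_test,
                 correlations = correlations,
                 psd_summary = psd_summary_table(per[[1]]$freqs, psd_rows,
                                                 subjects$group),
                 provenance = report_provenance(cfg)),
            class = "analysis_report")
}

#' Region-level group analysis
#'
#' Simulates region time series per subject (slowed patient oscillators
#' confined to the configured hemisphere, or bilateral), applies the
#' region-retention rule, extracts features per kept region, runs the
#' permutation/FDR group comparison over regions x features, and computes
#' the alpha-power-ratio lateralization index for every homologous pair
#' and subject.
#'
#' @param cfg an [analysis_config()].
#' @param n_regions number of simulated regions.
#' @param lateralization `"bilateral"`, `"right"` or `"left"`: hemisphere
#'   carrying the patients' slowed oscillators.
#' @param region_list,subjects optionally, precomputed
#'   [region_timeseries()] per subject and an aligned subject table.
#' @return An `analysis_report` with `tests`, `li` (per pair x group mean
#'   LI), `subject_li`, `region_meta`, `provenance`.
#' @export
run_region_analysis <- function(cfg = analysis_config(), n_regions = 12,
                                lateralization = c("bilateral", "right", "left"),
                                region_list = NULL, subjects = NULL) {
  lateralization <- match.arg(lateralization)
  if (is.null(region_list)) {
    sim <- run_stage("simulate", {
      draws <- simulate_cohort(cfg$cohort, simulate = FALSE)
      meta <- default_region_meta(n_regions)
      lst <- lapply(seq_along(draws$specs), function(i) {
        spec <- draws$specs[[i]]
        spec$artifacts <- NULL  # region traces emulate cleaned source data
        spec$oscillators <- lapply(spec$oscillators, function(o) {
          o$topography <- rep(1, n_regions); o
        })
        if (spec$group == "patient" && lateralization != "bilateral") {
          # slowing confined to one hemisphere: slowed oscillators drive
          # the affected side, a normal-speed counterpart the other side
          hemi <- c(right = "R", left = "L")[lateralization]
          affected <- as.numeric(meta$hemisphere == hemi)
          spare <- as.numeric(meta$hemisphere != hemi)
          mirrored <- lapply(spec$oscillators, function(o) {
            m <- o
            m$center_freq <- cfg$cohort$control$peak_freq
            m$topography <- spare
            m
          })
          spec$oscillators <- c(lapply(spec$oscillators, function(o) {
            o$topography <- affected; o
          }), if (any(vapply(spec$oscillators, `[[`, 0, "amplitude") > 0))
            mirrored)
        }
        simulate_regions(spec, region_meta = meta,
                         duration = cfg$cohort$duration,
                         sampling_rate = cfg$cohort$sampling_rate)
      })
      list(region_list = lst, subjects = draws$subjects, meta = meta)
    })
    region_list <- sim$region_list
    subjects <- sim$subjects
  }
  meta_full <- region_list[[1]]$region_meta
  kept <- run_stage("features", filter_regions(meta_full))
  if (nrow(kept) < 2)
    stop_invalid("fewer than 2 regions retained by the >20-grid-point rule")
  keep_idx <- match(kept$name, meta_full$name)
  per <- run_stage("features", lapply(region_list, function(rts) {
    rts$data <- rts$data[keep_idx, , drop = FALSE]
    rts$region_meta <- kept
    subject_features(rts, NULL, cfg$welch, cfg$bands)
  }))
  fm <- run_stage("features", stack_features(
    lapply(per, `[[`, "features"), subjects, signal_meta = kept))
  tests <- run_stage("compare", group_compare(
    fm, n_perm = cfg$n_permutations, seed = cfg$seed, level = cfg$level,
    fdr_family = cfg$fdr_family))
  li <- run_stage("lateralize", {
    pairs <- unique(stats::na.omit(kept$pair))
    pairs <- pairs[vapply(pairs, function(pp)
      sum(kept$pair == pp, na.rm = TRUE) == 2, TRUE)]
    if (!length(pairs)) NULL else {
      rows <- do.call(rbind, lapply(seq_along(per), function(i) {
        ft <- per[[i]]$features
        ratio <- stats::setNames(ft$alpha_power_ratio, ft$signal_id)
        data.frame(subject_id = subjects$subject_id[i],
                   group = subjects$group[i], pair = pairs,
                   li = vapply(pairs, function(pp) {
                     nm <- kept$name[which(kept$pair == pp)]
                     lf <- nm[endsWith(nm, "_L")]; rt <- nm[endsWith(nm, "_R")]
                     lateralization_index(ratio[lf], ratio[rt])
                   }, numeric(1)))
      }))
      rownames(rows) <- NULL
      rows
    }
  })
  li_summary <- if (!is.null(li))
    stats::aggregate(li ~ pair + group, li, mean) else NULL
  structure(list(level = "region", tests = tests,
                 subject_li = li, li = li_summary,
                 region_meta = kept, subjects = subjects,
                 provenance = report_provenance(cfg)),
            class = "analysis_report")
}

report_provenance <- function(cfg) {
  list(master_seed = cfg$cohort$master_seed %||% NA,
       stats_seed = cfg$seed,
       n_permutations = cfg$n_permutations,
       level = cfg$level,
       fdr_family = cfg$fdr_family,
       package_version = as.character(utils::packageVersion("megalpha")),
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %s level\n", x$level))
  print(x$tests)
  if (!is.null(x$avg_ratio_test))
    cat(sprintf("  whole-head alpha power ratio: t = %.2f, p = %.4g\n",
                x$avg_ratio_test$t_obs, x$avg_ratio_test$p_perm))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' CSV tables (test results, group means, correlations, PSD summary,
#' lateralization indices, per-subject averages) plus a JSON provenance
#' block.
#'
#' @param report an `analysis_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm) if (!is.null(df))
    utils::write.csv(df, file.path(dir, nm), row.names = FALSE)
  wr(report$tests$table, "tests.csv")
  wr(report$group_means, "group_means.csv")
  wr(report$correlations, "correlations.csv")
  wr(report$psd_summary, "psd_summary.csv")
  wr(report$subject_avg, "subject_averages.csv")
  wr(report$li, "lateralization.csv")
  prov <- c(report$provenance,
            list(level = report$level,
                 n_rejected = sum(report$tests$table$rejected)))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
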