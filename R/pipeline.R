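#' Pipeline configuration
#'
#' Single source of parameters for an end-to-end run: every downstream module
#' reads its tunables from here, and the configuration is serialized next to
#' the outputs for provenance.
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"files"` (read
#'   insole files from `input_dir` plus `meta_file`).
#' @param hs_profile,pd_profile group [gait_profile()]s (simulate mode).
#' @param n_hs,n_pd cohort sizes (simulate mode).
#' @param duration,sampling_rate trial length (s) and rate (Hz, simulate mode).
#' @param input_dir directory of insole text files (files mode); every file
#'   matching `*.txt` is read, file name stem = subject id.
#' @param meta_file metadata CSV (files mode).
#' @param dialect an [insole_dialect()] (files mode).
#' @param contact_threshold,min_phase_duration see [detect_contact()].
#' @param outlier_rule apply the stride-duration outlier rejection.
#' @param quantile_type quantile convention for medians and IQRs.
#' @param alpha,m_tests significance level and Bonferroni factor.
#' @param seed master seed (simulate mode).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param keep_recordings keep the recordings in the returned object (memory
#'   heavy for large cohorts; default `FALSE`, subjects are processed one at
#'   a time and discarded).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "files"),
                            hs_profile = hs_gait_profile(),
                            pd_profile = pd_gait_profile(),
                            n_hs = 88, n_pd = 108,
                            duration = 60, sampling_rate = 100,
                            input_dir = NULL, meta_file = NULL,
                            dialect = insole_dialect(),
                            contact_threshold = NULL,
                            min_phase_duration = 0.05,
                            outlier_rule = TRUE, quantile_type = 7,
                            alpha = 0.05, m_tests = 50,
                            seed = 1L, out_dir = NULL,
                            keep_recordings = FALSE) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  if (mode == "files" && (is.null(input_dir) || is.null(meta_file)))
    gm_stop("files mode needs input_dir and meta_file", "gaitmark_validation_error")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest/simulation, gait-cycle segmentation, feature
#' extraction and the group comparison suite; optionally writes `cycles.csv`,
#' `features.csv`, `ttest_kinematic.csv`, `ttest_dynamic.csv`, `roc.csv`,
#' `average_cycle.csv` and `run_log.json` into `out_dir`. Deterministic given
#' the seed and inputs: report files are byte-identical across re-runs (the
#' run log carries the only timestamp).
#'
#' Subjects whose trial fails segmentation (no gait, no accepted cycles) are
#' excluded with a reason in the run log rather than aborting the cohort.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `features`, `cycles`,
#'   `comparison` (a `comparison_suite`), `meta`, `avg_cycle`, `log`,
#'   `config`, and `recordings` when `keep_recordings = TRUE`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$mode == "simulate") {
    groups <- c(rep("HS", config$n_hs), rep("PD", config$n_pd))
    ids <- c(sprintf("HS%03d", seq_len(config$n_hs)),
             sprintf("PD%03d", seq_len(config$n_pd)))
    get_subject <- function(i) {
      prof <- if (groups[i] == "HS") config$hs_profile else config$pd_profile
      sim <- simulate_subject(prof, config$duration, config$sampling_rate,
                              seed = subject_seed(config$seed, i),
                              subject_id = ids[i], group = groups[i])
      list(recording = sim$recording, meta = sim$meta)
    }
    n_subj <- length(ids)
    meta_all <- NULL
    input_hashes <- NULL
  } else {
    files <- sort(list.files(config$input_dir, pattern = "\\.txt$",
                             full.names = TRUE))
    if (length(files) == 0)
      gm_stop(paste0("no .txt recordings under ", config$input_dir),
              "gaitmark_io_error")
    meta_all <- read_metadata(config$meta_file)
    ids <- sub("\\.txt$", "", basename(files))
    get_subject <- function(i) {
      m <- meta_all[meta_all$subject_id == ids[i], , drop = FALSE]
      if (nrow(m) == 0)
        gm_stop(paste0("no metadata for subject ", ids[i]),
                "gaitmark_validation_error")
      list(recording = read_insole_file(files[i], config$dialect), meta = m)
    }
    n_subj <- length(files)
    input_hashes <- as.list(tools::md5sum(c(files, config$meta_file)))
  }

  features <- list(); cycles <- list(); metas <- list(); log_subj <- list()
  recordings <- if (config$keep_recordings) list() else NULL
  avg_acc <- list()
  for (i in seq_len(n_subj)) {
    id <- ids[i]
    entry <- tryCatch({
      s <- get_subject(i)
      cs <- segment_recording(s$recording, config$contact_threshold,
                              config$min_phase_duration, config$outlier_rule)
      feat <- subject_features(s$recording, cs, s$meta, config$quantile_type)
      seg <- attr(cs, "segmentation")
      cyc <- rbind(cbind(cs$accepted, accepted = TRUE,
                         reason = NA_character_),
                   if (nrow(cs$rejected))
                     cbind(cs$rejected[setdiff(names(cs$rejected), "reason")],
                           accepted = FALSE, reason = cs$rejected$reason))
      cyc <- cbind(subject_id = id, cyc)
      avg_acc[[id]] <- subject_average_cycle(s$recording, cs)
      if (config$keep_recordings) recordings[[id]] <- s$recording
      list(ok = TRUE, feat = feat, cyc = cyc, meta = s$meta,
           log = list(subject_id = id, n_cycles = cs$n_total,
                      n_rejected_outlier = nrow(cs$rejected),
                      n_invalid = sum(!seg$valid),
                      invalid_reasons = unique(stats::na.omit(seg$reason))))
    }, gaitmark_error = function(e)
      list(ok = FALSE, log = list(subject_id = id, excluded = TRUE,
                                  reason = conditionMessage(e))))
    log_subj[[id]] <- entry$log
    if (entry$ok) {
      features[[id]] <- entry$feat
      cycles[[id]] <- entry$cyc
      metas[[id]] <- entry$meta
    }
  }
  if (length(features) == 0)
    gm_stop("no subject produced features", "gaitmark_nogait_error")
  features <- do.call(rbind, features)
  cycles <- do.call(rbind, c(cycles, list(make.row.names = FALSE)))
  meta <- if (config$mode == "simulate") do.call(rbind, metas) else meta_all
  comparison <- run_comparison_suite(features, meta, config$alpha, config$m_tests)
  avg_cycle <- group_average_cycle(avg_acc, meta)

  result <- structure(list(features = features, cycles = cycles,
                           comparison = comparison, meta = meta,
                           avg_cycle = avg_cycle,
                           log = list(subjects = log_subj,
                                      n_analyzed = length(metas),
                                      input_hashes = input_hashes),
                           config = config, recordings = recordings),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) if (!is.null(df))
    utils::write.csv(format(df, digits = 12, trim = TRUE),
                     file.path(out_dir, name), row.names = FALSE)
  wr(result$cycles, "cycles.csv")
  write_feature_table(result$features, file.path(out_dir, "features.csv"))
  wr(result$comparison$kinematic, "ttest_kinematic.csv")
  wr(result$comparison$dynamic, "ttest_dynamic.csv")
  wr(result$comparison$roc, "roc.csv")
  wr(result$avg_cycle, "average_cycle.csv")
  cfg <- result$config
  cfg_json <- jsonlite::toJSON(unclass(cfg)[!vapply(cfg, is.function, TRUE)],
                               auto_unbox = TRUE, digits = NA, null = "null",
                               force = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  log <- result$log
  log$config_hash <- unname(tools::md5sum(cfg_path))
  log$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, null = "null",
                              force = TRUE, pretty = TRUE),
             file.path(out_dir, "run_log.json"))
  invisible(out_dir)
}

# one subject's accepted cycles resampled to 0..100% of the gait cycle
# (101 points, linear interpolation) and averaged within the subject
subject_average_cycle <- function(recording, cycleset) {
  acc <- cycleset$accepted
  if (nrow(acc) == 0) return(NULL)
  grid <- 0:100
  resample <- function(total, a, b) {
    idx <- a:(b - 1)
    stats::approx(seq(0, 100, length.out = length(idx)), total[idx], grid)$y
  }
  lmat <- matrix(0, nrow(acc), 101); rmat <- matrix(0, nrow(acc), 101)
  for (i in seq_len(nrow(acc))) {
    lmat[i, ] <- resample(recording$left_total, acc$start[i], acc$end[i])
    rmat[i, ] <- resample(recording$right_total, acc$start[i], acc$end[i])
  }
  list(left = colMeans(lmat), right = colMeans(rmat))
}

group_average_cycle <- function(avg_acc, meta) {
  avg_acc <- avg_acc[!vapply(avg_acc, is.null, TRUE)]
  if (length(avg_acc) == 0) return(NULL)
  grp <- meta$group[match(names(avg_acc), meta$subject_id)]
  out <- list()
  for (g in unique(grp)) {
    sel <- avg_acc[grp == g]
    for (foot in c("left", "right")) {
      m <- colMeans(do.call(rbind, lapply(sel, `[[`, foot)))
      out[[paste(g, foot)]] <- data.frame(group = g, foot = foot,
                                          pct = 0:100, force = m)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Group-average gait-cycle force profile
#'
#' Resamples each accepted cycle's per-foot total force to a common 0-100%
#' gait-cycle axis (101 points, linear interpolation), averages within
#' subject and then across the subjects of each group (so long trials do not
#' dominate the group mean).
#'
#' @param recordings named list of [insole_recording()]s.
#' @param cyclesets matching named list of `cycle_set`s.
#' @param meta metadata table with `subject_id` and `group`.
#' @return data.frame with columns `group`, `foot`, `pct`, `force`.
#' @export
average_cycle_profile <- function(recordings, cyclesets, meta) {
  stopifnot(length(recordings) == length(cyclesets))
  avg <- mapply(subject_average_cycle, recordings, cyclesets, SIMPLIFY = FALSE)
  names(avg) <- vapply(recordings, `[[`, "", "subject_id")
  group_average_cycle(avg, meta)
}

#' QC plot of the differential GRF with cycle boundaries
#'
#' @param recording an [insole_recording()].
#' @param cycles optional [segment_cycles()] table; valid cycle starts are
#'   drawn as vertical lines.
#' @param xlim optional time window, seconds.
#' @return invisibly, the [differential_grf()] trace.
#' @export
plot_differential_grf <- function(recording, cycles = NULL, xlim = NULL) {
  d <- differential_grf(recording)
  if (!is.null(xlim)) d <- d[d$time >= xlim[1] & d$time <= xlim[2], ]
  plot(d$time, d$delta, type = "l", xlab = "time (s)",
       ylab = expression(delta == R[tot] - L[tot]),
       main = paste("differential GRF -", recording$subject_id))
  graphics::abline(h = 0, col = "grey60")
  if (!is.null(cycles)) {
    ts <- recording$time[cycles$start[cycles$valid]]
    if (!is.null(xlim)) ts <- ts[ts >= xlim[1] & ts <= xlim[2]]
    graphics::abline(v = ts, col = "red", lty = 3)
  }
  invisible(d)
}

#' Plot group-average gait-cycle force profiles
#'
#' @param profile output of [average_cycle_profile()] (or the `avg_cycle`
#'   element of a pipeline result).
#' @return `profile`, invisibly.
#' @export
plot_average_cycle <- function(profile) {
  plot(NULL, xlim = c(0, 100), ylim = range(profile$force),
       xlab = "% gait cycle", ylab = "total force",
       main = "average gait-cycle dynamics")
  combos <- unique(profile[c("group", "foot")])
  for (i in seq_len(nrow(combos))) {
    sel <- profile$group == combos$group[i] & profile$foot == combos$foot[i]
    graphics::lines(profile$pct[sel], profile$force[sel],
                    col = ifelse(combos$foot[i] == "right", "red", "darkgreen"),
                    lty = which(unique(profile$group) == combos$group[i]))
  }
  graphics::legend("topright", bty = "n",
                   legend = paste(combos$group, combos$foot),
                   col = ifelse(combos$foot == "right", "red", "darkgreen"),
                   lty = match(combos$group, unique(profile$group)))
  invisible(profile)
}
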