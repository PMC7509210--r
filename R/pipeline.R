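#' Cohort aggregation: mean ± SD plus boxplot statistics
#'
#' @param values per-subject scalars (finite, `n >= 1`).
#' @return list with `mean`, `sd` (sample SD, 0 for a single value),
#'   `median`, `q1`, `q3` (linear-interpolation quartiles), `n`.
#' @export
aggregate_stats <- function(values) {
  if (!length(values)) stop("usage error: empty value vector", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       median = q[2L], q1 = q[1L], q3 = q[3L], n = length(values))
}

#' Analysis parameters for the full pipeline
#'
#' Bundles the per-stage parameter blocks plus the rate at which the
#' correlation/delay analyses run: envelopes and torque are decimated to
#' `analysis_fs` (default 100 Hz -- ample for a 6-Hz envelope) before
#' cross-correlation, which sets the lag grid to `1000 / analysis_fs`
#' ms.
#'
#' @param preprocess a [preprocess_params].
#' @param segmentation a [segmentation_params].
#' @param correlation a [correlation_params].
#' @param analysis_fs sampling rate for correlation/delay analysis, Hz.
#' @param apen_fs,apen_m,apen_r_frac,ssd_window_s,ssd_step smoothness
#'   parameters (see [smoothness_report]).
#' @param seed seed for the permutation tests.
#' @return list of class `run_params`.
#' @export
run_params <- function(preprocess = preprocess_params(),
                       segmentation = segmentation_params(),
                       correlation = correlation_params(),
                       analysis_fs = 100,
                       apen_fs = 100, apen_m = 2L, apen_r_frac = 0.2,
                       ssd_window_s = 0.5, ssd_step = 1L, seed = 1L) {
  structure(list(preprocess = preprocess, segmentation = segmentation,
                 correlation = correlation, analysis_fs = analysis_fs,
                 apen_fs = apen_fs, apen_m = apen_m,
                 apen_r_frac = apen_r_frac, ssd_window_s = ssd_window_s,
                 ssd_step = ssd_step, seed = as.integer(seed)),
            class = "run_params")
}

#' Analyze a single trial end to end
#'
#' Envelope extraction and trial-max normalization per channel,
#' decimation to the analysis rate, direction segmentation on the
#' decimated torque, then per muscle x direction correlation and
#' amplitude, per-direction contribution ratios, per-muscle pooled-span
#' delays, and the smoothness metrics.
#'
#' @param trial a [steer_trial].
#' @param params a [run_params].
#' @return list with `results` (a [muscle_direction_results] table),
#'   `delays` (data.frame muscle/tau_ms/rho_at_tau/boundary),
#'   `smoothness` (a `smoothness_result`), and `segments`.
#' @export
analyze_trial <- function(trial, params = run_params()) {
  validate_trial(trial)
  stopifnot(inherits(params, "run_params"))
  n_ch <- nrow(trial$emg)
  envs <- matrix(0, nrow = n_ch,
                 ncol = length(decimate_signal(trial$torque, trial$fs,
                                               params$analysis_fs)$x))
  for (i in seq_len(n_ch)) {
    e <- emg_envelope(trial$emg[i, ], trial$fs, params$preprocess)
    e <- normalize_envelope(e, params$preprocess$norm_method)
    envs[i, ] <- decimate_signal(e, trial$fs, params$analysis_fs)$x
  }
  tq <- decimate_signal(trial$torque, trial$fs, params$analysis_fs)
  segs <- segment_directions(tq$x, tq$fs, params$segmentation)

  rows <- list()
  for (dir in c("cw", "ccw")) {
    rs <- vapply(seq_len(n_ch), function(i) {
      direction_correlation(envs[i, ], tq$x, segs, dir, tq$fs,
                            params$correlation)
    }, numeric(1))
    as_ <- vapply(seq_len(n_ch), function(i) {
      amplitude_statistic(envs[i, ], segs, dir)
    }, numeric(1))
    cs <- contribution_ratios(rs, as_)
    rows[[dir]] <- data.frame(muscle = trial$channel_labels, direction = dir,
                              r = rs, a = as_, c = cs,
                              stringsAsFactors = FALSE)
  }
  # whole-trial span for delays: concatenating segments would create
  # artificial joins that attenuate the correlation at large lags and
  # bias |tau| low (verified against injected leads)
  delays <- lapply(seq_len(n_ch), function(i) {
    d <- estimate_delay(envs[i, ], tq$x, tq$fs, segs = NULL,
                        max_lag_ms = params$correlation$max_lag_ms,
                        muscle = trial$channel_labels[i])
    data.frame(muscle = d$muscle, tau_ms = d$tau_ms,
               rho_at_tau = d$rho_at_tau, boundary = d$boundary,
               stringsAsFactors = FALSE)
  })
  delays <- do.call(rbind, delays)
  both <- rbind(rows$cw, rows$ccw)
  both$tau_ms <- delays$tau_ms[match(both$muscle, delays$muscle)]
  res <- muscle_direction_results(both$muscle, both$direction, both$r,
                                  both$a, both$c, both$tau_ms)
  sm <- smoothness_report(trial, m = params$apen_m,
                          r_frac = params$apen_r_frac,
                          apen_fs = params$apen_fs,
                          window_s = params$ssd_window_s,
                          step = params$ssd_step)
  list(results = res, delays = delays, smoothness = sm, segments = segs)
}

list_trial_files <- function(input_dir) {
  csvs <- list.files(input_dir, pattern = "\\.csv$", full.names = TRUE)
  csvs[file.exists(sub("\\.csv$", ".meta.json", csvs))]
}

#' Run the cohort pipeline over a directory of trials
#'
#' Reads every trial CSV with a `.meta.json` sidecar under `input_dir`,
#' analyzes each subject with [analyze_trial], and writes to
#' `output_dir`:
#' \describe{
#'   \item{`muscle_direction_results.csv`}{per subject x muscle x
#'     direction rows (subject column prepended).}
#'   \item{`delays.csv`}{per subject x muscle delay estimates.}
#'   \item{`smoothness.csv`}{per subject ApEn and SSD.}
#'   \item{`direction_tests.csv`}{per-muscle paired sign-flip
#'     permutation p-values for cw-vs-ccw correlation, raw and
#'     Holm-adjusted.}
#'   \item{`cohort_summary.csv`}{[cohort_summary] rows: mean, SD,
#'     median, quartiles per condition x direction x statistic.}
#'   \item{`manifest.csv`}{per-trial status; a failing trial is logged
#'     and skipped, the run continues.}
#' }
#' Outputs are deterministic given the seed in `params`.
#'
#' @param input_dir directory of trial CSV + meta JSON pairs.
#' @param output_dir output directory (created if needed).
#' @param params a [run_params].
#' @return invisibly, a list with the aggregated tables and the
#'   manifest.
#' @export
run_pipeline <- function(input_dir, output_dir, params = run_params()) {
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir,
                                   call. = FALSE)
  files <- list_trial_files(input_dir)
  if (!length(files)) stop("no trial files (csv + meta.json) in ", input_dir,
                           call. = FALSE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  per_subj <- list(); delays <- list(); smooth <- list(); manifest <- list()
  for (f in sort(files)) {
    status <- "ok"; msg <- ""
    res <- tryCatch({
      tr <- read_trial(f)
      out <- analyze_trial(tr, params)
      key <- data.frame(subject_id = tr$subject_id, arm_mode = tr$arm_mode,
                        task = tr$task, hand_position = tr$hand_position,
                        stringsAsFactors = FALSE)
      per_subj[[f]] <- cbind(key[rep(1, nrow(out$results)), , drop = FALSE],
                             as.data.frame(out$results))
      delays[[f]] <- cbind(key[rep(1, nrow(out$delays)), , drop = FALSE],
                           out$delays)
      smooth[[f]] <- cbind(key, apen = out$smoothness$apen,
                           ssd = out$smoothness$ssd)
      TRUE
    }, error = function(e) {
      status <<- "error"; msg <<- conditionMessage(e); FALSE
    })
    manifest[[f]] <- data.frame(file = basename(f), status = status,
                                message = msg, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  if (!any(manifest$status == "ok")) {
    utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                     row.names = FALSE)
    stop("all trials failed; see manifest.csv", call. = FALSE)
  }
  per_subj <- do.call(rbind, per_subj); rownames(per_subj) <- NULL
  delays <- do.call(rbind, delays); rownames(delays) <- NULL
  smooth <- do.call(rbind, smooth); rownames(smooth) <- NULL

  # direction-dependence permutation tests, per muscle, paired by subject
  tests <- direction_tests(per_subj, seed = params$seed)

  summary_df <- summarize_cohort(per_subj, delays, smooth)

  write_numeric_csv(per_subj,
                    file.path(output_dir, "muscle_direction_results.csv"),
                    comment = "# steerlimb_schema: per_subject_results v1")
  write_numeric_csv(delays, file.path(output_dir, "delays.csv"),
                    comment = "# steerlimb_schema: delays v1")
  write_numeric_csv(smooth, file.path(output_dir, "smoothness.csv"),
                    comment = "# steerlimb_schema: smoothness v1")
  write_numeric_csv(tests, file.path(output_dir, "direction_tests.csv"),
                    comment = "# steerlimb_schema: direction_tests v1")
  write_results(summary_df, file.path(output_dir, "cohort_summary.csv"))
  utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(per_subject = per_subj, delays = delays, smoothness = smooth,
                 direction_tests = tests, summary = summary_df,
                 manifest = manifest))
}

direction_tests <- function(per_subj, seed = 1L) {
  out <- list()
  for (m in sort(unique(per_subj$muscle))) {
    sub <- per_subj[per_subj$muscle == m, ]
    cw <- sub[sub$direction == "cw", c("subject_id", "r")]
    ccw <- sub[sub$direction == "ccw", c("subject_id", "r")]
    common <- intersect(cw$subject_id, ccw$subject_id)
    if (length(common) < 2L) next
    p <- direction_dependence_test(cw$r[match(common, cw$subject_id)],
                                   ccw$r[match(common, ccw$subject_id)],
                                   seed = seed)
    out[[m]] <- data.frame(muscle = m, n = length(common), p_raw = p,
                           stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, out)
  rownames(tests) <- NULL
  tests$p_holm <- stats::p.adjust(tests$p_raw, method = "holm")
  tests
}

summarize_cohort <- function(per_subj, delays, smooth) {
  rows <- list()
  add <- function(arm, task, hp, dir, stat, values) {
    a <- aggregate_stats(values)
    rows[[length(rows) + 1L]] <<- cohort_summary(
      arm, task, hp, dir, stat, a$mean, a$sd, a$median, a$q1, a$q3, a$n)
  }
  conds <- unique(per_subj[, c("arm_mode", "task", "hand_position")])
  for (i in seq_len(nrow(conds))) {
    cd <- conds[i, ]
    sel <- per_subj$arm_mode == cd$arm_mode & per_subj$task == cd$task &
      per_subj$hand_position == cd$hand_position
    for (dir in c("cw", "ccw")) {
      sub <- per_subj[sel & per_subj$direction == dir, ]
      for (m in sort(unique(sub$muscle))) {
        ms <- sub[sub$muscle == m, ]
        add(cd$arm_mode, cd$task, cd$hand_position, dir,
            paste0("r.", m), ms$r)
        add(cd$arm_mode, cd$task, cd$hand_position, dir,
            paste0("a.", m), ms$a)
        add(cd$arm_mode, cd$task, cd$hand_position, dir,
            paste0("c.", m), ms$c)
      }
    }
    dsel <- delays$arm_mode == cd$arm_mode & delays$task == cd$task &
      delays$hand_position == cd$hand_position
    for (m in sort(unique(delays$muscle[dsel]))) {
      add(cd$arm_mode, cd$task, cd$hand_position, "all",
          paste0("tau_ms.", m), delays$tau_ms[dsel & delays$muscle == m])
    }
    ssel <- smooth$arm_mode == cd$arm_mode & smooth$task == cd$task &
      smooth$hand_position == cd$hand_position
    add(cd$arm_mode, cd$task, cd$hand_position, "all", "apen",
        smooth$apen[ssel])
    add(cd$arm_mode, cd$task, cd$hand_position, "all", "ssd",
        smooth$ssd[ssel])
  }
  do.call(rbind, rows)
}
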