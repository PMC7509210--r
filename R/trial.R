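#' Trial objects: one synchronized EMG + steering recording
#'
#' A trial bundles 10 EMG channels (mV) with the steering torque (N·m)
#' and steering angle (degrees) sampled on a common uniform time base,
#' plus the metadata that identifies the recording condition. The sign
#' convention is pinned package-wide: positive torque is clockwise
#' steering effort (recorded in the metadata sidecar so importers of
#' real data with the opposite convention can flip the sign on read).
#'
#' @param subject_id character scalar.
#' @param arm_mode `"both"` or `"single"`.
#' @param hand_position one of `"0300"`, `"1010"`, `"1200"` (both-arm) or
#'   `"0300"`, `"0130"`, `"1200"` (single-arm).
#' @param task `"active"` (target following) or `"passive"`
#'   (disturbance rejection).
#' @param fs sampling rate in Hz.
#' @param time time stamps in seconds, strictly increasing with step
#'   `1/fs`.
#' @param torque steering torque in N·m (positive = clockwise).
#' @param angle steering angle in degrees.
#' @param emg 10 x N matrix of EMG channels in mV.
#' @param channel_labels 10 muscle codes (`MS1`..`MS10` or `MB1`..`MB10`).
#' @return an object of class `steer_trial`.
#' @export
steer_trial <- function(subject_id, arm_mode, hand_position, task, fs,
                        time, torque, angle, emg,
                        channel_labels = default_channel_labels(arm_mode)) {
  tr <- structure(
    list(subject_id = as.character(subject_id),
         arm_mode = arm_mode, hand_position = hand_position, task = task,
         fs = fs, time = as.numeric(time), torque = as.numeric(torque),
         angle = as.numeric(angle), emg = emg,
         channel_labels = as.character(channel_labels)),
    class = "steer_trial")
  validate_trial(tr)
}

#' @export
print.steer_trial <- function(x, ...) {
  cat(sprintf(
    "<steer_trial> subject %s | %s-arm %s | hand %s | %d ch x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$arm_mode, x$task, x$hand_position,
    nrow(x$emg), length(x$time), x$fs, length(x$time) / x$fs))
  invisible(x)
}

#' Muscle code labels for an arm mode
#' @param arm_mode `"both"` or `"single"`.
#' @return character vector of 10 codes.
#' @export
default_channel_labels <- function(arm_mode) {
  prefix <- switch(arm_mode, single = "MS", both = "MB",
                   stop("arm_mode must be 'both' or 'single'", call. = FALSE))
  paste0(prefix, 1:10)
}

hand_positions_for <- function(arm_mode) {
  switch(arm_mode,
         both = c("0300", "1010", "1200"),
         single = c("0300", "0130", "1200"),
         stop("arm_mode must be 'both' or 'single'", call. = FALSE))
}

#' Validate a trial against its structural invariants
#'
#' Checks metadata enums, series lengths, channel count, NaN/Inf
#' contamination, and uniformity of the time base (step `1/fs` to a
#' relative tolerance of 1e-9).
#'
#' @param tr a `steer_trial`.
#' @return `tr`, invisibly usable, after validation; errors otherwise.
#' @export
validate_trial <- function(tr) {
  if (!inherits(tr, "steer_trial")) stop("not a steer_trial", call. = FALSE)
  if (!tr$arm_mode %in% c("both", "single")) {
    stop("invalid arm_mode: ", tr$arm_mode, call. = FALSE)
  }
  if (!tr$task %in% c("active", "passive")) {
    stop("invalid task: ", tr$task, call. = FALSE)
  }
  allowed <- hand_positions_for(tr$arm_mode)
  if (!tr$hand_position %in% allowed) {
    stop("hand_position '", tr$hand_position, "' invalid for arm_mode '",
         tr$arm_mode, "' (allowed: ", paste(allowed, collapse = ", "), ")",
         call. = FALSE)
  }
  if (!is.numeric(tr$fs) || length(tr$fs) != 1L || tr$fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  n <- length(tr$time)
  if (length(tr$torque) != n || length(tr$angle) != n || ncol(tr$emg) != n) {
    stop("time, torque, angle and emg must share one length", call. = FALSE)
  }
  if (nrow(tr$emg) != 10L) {
    stop("emg must have exactly 10 channels, got ", nrow(tr$emg),
         call. = FALSE)
  }
  if (length(tr$channel_labels) != 10L) {
    stop("channel_labels must have length 10", call. = FALSE)
  }
  for (nm in c("time", "torque", "angle")) {
    bad <- which(!is.finite(tr[[nm]]))
    if (length(bad)) {
      stop("data error: non-finite value in '", nm, "' at row ", bad[1L],
           call. = FALSE)
    }
  }
  bad <- which(!is.finite(tr$emg))
  if (length(bad)) {
    row <- ((bad[1L] - 1L) %/% 10L) + 1L
    stop("data error: non-finite value in emg at row ", row, call. = FALSE)
  }
  check_uniform_time(tr$time, tr$fs)
  tr
}

check_uniform_time <- function(time, fs) {
  n <- length(time)
  if (n < 2L) stop("trial needs at least 2 samples", call. = FALSE)
  dt <- diff(time)
  step <- 1 / fs
  bad <- which(abs(dt - step) / step > 1e-9)
  if (any(dt <= 0)) {
    stop("timing error: time must be strictly increasing (first violation at row ",
         which(dt <= 0)[1L] + 1L, ")", call. = FALSE)
  }
  if (length(bad)) {
    stop("timing error: non-uniform time step at row ", bad[1L] + 1L,
         " (step ", signif(dt[bad[1L]], 6), " s, expected ", signif(step, 6),
         " s)", call. = FALSE)
  }
  invisible(TRUE)
}

trial_columns <- function() c("time", "torque", "angle", sprintf("emg_%02d", 1:10))

#' Read a trial from a CSV file plus JSON metadata sidecar
#'
#' The data file must be comma-delimited UTF-8 with a header row and
#' columns `time, torque, angle, emg_01, ..., emg_10` (this order is the
#' interchange contract; extra columns are rejected by name check only).
#' The sidecar (same basename, suffix `.meta.json`) carries
#' `subject_id`, `arm_mode`, `hand_position`, `task` and optionally
#' `channel_labels`. The sampling rate is inferred from the median time
#' step and the time base is validated against it.
#'
#' @param path_data path to the trial CSV.
#' @param path_meta path to the metadata JSON; defaults to the sidecar
#'   convention `<basename>.meta.json`.
#' @return a validated [steer_trial].
#' @export
read_trial <- function(path_data,
                       path_meta = sub("\\.csv$", ".meta.json", path_data)) {
  if (!file.exists(path_data)) stop("trial file not found: ", path_data, call. = FALSE)
  if (!file.exists(path_meta)) stop("metadata sidecar not found: ", path_meta, call. = FALSE)
  dt <- data.table::fread(path_data, sep = ",", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  need <- trial_columns()
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("format error: missing column '", missing_cols[1L], "' in ",
         path_data, call. = FALSE)
  }
  meta <- jsonlite::read_json(path_meta, simplifyVector = TRUE)
  for (k in c("subject_id", "arm_mode", "hand_position", "task")) {
    if (is.null(meta[[k]])) {
      stop("format error: metadata key '", k, "' missing in ", path_meta,
           call. = FALSE)
    }
  }
  time <- dt$time
  if (length(time) < 2L) stop("trial needs at least 2 samples", call. = FALSE)
  fs <- 1 / stats::median(diff(time))
  emg <- t(as.matrix(dt[, sprintf("emg_%02d", 1:10)]))
  labels <- if (!is.null(meta$channel_labels)) {
    unlist(meta$channel_labels)
  } else {
    default_channel_labels(meta$arm_mode)
  }
  dimnames(emg) <- NULL
  steer_trial(subject_id = meta$subject_id, arm_mode = meta$arm_mode,
              hand_position = meta$hand_position, task = meta$task,
              fs = fs, time = time, torque = dt$torque, angle = dt$angle,
              emg = emg, channel_labels = labels)
}

#' Write a trial to CSV + JSON sidecar
#'
#' Numeric fields are serialized with 17 significant digits so a
#' read-back reproduces them to better than 1e-12.
#'
#' @param tr a [steer_trial].
#' @param path_data output CSV path.
#' @param path_meta output metadata path (sidecar convention by default).
#' @return invisibly, the data path.
#' @export
write_trial <- function(tr, path_data,
                        path_meta = sub("\\.csv$", ".meta.json", path_data)) {
  validate_trial(tr)
  m <- cbind(tr$time, tr$torque, tr$angle, t(tr$emg))
  colnames(m) <- trial_columns()
  write_numeric_csv(as.data.frame(m), path_data)
  meta <- list(subject_id = tr$subject_id, arm_mode = tr$arm_mode,
               hand_position = tr$hand_position, task = tr$task,
               fs = tr$fs, channel_labels = tr$channel_labels,
               torque_sign_convention = "positive_clockwise")
  jsonlite::write_json(meta, path_meta, auto_unbox = TRUE, digits = NA)
  invisible(path_data)
}

# full-precision CSV writer shared by all result/table outputs;
# `comment` lines (schema tags) are prepended verbatim.
write_numeric_csv <- function(df, path, comment = NULL) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  })
  lines <- c(comment,
             paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

result_schemas <- list(
  muscle_direction_results = list(
    tag = "# steerlimb_schema: muscle_direction_results v1",
    cols = c("muscle", "direction", "r", "a", "c", "tau_ms"),
    numeric = c("r", "a", "c", "tau_ms")),
  cohort_summary = list(
    tag = "# steerlimb_schema: cohort_summary v1",
    cols = c("arm_mode", "task", "hand_position", "direction", "statistic",
             "mean", "sd", "median", "q1", "q3", "n_subjects"),
    numeric = c("mean", "sd", "median", "q1", "q3", "n_subjects"))
)

#' Construct a per-muscle, per-direction result table
#'
#' One row per muscle x steering direction: the EMG-torque correlation
#' `r`, the normalized amplitude `a`, the contribution ratio `c`
#' (summing to 1 over the 10 muscles of a direction), and the delay
#' `tau_ms` (negative = muscle activity leads the torque).
#'
#' @param muscle,direction,r,a,c,tau_ms aligned vectors.
#' @return data.frame of class `muscle_direction_results`.
#' @export
muscle_direction_results <- function(muscle, direction, r, a, c, tau_ms) {
  df <- data.frame(muscle = as.character(muscle),
                   direction = as.character(direction),
                   r = as.numeric(r), a = as.numeric(a), c = as.numeric(c),
                   tau_ms = as.numeric(tau_ms), stringsAsFactors = FALSE)
  if (!all(df$direction %in% c("cw", "ccw"))) {
    stop("direction must be 'cw' or 'ccw'", call. = FALSE)
  }
  if (any(df$r < -1e-12 | df$r > 1 + 1e-12)) stop("r must lie in [0,1]", call. = FALSE)
  if (any(df$a < -1e-12)) stop("a must be >= 0", call. = FALSE)
  if (any(df$c < -1e-12 | df$c > 1 + 1e-12)) stop("c must lie in [0,1]", call. = FALSE)
  class(df) <- c("muscle_direction_results", "data.frame")
  df
}

#' Construct a cohort summary table
#'
#' One row per (arm_mode, task, hand_position, direction, statistic)
#' with mean, SD, median, quartiles and the number of subjects, the
#' "mean ± SD plus boxplot" presentation used for cohort reporting.
#'
#' @param arm_mode,task,hand_position,direction,statistic condition keys.
#' @param mean,sd,median,q1,q3,n_subjects statistics.
#' @return data.frame of class `cohort_summary`.
#' @export
cohort_summary <- function(arm_mode, task, hand_position, direction,
                           statistic, mean, sd, median, q1, q3, n_subjects) {
  df <- data.frame(arm_mode = as.character(arm_mode),
                   task = as.character(task),
                   hand_position = as.character(hand_position),
                   direction = as.character(direction),
                   statistic = as.character(statistic),
                   mean = as.numeric(mean), sd = as.numeric(sd),
                   median = as.numeric(median), q1 = as.numeric(q1),
                   q3 = as.numeric(q3), n_subjects = as.integer(n_subjects),
                   stringsAsFactors = FALSE)
  if (any(df$sd < 0)) stop("sd must be >= 0", call. = FALSE)
  if (any(df$q1 > df$median + 1e-12 | df$median > df$q3 + 1e-12)) {
    stop("quartiles must satisfy q1 <= median <= q3", call. = FALSE)
  }
  if (any(df$n_subjects < 1L)) stop("n_subjects must be >= 1", call. = FALSE)
  class(df) <- c("cohort_summary", "data.frame")
  df
}

result_kind <- function(x) {
  if (inherits(x, "muscle_direction_results")) return("muscle_direction_results")
  if (inherits(x, "cohort_summary")) return("cohort_summary")
  stop("usage error: unrecognized result kind", call. = FALSE)
}

#' Write result tables to CSV
#'
#' Accepts one result table or a list of tables of one kind
#' ([muscle_direction_results] or [cohort_summary]); mixing kinds in a
#' single call is a usage error. Output carries a schema tag as a `#`
#' comment line and round-trips through [read_results] losslessly to
#' 1e-12.
#'
#' @param results result table or homogeneous list of them.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_results <- function(results, path) {
  if (is.data.frame(results)) results <- list(results)
  if (!length(results)) stop("usage error: empty result list", call. = FALSE)
  kinds <- vapply(results, result_kind, character(1))
  if (length(unique(kinds)) != 1L) {
    stop("usage error: mixed result kinds in one write_results() call",
         call. = FALSE)
  }
  schema <- result_schemas[[kinds[1L]]]
  df <- do.call(rbind, lapply(results, function(x) {
    as.data.frame(x)[, schema$cols]
  }))
  write_numeric_csv(df, path, comment = schema$tag)
  invisible(path)
}

#' Read a result table written by [write_results]
#' @param path CSV path.
#' @return table with the class recorded in its schema tag.
#' @export
read_results <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- NULL
  for (k in names(result_schemas)) {
    if (identical(first, result_schemas[[k]]$tag)) kind <- k
  }
  if (is.null(kind)) stop("format error: unrecognized schema tag in ", path,
                          call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  schema <- result_schemas[[kind]]
  missing_cols <- setdiff(schema$cols, names(df))
  if (length(missing_cols)) {
    stop("format error: missing column '", missing_cols[1L], "'", call. = FALSE)
  }
  class(df) <- c(kind, "data.frame")
  df
}
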