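#' @useDynLib emdtrigger, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Zero-phase IIR filtering: odd-reflection padding at both ends (length
# 3 * filter order), forward pass, time-reversed second pass, pad removal.
# The padding length and scheme are part of the envelope definition.
zero_phase_filter <- function(b, a, x) {
  nord <- max(length(a), length(b)) - 1L
  pad <- 3L * nord
  if (length(x) <= pad) {
    stop("series too short for zero-phase filtering", call. = FALSE)
  }
  zero_phase_filter_cpp(b, a, x, pad)
}

butter_coeffs <- function(order, cutoff_hz, rate, type) {
  bf <- signal::butter(order, 2 * cutoff_hz / rate, type = type)
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

# memoised coefficient cache keyed by (order, cutoff, rate, type)
.coef_cache <- new.env(parent = emptyenv())
butter_coeffs_cached <- function(order, cutoff_hz, rate, type) {
  key <- paste(order, cutoff_hz, rate, type, sep = "|")
  cf <- get0(key, envir = .coef_cache)
  if (is.null(cf)) {
    cf <- butter_coeffs(order, cutoff_hz, rate, type)
    assign(key, cf, envir = .coef_cache)
  }
  cf
}

#' Adaptive rest-period detection threshold
#'
#' The onset threshold is set 1% above the maximum squared EMG sample observed
#' during the rest period preceding the cue. An all-zero rest window yields a
#' machine-epsilon floor instead of a zero threshold.
#'
#' @param rest_emg numeric vector of raw EMG samples from the rest period.
#' @return list with `rest_max` (maximum squared sample) and `threshold`
#'   (`1.01 * rest_max`, floored at machine epsilon).
#' @export
compute_threshold <- function(rest_emg) {
  if (length(rest_emg) == 0L) stop("empty rest window", call. = FALSE)
  rest_max <- max(rest_emg^2)
  threshold <- 1.01 * rest_max
  if (threshold <= 0) threshold <- .Machine$double.eps
  list(rest_max = rest_max, threshold = threshold)
}

#' Detect EMG onset by squared-sample threshold crossing
#'
#' Returns the first sample index at or after `search_start` whose squared
#' raw value exceeds the threshold, mirroring the real-time trigger rule.
#' No smoothing is applied: detection operates on raw squared samples.
#'
#' @param emg numeric vector of raw EMG samples.
#' @param threshold squared-EMG threshold (see [compute_threshold()]).
#' @param search_start first index to inspect (typically the cue index).
#' @return integer index of the first crossing, or `NA_integer_` if the
#'   threshold is never exceeded.
#' @export
detect_onset <- function(emg, threshold, search_start) {
  n <- length(emg)
  stopifnot(search_start >= 1L, search_start <= n)
  seg <- emg[search_start:n]
  hit <- which(seg * seg > threshold)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(search_start + hit[1L] - 1L)
}

#' EMG envelope: rectification and band filtering
#'
#' Computes the amplitude envelope used for peak extraction: full-wave
#' rectification, then a zero-phase 4th-order Butterworth high-pass at 20 Hz,
#' then a zero-phase 4th-order Butterworth low-pass at 10 Hz, in that order.
#' Small negative excursions introduced by filtering are clipped at zero.
#'
#' @param raw numeric vector of raw EMG samples.
#' @param rate sampling rate in Hz (> 40).
#' @param hp_cutoff,lp_cutoff filter cutoffs in Hz.
#' @param order Butterworth order for both filters.
#' @return numeric vector, same length as `raw`, nonnegative.
#' @export
emg_envelope <- function(raw, rate, hp_cutoff = 20, lp_cutoff = 10, order = 4L) {
  if (rate <= 2 * max(hp_cutoff, lp_cutoff)) {
    stop("sampling rate too low for the filter cutoffs", call. = FALSE)
  }
  if (length(raw) <= 3L * 2L * order) {
    stop("EMG series too short for envelope filtering", call. = FALSE)
  }
  hp <- butter_coeffs_cached(order, hp_cutoff, rate, "high")
  lp <- butter_coeffs_cached(order, lp_cutoff, rate, "low")
  env <- zero_phase_filter(hp$b, hp$a, abs(raw))
  env <- zero_phase_filter(lp$b, lp$a, env)
  pmax(env, 0)
}

#' Peak activation in the post-onset window
#'
#' Maximum of the envelope over the 200 ms window beginning at the detected
#' onset. A window extending past the end of the series is truncated, not an
#' error.
#'
#' @param envelope numeric envelope series (see [emg_envelope()]).
#' @param onset_index sample index of detected onset (1-based).
#' @param rate sampling rate in Hz.
#' @param window window length in seconds (default 0.2).
#' @return peak envelope value in the window.
#' @export
peak_activation <- function(envelope, onset_index, rate, window = 0.2) {
  n <- length(envelope)
  if (is.na(onset_index) || onset_index < 1L || onset_index > n) {
    stop("onset index outside the series", call. = FALSE)
  }
  end <- min(n, onset_index + round(window * rate))
  max(envelope[onset_index:end])
}

#' Normalize activation peaks to the control-condition mean
#'
#' Expresses per-trial activation peaks as a percentage of the mean peak from
#' the control condition. Applied per participant and per muscle, so absolute
#' EMG units cancel.
#'
#' @param peaks numeric vector of per-trial peak values.
#' @param control_peaks peaks from the same participant's and muscle's control
#'   trials; must be non-empty with a positive mean.
#' @return `peaks * 100 / mean(control_peaks)`.
#' @export
normalize_peaks <- function(peaks, control_peaks) {
  if (length(control_peaks) == 0L || !is.finite(mean(control_peaks)) ||
      mean(control_peaks) <= 0) {
    stop("control peaks must have a positive mean", call. = FALSE)
  }
  peaks * 100 / mean(control_peaks)
}

unwrap_angle <- function(theta) {
  d <- diff(theta)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  theta - 2 * pi * jumps
}

#' Arm angular velocity from wrist and elbow markers
#'
#' The arm angle is the planar arctangent of the wrist marker relative to the
#' elbow marker in the transverse plane; its unwrapped central-difference
#' derivative gives angular velocity, with arm extension positive and flexion
#' negative. Endpoint samples use one-sided differences.
#'
#' @param wrist_xy,elbow_xy n x 2 matrices of planar marker positions (m).
#' @param rate marker sampling rate in Hz.
#' @return numeric vector of angular velocity (rad/s), length n.
#' @export
angular_velocity <- function(wrist_xy, elbow_xy, rate) {
  wrist_xy <- as.matrix(wrist_xy); elbow_xy <- as.matrix(elbow_xy)
  stopifnot(ncol(wrist_xy) == 2L, ncol(elbow_xy) == 2L,
            nrow(wrist_xy) == nrow(elbow_xy))
  dx <- wrist_xy[, 1] - elbow_xy[, 1]
  dy <- wrist_xy[, 2] - elbow_xy[, 2]
  if (any(dx == 0 & dy == 0)) {
    stop("wrist and elbow markers coincide", call. = FALSE)
  }
  theta <- unwrap_angle(atan2(dy, dx))
  n <- length(theta)
  if (n < 3L) stop("need at least 3 marker samples", call. = FALSE)
  v <- numeric(n)
  v[2:(n - 1)] <- (theta[3:n] - theta[1:(n - 2)]) * rate / 2
  v[1] <- (theta[2] - theta[1]) * rate
  v[n] <- (theta[n] - theta[n - 1]) * rate
  v
}

#' Reaction time from cue and onset indices
#'
#' Duration between the cue and the detected EMG onset, in milliseconds.
#'
#' @param cue_index,onset_index sample indices; `onset_index` must follow
#'   `cue_index`.
#' @param rate EMG sampling rate in Hz.
#' @return reaction time in ms.
#' @export
reaction_time <- function(cue_index, onset_index, rate) {
  if (is.na(onset_index) || onset_index <= cue_index) {
    stop("onset must follow the cue", call. = FALSE)
  }
  (onset_index - cue_index) / rate * 1000
}

#' Per-trial outcome metrics
#'
#' Runs the full per-trial pipeline on one trial record: recomputes onset
#' detection with the real-time rule (using the trial's logged full-rest
#' maximum when available, else the stored rest window), computes the EMG
#' envelope of both channels, extracts 200 ms post-onset activation peaks,
#' peak arm angular velocity over the 1.5 s following the cue (signed,
#' extension positive), and reaction time.
#'
#' Peaks are returned in raw envelope units; percent normalization to the
#' participant's control mean is applied cohort-wide by [compute_metrics()],
#' or can be applied here by passing `control_means`.
#'
#' @param trial a trial record (see [generate_trial()] or [read_dataset()]).
#' @param control_means optional list with elements `agonist` and
#'   `antagonist`: the participant's mean control peaks used for
#'   normalization.
#' @param velocity_window seconds after the cue over which the peak angular
#'   velocity is taken (default 1.5).
#' @return one-row data frame with identifiers, `onset_index`,
#'   `trigger_index` (real-time trigger logged by the generator, if any),
#'   `peak_agonist`, `peak_antagonist` (+ `_norm` columns if normalized),
#'   `peak_angular_velocity` (rad/s), `reaction_time_ms`, and a `flag`
#'   column (`"ok"`, `"missed_trigger"`, or `"no_voluntary_onset"`).
#' @export
trial_metrics <- function(trial, control_means = NULL, velocity_window = 1.5) {
  rate <- trial$emg_rate
  det <- recompute_detection(trial)
  onset <- det$onset_index

  out <- data.frame(
    participant = trial$participant_id,
    condition = trial$condition,
    phase = trial$phase,
    trial = trial$trial,
    order_position = trial$order_position,
    onset_index = NA_integer_,
    trigger_index = if (is.null(trial$trigger_index)) NA_integer_ else
      trial$trigger_index,
    peak_agonist = NA_real_,
    peak_antagonist = NA_real_,
    peak_angular_velocity = NA_real_,
    reaction_time_ms = NA_real_,
    flag = "ok",
    stringsAsFactors = FALSE
  )

  # kinematics do not depend on EMG detection
  vel <- angular_velocity(trial$wrist_xy, trial$elbow_xy, trial$mocap_rate)
  cue_m <- trial$cue_index_mocap
  end_m <- min(length(vel), cue_m + round(velocity_window * trial$mocap_rate))
  out$peak_angular_velocity <- max(vel[cue_m:end_m])

  voluntary <- isTRUE(trial$voluntary)
  if (is.na(onset)) {
    out$flag <- if (voluntary) "missed_trigger" else "no_voluntary_onset"
    return(out)
  }
  out$onset_index <- onset

  env_ag <- emg_envelope(trial$agonist_emg, rate)
  env_an <- emg_envelope(trial$antagonist_emg, rate)
  out$peak_agonist <- peak_activation(env_ag, onset, rate)
  out$peak_antagonist <- peak_activation(env_an, onset, rate)
  if (voluntary && onset > trial$cue_index) {
    out$reaction_time_ms <- reaction_time(trial$cue_index, onset, rate)
  } else if (!voluntary) {
    out$flag <- "no_voluntary_onset"
  }

  if (!is.null(control_means)) {
    out$peak_agonist_norm <-
      normalize_peaks(out$peak_agonist, control_means$agonist)
    out$peak_antagonist_norm <-
      normalize_peaks(out$peak_antagonist, control_means$antagonist)
  }
  out
}

# Recompute onset with the identical real-time rule. The generator logs the
# maximum squared EMG of the full inter-trial rest period (part of which is
# not stored in the trial record); external datasets fall back to the stored
# rest window (last 2 s before the cue when no boundaries are given).
recompute_detection <- function(trial) {
  if (!is.null(trial$rest_max)) {
    rest_max <- trial$rest_max
    threshold <- 1.01 * rest_max
    if (threshold <= 0) threshold <- .Machine$double.eps
  } else {
    rw <- trial$rest_window
    if (is.null(rw)) {
      rw <- c(max(1L, trial$cue_index - 2L * trial$emg_rate),
              trial$cue_index - 1L)
    }
    thr <- compute_threshold(trial$agonist_emg[rw[1]:rw[2]])
    rest_max <- thr$rest_max
    threshold <- thr$threshold
  }
  list(rest_max = rest_max, threshold = threshold,
       onset_index = detect_onset(trial$agonist_emg, threshold,
                                  trial$cue_index))
}

#' Cohort-level tidy metrics table
#'
#' Applies [trial_metrics()] to every trial and normalizes activation peaks
#' per participant and muscle to the mean peak of that participant's
#' pulled-phase control trials.
#'
#' @param trials list of trial records (e.g. `generate_cohort(...)$trials`).
#' @param velocity_window passed to [trial_metrics()].
#' @return data frame, one row per trial, with normalized peak columns
#'   `peak_agonist_norm` and `peak_antagonist_norm` (% of control mean).
#' @export
compute_metrics <- function(trials, velocity_window = 1.5) {
  rows <- lapply(trials, trial_metrics, velocity_window = velocity_window)
  metrics <- data.table::rbindlist(rows)
  normalize_metrics(metrics)
}

# per-participant, per-muscle normalization to the pulled-phase control mean
normalize_metrics <- function(metrics) {
  metrics <- data.table::as.data.table(metrics)
  ctrl <- metrics[metrics$condition == "control" & metrics$phase == "pulled" &
                    metrics$flag == "ok", ]
  if (nrow(ctrl) == 0L) {
    stop("no usable pulled-phase control trials to normalize against",
         call. = FALSE)
  }
  cm <- ctrl[, list(ctrl_agonist = mean(peak_agonist),
                    ctrl_antagonist = mean(peak_antagonist)),
             by = "participant"]
  metrics <- merge(metrics, cm, by = "participant", all.x = TRUE, sort = FALSE)
  metrics$peak_agonist_norm <-
    metrics$peak_agonist * 100 / metrics$ctrl_agonist
  metrics$peak_antagonist_norm <-
    metrics$peak_antagonist * 100 / metrics$ctrl_antagonist
  metrics$ctrl_agonist <- NULL
  metrics$ctrl_antagonist <- NULL
  data.table::setorderv(metrics, c("participant", "trial"))
  as.data.frame(metrics)
}
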