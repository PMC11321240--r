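#' Burst rise time (ms)
#'
#' Default rise time (time-to-peak) of the voluntary activation burst
#' envelope. Set equal to the 200 ms post-onset window in which peak
#' activation is measured, so that the burst peak is always observable
#' inside that window; 200 ms is also a physiologically sensible
#' time-to-peak for a ballistic extension burst.
#' @export
BURST_RISE_TAU_MS <- 200

#' Calibrated burst amplitude (rest-noise units)
#'
#' Default peak amplitude of the voluntary burst, expressed as a multiple of
#' the rest-noise SD. Calibrated by simulation sweep (see
#' `inst/scripts/calibrate_burst_rise_tau.R`) so that, with the default
#' 200 ms rise time, the closed-loop detector fires on rapid-condition
#' trials with a mean latency of about 23 ms after the true activation
#' onset.
#' @export
BURST_AMPLITUDE_DEFAULT <- 3.65

#' Default per-condition effect parameters
#'
#' Multiplicative condition effects on the agonist activation peak, the
#' antagonist activation peak and the peak arm angular velocity, plus an
#' additive reaction-time offset in ms. The control condition is the
#' reference (all multipliers 1, offset 0); the passive row carries neutral
#' multipliers because its voluntary burst and arm extension are suppressed
#' entirely.
#'
#' @return data frame with columns `condition`, `agonist`, `antagonist`,
#'   `velocity`, `rt_offset_ms`.
#' @export
default_condition_effects <- function() {
  data.frame(
    condition = CONDITION_NAMES,
    agonist    = c(1, 1.6897, 1.3160, 1.8191, 1.9211, 1),
    antagonist = c(1, 1.20,   1.20,   2.0035, 1.8581, 1),
    velocity   = c(1, 1.38,   1.20,   0.6049, 0.6140, 1),
    rt_offset_ms = c(0, -22.8, 0, 0, 22.7, 0),
    stringsAsFactors = FALSE
  )
}

#' Null condition effects (for calibration runs)
#'
#' All multipliers 1 and all reaction-time offsets 0: no condition effect on
#' any outcome. Used to check the type-I error of the downstream tests.
#' @return data frame in the format of [default_condition_effects()].
#' @export
null_condition_effects <- function() {
  eff <- default_condition_effects()
  eff$agonist <- 1; eff$antagonist <- 1; eff$velocity <- 1
  eff$rt_offset_ms <- 0
  eff
}

#' Generator parameters for synthetic cohorts
#'
#' Bundles every constant of the synthetic experiment. Defaults reproduce the
#' study conditions: 14 participants, 200 Hz motion capture, ~180 ms reaction
#' times, a 40 ms electromechanical delay, and condition effects equal to the
#' default effect table.
#'
#' @param n_participants cohort size.
#' @param emg_rate EMG sampling rate (Hz).
#' @param mocap_rate marker sampling rate (Hz).
#' @param pre_cue,post_cue stored seconds of signal before / after each cue.
#' @param reaction_mean,reaction_sd voluntary reaction time distribution (ms).
#' @param emd electromechanical delay between activation and movement onset
#'   (ms).
#' @param rest_noise_sd SD of rest EMG noise (arbitrary EMG units).
#' @param burst_amplitude peak SD of the voluntary burst modulation (same
#'   units); the default is calibrated to the closed-loop trigger latency
#'   (see [BURST_AMPLITUDE_DEFAULT]).
#' @param burst_rise_tau_ms burst envelope rise time (ms); see
#'   [BURST_RISE_TAU_MS].
#' @param antagonist_fraction antagonist burst amplitude relative to agonist.
#' @param condition_effects per-condition effect table (see
#'   [default_condition_effects()]).
#' @param between_participant_sd lognormal SD of the participant-level EMG
#'   amplitude scale.
#' @param velocity_peak peak voluntary arm angular velocity (rad/s).
#' @param velocity_width width (Gaussian SD, s) of the bell-shaped voluntary
#'   velocity profile.
#' @param velocity_sdlog lognormal SD of the participant-level velocity scale.
#' @param forearm_length wrist-to-elbow distance (m).
#' @param pull_gain arm angular speed contributed by an actuator pull
#'   (rad/s); the default makes passive-pull peak velocity comparable to the
#'   perturbation conditions.
#' @param passive_pull_delay seconds after the cue at which the passive-block
#'   pull is released (there is no voluntary EMG to trigger from).
#' @param marker_noise_sd optional Gaussian noise SD added to marker
#'   positions (m); 0 = noise-free markers.
#' @param include_passive add the passive block to every session.
#' @param seed integer master seed; every random draw in the cohort derives
#'   from it.
#' @return list of class `generator_params`.
#' @export
generator_params <- function(n_participants = 14,
                             emg_rate = 2000,
                             mocap_rate = 200,
                             pre_cue = 2.5,
                             post_cue = 3.0,
                             reaction_mean = 180,
                             reaction_sd = 25,
                             emd = 40,
                             rest_noise_sd = 1,
                             burst_amplitude = BURST_AMPLITUDE_DEFAULT,
                             burst_rise_tau_ms = BURST_RISE_TAU_MS,
                             antagonist_fraction = 1,
                             condition_effects = default_condition_effects(),
                             between_participant_sd = 0.25,
                             velocity_peak = 6,
                             velocity_width = 0.15,
                             velocity_sdlog = 0.1,
                             forearm_length = 0.25,
                             pull_gain = 3.6,
                             passive_pull_delay = 0.22,
                             marker_noise_sd = 0,
                             include_passive = FALSE,
                             seed = 1L) {
  p <- list(n_participants = n_participants, emg_rate = emg_rate,
            mocap_rate = mocap_rate, pre_cue = pre_cue, post_cue = post_cue,
            reaction_mean = reaction_mean, reaction_sd = reaction_sd,
            emd = emd, rest_noise_sd = rest_noise_sd,
            burst_amplitude = burst_amplitude,
            burst_rise_tau_ms = burst_rise_tau_ms,
            antagonist_fraction = antagonist_fraction,
            condition_effects = condition_effects,
            between_participant_sd = between_participant_sd,
            velocity_peak = velocity_peak, velocity_width = velocity_width,
            velocity_sdlog = velocity_sdlog,
            forearm_length = forearm_length, pull_gain = pull_gain,
            passive_pull_delay = passive_pull_delay,
            marker_noise_sd = marker_noise_sd,
            include_passive = include_passive, seed = as.integer(seed))
  validate_generator_params(p)
  class(p) <- "generator_params"
  p
}

validate_generator_params <- function(p) {
  pos <- c("emg_rate", "mocap_rate", "pre_cue", "post_cue", "reaction_mean",
           "reaction_sd", "rest_noise_sd", "burst_amplitude",
           "burst_rise_tau_ms", "antagonist_fraction", "velocity_peak",
           "velocity_width", "forearm_length", "pull_gain")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0) {
      stop("generator parameter '", f, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (p$n_participants < 1) stop("need at least one participant", call. = FALSE)
  eff <- p$condition_effects
  need <- c("condition", "agonist", "antagonist", "velocity", "rt_offset_ms")
  if (!all(need %in% names(eff))) {
    stop("condition_effects must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(CONDITION_NAMES %in% eff$condition)) {
    stop("condition_effects must cover all six conditions", call. = FALSE)
  }
  mult <- as.matrix(eff[, c("agonist", "antagonist", "velocity")])
  if (any(!is.finite(mult)) || any(mult <= 0)) {
    stop("condition-effect multipliers must be positive", call. = FALSE)
  }
  ctl <- eff[eff$condition == "control", ]
  if (any(c(ctl$agonist, ctl$antagonist, ctl$velocity) != 1) ||
      ctl$rt_offset_ms != 0) {
    stop("control condition effects must be exactly neutral", call. = FALSE)
  }
  invisible(p)
}

#' Voluntary activation burst envelope
#'
#' Unimodal gamma-shaped envelope of the voluntary activation burst:
#' `(t/tau) * exp(1 - t/tau) * amplitude` for `t >= 0`, and 0 before onset.
#' The peak equals `amplitude` and occurs at `t = tau`.
#'
#' @param t_since_onset time since activation onset (ms); may be a vector.
#' @param amplitude envelope peak (arbitrary EMG units).
#' @param rise_tau rise time (ms), > 0.
#' @return envelope values, same length as `t_since_onset`.
#' @export
burst_envelope <- function(t_since_onset, amplitude, rise_tau) {
  if (!is.numeric(rise_tau) || length(rise_tau) != 1L || rise_tau <= 0) {
    stop("rise_tau must be a positive number", call. = FALSE)
  }
  ifelse(t_since_onset < 0, 0,
         (t_since_onset / rise_tau) * exp(1 - t_since_onset / rise_tau) *
           amplitude)
}

# Exact draw of the maximum squared sample over the unstored part of the rest
# period: max of n iid N(0, sd)^2 has CDF F(x)^n, so a single inverse-CDF
# draw replaces simulating n samples.
sample_rest_max <- function(n, sd) {
  if (n <= 0L) return(0)
  u <- stats::runif(1)
  sd^2 * stats::qchisq(exp(log(u) / n), df = 1)
}

#' Generate one closed-loop synthetic trial
#'
#' Simulates a single cued arm extension: rest EMG noise plus (for voluntary
#' conditions) burst-modulated noise on both channels starting one
#' reaction-time draw after the cue; the real-time onset detector is run on
#' the agonist stream against the 1%-above-rest-maximum threshold; if it
#' fires on a pulled-phase trial the condition's pull command is issued and
#' its actuator contribution added to the arm kinematics. Wrist and elbow
#' markers are synthesized from the integrated arm angle at fixed forearm
#' length in the transverse plane.
#'
#' Draws come from the current RNG state; seed management belongs to
#' [generate_participant()] / [generate_cohort()].
#'
#' @param params `generator_params`.
#' @param spec one-row condition spec ([condition_spec()]).
#' @param phase `"pre"`, `"pulled"` or `"post"`; pulls only occur in the
#'   pulled phase.
#' @param cue_gap seconds since the previous cue (sets the rest-period
#'   length used for the detection threshold).
#' @param participant_scale participant-level EMG amplitude multiplier.
#' @param velocity_scale participant-level velocity multiplier.
#' @return trial record: a list of class `emd_trial` holding the stored EMG
#'   window (from `pre_cue` s before to `post_cue` s after the cue), marker
#'   trajectories, cue/true-onset/trigger indices, the logged rest maximum
#'   and threshold, the pull command (or `NULL`) and bookkeeping fields.
#' @export
generate_trial <- function(params, spec, phase = "pulled", cue_gap = 10,
                           participant_scale = 1, velocity_scale = 1) {
  rate <- params$emg_rate
  n_emg <- round((params$pre_cue + params$post_cue) * rate)
  cue_index <- round(params$pre_cue * rate) + 1L
  eff <- params$condition_effects
  eff <- eff[eff$condition == spec$name, ]

  agonist <- stats::rnorm(n_emg, 0, params$rest_noise_sd)
  antagonist <- stats::rnorm(n_emg, 0, params$rest_noise_sd)

  true_onset <- NA_integer_
  rt_ms <- NA_real_
  if (spec$voluntary) {
    rt_ms <- stats::rnorm(1, params$reaction_mean + eff$rt_offset_ms,
                          params$reaction_sd)
    rt_ms <- max(rt_ms, 50) # physiological floor
    true_onset <- cue_index + as.integer(round(rt_ms / 1000 * rate))
    idx <- true_onset:n_emg
    t_ms <- (idx - true_onset) / rate * 1000
    env_ag <- burst_envelope(
      t_ms, params$burst_amplitude * participant_scale * eff$agonist,
      params$burst_rise_tau_ms)
    agonist[idx] <- agonist[idx] + stats::rnorm(length(idx)) * env_ag
    env_an <- burst_envelope(
      t_ms, params$burst_amplitude * params$antagonist_fraction *
        participant_scale * eff$antagonist,
      params$burst_rise_tau_ms)
    antagonist[idx] <- antagonist[idx] + stats::rnorm(length(idx)) * env_an
  }

  # threshold over the full rest period: stored pre-cue window plus an exact
  # max draw for the unstored remainder of the inter-cue interval
  rest_len_s <- max(params$pre_cue, cue_gap - params$post_cue)
  n_extra <- round((rest_len_s - params$pre_cue) * rate)
  stored_max <- max(agonist[1:(cue_index - 1L)]^2)
  rest_max <- max(stored_max, sample_rest_max(n_extra, params$rest_noise_sd))
  threshold <- max(1.01 * rest_max, .Machine$double.eps)

  trigger <- detect_onset(agonist, threshold, cue_index)

  pull <- NULL
  if (phase == "pulled" && spec$direction != 0L) {
    if (spec$voluntary) {
      if (!is.na(trigger)) {
        pull <- make_pull_command(spec, (trigger - 1L) / rate)
      }
    } else {
      pull <- make_pull_command(spec, params$pre_cue +
                                  params$passive_pull_delay)
    }
  }
  missed <- isTRUE(spec$voluntary) && phase == "pulled" &&
    spec$direction != 0L && is.na(trigger)

  # kinematics at mocap rate on the same local time base (t = 0 at window
  # start, cue at pre_cue seconds)
  n_m <- round((params$pre_cue + params$post_cue) * params$mocap_rate)
  t_m <- (seq_len(n_m) - 1L) / params$mocap_rate
  v <- numeric(n_m)
  if (spec$voluntary) {
    t_mov <- (true_onset - 1L) / rate + params$emd / 1000
    lead <- 2.5 * params$velocity_width
    vpeak <- params$velocity_peak * velocity_scale * eff$velocity
    bell <- vpeak * exp(-((t_m - t_mov - lead)^2) /
                          (2 * params$velocity_width^2))
    v <- v + ifelse(t_m >= t_mov, bell, 0)
  }
  if (!is.null(pull)) {
    active <- t_m >= pull$start_time & t_m < pull$start_time + pull$duration
    v <- v + pull$direction * params$pull_gain * active
  }
  theta <- c(0, cumsum((v[-1] + v[-n_m]) / 2)) / params$mocap_rate
  wrist <- params$forearm_length * cbind(cos(theta), sin(theta))
  elbow <- matrix(0, n_m, 2)
  if (params$marker_noise_sd > 0) {
    wrist <- wrist + stats::rnorm(2 * n_m, 0, params$marker_noise_sd)
    elbow <- elbow + stats::rnorm(2 * n_m, 0, params$marker_noise_sd)
  }

  structure(list(
    participant_id = NA_character_,
    condition = spec$name,
    phase = phase,
    trial = NA_integer_,
    order_position = NA_integer_,
    cue_time = NA_real_,
    emg_rate = rate,
    mocap_rate = params$mocap_rate,
    cue_index = cue_index,
    cue_index_mocap = round(params$pre_cue * params$mocap_rate) + 1L,
    agonist_emg = agonist,
    antagonist_emg = antagonist,
    wrist_xy = wrist,
    elbow_xy = elbow,
    pull = pull,
    true_onset_index = true_onset,
    rt_true_ms = rt_ms,
    rest_window = c(1L, cue_index - 1L),
    rest_max = rest_max,
    threshold = threshold,
    trigger_index = trigger,
    voluntary = isTRUE(spec$voluntary),
    missed_trigger = missed
  ), class = "emd_trial")
}

#' Generate one participant's session
#'
#' Draws the participant's amplitude and velocity scales, schedules the
#' session, and simulates every trial in schedule order.
#'
#' @param params `generator_params`.
#' @param participant_id identifier.
#' @param seed participant-level seed (derived from the cohort seed by
#'   [generate_cohort()]).
#' @param phases phases to simulate (default all three); restricting to
#'   `"pulled"` skips trials that the condition-contrast analysis never uses.
#' @return list with `plan` (the session plan, all phases) and `trials`
#'   (list of trial records for the requested phases).
#' @export
generate_participant <- function(params, participant_id, seed,
                                 phases = c("pre", "pulled", "post")) {
  set.seed(as.integer(seed))
  scale <- exp(stats::rnorm(1, 0, params$between_participant_sd))
  vel_scale <- exp(stats::rnorm(1, 0, params$velocity_sdlog))
  plan <- schedule_session(participant_id, params$include_passive, seed = NULL)
  gaps <- diff(c(0, plan$cue_time))
  keep <- plan$phase %in% phases
  trials <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    spec <- condition_spec(plan$condition[i])
    tr <- generate_trial(params, spec, plan$phase[i], gaps[i],
                         participant_scale = scale,
                         velocity_scale = vel_scale)
    tr$participant_id <- participant_id
    tr$trial <- plan$trial[i]
    tr$order_position <- plan$order_position[i]
    tr$cue_time <- plan$cue_time[i]
    j <- j + 1L
    trials[[j]] <- tr
  }
  list(plan = plan, trials = trials)
}

participant_ids <- function(n) sprintf("P%02d", seq_len(n))

# one participant seed per participant, all derived from the master seed
derive_participant_seeds <- function(params) {
  set.seed(params$seed)
  sample.int(.Machine$integer.max - 1L, params$n_participants)
}

#' Generate a full synthetic cohort
#'
#' Simulates `n_participants` complete sessions. Fully reproducible: the same
#' `params$seed` yields a bit-identical cohort.
#'
#' @param params `generator_params`.
#' @param phases phases to simulate per participant (default all).
#' @return list of class `emd_cohort` with `params`, `plans` (stacked session
#'   plans) and `trials` (flat list of trial records).
#' @export
generate_cohort <- function(params = generator_params(),
                            phases = c("pre", "pulled", "post")) {
  seeds <- derive_participant_seeds(params)
  ids <- participant_ids(params$n_participants)
  sessions <- mapply(function(id, s) {
    generate_participant(params, id, s, phases = phases)
  }, ids, seeds, SIMPLIFY = FALSE)
  structure(list(
    params = params,
    plans = do.call(rbind, lapply(sessions, `[[`, "plan")),
    trials = do.call(c, lapply(sessions, `[[`, "trials"))
  ), class = "emd_cohort")
}

#' Simulate a cohort and return per-trial metrics (streaming)
#'
#' Memory-flat equivalent of `compute_metrics(generate_cohort(params)$trials)`
#' restricted to the requested phases: each trial's signals are discarded as
#' soon as its metrics are computed. With `phases = "pulled"` (the default)
#' only the trials entering the condition-contrast analysis are simulated.
#'
#' @param params `generator_params`.
#' @param phases phases to simulate and measure.
#' @return tidy metrics data frame (see [compute_metrics()]).
#' @export
simulate_metrics <- function(params = generator_params(), phases = "pulled") {
  seeds <- derive_participant_seeds(params)
  ids <- participant_ids(params$n_participants)
  parts <- vector("list", params$n_participants)
  for (k in seq_len(params$n_participants)) {
    sess <- generate_participant(params, ids[k], seeds[k], phases = phases)
    rows <- lapply(sess$trials, trial_metrics)
    parts[[k]] <- data.table::rbindlist(rows)
  }
  normalize_metrics(data.table::rbindlist(parts))
}

#' Detection latency on rapid-condition trials
#'
#' Simulates independent pulled-phase trials of the rapid conditions and
#' returns the per-trial latency between the generator's true activation
#' onset and the real-time trigger, in ms. Participant amplitude scales are
#' redrawn per trial from the cohort distribution.
#'
#' @param params `generator_params`.
#' @param n_trials number of trials (split evenly across `conditions`).
#' @param conditions condition names to simulate.
#' @param seed seed for this simulation.
#' @return data frame with `condition`, `latency_ms` (NA if the detector
#'   never fired) and `fired`.
#' @export
simulate_detection_latency <- function(params = generator_params(),
                                       n_trials = 1000,
                                       conditions = c("rapid_assist",
                                                      "rapid_perturb"),
                                       seed = params$seed) {
  set.seed(as.integer(seed))
  conds <- rep_len(conditions, n_trials)
  lat <- numeric(n_trials)
  fired <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    scale <- exp(stats::rnorm(1, 0, params$between_participant_sd))
    gap <- stats::runif(1, 5, 15)
    tr <- generate_trial(params, condition_spec(conds[i]), "pulled", gap,
                         participant_scale = scale)
    fired[i] <- !is.na(tr$trigger_index)
    lat[i] <- if (fired[i]) {
      (tr$trigger_index - tr$true_onset_index) / params$emg_rate * 1000
    } else NA_real_
  }
  data.frame(condition = conds, latency_ms = lat, fired = fired,
             stringsAsFactors = FALSE)
}
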