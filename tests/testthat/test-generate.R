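test_that("burst envelope is causal, unimodal, and peaks at tau", {
  A <- 4; tau <- 200
  expect_equal(burst_envelope(-5, A, tau), 0)
  expect_equal(burst_envelope(0, A, tau), 0)
  expect_equal(burst_envelope(tau, A, tau), A)
  # closed form at 10 tau
  expect_equal(burst_envelope(10 * tau, A, tau), A * 10 * exp(-9))
  t <- seq(0, 5 * tau, by = 1)
  env <- burst_envelope(t, A, tau)
  expect_equal(max(env), A)
  expect_equal(t[which.max(env)], tau)
  expect_error(burst_envelope(10, A, 0), "positive")
  expect_error(burst_envelope(10, A, -3), "positive")
})

test_that("generator parameter validation rejects broken configurations", {
  expect_error(generator_params(emg_rate = -1), "positive")
  expect_error(generator_params(burst_rise_tau_ms = 0), "positive")
  eff <- default_condition_effects()
  eff$agonist[eff$condition == "control"] <- 2
  expect_error(generator_params(condition_effects = eff), "neutral")
  eff2 <- default_condition_effects()
  eff2$velocity[2] <- -1
  expect_error(generator_params(condition_effects = eff2), "positive")
  expect_error(generator_params(condition_effects = data.frame(a = 1)),
               "columns")
})

test_that("default condition effects encode the calibrated study effects", {
  eff <- default_condition_effects()
  g <- function(cn, col) eff[eff$condition == cn, col]
  expect_equal(g("control", "agonist"), 1)
  expect_equal(g("rapid_assist", "agonist"), 1.6897)
  expect_equal(g("rapid_perturb", "agonist"), 1.8191)
  expect_equal(g("delayed_perturb", "agonist"), 1.9211)
  # delayed assist backed out of the delayed_perturb-vs-delayed_assist gap
  expect_equal(g("delayed_assist", "agonist"), 1.9211 / 1.4598,
               tolerance = 2e-4)
  expect_equal(g("rapid_perturb", "antagonist"), 2.0035)
  expect_equal(g("delayed_perturb", "antagonist"), 1.8581)
  expect_equal(g("rapid_perturb", "velocity"), 1 - 0.3951)
  expect_equal(g("delayed_perturb", "velocity"), 1 - 0.386)
  # the single printed reaction-time contrast split across the two arms
  expect_equal(g("delayed_perturb", "rt_offset_ms") -
                 g("rapid_assist", "rt_offset_ms"), 45.5)
  null <- null_condition_effects()
  expect_true(all(null$agonist == 1 & null$antagonist == 1 &
                    null$velocity == 1 & null$rt_offset_ms == 0))
})

test_that("closed-loop trials wire the trigger into the pull command", {
  set.seed(14)
  p <- generator_params()
  # control: no pull, voluntary extension still positive
  tr_c <- generate_trial(p, condition_spec("control"), "pulled", 10)
  expect_null(tr_c$pull)
  vel <- angular_velocity(tr_c$wrist_xy, tr_c$elbow_xy, p$mocap_rate)
  expect_gt(max(vel), 0)
  expect_gt(tr_c$true_onset_index, tr_c$cue_index)
  # rapid assist: pull launches at the trigger, before movement onset
  tr_a <- generate_trial(p, condition_spec("rapid_assist"), "pulled", 10)
  expect_false(is.null(tr_a$pull))
  t_move <- (tr_a$true_onset_index - 1) / p$emg_rate + p$emd / 1000
  expect_lt(tr_a$pull$start_time, t_move)
  # delayed conditions add 40 ms to the trigger time
  tr_d <- generate_trial(p, condition_spec("delayed_perturb"), "pulled", 10)
  expect_equal(tr_d$pull$start_time,
               (tr_d$trigger_index - 1) / p$emg_rate + 0.040)
  # pre-phase trials of pulled conditions receive no pull
  tr_pre <- generate_trial(p, condition_spec("rapid_assist"), "pre", 10)
  expect_null(tr_pre$pull)
})

test_that("passive trials have a pull but no voluntary activity", {
  set.seed(15)
  p <- generator_params()
  tr <- generate_trial(p, condition_spec("passive"), "pulled", 10)
  expect_true(is.na(tr$true_onset_index))
  expect_false(is.null(tr$pull))
  expect_equal(tr$pull$direction, 1L)
  # agonist stays at rest level: envelope peak near the rest-only level
  env <- emg_envelope(tr$agonist_emg, p$emg_rate)
  post <- env[tr$cue_index:(tr$cue_index + 2000)]
  rest <- env[1000:(tr$cue_index - 1000)]
  expect_lt(max(post), 5 * max(rest))
  # passive pull peak velocity is comparable to perturb-condition peaks
  vel <- angular_velocity(tr$wrist_xy, tr$elbow_xy, p$mocap_rate)
  expect_equal(max(vel), p$pull_gain, tolerance = 0.15)
})

test_that("trial record geometry is internally consistent", {
  set.seed(16)
  p <- generator_params()
  tr <- generate_trial(p, condition_spec("rapid_assist"), "pulled", 10)
  expect_length(tr$agonist_emg,
                round((p$pre_cue + p$post_cue) * p$emg_rate))
  expect_length(tr$antagonist_emg, length(tr$agonist_emg))
  expect_equal(nrow(tr$wrist_xy),
               round((p$pre_cue + p$post_cue) * p$mocap_rate))
  expect_equal(tr$rest_window, c(1L, tr$cue_index - 1L))
  expect_gt(tr$true_onset_index, tr$cue_index)
  # threshold honors the 1% rule over the logged rest maximum
  expect_equal(tr$threshold, 1.01 * tr$rest_max)
  expect_gte(tr$rest_max, max(tr$agonist_emg[1:(tr$cue_index - 1)]^2))
  # forearm length is preserved at every sample
  r <- sqrt(rowSums((tr$wrist_xy - tr$elbow_xy)^2))
  expect_equal(r, rep(p$forearm_length, length(r)), tolerance = 1e-12)
})

test_that("cohorts are reproducible and sized by the protocol", {
  p <- tiny_params()
  coh <- generate_cohort(p)
  expect_equal(length(coh$trials), 2 * 250L)
  expect_equal(nrow(coh$plans), 2 * 250L)
  coh2 <- generate_cohort(p)
  expect_identical(coh$trials[[37]]$agonist_emg,
                   coh2$trials[[37]]$agonist_emg)
  expect_identical(coh$plans$cue_time, coh2$plans$cue_time)
  # passive block appended last for every participant
  p6 <- tiny_params(include_passive = TRUE)
  coh6 <- generate_cohort(p6, phases = "pulled")
  per <- split(vapply(coh6$trials, `[[`, "", "condition"),
               vapply(coh6$trials, `[[`, "", "participant_id"))
  for (conds in per) {
    expect_length(conds, 6 * 30L)
    expect_equal(unname(conds[151:180]), rep("passive", 30))
  }
})

test_that("missed triggers are rare and flagged, not dropped", {
  lat <- simulate_detection_latency(generator_params(), n_trials = 400,
                                    seed = 3)
  expect_lt(mean(!lat$fired), 0.01)
  # a hopeless SNR produces flagged, metric-less records
  p_bad <- generator_params(burst_amplitude = 0.05)
  set.seed(4)
  tr <- generate_trial(p_bad, condition_spec("rapid_assist"), "pulled", 10)
  if (is.na(tr$trigger_index)) {
    expect_true(tr$missed_trigger)
    m <- trial_metrics(tr)
    expect_equal(m$flag, "missed_trigger")
    expect_true(is.na(m$peak_agonist))
  }
})

test_that("control reaction times match the generator distribution", {
  p <- generator_params(n_participants = 4, seed = 33)
  coh <- generate_cohort(p, phases = "pulled")
  is_ctl <- vapply(coh$trials, `[[`, "", "condition") == "control"
  rt_true <- vapply(coh$trials[is_ctl], `[[`, 0, "rt_true_ms")
  expect_length(rt_true, 4 * 30L)
  se <- stats::sd(rt_true) / sqrt(length(rt_true))
  expect_lt(abs(mean(rt_true) - p$reaction_mean), 3 * se)
  # measured reaction time = true reaction time + detection latency > truth
  metrics <- compute_metrics(coh$trials)
  rt_meas <- metrics$reaction_time_ms[metrics$condition == "control"]
  expect_gt(mean(rt_meas, na.rm = TRUE), mean(rt_true))
  expect_lt(mean(rt_meas, na.rm = TRUE), mean(rt_true) + p$emd + 10)
})
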