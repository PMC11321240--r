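# small generator configurations used across tests
tiny_params <- function(...) {
  generator_params(n_participants = 2, seed = 7L, ...)
}

# outcome-level null simulator for calibration checks: participant random
# intercepts plus residual noise, no condition or order effect
simulate_null_outcome_table <- function(n_participants = 14,
                                        trials_per_cell = 5,
                                        sd_participant = 10,
                                        sd_resid = 20) {
  conds <- c("control", "rapid_assist", "delayed_assist",
             "rapid_perturb", "delayed_perturb")
  ids <- sprintf("P%02d", seq_len(n_participants))
  intercepts <- stats::rnorm(n_participants, 100, sd_participant)
  rows <- expand.grid(participant = ids, condition = conds,
                      rep = seq_len(trials_per_cell),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # each participant sees the conditions in a random order
  ord <- t(vapply(ids, function(i) sample(5), integer(5)))
  rows$order_position <-
    ord[cbind(match(rows$participant, ids), match(rows$condition, conds))]
  rows$value <- intercepts[match(rows$participant, ids)] +
    stats::rnorm(nrow(rows), 0, sd_resid)
  data.frame(participant = factor(rows$participant),
             condition = factor(rows$condition, levels = conds),
             order_position = as.numeric(rows$order_position),
             value = rows$value)
}
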