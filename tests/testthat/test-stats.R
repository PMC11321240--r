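make_metrics_stub <- function(n_participants = 6, trials = 8,
                              cond_shift = c(control = 0, rapid_assist = 0,
                                             delayed_assist = 0,
                                             rapid_perturb = 0,
                                             delayed_perturb = 0),
                              sd_participant = 5, sd_resid = 10) {
  conds <- names(cond_shift)
  ids <- sprintf("P%02d", seq_len(n_participants))
  base <- stats::rnorm(n_participants, 100, sd_participant)
  rows <- expand.grid(participant = ids, condition = conds,
                      trial = seq_len(trials), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  ord <- t(vapply(ids, function(i) sample(5), integer(5)))
  rows$order_position <-
    ord[cbind(match(rows$participant, ids), match(rows$condition, conds))]
  rows$phase <- "pulled"
  val <- base[match(rows$participant, ids)] +
    cond_shift[rows$condition] + stats::rnorm(nrow(rows), 0, sd_resid)
  rows$peak_agonist_norm <- val
  rows$peak_antagonist_norm <- val
  rows$peak_angular_velocity <- val / 20
  rows$reaction_time_ms <- 180 + val - 100
  rows
}

test_that("outcome tables keep pulled-phase non-passive trials only", {
  set.seed(1)
  m <- make_metrics_stub()
  m$phase[1:5] <- "pre"
  extra <- m[1:4, ]
  extra$condition <- "passive"
  extra$phase <- "pulled"
  tab <- outcome_table(rbind(m, extra), "agonist")
  expect_equal(nrow(tab), nrow(m) - 5)
  expect_false("passive" %in% tab$condition)
  expect_equal(levels(tab$condition),
               c("control", "rapid_assist", "delayed_assist",
                 "rapid_perturb", "delayed_perturb"))
  one <- m[m$participant == "P01", ]
  expect_error(outcome_table(one, "agonist"), "two participants")
  expect_error(outcome_table(m, "nonexistent"), "no column")
})

test_that("the condition LRT has power and degenerates loudly", {
  set.seed(2)
  m <- make_metrics_stub(cond_shift = c(control = 0, rapid_assist = 60,
                                        delayed_assist = 0,
                                        rapid_perturb = 0,
                                        delayed_perturb = 0))
  tab <- outcome_table(m, "agonist")
  fit <- suppressWarnings(fit_outcome_model(tab))
  expect_equal(fit$lrt_df, 4)
  expect_lt(fit$lrt_p, 0.001)
  expect_equal(fit$n_participants, 6L)
  flat <- tab
  flat$value <- 1
  expect_error(fit_outcome_model(flat), "zero variance")
})

test_that("pairwise contrasts cover all 10 pairs with Holm adjustment", {
  set.seed(3)
  m <- make_metrics_stub(cond_shift = c(control = 0, rapid_assist = 30,
                                        delayed_assist = 10,
                                        rapid_perturb = -10,
                                        delayed_perturb = 20))
  fit <- suppressWarnings(fit_outcome_model(outcome_table(m, "agonist")))
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), choose(5, 2))
  expect_true(all(ct$holm_p >= ct$raw_p))
  expect_equal(ct$holm_p, stats::p.adjust(ct$raw_p, "holm"))
  # Holm never promotes: adjusted-significant set nests in the raw set
  expect_true(all(ct$raw_p[ct$holm_p < 0.05] < 0.05))
  # estimates agree with the EMM differences and are antisymmetric
  emm <- attr(ct, "emmeans")
  e <- stats::setNames(emm$emmean, emm$condition)
  expect_equal(ct$estimate, unname(e[ct$A] - e[ct$B]), tolerance = 1e-8)
  res <- list(agonist = list(contrasts = ct))
  fwd <- get_contrast(res, "agonist", "rapid_assist", "control")
  bwd <- get_contrast(res, "agonist", "control", "rapid_assist")
  expect_equal(fwd$estimate, -bwd$estimate)
})

test_that("percent differences follow the (A - B) / B convention", {
  expect_equal(percent_difference(168.97, 100), 68.97)
  expect_equal(percent_difference(5, 5), 0)
  expect_equal(percent_difference(50, 100), -50)
  expect_error(percent_difference(1, 0), "positive")
  expect_error(percent_difference(1, -2), "positive")
})

test_that("analyze_outcomes fits all four study outcomes", {
  set.seed(4)
  m <- make_metrics_stub(cond_shift = c(control = 0, rapid_assist = 40,
                                        delayed_assist = 5,
                                        rapid_perturb = 15,
                                        delayed_perturb = 25))
  res <- analyze_outcomes(m)
  expect_s3_class(res, "emd_results")
  expect_named(res, c("agonist", "antagonist", "velocity", "reaction_time"))
  for (r in res) {
    expect_equal(nrow(r$contrasts), 10L)
    expect_equal(r$lrt_df, 4)
  }
  out <- capture.output(print(res))
  expect_true(any(grepl("condition LRT", out)))
})
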