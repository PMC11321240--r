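test_that("condition specifications encode the protocol", {
  specs <- condition_specs()
  expect_equal(nrow(specs), 6L)
  expect_setequal(specs$name, c("control", "rapid_assist", "delayed_assist",
                                "rapid_perturb", "delayed_perturb", "passive"))
  ra <- condition_spec("rapid_assist")
  expect_equal(ra$pull_duration, 0.31)
  expect_equal(ra$artificial_delay, 0)
  dp <- condition_spec("delayed_perturb")
  expect_equal(dp$pull_duration, 0.1)
  expect_equal(dp$artificial_delay, 0.040)
  expect_equal(condition_spec("control")$direction, 0L)
  expect_equal(condition_spec("control")$pull_duration, 0)
  # assists pull with extension, perturbs against it
  expect_equal(specs$direction[specs$name %in%
                                 c("rapid_assist", "delayed_assist",
                                   "passive")], c(1L, 1L, 1L))
  expect_equal(specs$direction[specs$name %in%
                                 c("rapid_perturb", "delayed_perturb")],
               c(-1L, -1L))
  expect_false(condition_spec("passive")$voluntary)
  expect_error(condition_spec("sideways"), "unknown condition")
})

test_that("session schedules have the 10/30/10 block structure", {
  plan <- schedule_session("P01", seed = 11)
  expect_s3_class(plan, "session_plan")
  expect_equal(nrow(plan), 250L)
  plan6 <- schedule_session("P01", include_passive = TRUE, seed = 11)
  expect_equal(nrow(plan6), 300L)
  expect_equal(unique(plan6$condition[251:300]), "passive")
  for (p in list(plan, plan6)) {
    for (b in unique(p$block)) {
      blk <- p[p$block == b, ]
      expect_equal(nrow(blk), 50L)
      expect_equal(length(unique(blk$condition)), 1L)
      expect_equal(blk$phase, rep(c("pre", "pulled", "post"),
                                  times = c(10, 30, 10)))
    }
    # five non-passive blocks cover the five conditions exactly once
    first5 <- p$condition[seq(1, 201, by = 50)]
    expect_setequal(first5, c("control", "rapid_assist", "delayed_assist",
                              "rapid_perturb", "delayed_perturb"))
  }
})

test_that("cue intervals stay in [5, 15] s and schedules are seed-determined", {
  plan <- schedule_session("P01", seed = 42)
  gaps <- diff(c(0, plan$cue_time))
  expect_gte(min(gaps), 5)
  expect_lte(max(gaps), 15)
  expect_identical(plan, schedule_session("P01", seed = 42))
  expect_false(identical(plan$cue_time,
                         schedule_session("P01", seed = 43)$cue_time))
})

test_that("condition order is uniform over the 5! permutations", {
  n_seeds <- 10000L
  perm_id <- vapply(seq_len(n_seeds), function(s) {
    plan <- schedule_session("P", seed = s)
    paste(plan$condition[seq(1, 201, by = 50)], collapse = "|")
  }, "")
  counts <- table(perm_id)
  expect_equal(length(counts), 120L)
  chisq <- sum((counts - n_seeds / 120)^2 / (n_seeds / 120))
  p <- stats::pchisq(chisq, df = 119, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("pull commands apply the delay policy", {
  expect_null(make_pull_command(condition_spec("control"), 1.0))
  cmd <- make_pull_command(condition_spec("rapid_assist"), 2.00)
  expect_equal(cmd$start_time, 2.00)
  expect_equal(cmd$duration, 0.31)
  expect_equal(cmd$direction, 1L)
  expect_equal(cmd$angular_speed, 40)
  cmd <- make_pull_command(condition_spec("delayed_perturb"), 2.00)
  expect_equal(cmd$start_time, 2.04)
  expect_equal(cmd$duration, 0.1)
  expect_equal(cmd$direction, -1L)
})

test_that("session plans round-trip through CSV", {
  plan <- schedule_session("P03", seed = 5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_session_plan(plan, path)
  back <- read_session_plan(path)
  expect_equal(as.data.frame(back), as.data.frame(plan), tolerance = 1e-12)
})
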