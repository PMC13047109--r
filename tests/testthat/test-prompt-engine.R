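test_that("SRH schedules keep 5-9 day gaps and the expected count", {
  for (seed in 1:25) {
    st <- participant_state("A", seed = seed)
    pr <- schedule_srh(st, 84)
    gaps <- diff(pr$issued_at) / 1440
    expect_true(all(gaps >= 5 & gaps <= 9))
    expect_true(all(gaps == round(gaps)))
    expect_gte(nrow(pr), ceiling(84 / 9))
    expect_lte(nrow(pr), ceiling(84 / 5))
    expect_true(all(pr$expires_at - pr$issued_at == 2880))
  }
  # determinism
  a <- schedule_srh(participant_state("A", seed = 3), 84)
  b <- schedule_srh(participant_state("A", seed = 3), 84)
  expect_identical(a$issued_at, b$issued_at)
  # horizon shorter than the minimum gap still issues the first prompt
  short <- schedule_srh(participant_state("A", seed = 1), 4)
  expect_equal(nrow(short), 1)
})

test_that("SRH responses trigger the right prompts", {
  st <- participant_state("A", seed = 1)
  sel <- new_rng_stream(42)

  fair <- process_srh_response(st, survey_response("srh", "fair", time = 0))
  expect_setequal(fair$modality, c("symptom", "watch"))
  expect_true(all(fair$provenance == "srh_triggered"))
  expect_equal(st$last_srh_level, "fair")

  # good-or-better: watch prompt iff the seeded draw falls under p
  draws <- vapply(1:200, function(i) {
    s2 <- participant_state("A", seed = 1)
    r <- process_srh_response(s2, survey_response("srh", "good", time = 0),
                              p_random_watch = 0.5,
                              selection_stream = new_rng_stream(i))
    nrow(r)
  }, 0L)
  expect_true(all(draws %in% c(0L, 1L)))
  expect_gt(mean(draws), 0.35)
  expect_lt(mean(draws), 0.65)
  # p = 0 never issues, p = 1 always issues
  s0 <- participant_state("A", seed = 1)
  expect_equal(nrow(process_srh_response(
    s0, survey_response("srh", "excellent", time = 0),
    p_random_watch = 0, selection_stream = new_rng_stream(9))), 0)
  expect_equal(process_srh_response(
    s0, survey_response("srh", "excellent", time = 0),
    p_random_watch = 1, selection_stream = new_rng_stream(9))$provenance,
    "random_selection")

  expect_error(process_srh_response(
    st, survey_response("symptom", item_grades = c(0, 1), time = 0)),
    class = "remotewear_type_error")
})

test_that("symptom follow-up chains open at grade >= 2 and close at <= 1", {
  st <- participant_state("A", seed = 1)
  process_symptom_response(st, survey_response("symptom",
                                               item_grades = c(1, 2, 0),
                                               time = 1000),
                           prompt_issued_at = 500)
  expect_true(st$followup_open)
  expect_equal(st$followup_due, 500 + 3 * 1440)

  process_symptom_response(st, survey_response("symptom",
                                               item_grades = c(1, 1, 0),
                                               time = 2000))
  expect_false(st$followup_open)

  expect_error(survey_response("symptom", item_grades = c(0, 4)),
               class = "remotewear_validation_error")

  # chain 3 -> 2 -> 1: exactly two follow-ups then closure
  st2 <- participant_state("B", seed = 1)
  n_follow <- 0
  t_issue <- 0
  for (g in c(3, 2, 1)) {
    process_symptom_response(st2, survey_response(
      "symptom", item_grades = c(g, 0), time = t_issue + 600),
      prompt_issued_at = t_issue)
    if (st2$followup_open) {
      n_follow <- n_follow + 1
      t_issue <- st2$followup_due
    }
  }
  expect_equal(n_follow, 2)
  expect_false(st2$followup_open)
})

test_that("weekly scale prompts are issued every 7 days with 48-h expiry", {
  st <- participant_state("A", seed = 1)
  pr <- schedule_scale(st, 84)
  expect_equal(nrow(pr), 12)
  expect_equal(diff(pr$issued_at), rep(7 * 1440, 11))
  expect_true(all(pr$expires_at - pr$issued_at == 2880))
  expect_equal(nrow(schedule_scale(participant_state("B", 1), 6)), 1)
})

test_that("expiry is exact at +48 h with device failures attributed", {
  mk <- function(completed_at = NA_real_) {
    data.frame(participant_id = "A", prompt_id = "A-1", modality = "watch",
               provenance = "scheduled", issued_at = 0, expires_at = 2880,
               status = "pending", completed_at = completed_at)
  }
  # uncompleted past expiry -> expired
  expect_equal(expire_and_resolve(mk(), now = 2880)$status, "expired")
  # still open before expiry
  expect_equal(expire_and_resolve(mk(), now = 2879)$status, "pending")
  # completion at exactly +48 h counts (inclusive)
  expect_equal(expire_and_resolve(mk(2880))$status, "completed")
  expect_equal(expire_and_resolve(mk(2874))$status, "completed")
  # completion after expiry rejected with an audit note
  late <- expire_and_resolve(mk(2881), now = 1e9)
  expect_equal(late$status, "expired")
  expect_length(attr(late, "audit"), 1)
  # overlapping device failure -> device_failed
  fl <- data.frame(participant_id = "A", start = 100, end = 4000,
                   modality = "watch")
  expect_equal(expire_and_resolve(mk(), now = 1e9,
                                  device_failures = fl)$status,
               "device_failed")
  # failure of a different device leaves the prompt expired
  fl2 <- data.frame(participant_id = "A", start = 100, end = 4000,
                    modality = "scale")
  expect_equal(expire_and_resolve(mk(), now = 1e9,
                                  device_failures = fl2)$status, "expired")
})

test_that("simulation limits behave: all-complete and none-complete", {
  coh_all <- generate_cohort(3, behavior = list(
    p_complete = c(srh = 1, symptom = 1, scale = 1, watch = 1),
    p_device_failure = 0))
  led <- run_simulation(coh_all, seed = 2, horizon_days = 28)
  expect_equal(sum(led$prompts$status == "expired"), 0)
  expect_equal(sum(led$prompts$status == "device_failed"), 0)

  coh_none <- generate_cohort(3, behavior = list(
    p_complete = c(srh = 0, symptom = 0, scale = 0, watch = 0),
    p_device_failure = 0))
  led0 <- run_simulation(coh_none, seed = 2, horizon_days = 28)
  expect_equal(sum(led0$prompts$status == "completed"), 0)
})

test_that("simulated ledgers are deterministic and conserved", {
  coh <- generate_cohort(5, seed = 3)
  a <- run_simulation(coh, seed = 3, horizon_days = 56)
  b <- run_simulation(coh, seed = 3, horizon_days = 56)
  expect_identical(a$prompts, b$prompts)

  # independent brute-force recount of the conservation identity
  p <- a$prompts
  for (id in unique(p$participant_id)) {
    for (m in unique(p$modality)) {
      q <- p[p$participant_id == id & p$modality == m, ]
      expect_equal(nrow(q), sum(q$status == "completed") +
                     sum(q$status == "expired") +
                     sum(q$status == "device_failed"))
    }
  }
  # every watch initiation corresponds to a completed watch prompt
  expect_equal(nrow(a$initiations),
               sum(p$modality == "watch" & p$status == "completed"))
})

test_that("prompt provenance traces to a trigger", {
  led <- run_simulation(generate_cohort(6, seed = 9), seed = 9,
                        horizon_days = 84)
  p <- led$prompts
  expect_true(all(p$provenance[p$modality == "symptom"] %in%
                    c("srh_triggered", "symptom_followup")))
  expect_true(all(p$provenance[p$modality == "watch"] %in%
                    c("srh_triggered", "random_selection")))
  # follow-up prompts sit exactly 3 days after the previous chain prompt
  for (id in unique(p$participant_id)) {
    q <- p[p$participant_id == id & p$modality == "symptom", ]
    q <- q[order(q$issued_at), ]
    fu <- which(q$provenance == "symptom_followup")
    for (i in fu) {
      expect_true(any(abs(q$issued_at[i] - q$issued_at[-i] - 4320) < 1e-9))
    }
  }
})

test_that("ledgers round-trip through CSV", {
  led <- run_simulation(generate_cohort(2, seed = 4), seed = 4,
                        horizon_days = 28)
  p <- withr::local_tempfile(fileext = ".csv")
  write_ledger_csv(led, p)
  led2 <- read_ledger_csv(p)
  expect_equal(nrow(led2$prompts), nrow(led$prompts))
  expect_equal(
    completeness_percentages(tabulate_completeness(led2)),
    completeness_percentages(tabulate_completeness(led)))
})
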