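test_that("the pilot ledger reproduces every published completeness cell", {
  counts <- pilot_prompt_counts()
  tab <- tabulate_completeness(pilot_ledger())
  for (i in seq_len(nrow(counts))) {
    id <- counts$participant_id[i]
    for (m in c("srh", "symptom", "scale", "watch")) {
      row <- tab[tab$participant_id == id & tab$modality == m, ]
      expect_equal(row$scheduled, counts[[paste0(m, "_scheduled")]][i],
                   info = paste(id, m))
      expect_equal(row$completed, counts[[paste0(m, "_completed")]][i],
                   info = paste(id, m))
      expect_equal(row$incomplete_participant,
                   counts[[paste0(m, "_incomplete_participant")]][i],
                   info = paste(id, m))
      expect_equal(row$incomplete_device,
                   counts[[paste0(m, "_incomplete_device")]][i],
                   info = paste(id, m))
    }
  }
  tot <- tab[tab$participant_id == "Total", ]
  expect_equal(tot$scheduled[tot$modality == "srh"], 126)
  expect_equal(tot$completed[tot$modality == "srh"], 108)
  expect_equal(tot$scheduled[tot$modality == "symptom"], 53)
  expect_equal(tot$completed[tot$modality == "symptom"], 46)
  expect_equal(tot$scheduled[tot$modality == "scale"], 100)
  expect_equal(tot$completed[tot$modality == "scale"], 83)
  expect_equal(tot$scheduled[tot$modality == "watch"], 62)
  expect_equal(tot$completed[tot$modality == "watch"], 40)
})

test_that("completeness handles empty and simulated ledgers", {
  empty <- structure(list(prompts = remotewear:::empty_prompts()),
                     class = "prompt_ledger")
  tab <- tabulate_completeness(empty)
  expect_true(all(tab$scheduled == 0))
  expect_true(all(is.na(tab$pct_completed)))

  led <- run_simulation(generate_cohort(4, seed = 6), seed = 6,
                        horizon_days = 56)
  tab2 <- tabulate_completeness(led)
  # brute-force recount per cell
  p <- led$prompts
  for (i in which(tab2$participant_id != "Total")) {
    q <- p[p$participant_id == tab2$participant_id[i] &
             p$modality == tab2$modality[i], ]
    expect_equal(tab2$scheduled[i], nrow(q))
    expect_equal(tab2$completed[i], sum(q$status == "completed"))
  }

  # conservation violations raise an integrity error
  bad <- led
  bad$prompts$status[1] <- "pending"
  expect_error(tabulate_completeness(bad),
               class = "remotewear_integrity_error")
})

test_that("participant-attributable adherence shrinks the denominator", {
  led <- pilot_ledger()
  expect_equal(participant_attributable(led, "watch"), 40 / 54)
  expect_equal(round_half_up(100 * participant_attributable(led, "watch")),
               74)
  # no device failures: identical to end-to-end completeness
  expect_equal(participant_attributable(led, "srh"), 108 / 126)
  # attributable >= end-to-end whenever failures exist
  p <- led$prompts
  e2e <- sum(p$modality == "watch" & p$status == "completed") /
    sum(p$modality == "watch")
  expect_gt(participant_attributable(led, "watch"), e2e)
  # all-failed denominator is empty
  allf <- structure(list(prompts = data.frame(
    participant_id = "A", prompt_id = "A-1", modality = "watch",
    provenance = "scheduled", issued_at = 0, expires_at = 2880,
    status = "device_failed", completed_at = NA_real_)),
    class = "prompt_ledger")
  expect_true(is.na(participant_attributable(allf, "watch")))
})

test_that("published rounding identities hold under half-up rounding", {
  expect_equal(pct_half_up(108, 126), 86)
  expect_equal(pct_half_up(46, 53), 87)
  expect_equal(pct_half_up(83, 100), 83)
  expect_equal(pct_half_up(40, 62), 65)
  expect_equal(pct_half_up(40, 54), 74)
  # half-up, not banker's
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-0.5), -1)
})

test_that("block engagement pools modalities and applies the criterion", {
  mk_led <- function(fracs) {
    # one participant per fraction, 10 prompts per 28-day block
    rows <- list()
    for (k in seq_along(fracs)) {
      id <- sprintf("P%02d", k)
      for (b in 0:2) {
        n_done <- round(10 * fracs[k])
        for (j in 1:10) {
          done <- j <= n_done
          rows <- c(rows, list(data.frame(
            participant_id = id, prompt_id = sprintf("%s-%d-%d", id, b, j),
            modality = c("srh", "scale")[1 + j %% 2],
            provenance = "scheduled",
            issued_at = b * 28 * 1440 + j * 1440,
            expires_at = b * 28 * 1440 + j * 1440 + 2880,
            status = if (done) "completed" else "expired",
            completed_at = if (done) b * 28 * 1440 + j * 1440 + 60
                           else NA_real_)))
        }
      }
    }
    structure(list(prompts = do.call(rbind, rows)), class = "prompt_ledger")
  }
  # 5/10 completed meets the inclusive 50% threshold; 4/10 does not
  led <- mk_led(c(rep(0.5, 9), 0.4))
  be <- block_engagement(led)
  expect_equal(be$n_meeting, 9)
  expect_true(be$criterion_met)
  expect_true(all(be$blocks$met[be$blocks$participant_id != "P10"]))
  expect_false(any(be$blocks$met[be$blocks$participant_id == "P10"]))

  # fewer than 6 meeting fails the study criterion
  be2 <- block_engagement(mk_led(c(rep(0.6, 5), rep(0.3, 5))))
  expect_equal(be2$n_meeting, 5)
  expect_false(be2$criterion_met)

  # marking one more prompt completed never un-meets a block
  led3 <- mk_led(rep(0.5, 10))
  p3 <- led3$prompts
  flip <- which(p3$status == "expired")[1]
  p3$status[flip] <- "completed"
  p3$completed_at[flip] <- p3$issued_at[flip] + 60
  be3a <- block_engagement(led3)
  be3b <- block_engagement(structure(list(prompts = p3),
                                     class = "prompt_ledger"))
  expect_true(all(be3b$blocks$met >= be3a$blocks$met))

  # device-failed prompts drop out of the block denominator
  p4 <- led3$prompts
  p4$status[p4$status == "expired"] <- "device_failed"
  be4 <- block_engagement(structure(list(prompts = p4),
                                    class = "prompt_ledger"))
  expect_true(all(be4$blocks$fraction == 1))
})

test_that("SUS scoring matches the standard closed forms", {
  expect_equal(sus_score(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1)), 100)
  expect_equal(sus_score(rep(3, 10)), 50)
  expect_equal(sus_score(c(1, 5, 1, 5, 1, 5, 1, 5, 1, 5)), 0)
  # an interior profile, scored by hand: 2.5 * (sum(odd-1) + sum(5-even))
  items <- c(4, 2, 5, 1, 3, 3, 4, 2, 5, 2)
  expect_equal(sus_score(items), 2.5 * (sum(items[c(1, 3, 5, 7, 9)] - 1) +
                                          sum(5 - items[c(2, 4, 6, 8, 10)])))
  expect_error(sus_score(rep(3, 9)), class = "remotewear_validation_error")
  expect_error(sus_score(c(rep(3, 9), 6)),
               class = "remotewear_validation_error")
  expect_error(sus_score(c(rep(3, 9), NA)),
               class = "remotewear_validation_error")
})

test_that("geriatric-assessment change flags follow the thresholds", {
  base <- list(g8 = 14, carg = 6, cirsg = 8, g8_srh = 3, factg = 90)
  expect_equal(ga_change_flags(base, base)$flags, character(0))

  w <- list(g8 = 13, carg = 6, cirsg = 8, g8_srh = 3, factg = 90)
  expect_equal(ga_change_flags(base, w)$flags, "g8_decline")

  # FACT-G decline of exactly 3 does not flag; > 3 does
  w3 <- base; w3$factg <- 87
  expect_false("factg_decline" %in% ga_change_flags(base, w3)$flags)
  w4 <- base; w4$factg <- 86.5
  expect_true("factg_decline" %in% ga_change_flags(base, w4)$flags)

  wmulti <- list(g8 = 12, carg = 7, cirsg = 9, g8_srh = 2, factg = 80)
  expect_setequal(ga_change_flags(base, wmulti)$flags,
                  c("g8_decline", "carg_increase", "cirsg_increase",
                    "g8_srh_downgrade", "factg_decline"))

  # missing instrument recorded unevaluable, no flag
  miss <- ga_change_flags(base, list(g8 = 13))
  expect_equal(miss$flags, "g8_decline")
  expect_setequal(miss$unevaluable,
                  c("carg_increase", "cirsg_increase", "g8_srh_downgrade",
                    "factg_decline"))
})

test_that("the engagement report writes consistent artifacts", {
  dir <- withr::local_tempdir()
  s <- write_engagement_report(pilot_ledger(), dir)
  expect_true(file.exists(file.path(dir, "completeness.csv")))
  expect_true(file.exists(file.path(dir, "block_engagement.csv")))
  js <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(js$completion_pct$srh, 86)
  expect_equal(js$completion_pct$watch, 65)
  expect_equal(js$watch_participant_attributable_pct, 74)
})
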