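# Engagement and adherence accounting.
#
# End-to-end completeness keeps device failures in the denominator
# (completed/scheduled); participant-attributable adherence removes them
# (completed/(scheduled - device_failed)). Engagement is judged per
# 28-day block: a participant meets a block when at least 50% of their
# prompted tasks (all modalities pooled, device failures excluded) were
# completed, and the study-level criterion requires >= 6 of 10
# participants to meet every block. Printed percentages use half-up
# integer rounding throughout.

MODALITIES <- c("srh", "symptom", "scale", "watch")

#' Tabulate end-to-end completeness per participant and modality
#'
#' One row per participant plus a `Total` row; per modality: scheduled,
#' completed, incomplete split into participant-attributable (expired) and
#' device-attributable (device failure). Conservation
#' `scheduled = completed + incomplete_participant + incomplete_device`
#' is asserted for every row.
#'
#' @param ledger a `prompt_ledger`.
#' @return a `completeness_table` data frame (long form: one row per
#'   participant x modality, plus totals).
#' @export
tabulate_completeness <- function(ledger) {
  p <- ledger$prompts
  ids <- unique(p$participant_id)
  rows <- list()
  for (id in ids) {
    for (m in MODALITIES) {
      q <- p[p$participant_id == id & p$modality == m, , drop = FALSE]
      rows <- c(rows, list(data.frame(
        participant_id = id, modality = m,
        scheduled = nrow(q),
        completed = sum(q$status == "completed"),
        incomplete_participant = sum(q$status == "expired"),
        incomplete_device = sum(q$status == "device_failed"))))
    }
  }
  tab <- do.call(rbind, rows)
  bad <- tab$scheduled != tab$completed + tab$incomplete_participant +
    tab$incomplete_device
  if (any(bad)) {
    b <- tab[which(bad)[1], ]
    stop_rw("remotewear_integrity_error",
            "ledger conservation violated for participant %s, modality %s",
            b$participant_id, b$modality)
  }
  tot <- do.call(rbind, lapply(MODALITIES, function(m) {
    q <- tab[tab$modality == m, ]
    data.frame(participant_id = "Total", modality = m,
               scheduled = sum(q$scheduled), completed = sum(q$completed),
               incomplete_participant = sum(q$incomplete_participant),
               incomplete_device = sum(q$incomplete_device))
  }))
  out <- rbind(tab, tot)
  out$pct_completed <- pct_half_up(out$completed, out$scheduled)
  structure(out, class = c("completeness_table", "data.frame"))
}

#' Aggregate end-to-end completion percentages per modality
#'
#' @param tab a [tabulate_completeness()] table.
#' @return named numeric vector of half-up integer percentages.
#' @export
completeness_percentages <- function(tab) {
  tot <- tab[tab$participant_id == "Total", ]
  stats::setNames(tot$pct_completed, tot$modality)
}

#' Participant-attributable adherence for one modality
#'
#' Device-failed prompts are removed from the denominator:
#' completed / (scheduled - device_failed). `NA` when the denominator is 0.
#'
#' @param ledger a `prompt_ledger`.
#' @param modality one of srh/symptom/scale/watch.
#' @return a fraction in `[0, 1]`, or `NA`.
#' @export
participant_attributable <- function(ledger, modality) {
  modality <- match.arg(modality, MODALITIES)
  q <- ledger$prompts[ledger$prompts$modality == modality, , drop = FALSE]
  den <- nrow(q) - sum(q$status == "device_failed")
  if (den == 0) return(NA_real_)
  sum(q$status == "completed") / den
}

#' Per-block engagement and the study-level criterion
#'
#' Prompts are assigned to consecutive `block_days`-day blocks from each
#' participant's deployment start by issue time; within a block all
#' modalities pool into one fraction with device-failed prompts excluded
#' from the denominator. A block is met when the fraction reaches
#' `threshold` (inclusive). The final partial block is dropped from the
#' criterion when its scheduled prompts span fewer than `min_final_days`
#' days. The study criterion is met when at least `n_required`
#' participants meet every one of their blocks.
#'
#' @param ledger a `prompt_ledger`.
#' @param block_days block length in days (default 28).
#' @param threshold completion fraction defining a met block (default 0.5).
#' @param engagement_days length of the engagement window (default 84).
#' @param n_required participants required for the study criterion
#'   (default 6).
#' @param min_final_days minimum span of scheduled prompts for a final
#'   partial block to count (default 7).
#' @return list with `blocks` (per participant x block), `participants`
#'   (per-participant all-blocks flag) and `criterion_met`.
#' @export
block_engagement <- function(ledger, block_days = 28, threshold = 0.5,
                             engagement_days = 84, n_required = 6,
                             min_final_days = 7) {
  p <- ledger$prompts
  p <- p[p$issued_at < engagement_days * MIN_PER_DAY, , drop = FALSE]
  p <- p[p$status != "device_failed", , drop = FALSE]
  p$block <- floor(p$issued_at / (block_days * MIN_PER_DAY))
  n_blocks <- ceiling(engagement_days / block_days)
  # drop a final partial block with too little scheduled activity
  last <- n_blocks - 1
  if (engagement_days %% block_days != 0) {
    span_days <- {
      q <- p[p$block == last, , drop = FALSE]
      if (nrow(q)) (max(q$issued_at) - min(q$issued_at)) / MIN_PER_DAY + 1
      else 0
    }
    if (span_days < min_final_days) n_blocks <- n_blocks - 1
  }
  ids <- unique(p$participant_id)
  rows <- list()
  for (id in ids) {
    for (b in 0:(n_blocks - 1)) {
      q <- p[p$participant_id == id & p$block == b, , drop = FALSE]
      frac <- if (nrow(q)) sum(q$status == "completed") / nrow(q) else NA
      rows <- c(rows, list(data.frame(
        participant_id = id, block = b, scheduled = nrow(q),
        completed = sum(q$status == "completed"), fraction = frac,
        met = !is.na(frac) & frac >= threshold)))
    }
  }
  blocks <- do.call(rbind, rows)
  per <- vapply(ids, function(id) {
    all(blocks$met[blocks$participant_id == id])
  }, TRUE)
  list(blocks = blocks,
       participants = data.frame(participant_id = ids, all_blocks_met = per),
       n_meeting = sum(per),
       criterion_met = sum(per) >= n_required)
}

#' Score the System Usability Scale
#'
#' Ten items on a 1-5 agreement scale; odd items contribute `value - 1`,
#' even items `5 - value`, and the sum is scaled by 2.5 to a 0-100 score
#' (68 is the conventional adequacy cutoff). Missing or out-of-range items
#' raise a validation error -- no imputation.
#'
#' @param items numeric vector of the ten item responses, in order.
#' @return score in `[0, 100]`.
#' @export
sus_score <- function(items) {
  if (length(items) != 10 || anyNA(items) || any(!items %in% 1:5)) {
    stop_rw("remotewear_validation_error",
            "SUS requires ten complete items, each in 1..5")
  }
  odd <- items[c(1, 3, 5, 7, 9)]
  even <- items[c(2, 4, 6, 8, 10)]
  2.5 * (sum(odd - 1) + sum(5 - even))
}

#' Geriatric-assessment change flags (week 12 vs baseline)
#'
#' Prespecified decline thresholds: G8 decline >= 1, CARG increase >= 1,
#' CIRS-G increase >= 1, any G8 self-rated-health downgrade, FACT-G
#' decline > 3. Instruments missing at either timepoint are recorded as
#' unevaluable and contribute no flag.
#'
#' @param baseline,week12 named lists/vectors with any of `g8`, `carg`,
#'   `cirsg`, `g8_srh` (ordinal numeric), `factg`.
#' @return list with `flags` (character) and `unevaluable` (character).
#' @export
ga_change_flags <- function(baseline, week12) {
  both <- function(k) {
    !is.null(baseline[[k]]) && !is.null(week12[[k]]) &&
      !is.na(baseline[[k]]) && !is.na(week12[[k]])
  }
  flags <- character(0)
  unev <- character(0)
  rules <- list(
    g8_decline = function() baseline$g8 - week12$g8 >= 1,
    carg_increase = function() week12$carg - baseline$carg >= 1,
    cirsg_increase = function() week12$cirsg - baseline$cirsg >= 1,
    g8_srh_downgrade = function() week12$g8_srh < baseline$g8_srh,
    factg_decline = function() baseline$factg - week12$factg > 3)
  keys <- c(g8_decline = "g8", carg_increase = "carg",
            cirsg_increase = "cirsg", g8_srh_downgrade = "g8_srh",
            factg_decline = "factg")
  for (f in names(rules)) {
    if (!both(keys[[f]])) {
      unev <- c(unev, f)
    } else if (isTRUE(rules[[f]]())) {
      flags <- c(flags, f)
    }
  }
  list(flags = flags, unevaluable = unev)
}

#' Write the full engagement report to a directory
#'
#' Emits the completeness table (CSV), block-engagement table (CSV) and a
#' JSON summary with aggregate percentages, the participant-attributable
#' watch adherence and the engagement criterion.
#'
#' @param ledger a `prompt_ledger`.
#' @param out_dir output directory (created if missing).
#' @param ... passed to [block_engagement()].
#' @return the summary list, invisibly.
#' @export
write_engagement_report <- function(ledger, out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- tabulate_completeness(ledger)
  blocks <- block_engagement(ledger, ...)
  utils::write.csv(tab, file.path(out_dir, "completeness.csv"),
                   row.names = FALSE)
  utils::write.csv(blocks$blocks, file.path(out_dir, "block_engagement.csv"),
                   row.names = FALSE)
  summary <- list(
    completion_pct = as.list(completeness_percentages(tab)),
    watch_participant_attributable_pct =
      round_half_up(100 * participant_attributable(ledger, "watch")),
    participants_meeting_all_blocks = blocks$n_meeting,
    engagement_criterion_met = blocks$criterion_met)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
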