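# Surveillance statistics: per-trigger performance (rates per 100 medical
# records and positive predictive value), patient-level prevalence,
# detection-source breakdown, temporal quartiles of onset, and the
# underreporting rate against the spontaneous-report log. All table outputs
# are computed from integer counts and rounded (half away from zero) to one
# decimal only for display, so the printed PPV always equals the count
# ratio, not the ratio of rounded rates.

#' Triggers per 100 medical records
#'
#' @param hits trigger-hit data.frame (from \code{\link{scan_cohort}}).
#' @param trigger_id the trigger to count.
#' @param n_records number of records screened (> 0).
#' @param digits decimals for display rounding (default 1; \code{NA} for
#'   full precision).
#' @return rate per 100 records.
#' @export
triggers_per_100 <- function(hits, trigger_id, n_records, digits = 1) {
  if (n_records <= 0) stop("n_records must be positive")
  rate <- 100 * sum(hits$trigger_id == trigger_id) / n_records
  if (is.na(digits)) rate else round_half_up(rate, digits)
}

#' ADRs identified by a trigger per 100 medical records
#'
#' Counts adjudicated ADRs whose detection is the given trigger; several
#' ADRs identified by the same trigger in one record all count.
#'
#' @param adrs adjudicated ADR data.frame (from
#'   \code{\link{adjudicate_cohort}}).
#' @inheritParams triggers_per_100
#' @return rate per 100 records.
#' @export
adrs_per_100 <- function(adrs, trigger_id, n_records, digits = 1) {
  if (n_records <= 0) stop("n_records must be positive")
  cnt <- sum(adrs$detection == "TRIGGER" &
               !is.na(adrs$trigger_id) & adrs$trigger_id == trigger_id)
  rate <- 100 * cnt / n_records
  if (is.na(digits)) rate else round_half_up(rate, digits)
}

#' Positive predictive value of a trigger
#'
#' Computed from the raw counts (\code{100 * adr_count / hit_count}), which
#' equals the ratio of the unrounded per-100 rates; defined as 0 for
#' triggers that never fired.
#'
#' @param adr_count ADRs identified by the trigger.
#' @param hit_count times the trigger fired.
#' @param digits decimals for display rounding (default 1; \code{NA} for
#'   full precision).
#' @return PPV as a percentage in [0, 100].
#' @export
ppv <- function(adr_count, hit_count, digits = 1) {
  if (hit_count == 0) {
    if (adr_count != 0) stop("adr_count must be 0 when hit_count is 0")
    return(0)
  }
  if (adr_count > hit_count) {
    stop("adr_count cannot exceed hit_count")
  }
  out <- 100 * adr_count / hit_count
  if (is.na(digits)) out else round_half_up(out, digits)
}

#' Per-trigger performance table
#'
#' One row per catalog trigger with hit and ADR counts, both per-100 rates
#' and the PPV, ordered by decreasing PPV then rate.
#'
#' @param hits trigger hits.
#' @param adrs adjudicated ADRs.
#' @param n_records number of records screened.
#' @param catalog trigger catalog (defines the rows).
#' @return data.frame with \code{trigger_id, label, module, hit_count,
#'   adr_count, triggers_per_100, adrs_per_100, ppv_pct}.
#' @export
trigger_performance <- function(hits, adrs, n_records,
                                catalog = default_catalog()) {
  rows <- lapply(seq_len(nrow(catalog)), function(k) {
    tid <- catalog$trigger_id[k]
    hc <- sum(hits$trigger_id == tid)
    ac <- sum(adrs$detection == "TRIGGER" & !is.na(adrs$trigger_id) &
                adrs$trigger_id == tid)
    data.frame(trigger_id = tid, label = catalog$label[k],
               module = catalog$module[k], hit_count = hc, adr_count = ac,
               triggers_per_100 = round_half_up(100 * hc / n_records, 1),
               adrs_per_100 = round_half_up(100 * ac / n_records, 1),
               ppv_pct = ppv(ac, hc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$ppv_pct, -out$triggers_per_100), ]
  rownames(out) <- NULL
  out
}

#' Patient-level ADR prevalence
#'
#' Percentage of records with at least one ADR (counts patients, not ADRs).
#'
#' @param has_adr logical vector, one element per record.
#' @param digits display rounding.
#' @return percentage.
#' @export
prevalence <- function(has_adr, digits = 1) {
  if (!length(has_adr)) stop("prevalence of an empty cohort is undefined")
  round_half_up(100 * mean(has_adr), digits)
}

#' Detection-source breakdown of ADRs
#'
#' @param adrs adjudicated ADR data.frame.
#' @return list with \code{trigger_detected_pct} and \code{non_trigger_pct}
#'   (percentages of all ADRs, summing to 100), or an empty list when there
#'   are no ADRs.
#' @export
detection_breakdown <- function(adrs) {
  if (nrow(adrs) == 0) return(list())
  p <- 100 * mean(adrs$detection == "TRIGGER")
  list(trigger_detected_pct = round_half_up(p, 1),
       non_trigger_pct = round_half_up(100 - p, 1))
}

#' Quartile of the stay in which an ADR occurred
#'
#' \code{ceiling(4 * onset_day / los_days)}, clamped to 1..4: the onset day
#' relative to the patient's own length of stay.
#'
#' @param onset_day 1-based hospital day of onset.
#' @param los_days length of stay in whole days.
#' @return integer quartile in 1..4.
#' @export
temporal_quartile <- function(onset_day, los_days) {
  if (any(onset_day < 1 | onset_day > los_days)) {
    stop("onset_day must lie within 1..los_days")
  }
  pmin(pmax(ceiling(4 * onset_day / los_days), 1L), 4L)
}

#' Underreporting rate
#'
#' Percentage of adjudicated ADRs with no matching spontaneous report; the
#' matching key is the patient plus the synonym-normalized drug name.
#'
#' @param adrs adjudicated ADR data.frame (at least one row).
#' @param reports spontaneous-report data.frame.
#' @return percentage, or \code{NA} when there are no ADRs (undefined).
#' @export
underreporting_rate <- function(adrs, reports) {
  if (nrow(adrs) == 0) return(NA_real_)
  key_a <- paste(adrs$patient_id, normalize_drug(adrs$drug_name))
  key_r <- if (nrow(reports)) {
    paste(reports$patient_id, normalize_drug(reports$drug_name))
  } else character(0)
  round_half_up(100 * mean(!key_a %in% key_r), 1)
}

#' Full surveillance report
#'
#' Assembles the cohort-level surveillance statistics: prevalence, ADR
#' totals and detection breakdown, the per-trigger performance table, the
#' temporal quartile distribution of ADR onsets, mortality, mean triggers
#' per record, and the underreporting rate.
#'
#' @param x an \code{icu_cohort}.
#' @param hits trigger hits from \code{\link{scan_cohort}}.
#' @param adrs adjudicated ADRs from \code{\link{adjudicate_cohort}}.
#' @param catalog trigger catalog.
#' @return an object of class \code{surveillance_report}.
#' @export
surveillance_report <- function(x, hits, adrs, catalog = default_catalog()) {
  stopifnot(inherits(x, "icu_cohort"))
  n <- nrow(x$patients)
  if (n == 0) {
    return(structure(list(n_records = 0L), class = "surveillance_report"))
  }
  has_adr <- x$patients$patient_id %in% adrs$patient_id
  los_days <- ceiling(as.numeric(difftime(x$patients$discharge_time,
                                          x$patients$admit_time,
                                          units = "days")))
  quart <- if (nrow(adrs)) {
    ad_los <- los_days[match(adrs$patient_id, x$patients$patient_id)]
    table(factor(temporal_quartile(pmin(adrs$onset_day, ad_los), ad_los),
                 levels = 1:4))
  } else table(factor(integer(0), levels = 1:4))
  structure(list(
    n_records = n,
    prevalence_pct = prevalence(has_adr),
    patients_with_adr = sum(has_adr),
    total_adrs = nrow(adrs),
    adrs_by_detection = table(factor(adrs$detection,
                                     levels = c("TRIGGER",
                                                "NON_TRIGGER_REVIEW",
                                                "SPONTANEOUS"))),
    detection_breakdown = detection_breakdown(adrs),
    total_trigger_hits = nrow(hits),
    mean_triggers_per_record = nrow(hits) / n,
    mortality_pct = round_half_up(100 * mean(x$patients$outcome == "death"),
                                  1),
    performance = trigger_performance(hits, adrs, n, catalog),
    quartile_distribution = quart,
    underreporting_pct = underreporting_rate(adrs, x$spontaneous_reports)
  ), class = "surveillance_report")
}

#' @export
print.surveillance_report <- function(x, ...) {
  cat("Trigger-tool surveillance report\n")
  cat(sprintf("  records screened: %d\n", x$n_records))
  if (x$n_records == 0) {
    cat("  (empty cohort)\n")
    return(invisible(x))
  }
  cat(sprintf("  patients with >=1 ADR: %d (%.1f%%)\n",
              x$patients_with_adr, x$prevalence_pct))
  cat(sprintf("  total ADRs: %d", x$total_adrs))
  if (length(x$detection_breakdown)) {
    cat(sprintf(" (%.1f%% trigger-detected)",
                x$detection_breakdown$trigger_detected_pct))
  }
  cat("\n")
  cat(sprintf("  trigger hits: %d (%.1f per record)\n",
              x$total_trigger_hits, x$mean_triggers_per_record))
  cat(sprintf("  ICU mortality: %.1f%%\n", x$mortality_pct))
  if (!is.na(x$underreporting_pct)) {
    cat(sprintf("  underreporting rate: %.1f%%\n", x$underreporting_pct))
  }
  cat("  top triggers by PPV:\n")
  perf <- head(x$performance[x$performance$hit_count > 0, ], 5)
  for (i in seq_len(nrow(perf))) {
    cat(sprintf("    %-38s %6.1f /100  PPV %5.1f%%\n", perf$label[i],
                perf$triggers_per_100[i], perf$ppv_pct[i]))
  }
  invisible(x)
}
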