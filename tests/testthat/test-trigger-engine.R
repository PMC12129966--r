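test_that("the default catalog is the 28-trigger adapted set", {
  cat28 <- default_catalog()
  expect_equal(nrow(cat28), 28)
  expect_equal(as.integer(table(cat28$module)[c("MEDICATION", "CARE",
                                                "LAB")]),
               c(21L, 3L, 4L))
  lab_ids <- cat28$trigger_id[cat28$module == "LAB"]
  expect_setequal(lab_ids, c("sodium_lt_135", "potassium_lt_3_0",
                             "potassium_gt_5_5", "platelets_lt_50000"))
  # the ICU-adapted thresholds, not the original GTT ones
  ptt <- cat28$params[[which(cat28$trigger_id == "ptt_gt_50")]]
  expect_equal(ptt$threshold, 50)
  inr <- cat28$params[[which(cat28$trigger_id == "inr_gt_3")]]
  expect_equal(inr$threshold, 3)
})

test_that("lab threshold rule: strict inequality and daily dedup", {
  labs <- lab_rows("P1", c(1, 2), 8, "PTT_s", c(38, 61))
  hits <- rule_lab_threshold(labs, "PTT_s", "GT", 50)
  expect_equal(nrow(hits), 1)
  expect_match(hits$evidence, "61")

  # boundary: exactly at the threshold never fires
  labs <- lab_rows("P1", 1, 8, "INR", 3.0)
  expect_equal(nrow(rule_lab_threshold(labs, "INR", "GT", 3)), 0)

  # two qualifying values on the same day collapse to one hit
  labs <- lab_rows("P1", c(2, 2), c(8, 14), "POTASSIUM_mmol_L", c(5.6, 5.8))
  hits <- rule_lab_threshold(labs, "POTASSIUM_mmol_L", "GT", 5.5)
  expect_equal(nrow(hits), dedup_days_oracle(labs$timestamp))
  expect_match(hits$evidence, "5.6")  # first qualifying value is evidence
})

test_that("boundary strictness holds for every threshold trigger in the catalog", {
  cat28 <- default_catalog()
  thr <- cat28[cat28$rule_kind %in% c("LAB_THRESHOLD", "VITAL_THRESHOLD"), ]
  for (k in seq_len(nrow(thr))) {
    p <- thr$params[[k]]
    eps <- if (p$threshold >= 1000) 1 else 0.01
    at <- lab_rows("P1", 1, 8, p$analyte, p$threshold)
    beyond_val <- if (p$direction == "LT") p$threshold - eps else
      p$threshold + eps
    beyond <- lab_rows("P1", 2, 8, p$analyte, beyond_val)
    expect_equal(nrow(rule_lab_threshold(at, p$analyte, p$direction,
                                         p$threshold)), 0,
                 info = thr$trigger_id[k])
    expect_equal(nrow(rule_lab_threshold(beyond, p$analyte, p$direction,
                                         p$threshold)), 1,
                 info = thr$trigger_id[k])
  }
})

test_that("relative-change rule: drops, rises, episodes", {
  # 25% drop fires (8.9 <= 0.75 * 12.0)
  labs <- lab_rows("P1", c(1, 2), 8, "HEMOGLOBIN_g_dL", c(12.0, 8.9))
  expect_equal(nrow(rule_relative_change(labs, "HEMOGLOBIN_g_dL",
                                         "DROP_PCT", 0.25)), 1)
  # monotone rising series never fires the drop rule
  labs <- lab_rows("P1", 1:4, 8, "HEMOGLOBIN_g_dL", c(9, 10, 11, 12))
  expect_equal(nrow(rule_relative_change(labs, "HEMOGLOBIN_g_dL",
                                         "DROP_PCT", 0.25)), 0)
  # 2x rise over the admission baseline
  labs <- lab_rows("P1", c(1, 3), 8, "CREATININE_mg_dL", c(1.0, 2.1))
  expect_equal(nrow(rule_relative_change(labs, "CREATININE_mg_dL",
                                         "RISE_FOLD", 2)), 1)
  # one sustained episode = one hit; recovery then relapse = two hits
  labs <- lab_rows("P1", 1:5, 8, "HEMOGLOBIN_g_dL",
                   c(12, 8.5, 8.2, 11.8, 8.4))
  expect_equal(nrow(rule_relative_change(labs, "HEMOGLOBIN_g_dL",
                                         "DROP_PCT", 0.25)), 2)
  # fewer than two measurements cannot fire
  labs <- lab_rows("P1", 1, 8, "HEMOGLOBIN_g_dL", 5)
  expect_equal(nrow(rule_relative_change(labs, "HEMOGLOBIN_g_dL",
                                         "DROP_PCT", 0.25)), 0)
})

test_that("medication administration rule: daily dedup and synonym matching", {
  adm <- data.frame(patient_id = "P1", drug_name = "Protamine",
                    timestamp = ts_day(2, 9), stringsAsFactors = FALSE)
  expect_equal(nrow(rule_med_administered(adm, "protamine")), 1)

  adm <- data.frame(patient_id = "P1", drug_name = "HYDROCORTISONE",
                    timestamp = ts_day(c(3, 4, 5), 9),
                    stringsAsFactors = FALSE)
  hits <- rule_med_administered(adm, "hydrocortisone")
  expect_equal(nrow(hits), dedup_days_oracle(adm$timestamp))

  adm <- data.frame(patient_id = "P1", drug_name = "Paracetamol",
                    timestamp = ts_day(2, 9), stringsAsFactors = FALSE)
  cat28 <- default_catalog()
  med_drugs <- unlist(lapply(cat28$params[cat28$rule_kind ==
                                            "MED_ADMINISTERED"], `[[`,
                             "drugs"))
  expect_equal(nrow(rule_med_administered(adm, med_drugs)), 0)
})

test_that("abrupt stop rule: early stop fires, censoring and as-needed do not", {
  mk_course <- function(stop_day, intended_day, scheduled = TRUE) {
    data.frame(patient_id = "P1", drug_name = "Ceftriaxone", atc_code = "",
               course_id = 1L, start_time = ts_day(1, 1),
               stop_time = ts_day(stop_day, 1),
               intended_end_time = ts_day(intended_day, 1),
               scheduled = scheduled, route = "IV", stringsAsFactors = FALSE)
  }
  no_adm <- data.frame(patient_id = character(0), drug_name = character(0),
                       timestamp = as.POSIXct(character(0), tz = "UTC"),
                       stringsAsFactors = FALSE)
  discharge <- ts_day(12, 1)
  # intended through day 10, stopped day 4, discharged day 12 -> fires
  expect_equal(nrow(rule_abrupt_stop(mk_course(4, 10), no_adm, discharge)), 1)
  # stopped at discharge (same day) -> censored, no hit
  expect_equal(nrow(rule_abrupt_stop(mk_course(12, 14), no_adm, discharge)), 0)
  # as-needed course never fires
  expect_equal(nrow(rule_abrupt_stop(mk_course(4, 10, scheduled = FALSE),
                                     no_adm, discharge)), 0)
  # no intended end -> never fires
  m <- mk_course(4, 10); m$intended_end_time <- NA
  expect_equal(nrow(rule_abrupt_stop(m, no_adm, discharge)), 0)
  # a same-drug administration within 24 h of the stop suppresses the hit
  adm <- data.frame(patient_id = "P1", drug_name = "Ceftriaxone",
                    timestamp = ts_day(4, 20), stringsAsFactors = FALSE)
  expect_equal(nrow(rule_abrupt_stop(mk_course(4, 10), adm, discharge)), 0)
})

test_that("over-sedation/hypotension rule fires on MAP alone, flagging sedative context", {
  labs <- lab_rows("P1", 2, 10, "MAP_mmHg", 65)
  seds <- data.frame(patient_id = "P1", drug_name = "Midazolam",
                     atc_code = "", course_id = 1L, start_time = ts_day(1, 1),
                     stop_time = ts_day(5, 1), intended_end_time = NA,
                     scheduled = TRUE, route = "IV", stringsAsFactors = FALSE)
  hits <- rule_vital_threshold(labs, seds, 70)
  expect_equal(nrow(hits), 1)
  expect_match(hits$evidence, "sedative active")
  # without any sedative the hit still fires
  hits <- rule_vital_threshold(labs, seds[0, ], 70)
  expect_equal(nrow(hits), 1)
  expect_match(hits$evidence, "no sedative")
  # boundary 70 exactly: no hit
  expect_equal(nrow(rule_vital_threshold(lab_rows("P1", 2, 10, "MAP_mmHg",
                                                  70), seds, 70)), 0)
  # two qualifying days -> two hits
  expect_equal(nrow(rule_vital_threshold(lab_rows("P1", c(2, 4), 10,
                                                  "MAP_mmHg", 65),
                                         seds, 70)), 2)
})

test_that("note-event rule counts each documented event, exempt from daily dedup", {
  notes <- data.frame(patient_id = "P1", timestamp = ts_day(c(2, 2), c(9, 15)),
                      kind = "SKIN_RASH", text = "rash",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(rule_note_event(notes, "SKIN_RASH")), 2)
  expect_equal(nrow(rule_note_event(notes, "PATIENT_FALL")), 0)
})

test_that("scanning a record equals the union of its per-rule evaluations", {
  cat28 <- default_catalog()
  set.seed(404)
  analytes <- c("PTT_s", "INR", "GLUCOSE_mg_dL", "SODIUM_mEq_L",
                "POTASSIUM_mmol_L", "PLATELETS_per_uL", "HEMOGLOBIN_g_dL",
                "CREATININE_mg_dL", "MAP_mmHg")
  ranges <- list(c(20, 90), c(0.8, 5), c(30, 200), c(120, 150), c(2, 7),
                 c(10000, 300000), c(5, 15), c(0.5, 6), c(50, 110))
  drugs <- c("Ondansetron", "Hydrocortisone", "Protamine", "Paracetamol")
  for (iter in 1:200) {
    los <- sample(3:8, 1)
    n_lab <- sample(5:25, 1)
    ai <- sample(length(analytes), n_lab, replace = TRUE)
    labs <- data.frame(
      patient_id = "P1",
      timestamp = ts_day(sample(los, n_lab, TRUE), sample(0:23, n_lab, TRUE)),
      analyte = analytes[ai],
      value = vapply(ai, function(j) runif(1, ranges[[j]][1],
                                           ranges[[j]][2]), 0),
      stringsAsFactors = FALSE)
    n_adm <- sample(0:5, 1)
    adm <- if (n_adm > 0) data.frame(
      patient_id = "P1",
      drug_name = sample(drugs, n_adm, TRUE),
      timestamp = ts_day(sample(los, n_adm, TRUE), sample(0:23, n_adm, TRUE)),
      stringsAsFactors = FALSE) else NULL
    meds <- if (!is.null(adm)) data.frame(
      patient_id = "P1", drug_name = unique(adm$drug_name), atc_code = "",
      start_time = T0, stop_time = T0 + los * 86400,
      intended_end_time = NA, scheduled = FALSE, route = "IV",
      stringsAsFactors = FALSE) else NULL
    notes <- if (runif(1) < 0.3) data.frame(
      patient_id = "P1", timestamp = ts_day(sample(los, 1), 12),
      kind = sample(c("SKIN_RASH", "PATIENT_FALL"), 1), text = "event",
      stringsAsFactors = FALSE) else NULL
    co <- make_cohort(los_days = los, labs = labs, medications = meds,
                      administrations = adm, notes = notes)
    rec <- patient_record(co, "P1")
    scanned <- scan_record(rec, cat28)
    # oracle: evaluate each rule independently, dedup per calendar day
    expected <- 0L
    for (k in seq_len(nrow(cat28))) {
      h <- icutrigger:::eval_rule(cat28$rule_kind[k], cat28$params[[k]], rec)
      expected <- expected +
        if (cat28$rule_kind[k] == "NOTE_EVENT") nrow(h) else
          dedup_days_oracle(h$timestamp)
    }
    expect_equal(nrow(scanned), expected)
    expect_true(all(scanned$timestamp >= rec$patient$admit_time &
                      scanned$timestamp <= rec$patient$discharge_time))
    # determinism
    expect_identical(scan_record(rec, cat28), scanned)
  }
})

test_that("a record with no abnormal events yields no hits", {
  labs <- rbind(lab_rows("P1", 1:3, 8, "GLUCOSE_mg_dL", c(180, 95, 120)),
                lab_rows("P1", 1:3, 8, "SODIUM_mEq_L", c(140, 141, 139)))
  rec <- make_record(labs = labs)
  expect_equal(nrow(scan_record(rec)), 0)
  # one glucose excursion in an otherwise normal series -> exactly one hit
  labs <- lab_rows("P1", 1:3, 8, "GLUCOSE_mg_dL", c(180, 44, 95))
  rec <- make_record(labs = labs)
  hits <- scan_record(rec)
  expect_equal(hits$trigger_id, "glucose_lt_50")
  expect_match(hits$evidence, "44")
})
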