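test_that("the default calibration encodes the study conditions", {
  cfg <- default_config()
  expect_equal(cfg$n_patients, 135)
  expect_equal(cfg$units$G_ICU$fraction, 76 / 135)
  expect_equal(cfg$mortality_prob, 94 / 135)
  expect_equal(cfg$adr_patient_prevalence, 55 / 135)
  expect_equal(cfg$spontaneous_report_prob, 0)
  tpl <- cfg$templates
  expect_equal(sum(tpl$weight), 85)
  # marginal targets of the template mix
  sev <- tapply(tpl$weight, vapply(seq_len(nrow(tpl)), function(i) {
    do.call(classify_severity, as.list(setNames(
      strsplit(tpl$sev_facts[i], "")[[1]] == "y",
      c("intervention_required", "therapy_change",
        "life_threatening_or_prolonging"))))
  }, ""), sum)
  expect_equal(sev[["mild"]], 12)
  expect_equal(sev[["moderate"]], 48)
  expect_equal(sev[["severe"]], 25)
  mech <- tapply(tpl$weight, tpl$mech_facts == "yy", sum)
  expect_equal(mech[["TRUE"]], 82)    # Type A
  expect_equal(mech[["FALSE"]], 3)    # Type B
  expect_equal(sum(tpl$weight[tpl$signature == "NONE"]), 21)
  # every signature id exists in the catalog
  expect_true(all(tpl$signature %in%
                    c(default_catalog()$trigger_id, "NONE")))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_cohort(default_config(n_patients = 20), seed = 7)
  b <- generate_cohort(default_config(n_patients = 20), seed = 7)
  expect_identical(a, b)
  c2 <- generate_cohort(default_config(n_patients = 20), seed = 8)
  expect_false(identical(a$cohort$labs, c2$cohort$labs))
})

test_that("zero prevalence and zero noise produce a hit-free cohort", {
  cfg <- default_config(n_patients = 30, adr_patient_prevalence = 0,
                        trigger_noise_rates =
                          setNames(rep(0, 28),
                                   names(icutrigger:::default_noise_rates())))
  sim <- generate_cohort(cfg, seed = 3)
  expect_equal(nrow(sim$ground_truth), 0)
  hits <- scan_cohort(sim$cohort)
  expect_equal(nrow(hits), 0)
})

test_that("calibration recovery at n = 5000: demographics within 3 SE", {
  cfg <- default_config(n_patients = 5000)
  set.seed(77)
  p <- generate_patients(cfg)
  n <- nrow(p)
  within3se <- function(x, target, se) abs(x - target) <= 3 * se
  expect_true(within3se(mean(p$unit == "G_ICU"), 76 / 135,
                        sqrt(76 / 135 * 59 / 135 / n)))
  expect_true(within3se(mean(p$outcome == "death"), 94 / 135,
                        sqrt(0.696 * 0.304 / n)))
  expect_true(within3se(mean(p$has_adr), 55 / 135,
                        sqrt(0.407 * 0.593 / n)))
  for (un in c("G_ICU", "C19_ICU")) {
    i <- p$unit == un
    u <- cfg$units[[un]]
    expect_true(within3se(mean(p$age[i]), u$age_mean,
                          u$age_sd / sqrt(sum(i))), label = paste(un, "age"))
    expect_true(within3se(mean(p$los[i]), u$los_mean,
                          u$los_sd / sqrt(sum(i))), label = paste(un, "los"))
    expect_true(within3se(mean(p$sex[i] == "male"), u$sex_male_prob,
                          sqrt(u$sex_male_prob * (1 - u$sex_male_prob) /
                                 sum(i))), label = paste(un, "sex"))
  }
  expect_true(all(p$age >= 19 & p$age <= 100))
  expect_true(all(p$los > 1))
})

test_that("every embedded signature ADR fires its trigger within one day of onset", {
  # cohort sized to carry well over 500 signature ADRs
  sim <- generate_cohort(default_config(n_patients = 1200), seed = 55)
  hits <- scan_cohort(sim$cohort)
  gt <- sim$ground_truth
  sig <- gt[gt$signature_trigger != "NONE", ]
  expect_gt(nrow(sig), 500)
  hit_key <- paste(hits$patient_id, hits$trigger_id, hits$hospital_day)
  recovered <- vapply(seq_len(nrow(sig)), function(i) {
    any(paste(sig$patient_id[i], sig$signature_trigger[i],
              sig$onset_day[i] + (-1:1)) %in% hit_key)
  }, logical(1))
  expect_true(all(recovered))
})

test_that("embedding a template places its drug course and signature event", {
  tpl <- default_templates()
  rec <- make_record(los_days = 8,
                     labs = lab_rows("P1", 1, 0, "GLUCOSE_mg_dL", 120))
  hypo <- tpl[tpl$template_id == "insulin_hypo", ]
  rec2 <- embed_adr(rec, hypo, onset_day = 3)
  glu <- rec2$labs[rec2$labs$analyte == "GLUCOSE_mg_dL" &
                     rec2$labs$value < 50, ]
  expect_equal(nrow(glu), 1)
  expect_equal(icutrigger:::hospital_day(glu$timestamp,
                                         rec2$patient$admit_time), 3L)
  ins <- rec2$medications[rec2$medications$drug_name == "Regular insulin", ]
  expect_equal(nrow(ins), 1)
  expect_true(ins$start_time <= ts_day(3, 0) &&
                ins$stop_time >= ts_day(3, 23))
  hits <- scan_record(rec2)
  expect_true("glucose_lt_50" %in% hits$trigger_id)

  # skin-rash template: note event plus antihistamine administration
  rash <- tpl[tpl$template_id == "ampsulb_rash", ]
  rec3 <- embed_adr(make_record(los_days = 8), rash, onset_day = 2)
  expect_true(any(rec3$notes$kind == "SKIN_RASH"))
  expect_true("Hydroxyzine" %in% rec3$administrations$drug_name)
  hits <- scan_record(rec3)
  expect_true(all(c("skin_rash", "hydroxyzine") %in% hits$trigger_id))

  # NONE-signature template: no catalog trigger fires on its events
  none <- tpl[tpl$template_id == "tramadol_nausea", ]
  rec4 <- embed_adr(make_record(los_days = 8), none, onset_day = 4)
  expect_equal(nrow(scan_record(rec4)), 0)

  expect_error(embed_adr(make_record(los_days = 4), hypo, onset_day = 9),
               "beyond the stay")
})

test_that("onset day infeasible for an abrupt stop degrades to chart-review detection", {
  # generated stays barely over one day cannot host a clean abrupt stop
  sim <- generate_cohort(default_config(n_patients = 200), seed = 14)
  gt <- sim$ground_truth
  abrupt <- gt[grepl("abrupt", gt$signature_trigger), ]
  los <- as.numeric(difftime(
    sim$cohort$patients$discharge_time, sim$cohort$patients$admit_time,
    units = "days"))[match(abrupt$patient_id,
                           sim$cohort$patients$patient_id)]
  expect_true(all(los >= 1.5))
})
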