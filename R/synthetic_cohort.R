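# Synthetic two-unit ICU cohort generator. The generator is the package's
# stand-in for hospital chart data: it reproduces the statistical structure
# the surveillance analysis assumes -- unit mix, demographics, length of
# stay, SOFA trajectories, background ("noise") trigger events at calibrated
# per-100-record rates, and embedded ground-truth ADRs whose signature events
# (lab excursions, rescue-drug administrations, abrupt course stops, note
# events) fire the corresponding catalog triggers at the onset day.
#
# Timing conventions inside a generated stay (admission = hospital day 1):
#   * routine daily labs at day start (admission instant + 24 h steps);
#   * background abnormal excursions at day start + 10 h, recoveries at
#     + 16 h, so they fire triggers but never sit on the daily SOFA grid;
#   * embedded-ADR signature events and the assessment note share the + 12 h
#     offset, so they fall on the same calendar hospital day as the onset.

HOUR <- 3600
DAY <- 86400

#' ADR templates of the synthetic generator
#'
#' One row per drug-reaction pair of the calibration study, with the
#' template's sampling weight (the published ADR count), the signature
#' trigger that detects it (\code{"NONE"} for reactions found only by chart
#' review), and the embedded classification facts: WHO severity facts,
#' Rawlins-Thompson mechanism facts, the 10 Naranjo responses and the
#' WHO-UMC facts.
#'
#' @return data.frame of templates.
#' @export
default_templates <- function() {
  # severity fact triplets (intervention_required, therapy_change,
  # life-threatening/prolonging) by target class
  sev <- list(mild = "nnn", moderate = "yyn", severe = "yyy")
  mech <- list(A = "yy", B = "nn")
  # Naranjo response strings (Q1..Q10) by target band
  nar <- list(probable = "yyyunuuuuu",   # 1+2+1+2 = 6
              possible = "yyuuyuuuuu",   # 1+2-1   = 2
              possible3 = "yyyuyuuuuu",  # 1+2+1-1 = 3
              doubtful = "unuuyuuuuu")   # -1-1    = -2
  # WHO-UMC fact strings t:a:d:r:s
  who <- list(probable = "t:y;a:e;d:p;r:x;s:1",
              possible = "t:y;a:p;d:x;r:x;s:1",
              unlikely = "t:n;a:p;d:x;r:x;s:1",
              conditional = "t:u;a:u;d:x;r:x;s:1")
  t_row <- function(id, drug, reaction, w, sig, s, m, n, wh, co = "") {
    data.frame(template_id = id, drug = drug, reaction = reaction,
               weight = w, signature = sig, sev_facts = sev[[s]],
               mech_facts = mech[[m]], naranjo_answers = nar[[n]],
               who_facts = who[[wh]], co_admin = co,
               stringsAsFactors = FALSE)
  }
  rbind(
    t_row("insulin_hypo", "Regular insulin", "Hypoglycemia", 22,
          "glucose_lt_50", "moderate", "A", "probable", "probable"),
    t_row("morphine_constip", "Morphine", "Constipation", 13,
          "NONE", "moderate", "A", "possible", "possible"),
    t_row("morphine_rash", "Morphine", "Skin rash", 1,
          "skin_rash", "mild", "B", "possible", "possible"),
    t_row("enox_bleed", "Enoxaparin", "Oral cavity bleeding", 6,
          "hb_ht_drop_25pct", "severe", "A", "possible", "possible"),
    t_row("enox_hematuria", "Enoxaparin", "Hematuria", 1,
          "abrupt_medication_stop", "severe", "A", "possible", "possible"),
    t_row("hep_bleed_ptt", "Heparin", "Oral cavity bleeding", 3,
          "ptt_gt_50", "severe", "A", "possible", "possible"),
    t_row("hep_bleed_stop", "Heparin", "Oral cavity bleeding", 3,
          "abrupt_medication_stop", "severe", "A", "possible", "possible"),
    t_row("hep_epistaxis", "Heparin", "Epistaxis", 1,
          "protamine", "severe", "A", "possible3", "probable"),
    t_row("fentanyl_brady", "Fentanyl", "Bradycardia", 4,
          "abrupt_medication_stop", "moderate", "A", "possible", "possible"),
    t_row("fentanyl_rigid", "Fentanyl", "Chest rigidity", 2,
          "NONE", "severe", "A", "possible", "possible"),
    t_row("amikacin_renal", "Amikacin", "Worsening renal function", 3,
          "bun_cr_rise_2x", "severe", "A", "probable", "probable"),
    t_row("amiodarone_brady", "Amiodarone", "Bradycardia", 2,
          "abrupt_medication_stop", "moderate", "A", "possible", "possible"),
    t_row("bromopride_diarrhea", "Bromopride", "Diarrhea", 2,
          "abrupt_medication_stop", "mild", "A", "possible", "possible"),
    t_row("furosemide_hypok", "Furosemide", "Hypokalemia", 2,
          "potassium_lt_3_0", "moderate", "A", "probable", "probable"),
    t_row("ripe_vomit", "RIPE", "Vomiting", 2,
          "abrupt_medication_stop", "mild", "A", "possible", "possible"),
    t_row("risperidone_loc", "Risperidone", "Decreased level of consciousness",
          2, "oversedation_hypotension", "severe", "A", "possible",
          "possible"),
    t_row("tramadol_nausea", "Tramadol", "Nausea", 2,
          "NONE", "mild", "A", "possible", "possible"),
    t_row("ampsulb_rash", "Ampicillin + Sulbactam", "Skin rash", 1,
          "skin_rash", "mild", "B", "possible", "possible",
          co = "Hydroxyzine"),
    t_row("ampho_hypok", "Amphotericin B", "Hypokalemia", 1,
          "potassium_lt_3_0", "moderate", "A", "probable", "probable"),
    t_row("carvedilol_brady", "Carvedilol", "Bradycardia", 1,
          "NONE", "mild", "A", "doubtful", "unlikely"),
    t_row("clopidogrel_bleed", "Clopidogrel", "Bleeding in tracheostomy", 1,
          "hb_ht_drop_25pct", "severe", "A", "possible", "possible"),
    t_row("scopolamine_ileus", "Scopolamine", "Paralytic ileus", 1,
          "abrupt_medication_stop", "moderate", "A", "possible",
          "conditional"),
    t_row("spirono_hyperk", "Spironolactone", "Hyperkalemia", 1,
          "potassium_gt_5_5", "moderate", "A", "possible", "possible"),
    t_row("hydralazine_hypot", "Hydralazine", "Hypotension", 1,
          "oversedation_hypotension", "severe", "A", "possible", "possible"),
    t_row("hctz_siadh", "Hydrochlorothiazide",
          "Syndrome of inappropriate antidiuretic hormone secretion", 1,
          "sodium_lt_135", "moderate", "A", "possible", "possible"),
    t_row("lactulose_diarrhea", "Lactulose", "Diarrhea", 1,
          "NONE", "mild", "A", "possible", "possible"),
    t_row("levomeprom_loc", "Levomepromazine",
          "Decreased level of consciousness", 1,
          "oversedation_hypotension", "severe", "A", "possible", "possible"),
    t_row("metoclo_agit", "Metoclopramide", "Psychomotor agitation", 1,
          "NONE", "mild", "B", "possible", "possible"),
    t_row("neostig_diarrhea", "Neostigmine", "Diarrhea", 1,
          "NONE", "mild", "A", "possible", "possible"),
    t_row("smx_hyperk", "Sulfamethoxazole + Trimethoprim", "Hyperkalemia", 1,
          "potassium_gt_5_5", "moderate", "A", "possible", "possible"),
    t_row("warfarin_ugib", "Warfarin", "Upper digestive hemorrhage", 1,
          "inr_gt_3", "severe", "A", "probable", "probable")
  )
}

# Background trigger rates per 100 records NOT linked to any embedded ADR:
# the published per-trigger rate minus its ADR-linked rate.
default_noise_rates <- function() {
  c(ptt_gt_50 = 0, inr_gt_3 = 3.0, glucose_lt_50 = 47.4,
    bun_cr_rise_2x = 56.3, ondansetron = 23.7, bromopride = 43.0,
    metoclopramide = 71.2, phytomenadione = 8.9, flumazenil = 0,
    naloxone = 0, protamine = 0, dexchlorpheniramine = 0, hydroxyzine = 0,
    diphenhydramine = 5.2, loratadine = 0, hydrocortisone = 71.1,
    methylprednisolone = 23.0, promethazine = 2.2, prednisone = 7.4,
    oversedation_hypotension = 109.6, abrupt_medication_stop = 27.4,
    hb_ht_drop_25pct = 43.7, patient_fall = 0, skin_rash = 0,
    sodium_lt_135 = 105.2, potassium_lt_3_0 = 49.6,
    potassium_gt_5_5 = 95.6, platelets_lt_50000 = 11.9)
}

#' Default generator calibration
#'
#' The packaged calibration reproduces the study conditions of the
#' surveillance cohort the package emulates: 135 patients, 76/135 in the
#' general ICU and 59/135 in the COVID-19 ICU; per-unit age (60.5 +/- 15.6 vs
#' 62.3 +/- 14.5 years), length of stay (12.2 +/- 10.9 vs 13.8 +/- 11.0 days)
#' and male fraction (39/76 vs 35/59); ICU mortality 94/135; patient-level
#' ADR prevalence 55/135 with the unit/age/stay odds structure of the
#' published risk model (OR 2.379 for the COVID unit, 1.039 per year of age,
#' 1.100 per hospital day); a truncated-geometric ADR count per affected
#' patient with mean 85/55; ADR onset days Beta(2,2) over the stay fraction;
#' per-trigger background rates equal to the published trigger rates minus
#' their ADR-linked share; and a spontaneous reporting probability of 0
#' (every ADR unreported, plus 5 decoy reports from outside the cohort).
#'
#' @param n_patients cohort size.
#' @param adr_patient_prevalence probability that a patient has at least one
#'   ADR (marginal, after covariate effects).
#' @param trigger_noise_rates named numeric vector of background rates per
#'   100 records.
#' @param spontaneous_report_prob probability that an embedded ADR is also
#'   spontaneously reported.
#' @param seed default seed used by \code{\link{generate_cohort}}.
#' @return a \code{gtt_sim_config} list.
#' @export
default_config <- function(n_patients = 135,
                           adr_patient_prevalence = 55 / 135,
                           trigger_noise_rates = default_noise_rates(),
                           spontaneous_report_prob = 0,
                           seed = 1L) {
  structure(list(
    n_patients = n_patients,
    units = list(
      G_ICU = list(fraction = 76 / 135, age_mean = 60.5, age_sd = 15.6,
                   los_mean = 12.2, los_sd = 10.9, sex_male_prob = 39 / 76),
      C19_ICU = list(fraction = 59 / 135, age_mean = 62.3, age_sd = 14.5,
                     los_mean = 13.8, los_sd = 11.0, sex_male_prob = 35 / 59)
    ),
    mortality_prob = 94 / 135,
    adr_patient_prevalence = adr_patient_prevalence,
    adr_count_p = 55 / 85,        # truncated geometric, mean ~ 85/55
    adr_count_max = 6L,
    or_age = 1.039, or_los = 1.100, or_c19 = 2.379,
    ref_age = 61.0, ref_los = 13.0,   # centering constants for the intercept
    onset_shape = c(2, 2),            # Beta over the stay fraction
    sofa = list(admission_mean = 8.0, admission_sd = 4.6,
                drift_death = 0.25, drift_survive = -0.35, walk_sd = 0.8),
    trigger_noise_rates = trigger_noise_rates,
    templates = default_templates(),
    spontaneous_report_prob = spontaneous_report_prob,
    n_external_reports = 5L,
    study_start = as.Date("2020-01-01"),
    study_end = as.Date("2020-12-31"),
    seed = as.integer(seed)
  ), class = "gtt_sim_config")
}

# Mean ADRs per affected patient implied by the truncated geometric.
adr_count_mean <- function(config) {
  p <- config$adr_count_p
  k <- seq_len(config$adr_count_max)
  pr <- p * (1 - p)^(k - 1)
  pr[length(pr)] <- (1 - p)^(config$adr_count_max - 1)  # lump the tail
  sum(k * pr)
}

#' Config-implied per-trigger performance
#'
#' The expected hits per 100 records (background plus signature and
#' co-administration emissions), ADR-linked hits per 100 records, and PPV
#' implied by a generator configuration. These are the values synthetic-
#' recovery tests compare measured performance against. Day-level
#' deduplication collisions and short-stay truncation make realized rates
#' very slightly lower; see the methods vignette.
#'
#' @param config a \code{gtt_sim_config}.
#' @return data.frame with \code{trigger_id, hits_per_100, adrs_per_100,
#'   ppv_pct}.
#' @export
expected_performance <- function(config = default_config()) {
  adr_per_100 <- 100 * config$adr_patient_prevalence * adr_count_mean(config)
  tpl <- config$templates
  w <- tpl$weight / sum(tpl$weight)
  ids <- names(config$trigger_noise_rates)
  signal <- setNames(numeric(length(ids)), ids)
  linked <- signal
  for (i in seq_len(nrow(tpl))) {
    sig <- tpl$signature[i]
    if (sig != "NONE") {
      signal[sig] <- signal[sig] + adr_per_100 * w[i]
      linked[sig] <- linked[sig] + adr_per_100 * w[i]
    }
    if (nzchar(tpl$co_admin[i])) {
      co <- tolower(tpl$co_admin[i])
      if (co %in% ids) signal[co] <- signal[co] + adr_per_100 * w[i]
    }
  }
  hits <- config$trigger_noise_rates + signal
  data.frame(trigger_id = ids,
             hits_per_100 = unname(hits),
             adrs_per_100 = unname(linked),
             ppv_pct = unname(ifelse(hits > 0, 100 * linked / hits, 0)),
             stringsAsFactors = FALSE)
}

#' Generate the patient-level table
#'
#' Draws demographics, stay, outcome and the ADR assignment (the lightweight
#' core of \code{\link{generate_cohort}}, usable on its own for risk-model
#' simulations). Ages are normal, truncated to [19, 100] and rounded; stays
#' are log-normal matched to the per-unit mean/SD and truncated above 1 day.
#' ADR carriage follows a logistic model with the configured odds ratios for
#' age, length of stay and the COVID unit; the intercept is calibrated so the
#' expected prevalence over the drawn covariates equals the configured
#' marginal prevalence.
#'
#' Uses the current RNG state; callers wanting reproducibility set a seed
#' (as \code{\link{generate_cohort}} does).
#'
#' @param config a \code{gtt_sim_config}.
#' @param n number of patients (default \code{config$n_patients}).
#' @return data.frame with one row per patient.
#' @export
generate_patients <- function(config = default_config(),
                              n = config$n_patients) {
  u <- config$units
  unit <- sample(names(u), n, replace = TRUE,
                 prob = vapply(u, `[[`, 0, "fraction"))
  draw_trunc_norm <- function(n, mean, sd, lo, hi) {
    x <- rnorm(n, mean, sd)
    for (it in 1:50) {
      bad <- x < lo | x > hi
      if (!any(bad)) break
      x[bad] <- rnorm(sum(bad), mean, sd)
    }
    pmin(pmax(x, lo), hi)
  }
  age <- numeric(n); los <- numeric(n); male <- logical(n)
  for (un in names(u)) {
    i <- unit == un
    if (!any(i)) next
    p <- u[[un]]
    age[i] <- round(draw_trunc_norm(sum(i), p$age_mean, p$age_sd, 19, 100))
    sigma2 <- log(1 + (p$los_sd / p$los_mean)^2)
    mu <- log(p$los_mean) - sigma2 / 2
    x <- rlnorm(sum(i), mu, sqrt(sigma2))
    for (it in 1:50) {
      bad <- x <= 1 | x > 120
      if (!any(bad)) break
      x[bad] <- rlnorm(sum(bad), mu, sqrt(sigma2))
    }
    los[i] <- pmin(pmax(x, 1.01), 120)
    male[i] <- runif(sum(i)) < p$sex_male_prob
  }
  los_days <- ceiling(los)
  max_offset <- as.integer(config$study_end - config$study_start) - los_days
  admit <- as.POSIXct(config$study_start, tz = "UTC") +
    floor(runif(n) * pmax(max_offset, 1)) * DAY +
    floor(runif(n, 0, 24)) * HOUR
  discharge <- admit + round(los * DAY)
  outcome <- ifelse(runif(n) < config$mortality_prob, "death", "discharge")

  eta <- log(config$or_age) * (age - config$ref_age) +
    log(config$or_los) * (los_days - config$ref_los) +
    log(config$or_c19) * (unit == "C19_ICU")
  prev <- config$adr_patient_prevalence
  if (prev <= 0) {
    p_adr <- rep(0, n)
  } else if (prev >= 1) {
    p_adr <- rep(1, n)
  } else {
    b0 <- uniroot(function(b) mean(stats::plogis(b + eta)) - prev,
                  c(-25, 25))$root
    p_adr <- stats::plogis(b0 + eta)
  }
  has_adr <- runif(n) < p_adr
  n_adrs <- integer(n)
  if (any(has_adr)) {
    n_adrs[has_adr] <- pmin(1L + rgeom(sum(has_adr), config$adr_count_p),
                            config$adr_count_max)
  }
  data.frame(patient_id = sprintf("P%05d", seq_len(n)),
             unit = unit,
             sex = ifelse(male, "male", "female"),
             age = as.integer(age),
             admit_time = admit,
             discharge_time = discharge,
             outcome = outcome,
             los = los, los_days = as.integer(los_days),
             has_adr = has_adr, n_adrs = n_adrs,
             stringsAsFactors = FALSE)
}

## --- event emission ---------------------------------------------------------

# Value bands per SOFA subscore level (values drawn uniformly inside; the
# coagulation level is capped at 2 in routine allocation so that routine
# labs never cross the platelets < 50,000 trigger, and cardiovascular
# level 1 -- MAP below 70 without support -- is reserved for the background
# hypotension process).
sofa_bands <- list(
  respiratory = list(c(405, 495), c(305, 395), c(205, 295), c(105, 195),
                     c(60, 95)),
  coagulation = list(c(160000, 320000), c(105000, 148000), c(55000, 98000),
                     c(25000, 45000), c(8000, 18000)),
  hepatic = list(c(0.3, 1.1), c(1.25, 1.9), c(2.1, 5.8), c(6.1, 11.8),
                 c(12.2, 20)),
  cardiovascular = list(c(75, 95), c(60, 68), c(72, 90), c(72, 90),
                        c(72, 90)),
  neurological = list(c(15, 15), c(13, 14), c(10, 12), c(6, 9), c(3, 5)),
  renal = list(c(0.5, 1.1), c(1.25, 1.9), c(2.05, 3.3), c(3.55, 4.9),
               c(5.1, 7.5))
)
sofa_band_value <- function(organ, level) {
  b <- sofa_bands[[organ]][[level + 1L]]
  if (organ == "neurological") {
    b[1] + sample.int(b[2] - b[1] + 1L, 1L) - 1L
  } else runif(1, b[1], b[2])
}

# Largest-remainder allocation of `points` across the six organs with caps
# (coagulation <= 2) and a cardiovascular level set of {0,2,3,4}.
alloc_subscores <- function(points, w, renal_fixed = NA) {
  caps <- c(respiratory = 4, coagulation = 2, hepatic = 4,
            cardiovascular = 4, neurological = 4, renal = 4)
  s <- setNames(integer(6), names(caps))
  if (!is.na(renal_fixed)) {
    s["renal"] <- renal_fixed
    caps["renal"] <- renal_fixed
    points <- max(points - renal_fixed, 0)
  }
  free <- setdiff(names(caps), if (!is.na(renal_fixed)) "renal" else NULL)
  raw <- points * w[free] / sum(w[free])
  s[free] <- pmin(floor(raw), caps[free])
  frac <- raw - floor(raw)
  guard <- 0L
  while ((rem <- points - sum(s[free])) > 0 && guard < 10L) {
    head <- free[s[free] < caps[free]]
    if (!length(head)) break
    ord <- head[order(-frac[head])]
    take <- ord[seq_len(min(rem, length(ord)))]
    s[take] <- s[take] + 1L
    guard <- guard + 1L
  }
  # cardiovascular level 1 is not emitted by routine allocation
  if (s[["cardiovascular"]] == 1L) {
    s["cardiovascular"] <- 0L
    head <- free[s[free] < caps[free] & free != "cardiovascular"]
    if (length(head)) {
      j <- head[order(-frac[head])][1L]
      s[j] <- s[j] + 1L
    }
  }
  s
}

# Event rows for one embedded ADR. Returns lists of lab rows, courses,
# administrations and notes. `day_time(d, h)` maps hospital day + hour offset
# to a POSIXct within the stay.
adr_event_rows <- function(tpl, onset, day_time, discharge, hb0, creat0,
                           have_drug_course, suppress_admin = FALSE) {
  labs <- list(); courses <- list(); admins <- list(); notes <- list()
  add_lab <- function(d, h, analyte, value) {
    labs[[length(labs) + 1L]] <<- list(timestamp = day_time(d, h),
                                       analyte = analyte, value = value)
  }
  add_course <- function(drug, start, stop, intended = NA, scheduled = TRUE,
                         route = "IV") {
    courses[[length(courses) + 1L]] <<- list(
      drug_name = drug, start_time = start, stop_time = stop,
      intended_end_time = intended, scheduled = scheduled, route = route)
  }
  add_admin <- function(drug, ts) {
    admins[[length(admins) + 1L]] <<- list(drug_name = drug, timestamp = ts)
  }
  sig <- tpl$signature
  # suspected drugs that are themselves administration triggers get a course
  # but no recorded administration, so they do not add to that trigger's
  # hit rate beyond the configured background
  skip_admin <- suppress_admin ||
    normalize_drug(tpl$drug) %in% c("bromopride", "metoclopramide")
  # suspected drug course
  # all signature events share the assessment note's hour offset (+12 h)
  # so they fall on the same calendar hospital day as the recorded onset
  if (sig == "abrupt_medication_stop") {
    start <- max(day_time(1, 0), day_time(onset, 12) - 2 * DAY)
    stop <- day_time(onset, 12)
    add_course(tpl$drug, start, stop, intended = stop + 3 * DAY)
    if (!skip_admin) add_admin(tpl$drug, day_time(onset, 11))
  } else if (sig == "protamine") {
    # antidote reversal of the suspected anticoagulant
    add_course(tpl$drug, day_time(1, 0), discharge)
    if (!skip_admin) add_admin(tpl$drug, day_time(onset, 8))
    add_course("Protamine", day_time(onset, 11), day_time(onset, 14),
               scheduled = FALSE)
    add_admin("Protamine", day_time(onset, 12))
  } else if (!have_drug_course) {
    add_course(tpl$drug, day_time(1, 0), discharge)
    if (!skip_admin) add_admin(tpl$drug, day_time(onset, 8))
  } else if (!skip_admin) {
    add_admin(tpl$drug, day_time(onset, 8))
  }
  # signature events
  if (sig == "glucose_lt_50") add_lab(onset, 12, "GLUCOSE_mg_dL", runif(1, 35, 46))
  if (sig == "ptt_gt_50") add_lab(onset, 12, "PTT_s", runif(1, 55, 80))
  if (sig == "inr_gt_3") add_lab(onset, 12, "INR", runif(1, 3.3, 4.5))
  if (sig == "sodium_lt_135") add_lab(onset, 12, "SODIUM_mEq_L", runif(1, 124, 132))
  if (sig == "potassium_lt_3_0") add_lab(onset, 12, "POTASSIUM_mmol_L", runif(1, 2.4, 2.9))
  if (sig == "potassium_gt_5_5") add_lab(onset, 12, "POTASSIUM_mmol_L", runif(1, 5.7, 6.5))
  if (sig == "hb_ht_drop_25pct") {
    add_lab(onset, 12, "HEMOGLOBIN_g_dL", 0.68 * hb0)
    add_lab(onset, 16, "HEMOGLOBIN_g_dL", hb0)
  }
  if (sig == "bun_cr_rise_2x") {
    add_lab(onset, 12, "CREATININE_mg_dL", 2.2 * creat0)
    add_lab(onset, 16, "CREATININE_mg_dL", creat0)
  }
  if (sig == "oversedation_hypotension") {
    add_lab(onset, 12, "MAP_mmHg", runif(1, 55, 68))
    add_lab(onset, 16, "MAP_mmHg", runif(1, 75, 90))
  }
  if (sig == "skin_rash") {
    notes[[length(notes) + 1L]] <- list(timestamp = day_time(onset, 12),
                                        kind = "SKIN_RASH",
                                        text = "maculopapular rash on trunk")
    if (nzchar(tpl$co_admin)) {
      add_course(tpl$co_admin, day_time(onset, 12), day_time(onset, 14),
                 scheduled = FALSE, route = "PO")
      add_admin(tpl$co_admin, day_time(onset, 12))
    }
  }
  # the structured chart-review assessment note
  notes[[length(notes) + 1L]] <- list(
    timestamp = day_time(onset, 12), kind = "OTHER",
    text = format_adr_note(
      tpl$drug, tpl$reaction,
      strsplit(tpl$naranjo_answers, "")[[1L]],
      strsplit(tpl$sev_facts, "")[[1L]] == "y",
      strsplit(tpl$mech_facts, "")[[1L]] == "y",
      parse_who_facts(tpl$who_facts)))
  list(labs = labs, courses = courses, admins = admins, notes = notes)
}

parse_who_facts <- function(code) {
  wf <- strsplit(strsplit(code, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  wv <- setNames(vapply(wf, `[[`, "", 2L), vapply(wf, `[[`, "", 1L))
  list(temporal_plausibility = c(y = "yes", n = "no", u = "unknown")[[wv[["t"]]]],
       alternative_causes = c(e = "excluded", p = "present",
                              u = "unknown")[[wv[["a"]]]],
       dechallenge = c(p = "positive", n = "negative", x = "none")[[wv[["d"]]]],
       rechallenge = c(p = "positive", n = "negative", x = "none")[[wv[["r"]]]],
       data_sufficient = wv[["s"]] == "1")
}

#' Embed one templated ADR into a patient record
#'
#' Adds the template's suspected-drug course, its signature events (the lab
#' excursion, rescue-drug administration, course stop or note event that
#' makes the signature trigger fire at the onset day) and the structured
#' assessment note to a single record. Used by the generator; exposed for
#' testing single-record behaviour.
#'
#' @param record a \code{patient_record}.
#' @param template one row of \code{\link{default_templates}}.
#' @param onset_day 1-based hospital day of onset.
#' @return the modified \code{patient_record}.
#' @export
embed_adr <- function(record, template, onset_day) {
  stopifnot(inherits(record, "patient_record"))
  p <- record$patient
  los <- as.numeric(difftime(p$discharge_time, p$admit_time, units = "days"))
  if (onset_day > ceiling(los)) {
    stop("onset day ", onset_day, " is beyond the stay (", ceiling(los),
         " days)")
  }
  day_time <- function(d, h) p$admit_time + ((d - 1) * 24 + h) * HOUR
  hb <- record$labs$value[record$labs$analyte == "HEMOGLOBIN_g_dL"]
  cr <- record$labs$value[record$labs$analyte == "CREATININE_mg_dL"]
  t8 <- day_time(onset_day, 8)
  have <- any(normalize_drug(record$medications$drug_name) ==
                normalize_drug(template$drug) &
                record$medications$start_time <= t8 &
                (is.na(record$medications$stop_time) |
                   record$medications$stop_time >= t8))
  ev <- adr_event_rows(template, onset_day, day_time, p$discharge_time,
                       hb0 = if (length(hb)) hb[1L] else 11,
                       creat0 = if (length(cr)) cr[1L] else 1.0,
                       have_drug_course = have)
  bind_rows_list <- function(lst) {
    if (!length(lst)) return(NULL)
    do.call(rbind, lapply(lst, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  append_tab <- function(old, rows, defaults = list()) {
    if (is.null(rows)) return(old)
    rows$patient_id <- p$patient_id
    for (nm in names(defaults)) if (!nm %in% names(rows)) rows[[nm]] <- defaults[[nm]]
    extra <- setdiff(names(old), names(rows))
    for (nm in extra) rows[[nm]] <- old[[nm]][NA_integer_][seq_len(nrow(rows))]
    rbind(old, rows[, names(old), drop = FALSE])
  }
  if (!is.null(ev$labs)) {
    record$labs <- append_tab(record$labs, bind_rows_list(ev$labs))
  }
  crs <- bind_rows_list(ev$courses)
  if (!is.null(crs)) {
    crs$intended_end_time <- as.POSIXct(
      ifelse(is.na(crs$intended_end_time), NA, crs$intended_end_time),
      tz = "UTC", origin = "1970-01-01")
    crs$atc_code <- suppressWarnings(atc_lookup(crs$drug_name))
    crs$course_id <- max(0L, record$medications$course_id) +
      seq_len(nrow(crs))
    record$medications <- append_tab(record$medications, crs)
  }
  if (!is.null(ev$admins)) {
    adm <- bind_rows_list(ev$admins)
    adm$course_id <- NA_integer_
    record$administrations <- append_tab(record$administrations, adm)
  }
  if (!is.null(ev$notes)) {
    record$notes <- append_tab(record$notes, bind_rows_list(ev$notes))
  }
  record
}

## --- whole-cohort generation ------------------------------------------------

#' Generate a synthetic ICU cohort with ground truth
#'
#' Draws the patient table (\code{\link{generate_patients}}), then emits per
#' patient: daily SOFA-variable labs following an admission score with an
#' outcome-dependent drift and a small random walk; daily routine chemistry,
#' haematology and coagulation values in normal ranges; background trigger
#' events at the configured per-100-record rates (Poisson per record, placed
#' on distinct days); and the embedded ADRs -- templates sampled by their
#' calibration weights, onset days Beta-distributed over the stay, each with
#' its suspected-drug course, signature events and structured assessment
#' note. Every embedded ADR is recorded in the returned ground truth with
#' its classification labels derived from the template facts.
#'
#' Identical seeds give identical output.
#'
#' @param config a \code{gtt_sim_config} from \code{\link{default_config}}.
#' @param seed integer seed (default \code{config$seed}).
#' @return list with \code{cohort} (an \code{icu_cohort}) and
#'   \code{ground_truth} (data.frame, one row per embedded ADR).
#' @export
generate_cohort <- function(config = default_config(), seed = config$seed) {
  set.seed(seed)
  pts <- generate_patients(config, config$n_patients)
  n <- nrow(pts)
  tpl <- config$templates
  tpl_prob <- tpl$weight / sum(tpl$weight)
  noise_rates <- config$trigger_noise_rates
  noise_ids <- names(noise_rates)
  # per-record Poisson noise counts, drawn up front (column per trigger)
  noise_k <- vapply(noise_ids, function(t) rpois(n, noise_rates[[t]] / 100),
                    integer(n))
  if (n == 1L) noise_k <- matrix(noise_k, nrow = 1,
                                 dimnames = list(NULL, noise_ids))
  noise_value <- list(
    glucose_lt_50 = list(analyte = "GLUCOSE_mg_dL", lo = 35, hi = 46),
    sodium_lt_135 = list(analyte = "SODIUM_mEq_L", lo = 124, hi = 132),
    potassium_lt_3_0 = list(analyte = "POTASSIUM_mmol_L", lo = 2.4, hi = 2.9),
    potassium_gt_5_5 = list(analyte = "POTASSIUM_mmol_L", lo = 5.7, hi = 6.5),
    inr_gt_3 = list(analyte = "INR", lo = 3.3, hi = 4.5),
    ptt_gt_50 = list(analyte = "PTT_s", lo = 55, hi = 80),
    platelets_lt_50000 = list(analyte = "PLATELETS_per_uL", lo = 25000,
                              hi = 45000, rec_lo = 160000, rec_hi = 320000),
    oversedation_hypotension = list(analyte = "MAP_mmHg", lo = 55, hi = 68,
                                    rec_lo = 75, rec_hi = 90)
  )
  med_noise_drug <- c(ondansetron = "Ondansetron", bromopride = "Bromopride",
                      metoclopramide = "Metoclopramide",
                      phytomenadione = "Phytomenadione",
                      flumazenil = "Flumazenil", naloxone = "Naloxone",
                      protamine = "Protamine",
                      dexchlorpheniramine = "Dexchlorpheniramine",
                      hydroxyzine = "Hydroxyzine",
                      diphenhydramine = "Diphenhydramine",
                      loratadine = "Loratadine",
                      hydrocortisone = "Hydrocortisone",
                      methylprednisolone = "Methylprednisolone",
                      promethazine = "Promethazine", prednisone = "Prednisone")
  abrupt_decoys <- c("Ceftriaxone", "Vancomycin", "Meropenem")

  acc <- list(labs = list(), meds = list(), admins = list(), notes = list(),
              gt = list())
  sofa_cfg <- config$sofa
  organs <- names(sofa_bands)

  for (i in seq_len(n)) {
    pid <- pts$patient_id[i]
    admit <- as.numeric(pts$admit_time[i])
    discharge_num <- as.numeric(pts$discharge_time[i])
    los <- pts$los[i]
    D <- pts$los_days[i]
    day_num <- function(d, h) admit + ((d - 1) * 24 + h) * HOUR
    D_ex <- max(1L, as.integer(floor(los + 1 / 3)))     # +16 h offset fits
    s_abrupt <- as.integer(floor(los - 0.5))            # stop at +12 h, >24 h pre-discharge

    l_ts <- numeric(0); l_an <- character(0); l_val <- numeric(0)
    add_lab <- function(d, h, analyte, value) {
      l_ts <<- c(l_ts, day_num(d, h)); l_an <<- c(l_an, analyte)
      l_val <<- c(l_val, value)
    }
    m_drug <- character(0); m_start <- numeric(0); m_stop <- numeric(0)
    m_int <- numeric(0); m_sched <- logical(0); m_route <- character(0)
    add_course <- function(drug, start, stop, intended = NA_real_,
                           scheduled = TRUE, route = "IV") {
      m_drug <<- c(m_drug, drug); m_start <<- c(m_start, start)
      m_stop <<- c(m_stop, stop); m_int <<- c(m_int, intended)
      m_sched <<- c(m_sched, scheduled); m_route <<- c(m_route, route)
    }
    a_drug <- character(0); a_ts <- numeric(0)
    add_admin <- function(drug, ts) {
      a_drug <<- c(a_drug, drug); a_ts <<- c(a_ts, ts)
    }
    n_ts <- numeric(0); n_kind <- character(0); n_text <- character(0)
    add_note <- function(ts, kind, text) {
      n_ts <<- c(n_ts, ts); n_kind <<- c(n_kind, kind)
      n_text <<- c(n_text, text)
    }

    ## SOFA trajectory targets and daily variable emission
    adm_score <- min(max(round(rnorm(1, sofa_cfg$admission_mean,
                                     sofa_cfg$admission_sd)), 0), 20)
    drift <- if (pts$outcome[i] == "death") sofa_cfg$drift_death else
      sofa_cfg$drift_survive
    walk <- cumsum(c(0, rnorm(D - 1, 0, sofa_cfg$walk_sd)))
    targets <- pmin(pmax(round(adm_score + drift * (seq_len(D) - 1) + walk),
                         0), 20)
    w <- setNames(rgamma(6, 1) + 0.05, organs)
    renal0 <- NA
    hb0 <- runif(1, 9.5, 13.5)
    creat0 <- NA
    for (d in seq_len(D)) {
      s <- alloc_subscores(targets[d], w, renal_fixed = renal0)
      if (d == 1L) renal0 <- s[["renal"]]
      for (o in organs) {
        lv <- s[[o]]
        if (o == "renal") {
          if (is.na(creat0)) creat0 <- sofa_band_value("renal", lv)
          band <- sofa_bands$renal[[lv + 1L]]
          val <- min(max(creat0 * runif(1, 0.98, 1.02), band[1]), band[2])
        } else {
          val <- sofa_band_value(o, lv)
        }
        analyte <- switch(o, respiratory = "PAO2_FIO2_ratio",
                          coagulation = "PLATELETS_per_uL",
                          hepatic = "BILIRUBIN_mg_dL",
                          cardiovascular = "MAP_mmHg",
                          neurological = "GCS_points",
                          renal = "CREATININE_mg_dL")
        add_lab(d, 0, analyte, val)
        if (o == "cardiovascular" && lv >= 2) {
          agents <- switch(as.character(lv), "2" = "Dopamine",
                           "3" = "Norepinephrine",
                           c("Norepinephrine", "Epinephrine"))
          for (ag in agents) {
            add_course(ag, day_num(d, 0), min(day_num(d, 24), discharge_num))
          }
        }
      }
      add_lab(d, 0, "GLUCOSE_mg_dL", runif(1, 90, 180))
      add_lab(d, 0, "SODIUM_mEq_L", runif(1, 137, 144))
      add_lab(d, 0, "POTASSIUM_mmol_L", runif(1, 3.6, 4.9))
      add_lab(d, 0, "HEMOGLOBIN_g_dL", hb0 * runif(1, 0.98, 1.02))
      add_lab(d, 0, "PTT_s", runif(1, 26, 38))
      add_lab(d, 0, "INR", runif(1, 0.9, 1.4))
    }

    ## background medication + sedation
    add_course("Omeprazole", day_num(1, 0.5), discharge_num, route = "PO")
    add_admin("Omeprazole", day_num(1, 1))
    add_course("Dipyrone", day_num(1, 0.5), discharge_num)
    add_admin("Dipyrone", day_num(1, 1))
    if (runif(1) < 0.6) {
      add_course("Midazolam", day_num(1, 0.5),
                 min(day_num(min(5, D), 20), discharge_num))
      add_admin("Midazolam", day_num(1, 1))
    }

    ## background (noise) trigger events
    for (t in noise_ids) {
      k <- noise_k[i, t]
      if (k == 0L) next
      if (t %in% names(noise_value)) {
        nv <- noise_value[[t]]
        days <- sample(seq_len(D_ex), min(k, D_ex))
        for (d in days) {
          add_lab(d, 10, nv$analyte, runif(1, nv$lo, nv$hi))
          if (!is.null(nv$rec_lo)) {
            add_lab(d, 16, nv$analyte, runif(1, nv$rec_lo, nv$rec_hi))
          }
        }
      } else if (t == "hb_ht_drop_25pct") {
        days <- sample(seq_len(D_ex), min(k, D_ex))
        for (d in days) {
          add_lab(d, 10, "HEMOGLOBIN_g_dL", 0.70 * hb0)
          add_lab(d, 16, "HEMOGLOBIN_g_dL", hb0)
        }
      } else if (t == "bun_cr_rise_2x") {
        days <- sample(seq_len(D_ex), min(k, D_ex))
        for (d in days) {
          add_lab(d, 10, "CREATININE_mg_dL", 2.2 * creat0)
          add_lab(d, 16, "CREATININE_mg_dL", creat0)
        }
      } else if (t %in% names(med_noise_drug)) {
        drug <- med_noise_drug[[t]]
        days <- sort(sample(seq_len(D_ex), min(k, D_ex)))
        add_course(drug, day_num(min(days), 8), day_num(max(days), 10),
                   scheduled = FALSE)
        for (d in days) add_admin(drug, day_num(d, 9))
      } else if (t == "abrupt_medication_stop") {
        if (s_abrupt >= 1L) {
          days <- sample(seq_len(s_abrupt),
                         min(k, s_abrupt, length(abrupt_decoys)))
          for (j in seq_along(days)) {
            drug <- abrupt_decoys[j]
            stop_t <- day_num(days[j], 2)
            add_course(drug, day_num(1, 1), stop_t,
                       intended = stop_t + 3 * DAY)
            add_admin(drug, day_num(1, 1.5))
            if (days[j] > 1) add_admin(drug, day_num(days[j], 1.5))
          }
        }
      } else if (t == "patient_fall") {
        days <- sample(seq_len(D_ex), min(k, D_ex))
        for (d in days) add_note(day_num(d, 12), "PATIENT_FALL",
                                 "patient found on floor")
      } else if (t == "skin_rash") {
        days <- sample(seq_len(D_ex), min(k, D_ex))
        for (d in days) add_note(day_num(d, 11), "SKIN_RASH",
                                 "erythematous rash")
      }
    }

    ## embedded ADRs
    k_adr <- pts$n_adrs[i]
    if (k_adr > 0L) {
      chosen <- sample(seq_len(nrow(tpl)), k_adr, replace = TRUE,
                       prob = tpl_prob)
      used_days <- integer(0)
      drug_days <- list()  # onset days already used per suspected drug
      for (ti in chosen) {
        trow <- tpl[ti, , drop = FALSE]
        eff_sig <- trow$signature
        allowed <- if (eff_sig == "abrupt_medication_stop") {
          if (s_abrupt < 1L) { eff_sig <- "NONE"; seq_len(D_ex) } else
            seq_len(min(s_abrupt, D_ex))
        } else seq_len(D_ex)
        free <- setdiff(allowed, used_days)
        if (!length(free)) next  # stay too short for another distinct onset
        # keep repeat ADRs of the same drug >= 2 days apart, so one ADR's
        # administrations cannot mask another's abrupt-stop signature
        dkey <- normalize_drug(trow$drug)
        prior <- drug_days[[dkey]]
        suppress <- FALSE
        if (!is.null(prior)) {
          apart <- free[vapply(free, function(d) all(abs(d - prior) >= 2),
                               logical(1))]
          if (length(apart)) {
            free <- apart
          } else {
            # cannot keep same-drug events 2 days apart: no administrations
            # for this ADR (and no stop), so earlier signatures stay intact
            suppress <- TRUE
            if (eff_sig == "abrupt_medication_stop") eff_sig <- "NONE"
          }
        }
        if (eff_sig == "abrupt_medication_stop") {
          # an administration of the same drug (e.g. an as-needed background
          # course) inside the 24 h after the stop would censor the trigger;
          # keep only onset days with a clean post-stop window
          same <- a_drug == trow$drug
          clean <- free[vapply(free, function(d) {
            stop_t <- day_num(d, 12)
            !any(same & a_ts > stop_t & a_ts <= stop_t + DAY)
          }, logical(1))]
          if (length(clean)) free <- clean else eff_sig <- "NONE"
        }
        onset <- ceiling(rbeta(1, config$onset_shape[1],
                               config$onset_shape[2]) * los)
        onset <- max(1L, min(onset, max(allowed)))
        if (!onset %in% free) onset <- free[which.min(abs(free - onset))]
        used_days <- c(used_days, onset)
        drug_days[[dkey]] <- c(prior, onset)
        trow$signature <- eff_sig
        # does an existing course of this drug cover the onset administration?
        t8 <- day_num(onset, 8)
        have <- any(normalize_drug(m_drug) == normalize_drug(trow$drug) &
                      m_start <= t8 & m_stop >= t8)
        ev <- adr_event_rows(trow, onset, function(d, h) day_num(d, h),
                             discharge_num, hb0, creat0,
                             have_drug_course = have,
                             suppress_admin = suppress)
        for (r in ev$labs) {
          l_ts <- c(l_ts, as.numeric(r$timestamp))
          l_an <- c(l_an, r$analyte)
          l_val <- c(l_val, r$value)
        }
        for (r in ev$courses) {
          add_course(r$drug_name, as.numeric(r$start_time),
                     as.numeric(r$stop_time),
                     intended = if (is.na(r$intended_end_time)) NA_real_ else
                       as.numeric(r$intended_end_time),
                     scheduled = r$scheduled, route = r$route)
        }
        for (r in ev$admins) add_admin(r$drug_name, as.numeric(r$timestamp))
        for (r in ev$notes) add_note(as.numeric(r$timestamp), r$kind, r$text)
        ans <- c(y = "yes", n = "no",
                 u = "unknown")[strsplit(trow$naranjo_answers, "")[[1L]]]
        score <- naranjo_score(unname(ans))
        # onset recorded as the calendar hospital day of the assessment
        # note (the same convention trigger hits and adjudication use)
        onset_cal <- hospital_day(
          as.POSIXct(day_num(onset, 12), tz = "UTC",
                     origin = "1970-01-01"), pts$admit_time[i])
        acc$gt[[length(acc$gt) + 1L]] <- data.frame(
          patient_id = pid, template_id = trow$template_id,
          drug_name = trow$drug,
          atc_code = suppressWarnings(atc_lookup(trow$drug)),
          reaction = trow$reaction, onset_day = onset_cal,
          signature_trigger = eff_sig,
          severity = do.call(classify_severity, as.list(
            setNames(strsplit(trow$sev_facts, "")[[1L]] == "y",
                     c("intervention_required", "therapy_change",
                       "life_threatening_or_prolonging")))),
          mechanism = classify_mechanism(
            substr(trow$mech_facts, 1, 1) == "y",
            substr(trow$mech_facts, 2, 2) == "y"),
          naranjo_score = score,
          naranjo_category = naranjo_category(score),
          who_causality = do.call(who_causality,
                                  parse_who_facts(trow$who_facts)),
          stringsAsFactors = FALSE)
      }
    }

    acc$labs[[i]] <- list(pid = rep(pid, length(l_ts)), ts = l_ts,
                          an = l_an, val = l_val)
    acc$meds[[i]] <- list(pid = rep(pid, length(m_drug)), drug = m_drug,
                          start = m_start, stop = m_stop, int = m_int,
                          sched = m_sched, route = m_route)
    acc$admins[[i]] <- list(pid = rep(pid, length(a_drug)), drug = a_drug,
                            ts = a_ts)
    acc$notes[[i]] <- list(pid = rep(pid, length(n_ts)), ts = n_ts,
                           kind = n_kind, text = n_text)
  }

  cat_field <- function(lst, f) unlist(lapply(lst, `[[`, f), use.names = FALSE)
  posix <- function(x) as.POSIXct(x, tz = "UTC", origin = "1970-01-01")
  labs <- data.frame(patient_id = cat_field(acc$labs, "pid"),
                     timestamp = posix(cat_field(acc$labs, "ts")),
                     analyte = cat_field(acc$labs, "an"),
                     value = cat_field(acc$labs, "val"),
                     stringsAsFactors = FALSE)
  meds <- data.frame(patient_id = cat_field(acc$meds, "pid"),
                     drug_name = cat_field(acc$meds, "drug"),
                     atc_code = "",
                     start_time = posix(cat_field(acc$meds, "start")),
                     stop_time = posix(cat_field(acc$meds, "stop")),
                     intended_end_time = posix(cat_field(acc$meds, "int")),
                     scheduled = cat_field(acc$meds, "sched"),
                     route = cat_field(acc$meds, "route"),
                     stringsAsFactors = FALSE)
  meds$atc_code <- suppressWarnings(atc_lookup(meds$drug_name))
  admins <- data.frame(patient_id = cat_field(acc$admins, "pid"),
                       drug_name = cat_field(acc$admins, "drug"),
                       timestamp = posix(cat_field(acc$admins, "ts")),
                       stringsAsFactors = FALSE)
  notes <- data.frame(patient_id = cat_field(acc$notes, "pid"),
                      timestamp = posix(cat_field(acc$notes, "ts")),
                      kind = cat_field(acc$notes, "kind"),
                      text = cat_field(acc$notes, "text"),
                      stringsAsFactors = FALSE)
  gt <- if (length(acc$gt)) do.call(rbind, acc$gt) else
    data.frame(patient_id = character(0), template_id = character(0),
               drug_name = character(0), atc_code = character(0),
               reaction = character(0), onset_day = integer(0),
               signature_trigger = character(0), severity = character(0),
               mechanism = character(0), naranjo_score = integer(0),
               naranjo_category = character(0), who_causality = character(0),
               stringsAsFactors = FALSE)
  rownames(gt) <- NULL

  ## spontaneous reports: decoys from outside the cohort plus (optionally)
  ## reported embedded ADRs
  sp <- data.frame(patient_id = character(0), report_date = as.Date(character(0)),
                   drug_name = character(0), reaction_text = character(0),
                   stringsAsFactors = FALSE)
  if (config$n_external_reports > 0) {
    sp <- rbind(sp, data.frame(
      patient_id = sprintf("EXT%03d", seq_len(config$n_external_reports)),
      report_date = config$study_start +
        sample.int(as.integer(config$study_end - config$study_start),
                   config$n_external_reports, replace = TRUE),
      drug_name = "Dipyrone",
      reaction_text = "skin rash / pruritus",
      stringsAsFactors = FALSE))
  }
  if (config$spontaneous_report_prob > 0 && nrow(gt) > 0) {
    rep_i <- which(runif(nrow(gt)) < config$spontaneous_report_prob)
    if (length(rep_i)) {
      adm_idx <- match(gt$patient_id[rep_i], pts$patient_id)
      sp <- rbind(sp, data.frame(
        patient_id = gt$patient_id[rep_i],
        report_date = as.Date(pts$admit_time[adm_idx], tz = "UTC") +
          gt$onset_day[rep_i],
        drug_name = gt$drug_name[rep_i],
        reaction_text = gt$reaction[rep_i],
        stringsAsFactors = FALSE))
    }
  }

  co <- cohort(patients = pts[, c("patient_id", "unit", "sex", "age",
                                  "admit_time", "discharge_time", "outcome")],
               labs = labs, medications = meds, administrations = admins,
               notes = notes, spontaneous_reports = sp)
  v <- cohort_violations(co); e <- cohort_exclusions(co)
  if (nrow(v) > 0 || nrow(e) > 0) {
    detail <- if (nrow(v)) {
      paste(utils::capture.output(print(head(v, 5))), collapse = "\n")
    } else paste(e$reason[1], collapse = "; ")
    stop("internal error: generated cohort is not clean (", nrow(v),
         " violations, ", nrow(e), " exclusions)\n", detail)
  }
  list(cohort = co, ground_truth = gt)
}
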