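test_that("length of stay arithmetic and whole-day reporting", {
  rec <- make_record(los_days = 13)
  expect_equal(length_of_stay(rec), 13)

  co <- cohort(patients = data.frame(
    patient_id = "A", unit = "G_ICU", sex = "female", age = 70,
    admit_time = as.POSIXct("2020-01-01 08:00:00", tz = "UTC"),
    discharge_time = as.POSIXct("2020-01-02 20:00:00", tz = "UTC"),
    outcome = "discharge"),
    medications = data.frame(
      patient_id = "A", drug_name = "Dipyrone", atc_code = "",
      start_time = as.POSIXct("2020-01-01 09:00:00", tz = "UTC"),
      stop_time = as.POSIXct("2020-01-02 09:00:00", tz = "UTC"),
      intended_end_time = NA, scheduled = TRUE, route = "IV"))
  rec <- patient_record(co, "A")
  expect_equal(length_of_stay(rec), 1.5)
  expect_equal(length_of_stay(rec, whole = TRUE), 2)
})

test_that("eligibility screen excludes minors, short stays and unmedicated records", {
  patients <- data.frame(
    patient_id = c("OK", "YOUNG", "SHORT", "NOMED"),
    unit = "G_ICU", sex = "male", age = c(60, 18, 60, 60),
    admit_time = T0,
    discharge_time = c(T0 + 5 * 86400, T0 + 5 * 86400,
                       T0 + 20 * 3600,        # 20-hour stay
                       T0 + 5 * 86400),
    outcome = "discharge", stringsAsFactors = FALSE)
  meds <- data.frame(patient_id = c("OK", "YOUNG", "SHORT"),
                     drug_name = "Dipyrone", atc_code = "",
                     start_time = T0 + 3600, stop_time = T0 + 7200,
                     intended_end_time = NA, scheduled = TRUE, route = "IV",
                     stringsAsFactors = FALSE)
  co <- cohort(patients = patients, medications = meds)
  expect_equal(co$patients$patient_id, "OK")
  excl <- cohort_exclusions(co)
  expect_setequal(excl$patient_id, c("YOUNG", "SHORT", "NOMED"))
  expect_match(excl$reason[excl$patient_id == "SHORT"], "24 hours")
  expect_match(excl$reason[excl$patient_id == "YOUNG"], "age")
  expect_match(excl$reason[excl$patient_id == "NOMED"], "medication")
})

test_that("invariant-violating rows are collected with their location, not silently dropped", {
  co <- make_cohort(labs = rbind(
    lab_rows("P1", 2, 8, "PLATELETS_per_uL", -5),      # negative count
    lab_rows("P1", 2, 9, "PLATELETS_per_uL", 180000),
    lab_rows("P1", 30, 0, "SODIUM_mEq_L", 140),        # outside the stay
    lab_rows("P1", 3, 0, "GCS_points", 17)))           # outside 3..15
  v <- cohort_violations(co)
  expect_equal(nrow(v), 3)
  expect_setequal(v$table, "labs")
  expect_true(all(c(2, 4, 5) %in% v$line))  # header is line 1
  expect_equal(nrow(co$labs), 1)
  expect_equal(co$labs$value, 180000)
})

test_that("unit strings outside the two ICUs are violations", {
  patients <- data.frame(patient_id = c("A", "B"),
                         unit = c("G-ICU", "WARD_3"), sex = "male",
                         age = 50, admit_time = T0,
                         discharge_time = T0 + 3 * 86400,
                         outcome = "death", stringsAsFactors = FALSE)
  meds <- data.frame(patient_id = c("A", "B"), drug_name = "Dipyrone",
                     atc_code = "", start_time = T0 + 3600,
                     stop_time = T0 + 7200, intended_end_time = NA,
                     scheduled = TRUE, route = "IV", stringsAsFactors = FALSE)
  co <- cohort(patients = patients, medications = meds)
  expect_equal(co$patients$patient_id, "A")  # G-ICU normalized to G_ICU
  v <- cohort_violations(co)
  expect_true(any(v$field == "unit" & v$patient_id == "B"))
})

test_that("write_cohort then read_cohort is the identity on generated cohorts", {
  sim <- generate_cohort(default_config(n_patients = 12), seed = 31)
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim$cohort, dir)
  expect_setequal(names(paths),
                  c("patients", "labs", "medications", "administrations",
                    "notes", "spontaneous_reports"))
  back <- read_cohort(dir)
  expect_equal(nrow(cohort_violations(back)), 0)
  expect_equal(nrow(cohort_exclusions(back)), 0)
  for (tab in c("patients", "labs", "notes", "spontaneous_reports")) {
    a <- sim$cohort[[tab]]; b <- back[[tab]]
    a <- a[do.call(order, a[1:2]), ]; b <- b[do.call(order, b[1:2]), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a, tolerance = 1e-9)
  }
  # medications/administrations: compare without the internal course ids
  a <- sim$cohort$medications[, cohort_schemas$medications]
  b <- back$medications[, cohort_schemas$medications]
  ord <- function(d) d[order(d$patient_id, d$drug_name, d$start_time), ]
  expect_equal(`rownames<-`(ord(b), NULL), `rownames<-`(ord(a), NULL),
               tolerance = 1e-9)
  a <- sim$cohort$administrations[, cohort_schemas$administrations]
  b <- back$administrations[, cohort_schemas$administrations]
  ord <- function(d) d[order(d$patient_id, d$drug_name, d$timestamp), ]
  expect_equal(`rownames<-`(ord(b), NULL), `rownames<-`(ord(a), NULL),
               tolerance = 1e-9)
  # row counts on disk match the in-memory event counts
  for (tab in names(paths)) {
    n_disk <- nrow(utils::read.csv(paths[[tab]]))
    expect_equal(n_disk, nrow(sim$cohort[[tab]]), info = tab)
  }
})

test_that("an empty cohort writes headers-only files", {
  patients <- data.frame(patient_id = character(0), unit = character(0),
                         sex = character(0), age = integer(0),
                         admit_time = character(0),
                         discharge_time = character(0),
                         outcome = character(0))
  co <- cohort(patients = patients)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  for (p in paths) {
    expect_equal(length(readLines(p)), 1L)
  }
  back <- read_cohort(dir)
  expect_equal(nrow(back$patients), 0)
})

test_that("event timestamps of accepted records always lie inside the stay", {
  sim <- generate_cohort(default_config(n_patients = 25), seed = 8)
  co <- sim$cohort
  idx <- match(co$labs$patient_id, co$patients$patient_id)
  expect_true(all(co$labs$timestamp >= co$patients$admit_time[idx] &
                    co$labs$timestamp <= co$patients$discharge_time[idx]))
  idx <- match(co$notes$patient_id, co$patients$patient_id)
  expect_true(all(co$notes$timestamp >= co$patients$admit_time[idx] &
                    co$notes$timestamp <= co$patients$discharge_time[idx]))
  idx <- match(co$medications$patient_id, co$patients$patient_id)
  expect_true(all(co$medications$start_time >= co$patients$admit_time[idx] &
                    co$medications$stop_time <=
                      co$patients$discharge_time[idx]))
})
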