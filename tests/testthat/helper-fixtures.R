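# Shared fixture builders. All records are anchored at a midnight admission
# so hospital days coincide with 24-hour blocks, which keeps hand-computed
# expectations simple.

T0 <- as.POSIXct("2020-03-01 00:00:00", tz = "UTC")

ts_day <- function(day, hour = 0) T0 + ((day - 1) * 24 + hour) * 3600

# A single-patient cohort with sensible defaults; extra event rows can be
# supplied as data.frames. Always includes one medication course so the
# record passes the eligibility screen.
make_cohort <- function(id = "P1", unit = "G_ICU", sex = "male", age = 60,
                        los_days = 10, outcome = "discharge",
                        labs = NULL, medications = NULL,
                        administrations = NULL, notes = NULL,
                        spontaneous_reports = NULL,
                        admit = T0) {
  patients <- data.frame(patient_id = id, unit = unit, sex = sex, age = age,
                         admit_time = admit,
                         discharge_time = admit + los_days * 86400,
                         outcome = outcome, stringsAsFactors = FALSE)
  base_med <- data.frame(patient_id = id, drug_name = "Omeprazole",
                         atc_code = "A02BC01", start_time = admit + 3600,
                         stop_time = admit + los_days * 86400 - 3600,
                         intended_end_time = as.POSIXct(NA, tz = "UTC"),
                         scheduled = TRUE, route = "PO",
                         stringsAsFactors = FALSE)
  medications <- if (is.null(medications)) base_med else
    rbind(base_med, medications)
  cohort(patients = patients, labs = labs, medications = medications,
         administrations = administrations, notes = notes,
         spontaneous_reports = spontaneous_reports)
}

make_record <- function(...) {
  co <- make_cohort(...)
  patient_record(co, co$patients$patient_id[1])
}

lab_rows <- function(id, days, hours, analyte, values) {
  data.frame(patient_id = id, timestamp = ts_day(days, hours),
             analyte = analyte, value = values, stringsAsFactors = FALSE)
}

# Independent daily-deduplication oracle: qualifying timestamps grouped by
# calendar day, one hit per day.
dedup_days_oracle <- function(timestamps) {
  length(unique(as.Date(timestamps, tz = "UTC")))
}
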