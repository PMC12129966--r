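# Structured EHR data model: one ICU stay per patient with time-stamped
# laboratory results, medication courses/administrations, clinical note
# events, and a hospital-wide spontaneous-report log. The on-disk interchange
# format is a set of six delimited UTF-8 files with fixed headers (see
# read_cohort); the in-memory form is an "icu_cohort" list of data.frames.

UNITS <- c("G_ICU", "C19_ICU")
SEXES <- c("male", "female")
OUTCOMES <- c("death", "discharge")
ANALYTES <- c("PTT_s", "INR", "GLUCOSE_mg_dL", "SODIUM_mEq_L",
              "POTASSIUM_mmol_L", "PLATELETS_per_uL", "HEMOGLOBIN_g_dL",
              "HEMATOCRIT_pct", "BUN_mg_dL", "CREATININE_mg_dL",
              "BILIRUBIN_mg_dL", "PAO2_FIO2_ratio", "GCS_points", "MAP_mmHg")
NOTE_KINDS <- c("SKIN_RASH", "PATIENT_FALL", "OVER_SEDATION", "OTHER")
ATC_PATTERN <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

cohort_schemas <- list(
  patients = c("patient_id", "unit", "sex", "age", "admit_time",
               "discharge_time", "outcome"),
  labs = c("patient_id", "timestamp", "analyte", "value"),
  medications = c("patient_id", "drug_name", "atc_code", "start_time",
                  "stop_time", "intended_end_time", "scheduled", "route"),
  administrations = c("patient_id", "drug_name", "timestamp"),
  notes = c("patient_id", "timestamp", "kind", "text"),
  spontaneous_reports = c("patient_id", "report_date", "drug_name",
                          "reaction_text")
)

new_violation <- function(table, line, patient_id, field, message) {
  data.frame(table = table, line = line, patient_id = patient_id,
             field = field, message = message, stringsAsFactors = FALSE)
}

#' Assemble and validate an ICU cohort
#'
#' Builds an \code{icu_cohort} from its component tables, enforcing the data
#' model invariants. Rows that violate an invariant are removed from the
#' valid cohort and collected in the \code{violations} attribute (table, line,
#' patient, field, message) rather than silently dropped. Whole records that
#' fail the eligibility screen (adults over 18 years, admitted for more than
#' 24 hours, at least one prescribed medication) are excluded with a logged
#' reason in the \code{exclusions} attribute.
#'
#' @param patients data.frame with columns \code{patient_id, unit, sex, age,
#'   admit_time, discharge_time, outcome}.
#' @param labs data.frame with \code{patient_id, timestamp, analyte, value}.
#' @param medications data.frame with \code{patient_id, drug_name, atc_code,
#'   start_time, stop_time, intended_end_time, scheduled, route}.
#' @param administrations data.frame with \code{patient_id, drug_name, timestamp}.
#' @param notes data.frame with \code{patient_id, timestamp, kind, text}.
#' @param spontaneous_reports data.frame with \code{patient_id, report_date,
#'   drug_name, reaction_text}.
#' @return an object of class \code{icu_cohort}: a list of the six normalized
#'   tables with attributes \code{violations} and \code{exclusions}.
#' @export
cohort <- function(patients,
                   labs = NULL, medications = NULL, administrations = NULL,
                   notes = NULL, spontaneous_reports = NULL) {
  viol <- list()
  add_viol <- function(...) viol[[length(viol) + 1L]] <<- new_violation(...)

  patients <- normalize_table(patients, "patients")
  labs <- normalize_table(labs, "labs")
  medications <- normalize_table(medications, "medications")
  administrations <- normalize_table(administrations, "administrations")
  notes <- normalize_table(notes, "notes")
  spontaneous_reports <- normalize_table(spontaneous_reports, "spontaneous_reports")

  ## --- patient-level checks -------------------------------------------------
  keep <- rep(TRUE, nrow(patients))
  dup <- duplicated(patients$patient_id)
  for (i in which(dup)) {
    add_viol("patients", patients$.line[i], patients$patient_id[i],
             "patient_id", "duplicate patient_id; first occurrence kept")
  }
  keep[dup] <- FALSE
  bad_unit <- !patients$unit %in% UNITS
  bad_sex <- !patients$sex %in% SEXES
  bad_outcome <- !patients$outcome %in% OUTCOMES
  bad_time <- is.na(patients$admit_time) | is.na(patients$discharge_time) |
    patients$discharge_time <= patients$admit_time
  bad_age <- is.na(patients$age) | patients$age < 0
  for (i in which(keep & bad_unit)) {
    add_viol("patients", patients$.line[i], patients$patient_id[i], "unit",
             paste0("unit must be one of G-ICU, C19-ICU: got '",
                    patients$unit[i], "'"))
  }
  for (i in which(keep & bad_sex)) {
    add_viol("patients", patients$.line[i], patients$patient_id[i], "sex",
             "sex must be male or female")
  }
  for (i in which(keep & bad_outcome)) {
    add_viol("patients", patients$.line[i], patients$patient_id[i], "outcome",
             "outcome must be death or discharge")
  }
  for (i in which(keep & bad_time)) {
    add_viol("patients", patients$.line[i], patients$patient_id[i],
             "discharge_time", "discharge_time must be after admit_time")
  }
  for (i in which(keep & bad_age)) {
    add_viol("patients", patients$.line[i], patients$patient_id[i], "age",
             "age missing or negative")
  }
  keep <- keep & !(bad_unit | bad_sex | bad_outcome | bad_time | bad_age)
  patients <- patients[keep, , drop = FALSE]

  stay <- patients[, c("patient_id", "admit_time", "discharge_time")]

  ## --- event-table checks ---------------------------------------------------
  check_events <- function(df, table, ts_col) {
    if (nrow(df) == 0) return(df)
    idx <- match(df$patient_id, stay$patient_id)
    ok <- !is.na(idx)
    for (i in which(!ok)) {
      add_viol(table, df$.line[i], df$patient_id[i], "patient_id",
               "no such patient in patients table")
    }
    ts <- df[[ts_col]]
    bad_ts <- ok & (is.na(ts) | ts < stay$admit_time[idx] |
                      ts > stay$discharge_time[idx])
    for (i in which(bad_ts)) {
      add_viol(table, df$.line[i], df$patient_id[i], ts_col,
               "timestamp missing or outside the stay window")
    }
    df[ok & !bad_ts, , drop = FALSE]
  }

  # labs: value range invariants
  if (nrow(labs) > 0) {
    bad_an <- !labs$analyte %in% ANALYTES
    for (i in which(bad_an)) {
      add_viol("labs", labs$.line[i], labs$patient_id[i], "analyte",
               paste0("unknown analyte '", labs$analyte[i], "'"))
    }
    labs <- labs[!bad_an, , drop = FALSE]
    bad_val <- is.na(labs$value) | !is.finite(labs$value) | labs$value < 0 |
      (labs$analyte == "GCS_points" & (labs$value < 3 | labs$value > 15)) |
      (labs$analyte == "MAP_mmHg" & labs$value >= 300)
    for (i in which(bad_val)) {
      add_viol("labs", labs$.line[i], labs$patient_id[i], "value",
               paste0("invalid value ", labs$value[i], " for ", labs$analyte[i]))
    }
    labs <- labs[!bad_val, , drop = FALSE]
  }
  labs <- check_events(labs, "labs", "timestamp")
  notes_bad <- nrow(notes) > 0 & !notes$kind %in% NOTE_KINDS
  for (i in which(notes_bad)) {
    add_viol("notes", notes$.line[i], notes$patient_id[i], "kind",
             paste0("unknown note kind '", notes$kind[i], "'"))
  }
  if (nrow(notes) > 0) notes <- notes[notes$kind %in% NOTE_KINDS, , drop = FALSE]
  notes <- check_events(notes, "notes", "timestamp")

  if (nrow(medications) > 0) {
    idx <- match(medications$patient_id, stay$patient_id)
    ok <- !is.na(idx)
    for (i in which(!ok)) {
      add_viol("medications", medications$.line[i], medications$patient_id[i],
               "patient_id", "no such patient in patients table")
    }
    medications <- medications[ok, , drop = FALSE]
    idx <- idx[ok]
    bad <- is.na(medications$start_time) |
      (!is.na(medications$stop_time) &
         medications$stop_time < medications$start_time) |
      medications$start_time < stay$admit_time[idx] |
      (!is.na(medications$stop_time) &
         medications$stop_time > stay$discharge_time[idx])
    for (i in which(bad)) {
      add_viol("medications", medications$.line[i], medications$patient_id[i],
               "start_time", "course times missing, reversed or outside stay")
    }
    medications <- medications[!bad, , drop = FALSE]
    bad_atc <- nzchar(medications$atc_code) &
      !grepl(ATC_PATTERN, medications$atc_code)
    for (i in which(bad_atc)) {
      add_viol("medications", medications$.line[i], medications$patient_id[i],
               "atc_code", paste0("malformed ATC code '",
                                  medications$atc_code[i], "' blanked"))
    }
    medications$atc_code[bad_atc] <- ""
  }
  if (!"course_id" %in% names(medications)) {
    medications$course_id <- seq_len(nrow(medications))
  }

  administrations <- check_events(administrations, "administrations", "timestamp")
  administrations <- link_administrations(administrations, medications, add_viol)

  ## --- eligibility screen ---------------------------------------------------
  los_days <- as.numeric(difftime(patients$discharge_time,
                                  patients$admit_time, units = "days"))
  has_med <- patients$patient_id %in% medications$patient_id
  excl_reason <- rep(NA_character_, nrow(patients))
  excl_reason[patients$age <= 18] <- "age 18 years or younger"
  excl_reason[is.na(excl_reason) & los_days <= 1] <-
    "stay of 24 hours or less"
  excl_reason[is.na(excl_reason) & !has_med] <- "no prescribed medication"
  exclusions <- data.frame(patient_id = patients$patient_id[!is.na(excl_reason)],
                           reason = excl_reason[!is.na(excl_reason)],
                           stringsAsFactors = FALSE)
  eligible <- is.na(excl_reason)
  patients <- patients[eligible, , drop = FALSE]
  keep_pid <- function(df) df[df$patient_id %in% patients$patient_id, , drop = FALSE]
  labs <- keep_pid(labs)
  medications <- keep_pid(medications)
  administrations <- keep_pid(administrations)
  notes <- keep_pid(notes)

  drop_line <- function(df) { df$.line <- NULL; rownames(df) <- NULL; df }
  out <- list(patients = drop_line(patients),
              labs = drop_line(labs),
              medications = drop_line(medications),
              administrations = drop_line(administrations),
              notes = drop_line(notes),
              spontaneous_reports = drop_line(spontaneous_reports))
  violations <- if (length(viol)) do.call(rbind, viol) else
    new_violation(character(0), integer(0), character(0), character(0),
                  character(0))
  structure(out, class = "icu_cohort",
            violations = violations, exclusions = exclusions)
}

# Coerce a raw table to the internal column types; tolerate NULL.
normalize_table <- function(df, table) {
  schema <- cohort_schemas[[table]]
  if (is.null(df) || nrow(as.data.frame(df)) == 0) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(schema)),
                                 schema), stringsAsFactors = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(schema, names(df))
  if (length(missing)) {
    stop("table '", table, "' is missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (!".line" %in% names(df)) df$.line <- seq_len(nrow(df)) + 1L
  df$patient_id <- as.character(df$patient_id)
  ts_cols <- intersect(c("timestamp", "admit_time", "discharge_time",
                         "start_time", "stop_time", "intended_end_time"),
                       schema)
  for (col in ts_cols) {
    if (!inherits(df[[col]], "POSIXct")) df[[col]] <- parse_timestamp(df[[col]])
    attr(df[[col]], "tzone") <- "UTC"
  }
  if (table == "patients") {
    df$age <- as.integer(df$age)
    df$unit <- gsub("-", "_", toupper(as.character(df$unit)))
    df$sex <- tolower(as.character(df$sex))
    df$outcome <- tolower(as.character(df$outcome))
  }
  if (table == "labs") {
    df$analyte <- as.character(df$analyte)
    df$value <- suppressWarnings(as.numeric(df$value))
  }
  if (table == "medications") {
    df$drug_name <- as.character(df$drug_name)
    df$atc_code <- ifelse(is.na(df$atc_code), "", as.character(df$atc_code))
    df$scheduled <- as.logical(df$scheduled)
    df$route <- as.character(df$route)
  }
  if (table == "administrations") df$drug_name <- as.character(df$drug_name)
  if (table == "notes") {
    df$kind <- as.character(df$kind)
    df$text <- as.character(df$text)
  }
  if (table == "spontaneous_reports") {
    df$report_date <- as.Date(as.character(df$report_date))
    df$drug_name <- as.character(df$drug_name)
    df$reaction_text <- as.character(df$reaction_text)
  }
  df
}

# Attach each administration to the medication course of the same patient and
# drug whose [start, stop] window contains it; unmatched ones are violations.
link_administrations <- function(admins, meds, add_viol) {
  if (nrow(admins) == 0) { admins$course_id <- integer(0); return(admins) }
  admins$course_id <- NA_integer_
  key_a <- paste(admins$patient_id, normalize_drug(admins$drug_name))
  key_m <- paste(meds$patient_id, normalize_drug(meds$drug_name))
  med_idx <- split(seq_len(nrow(meds)), key_m)
  for (i in seq_len(nrow(admins))) {
    cand <- med_idx[[key_a[i]]]
    if (is.null(cand)) next
    ok <- meds$start_time[cand] <= admins$timestamp[i] &
      (is.na(meds$stop_time[cand]) |
         meds$stop_time[cand] >= admins$timestamp[i])
    if (any(ok)) admins$course_id[i] <- meds$course_id[cand[ok][1L]]
  }
  bad <- is.na(admins$course_id)
  for (i in which(bad)) {
    add_viol("administrations", admins$.line[i], admins$patient_id[i],
             "timestamp", paste0("administration of '", admins$drug_name[i],
                                 "' matches no course window"))
  }
  admins[!bad, , drop = FALSE]
}

#' Read a cohort from its delimited-text files
#'
#' Reads the six interchange CSVs (\code{patients.csv}, \code{labs.csv},
#' \code{medications.csv}, \code{administrations.csv}, \code{notes.csv},
#' \code{spontaneous_reports.csv}) from a directory and validates them.
#' Malformed rows are collected as violations with their source line numbers;
#' records failing the eligibility screen are excluded with a logged reason
#' (see \code{\link{cohort}}). A missing \code{patients.csv} is fatal; the
#' event files may be absent (treated as empty).
#'
#' @param dir directory containing the CSV files.
#' @return an \code{icu_cohort}; inspect \code{\link{cohort_violations}} and
#'   \code{\link{cohort_exclusions}}.
#' @export
read_cohort <- function(dir) {
  read_one <- function(name, required = FALSE) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      if (required) stop("required file missing: ", path)
      return(NULL)
    }
    df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    schema <- cohort_schemas[[name]]
    if (!identical(names(df), schema)) {
      stop(path, ": header must be exactly '",
           paste(schema, collapse = ","), "'")
    }
    df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
    df
  }
  cohort(patients = read_one("patients", required = TRUE),
         labs = read_one("labs"),
         medications = read_one("medications"),
         administrations = read_one("administrations"),
         notes = read_one("notes"),
         spontaneous_reports = read_one("spontaneous_reports"))
}

#' Write a cohort to delimited-text files
#'
#' Writes the six interchange CSVs to \code{dir} (created if needed) so that
#' \code{\link{read_cohort}} recovers a semantically identical cohort. An
#' empty cohort yields headers-only files.
#'
#' @param x an \code{icu_cohort}.
#' @param dir output directory.
#' @return invisibly, the named character vector of file paths.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "icu_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (name in names(cohort_schemas)) {
    df <- x[[name]][, cohort_schemas[[name]], drop = FALSE]
    for (col in names(df)) {
      if (inherits(df[[col]], "POSIXct")) {
        df[[col]] <- ifelse(is.na(df[[col]]), "", format_timestamp(df[[col]]))
      } else if (inherits(df[[col]], "Date")) {
        df[[col]] <- format(df[[col]], "%Y-%m-%d")
      } else if (is.numeric(df[[col]])) {
        df[[col]] <- format(df[[col]], digits = 15, trim = TRUE,
                            scientific = FALSE)
      }
    }
    path <- file.path(dir, paste0(name, ".csv"))
    write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
    paths[name] <- path
  }
  invisible(paths)
}

#' Violations and exclusions recorded while building a cohort
#'
#' @param x an \code{icu_cohort}.
#' @return \code{cohort_violations}: data.frame of invariant-violating rows
#'   (table, line, patient_id, field, message). \code{cohort_exclusions}:
#'   data.frame of whole records excluded by the eligibility screen
#'   (patient_id, reason).
#' @export
cohort_violations <- function(x) attr(x, "violations")

#' @rdname cohort_violations
#' @export
cohort_exclusions <- function(x) attr(x, "exclusions")

#' Extract one patient's record from a cohort
#'
#' @param x an \code{icu_cohort}.
#' @param patient_id the record to extract.
#' @return a \code{patient_record}: list with \code{patient} (1-row
#'   data.frame), \code{labs}, \code{medications}, \code{administrations},
#'   \code{notes}.
#' @export
patient_record <- function(x, patient_id) {
  stopifnot(inherits(x, "icu_cohort"))
  i <- match(patient_id, x$patients$patient_id)
  if (is.na(i)) stop("no such patient: ", patient_id)
  pick <- function(df) df[df$patient_id == patient_id, , drop = FALSE]
  structure(list(patient = x$patients[i, , drop = FALSE],
                 labs = pick(x$labs),
                 medications = pick(x$medications),
                 administrations = pick(x$administrations),
                 notes = pick(x$notes)),
            class = "patient_record")
}

#' Length of stay
#'
#' Fractional days between admission and discharge. Whole-day summaries use
#' the ceiling (\code{whole = TRUE}) so that, for example, a 25-hour stay
#' counts as 2 hospital days and any included stay is at least 1 day.
#'
#' @param record a \code{patient_record}.
#' @param whole round up to whole days?
#' @return numeric days.
#' @export
length_of_stay <- function(record, whole = FALSE) {
  stopifnot(inherits(record, "patient_record"))
  los <- as.numeric(difftime(record$patient$discharge_time,
                             record$patient$admit_time, units = "days"))
  if (whole) ceiling(los) else los
}

#' @export
print.icu_cohort <- function(x, ...) {
  n <- nrow(x$patients)
  cat("ICU cohort:", n, "eligible records\n")
  if (n > 0) {
    tab <- table(factor(x$patients$unit, levels = UNITS))
    cat(sprintf("  units: G-ICU %d, C19-ICU %d\n", tab[["G_ICU"]],
                tab[["C19_ICU"]]))
  }
  cat(sprintf("  events: %d labs, %d medication courses, %d administrations, %d notes\n",
              nrow(x$labs), nrow(x$medications), nrow(x$administrations),
              nrow(x$notes)))
  cat(sprintf("  spontaneous reports: %d\n", nrow(x$spontaneous_reports)))
  v <- cohort_violations(x); e <- cohort_exclusions(x)
  cat(sprintf("  validation: %d violations, %d excluded records\n",
              nrow(v), nrow(e)))
  invisible(x)
}
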