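# Trigger scanning engine. A trigger is a predefined, automatically checkable
# signal in the record (abnormal laboratory value, rescue-drug administration,
# care event) that prompts ADR investigation; a hit does not itself imply an
# ADR. The default catalog holds the 28 adapted GTT triggers in three
# modules: medication (21), care (3), laboratory test results (4).
#
# Conventions shared by all rules:
#   * thresholds are strict: a value exactly at the threshold never fires;
#   * hits are deduplicated to one per trigger per calendar day, except
#     note-event triggers where each documented event is a distinct hit;
#   * relative-change rules fire once per excursion episode, resetting when
#     the series recovers past the threshold.

#' The 28-trigger adapted GTT catalog
#'
#' Loads the packaged trigger catalog (or an alternative YAML file). The
#' default contains the adapted Global Trigger Tool set for adult ICUs:
#' the medication module (PTT > 50 s, INR > 3, glucose < 50 mg/dL, BUN or
#' creatinine rising 2x over baseline, thirteen antidote / rescue / hyper-
#' sensitivity-management drug administrations, over-sedation/hypotension
#' with MAP < 70 mmHg, abrupt medication stop), the care module (Hb/Ht drop
#' of 25\% or more, patient fall, skin rash) and the laboratory module
#' (sodium < 135 mEq/L, potassium < 3.0 mmol/L, potassium > 5.5 mmol/L,
#' platelets < 50,000/uL).
#'
#' @param path optional alternative catalog YAML.
#' @return data.frame with one row per trigger: \code{trigger_id},
#'   \code{label}, \code{module}, \code{rule_kind} and a \code{params} list
#'   column of rule-specific parameters.
#' @export
default_catalog <- function(path = NULL) {
  raw <- if (is.null(path)) {
    cached("catalog_raw",
           function() yaml::read_yaml(asset_path("trigger_catalog.yaml")))
  } else yaml::read_yaml(path)
  defs <- raw$triggers
  ids <- vapply(defs, `[[`, "", "trigger_id")
  if (anyDuplicated(ids)) stop("duplicate trigger_id in catalog")
  data.frame(trigger_id = ids,
             label = vapply(defs, `[[`, "", "label"),
             module = vapply(defs, `[[`, "", "module"),
             rule_kind = vapply(defs, `[[`, "", "rule_kind"),
             params = I(lapply(defs, function(d) {
               d[setdiff(names(d), c("trigger_id", "label", "module",
                                     "rule_kind"))]
             })),
             stringsAsFactors = FALSE)
}

hit_df <- function(timestamp = as.POSIXct(character(0), tz = "UTC"),
                   evidence = character(0)) {
  data.frame(timestamp = timestamp, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Laboratory threshold rule
#'
#' Fires on each calendar day with at least one value strictly beyond the
#' threshold; the first qualifying value of the day is the evidence.
#'
#' @param labs data.frame of lab results (\code{timestamp, analyte, value}).
#' @param analyte analyte name to test.
#' @param direction \code{"LT"} or \code{"GT"}.
#' @param threshold numeric threshold in the analyte's units (strict).
#' @return data.frame of hits (\code{timestamp, evidence}).
#' @export
rule_lab_threshold <- function(labs, analyte, direction, threshold) {
  s <- labs[labs$analyte == analyte, , drop = FALSE]
  if (nrow(s) == 0) return(hit_df())
  s <- s[order(s$timestamp), , drop = FALSE]
  qual <- if (direction == "LT") s$value < threshold else s$value > threshold
  s <- s[qual, , drop = FALSE]
  if (nrow(s) == 0) return(hit_df())
  day <- as.Date(s$timestamp, tz = "UTC")
  first <- !duplicated(day)
  hit_df(s$timestamp[first],
         sprintf("lab:%s=%g", analyte, s$value[first]))
}

#' Relative-change rule (drops and fold-rises)
#'
#' \code{DROP_PCT} fires when a value falls to or below
#' \code{(1 - magnitude)} times the running maximum of all prior values
#' (GTT practice for haemoglobin/haematocrit drops); \code{RISE_FOLD} fires
#' when a value reaches \code{magnitude} times the admission (first) value.
#' Each excursion episode yields one hit; the episode resets once the series
#' recovers past the threshold, so a single bleed or creatinine rise is not
#' double-counted. Fewer than two measurements cannot fire.
#'
#' @param labs lab results data.frame.
#' @param analyte analyte to evaluate.
#' @param mode \code{"DROP_PCT"} or \code{"RISE_FOLD"}.
#' @param magnitude drop fraction (e.g. 0.25) or rise factor (e.g. 2).
#' @return data.frame of hits.
#' @export
rule_relative_change <- function(labs, analyte, mode, magnitude) {
  stopifnot(magnitude > 0)
  s <- labs[labs$analyte == analyte, , drop = FALSE]
  if (nrow(s) < 2) return(hit_df())
  s <- s[order(s$timestamp), , drop = FALSE]
  v <- s$value
  ts <- s$timestamp
  hits_i <- integer(0)
  in_episode <- FALSE
  if (mode == "DROP_PCT") {
    run_max <- v[1L]
    for (i in 2:length(v)) {
      fire_at <- (1 - magnitude) * run_max
      if (!in_episode && v[i] <= fire_at) {
        hits_i <- c(hits_i, i); in_episode <- TRUE
      } else if (in_episode && v[i] > fire_at) {
        in_episode <- FALSE
      }
      run_max <- max(run_max, v[i])
    }
    ev <- sprintf("lab:%s=%g (drop >= %g%% from baseline)", analyte,
                  v[hits_i], 100 * magnitude)
  } else if (mode == "RISE_FOLD") {
    base <- v[which(v > 0)[1L]]
    if (is.na(base)) return(hit_df())
    for (i in 2:length(v)) {
      if (!in_episode && v[i] >= magnitude * base) {
        hits_i <- c(hits_i, i); in_episode <- TRUE
      } else if (in_episode && v[i] < magnitude * base) {
        in_episode <- FALSE
      }
    }
    ev <- sprintf("lab:%s=%g (>= %gx baseline %g)", analyte, v[hits_i],
                  magnitude, base)
  } else stop("unknown mode: ", mode)
  hit_df(ts[hits_i], ev)
}

#' Medication-administration rule
#'
#' One hit per calendar day on which any of the listed drugs was
#' administered. Matching is case-insensitive through the packaged synonym
#' table.
#'
#' @param administrations data.frame (\code{drug_name, timestamp}).
#' @param drugs character vector of trigger drug names.
#' @return data.frame of hits.
#' @export
rule_med_administered <- function(administrations, drugs) {
  if (nrow(administrations) == 0) return(hit_df())
  adm <- administrations[normalize_drug(administrations$drug_name) %in%
                           normalize_drug(drugs), , drop = FALSE]
  if (nrow(adm) == 0) return(hit_df())
  adm <- adm[order(adm$timestamp), , drop = FALSE]
  day <- as.Date(adm$timestamp, tz = "UTC")
  first <- !duplicated(day)
  hit_df(adm$timestamp[first], sprintf("med:%s", adm$drug_name[first]))
}

#' Abrupt medication stop rule
#'
#' Fires when a scheduled course stops before its intended end, more than
#' 24 hours before discharge (stops explained by discharge or death are
#' censored), with no administration of the same drug in the following
#' 24 hours. Courses without an intended end time never fire; this is the
#' narrowest auditable operationalisation of the trigger.
#'
#' @param medications data.frame of courses.
#' @param administrations data.frame of administrations.
#' @param discharge_time the record's discharge timestamp.
#' @return data.frame of hits.
#' @export
rule_abrupt_stop <- function(medications, administrations, discharge_time) {
  m <- medications
  if (nrow(m) == 0) return(hit_df())
  cand <- !is.na(m$scheduled) & m$scheduled &
    !is.na(m$intended_end_time) & !is.na(m$stop_time) &
    m$stop_time < m$intended_end_time &
    m$stop_time <= discharge_time - 24 * 3600
  m <- m[cand, , drop = FALSE]
  if (nrow(m) == 0) return(hit_df())
  keep <- vapply(seq_len(nrow(m)), function(i) {
    later <- normalize_drug(administrations$drug_name) ==
      normalize_drug(m$drug_name[i]) &
      administrations$timestamp > m$stop_time[i] &
      administrations$timestamp <= m$stop_time[i] + 24 * 3600
    !any(later)
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  hit_df(m$stop_time, sprintf("stop:%s", m$drug_name))
}

#' Over-sedation / hypotension rule
#'
#' One hit per calendar day with MAP strictly below the threshold. The
#' trigger fires on MAP alone; whether a sedative or opioid course was
#' active at the time is recorded in the evidence.
#'
#' @param labs lab/vital results data.frame.
#' @param medications courses, used only to flag sedative co-occurrence.
#' @param threshold MAP threshold in mmHg (default 70).
#' @return data.frame of hits.
#' @export
rule_vital_threshold <- function(labs, medications, threshold = 70) {
  hits <- rule_lab_threshold(labs, "MAP_mmHg", "LT", threshold)
  if (nrow(hits) == 0) return(hits)
  sedatives <- c("midazolam", "propofol", "fentanyl", "morphine",
                 "dexmedetomidine", "ketamine")
  active <- vapply(hits$timestamp, function(ts) {
    any(normalize_drug(medications$drug_name) %in% sedatives &
          medications$start_time <= ts &
          (is.na(medications$stop_time) | medications$stop_time >= ts))
  }, logical(1))
  hits$evidence <- paste0(hits$evidence,
                          ifelse(active, " [sedative active]",
                                 " [no sedative]"))
  hits
}

#' Note-event rule
#'
#' One hit per matching note event; distinct documented events are not
#' collapsed by day.
#'
#' @param notes note events data.frame.
#' @param kind note kind to match (e.g. \code{"SKIN_RASH"}).
#' @return data.frame of hits.
#' @export
rule_note_event <- function(notes, kind) {
  s <- notes[notes$kind == kind, , drop = FALSE]
  if (nrow(s) == 0) return(hit_df())
  s <- s[order(s$timestamp), , drop = FALSE]
  hit_df(s$timestamp, sprintf("note:%s", kind))
}

eval_rule <- function(def_kind, params, record) {
  switch(def_kind,
    LAB_THRESHOLD = rule_lab_threshold(record$labs, params$analyte,
                                       params$direction, params$threshold),
    RELATIVE_CHANGE = {
      parts <- lapply(params$analytes, function(a) {
        rule_relative_change(record$labs, a, params$mode, params$magnitude)
      })
      do.call(rbind, parts)
    },
    MED_ADMINISTERED = rule_med_administered(record$administrations,
                                             params$drugs),
    ABRUPT_STOP = rule_abrupt_stop(record$medications,
                                   record$administrations,
                                   record$patient$discharge_time),
    VITAL_THRESHOLD = rule_vital_threshold(record$labs, record$medications,
                                           params$threshold),
    NOTE_EVENT = rule_note_event(record$notes, params$note_kind),
    stop("unknown rule_kind: ", def_kind)
  )
}

#' Scan one patient record against a trigger catalog
#'
#' Evaluates every rule, deduplicates to one hit per trigger per calendar day
#' (note-event triggers exempt) and returns time-sorted hits.
#'
#' @param record a \code{patient_record}.
#' @param catalog a catalog data.frame from \code{\link{default_catalog}}.
#' @return data.frame of trigger hits: \code{patient_id, trigger_id,
#'   timestamp, hospital_day, evidence}.
#' @export
scan_record <- function(record, catalog = default_catalog()) {
  stopifnot(inherits(record, "patient_record"))
  out <- vector("list", nrow(catalog))
  for (k in seq_len(nrow(catalog))) {
    hits <- eval_rule(catalog$rule_kind[k], catalog$params[[k]], record)
    if (nrow(hits) == 0) next
    if (catalog$rule_kind[k] != "NOTE_EVENT") {
      hits <- hits[order(hits$timestamp), , drop = FALSE]
      day <- as.Date(hits$timestamp, tz = "UTC")
      hits <- hits[!duplicated(day), , drop = FALSE]
    }
    hits$trigger_id <- catalog$trigger_id[k]
    out[[k]] <- hits
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(patient_id = character(0), trigger_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      hospital_day = integer(0), evidence = character(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits$patient_id <- record$patient$patient_id
  hits$hospital_day <- hospital_day(hits$timestamp,
                                    record$patient$admit_time)
  hits <- hits[order(hits$timestamp, hits$trigger_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("patient_id", "trigger_id", "timestamp", "hospital_day",
           "evidence")]
}

#' Scan a whole cohort
#'
#' @param x an \code{icu_cohort}.
#' @param catalog trigger catalog.
#' @return data.frame of hits across all records (see
#'   \code{\link{scan_record}}).
#' @export
scan_cohort <- function(x, catalog = default_catalog()) {
  stopifnot(inherits(x, "icu_cohort"))
  ids <- x$patients$patient_id
  split_tab <- function(df) split(df, factor(df$patient_id, levels = ids))
  labs_s <- split_tab(x$labs)
  meds_s <- split_tab(x$medications)
  adm_s <- split_tab(x$administrations)
  notes_s <- split_tab(x$notes)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rec <- structure(list(patient = x$patients[i, , drop = FALSE],
                          labs = labs_s[[i]], medications = meds_s[[i]],
                          administrations = adm_s[[i]], notes = notes_s[[i]]),
                     class = "patient_record")
    out[[i]] <- scan_record(rec, catalog)
  }
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  hits
}
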