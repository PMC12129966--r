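# Sequential Organ Failure Assessment. Six organ systems are scored 0-4
# (0 = normal, 4 = severe dysfunction) from PaO2/FiO2 ratio, platelet count,
# bilirubin, MAP (plus vasopressor support), Glasgow Coma Scale and
# creatinine; the total ranges 0-24. Scores are computed on a fixed grid
# from admission with last-observation-carried-forward per variable.

SOFA_ORGANS <- c("respiratory", "coagulation", "hepatic", "cardiovascular",
                 "neurological", "renal")

score_from_breaks <- function(value, breaks, direction) {
  if (direction == "lower_worse") {
    vapply(value, function(v) sum(v < breaks), numeric(1))
  } else {
    vapply(value, function(v) sum(v >= breaks), numeric(1))
  }
}

#' One SOFA organ subscore
#'
#' Scores a single measurement against the packaged cut-point table.
#' For the cardiovascular system the measurement is MAP and \code{support}
#' names the vasopressor agents active at the time: with no support the
#' subscore is 0 (MAP at or above 70 mmHg) or 1 (below 70); dopamine scores
#' 2, norepinephrine or epinephrine 3, and two or more concurrent agents 4
#' (doses are not part of the data model).
#'
#' @param organ one of \code{"respiratory"}, \code{"coagulation"},
#'   \code{"hepatic"}, \code{"cardiovascular"}, \code{"neurological"},
#'   \code{"renal"}.
#' @param value the measurement in the organ's units (PaO2/FiO2, platelets/uL,
#'   bilirubin mg/dL, MAP mmHg, GCS points, creatinine mg/dL). \code{NA}
#'   scores 0 (no observation yet).
#' @param support character vector of active vasopressor agents
#'   (cardiovascular only).
#' @param cutpoints cut-point table (default: packaged).
#' @return integer subscore in 0..4.
#' @export
sofa_subscore <- function(organ, value, support = character(0),
                          cutpoints = sofa_cutpoints()) {
  if (!organ %in% SOFA_ORGANS) stop("unknown organ: ", organ)
  cp <- cutpoints[[organ]]
  if (organ == "cardiovascular") {
    support <- normalize_drug(support)
    support <- intersect(support, cp$vasopressors)
    if (length(support) >= 2) return(as.integer(cp$support_scores$multiple))
    if (any(support %in% c("norepinephrine", "epinephrine"))) {
      return(as.integer(cp$support_scores$catecholamine))
    }
    if ("dopamine" %in% support) return(as.integer(cp$support_scores$dopamine))
    if (is.na(value)) return(0L)
    return(if (value < cp$map_threshold) 1L else 0L)
  }
  if (is.na(value)) return(0L)
  as.integer(score_from_breaks(value, unlist(cp$breaks), cp$direction))
}

#' SOFA trajectory of one ICU stay
#'
#' Computes one assessment per \code{interval} hours from admission (grid
#' points strictly before discharge), each using the most recent observation
#' of every variable (last observation carried forward; 0 with a warning
#' before the first observation of a variable). Vasopressor support is read
#' from the record's medication courses.
#'
#' @param record a \code{patient_record}.
#' @param interval grid spacing in hours (default 24; the source charts
#'   documented scores at least every 48 h).
#' @param cutpoints cut-point table.
#' @return data.frame with one row per assessment: \code{timestamp}, the six
#'   subscores and \code{total}.
#' @export
sofa_trajectory <- function(record, interval = 24,
                            cutpoints = sofa_cutpoints()) {
  stopifnot(inherits(record, "patient_record"))
  admit <- record$patient$admit_time
  discharge <- record$patient$discharge_time
  times <- seq(from = admit, to = discharge, by = interval * 3600)
  times <- times[times < discharge]
  if (length(times) == 0) times <- admit
  labs <- record$labs[order(record$labs$timestamp), , drop = FALSE]
  vars <- vapply(SOFA_ORGANS, function(o) cutpoints[[o]]$variable, "")
  missing_vars <- setdiff(vars, labs$analyte)
  if (length(missing_vars)) {
    warning("no observations for ", paste(missing_vars, collapse = ", "),
            " in record ", record$patient$patient_id,
            "; subscore 0 carried")
  }
  pressors <- cutpoints$cardiovascular$vasopressors
  meds <- record$medications
  med_names <- normalize_drug(meds$drug_name)
  locf <- function(analyte, at) {
    s <- labs[labs$analyte == analyte & labs$timestamp <= at, , drop = FALSE]
    if (nrow(s) == 0) NA_real_ else s$value[nrow(s)]
  }
  rows <- lapply(times, function(at) {
    active <- med_names[meds$start_time <= at &
                          (is.na(meds$stop_time) | meds$stop_time >= at)]
    sub <- vapply(SOFA_ORGANS, function(o) {
      sofa_subscore(o, locf(vars[[o]], at),
                    support = intersect(active, pressors),
                    cutpoints = cutpoints)
    }, integer(1))
    c(list(timestamp = at), as.list(sub), list(total = sum(sub)))
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  names(out) <- c("timestamp", SOFA_ORGANS, "total")
  out
}

#' Per-stay SOFA summary
#'
#' @param trajectory a trajectory data.frame from \code{\link{sofa_trajectory}}
#'   (at least one assessment).
#' @return list with \code{admission} (first total), \code{minimum},
#'   \code{maximum} and \code{mean} of the totals.
#' @export
sofa_summary <- function(trajectory) {
  if (is.null(trajectory) || nrow(trajectory) == 0) {
    stop("cannot summarise an empty SOFA trajectory")
  }
  tot <- trajectory$total
  list(admission = tot[1L], minimum = min(tot), maximum = max(tot),
       mean = mean(tot))
}

#' Cohort-level SOFA summaries
#'
#' Computes the per-patient trajectory summary for every record and returns
#' one row per patient (admission, minimum, maximum, mean of the total
#' score).
#'
#' @param x an \code{icu_cohort}.
#' @param interval grid spacing in hours.
#' @return data.frame with \code{patient_id, admission, minimum, maximum,
#'   mean}.
#' @export
cohort_sofa_summary <- function(x, interval = 24) {
  stopifnot(inherits(x, "icu_cohort"))
  cp <- sofa_cutpoints()
  ids <- x$patients$patient_id
  labs_s <- split(x$labs, factor(x$labs$patient_id, levels = ids))
  meds_s <- split(x$medications, factor(x$medications$patient_id,
                                        levels = ids))
  rows <- lapply(seq_along(ids), function(i) {
    rec <- structure(list(patient = x$patients[i, , drop = FALSE],
                          labs = labs_s[[i]], medications = meds_s[[i]],
                          administrations = NULL, notes = NULL),
                     class = "patient_record")
    s <- sofa_summary(sofa_trajectory(rec, interval = interval,
                                      cutpoints = cp))
    data.frame(patient_id = ids[i], admission = s$admission,
               minimum = s$minimum, maximum = s$maximum, mean = s$mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
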