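# ADR adjudication: causality (Naranjo score/category and the WHO-UMC
# decision table), WHO three-level severity, Rawlins-Thompson mechanism,
# ATC coding, and the dual-reviewer merge. The automated pipeline mode
# consumes structured ADR assessment notes embedded in the record (kind
# OTHER, machine-parseable key=value text) -- the stand-in for human chart
# review -- and re-derives every classification from the recorded facts.

NARANJO_RESPONSES <- c("yes", "no", "unknown")
SEVERITIES <- c("mild", "moderate", "severe")
WHO_CATEGORIES <- c("certain", "probable", "possible", "unlikely",
                    "conditional_unclassified", "unassessable_unclassifiable")

#' Naranjo causality score
#'
#' Sums the per-question points of the 10-item Naranjo ADR probability scale
#' over a vector of responses.
#'
#' @param answers character vector of exactly 10 responses, each
#'   \code{"yes"}, \code{"no"} or \code{"unknown"}.
#' @param points points table, by default the packaged one
#'   (\code{\link{naranjo_points}}).
#' @return integer score.
#' @export
naranjo_score <- function(answers, points = naranjo_points()) {
  if (length(answers) != 10) {
    stop("Naranjo assessment requires exactly 10 answers, got ",
         length(answers))
  }
  if (!all(answers %in% NARANJO_RESPONSES)) {
    stop("answers must be 'yes', 'no' or 'unknown'")
  }
  sum(vapply(seq_len(10), function(q) {
    as.integer(points$questions[[q]][[answers[q]]])
  }, integer(1)))
}

#' Naranjo score band to causality category
#'
#' Scores of 9 or more are definite, 5-8 probable, 1-4 possible, and 0 or
#' less doubtful.
#'
#' @param score integer Naranjo score.
#' @return one of \code{"definite"}, \code{"probable"}, \code{"possible"},
#'   \code{"doubtful"}.
#' @export
naranjo_category <- function(score) {
  vapply(score, function(s) {
    if (s >= 9) "definite"
    else if (s >= 5) "probable"
    else if (s >= 1) "possible"
    else "doubtful"
  }, character(1))
}

#' WHO-UMC causality assessment
#'
#' Maps a structured fact set to one of the six WHO-UMC categories through
#' the packaged first-match decision table (\code{\link{who_umc_rules}}).
#' Adding supporting evidence never weakens the category.
#'
#' @param temporal_plausibility \code{"yes"}, \code{"no"} or \code{"unknown"}:
#'   is the time relationship to drug intake plausible?
#' @param alternative_causes \code{"excluded"}, \code{"present"} or
#'   \code{"unknown"}.
#' @param dechallenge \code{"positive"}, \code{"negative"} or \code{"none"}.
#' @param rechallenge \code{"positive"}, \code{"negative"} or \code{"none"}.
#' @param data_sufficient logical; FALSE when the record cannot support any
#'   judgement.
#' @param rules decision table (default: packaged).
#' @return a WHO-UMC category string.
#' @export
who_causality <- function(temporal_plausibility, alternative_causes,
                          dechallenge = "none", rechallenge = "none",
                          data_sufficient = TRUE, rules = who_umc_rules()) {
  temporal_plausibility <- match.arg(temporal_plausibility,
                                     c("yes", "no", "unknown"))
  alternative_causes <- match.arg(alternative_causes,
                                  c("excluded", "present", "unknown"))
  dechallenge <- match.arg(dechallenge, c("positive", "negative", "none"))
  rechallenge <- match.arg(rechallenge, c("positive", "negative", "none"))
  if (rechallenge == "positive" && !data_sufficient) {
    stop("contradictory facts: a positive rechallenge implies sufficient data")
  }
  facts <- list(temporal_plausibility = temporal_plausibility,
                alternative_causes = alternative_causes,
                dechallenge = dechallenge,
                rechallenge = rechallenge,
                data_sufficient = tolower(as.character(data_sufficient)))
  for (rule in rules) {
    cond <- rule$when
    ok <- all(vapply(names(cond), function(f) {
      identical(as.character(cond[[f]]), facts[[f]])
    }, logical(1)))
    if (ok) return(rule$category)
  }
  stop("no WHO-UMC rule matched; the decision table must be total")
}

#' WHO severity classification
#'
#' Mild reactions require no intervention or therapy change; moderate ones
#' require a change in drug therapy or specific treatment; severe ones are
#' life-threatening or cause/prolong hospitalization.
#'
#' @param intervention_required logical: specific treatment was needed.
#' @param therapy_change logical: drug therapy was changed (dose change,
#'   suspension, substitution).
#' @param life_threatening_or_prolonging logical.
#' @return \code{"mild"}, \code{"moderate"} or \code{"severe"}.
#' @export
classify_severity <- function(intervention_required, therapy_change,
                              life_threatening_or_prolonging) {
  if (life_threatening_or_prolonging) return("severe")
  if (intervention_required || therapy_change) return("moderate")
  "mild"
}

#' Rawlins-Thompson mechanism classification
#'
#' Type A reactions are dose-dependent and predictable from the drug's
#' pharmacology (augmented effect); everything else is Type B
#' (idiosyncratic).
#'
#' @param dose_dependent logical.
#' @param pharmacologically_predictable logical.
#' @return \code{"A"} or \code{"B"}.
#' @export
classify_mechanism <- function(dose_dependent, pharmacologically_predictable) {
  if (dose_dependent && pharmacologically_predictable) "A" else "B"
}

#' ATC code lookup
#'
#' Looks a drug name up in the packaged ATC mini-dictionary (all suspected
#' drugs of the calibration study plus the trigger-list drugs), through the
#' synonym table, case-insensitively. Unmatched names return an empty code
#' with a warning.
#'
#' @param drug_name character vector of drug names.
#' @return character vector of 7-character ATC codes (\code{""} when
#'   unmatched).
#' @export
atc_lookup <- function(drug_name) {
  dict <- atc_dictionary()
  idx <- match(normalize_drug(drug_name), normalize_drug(dict$drug_name))
  out <- ifelse(is.na(idx), "", dict$atc_code[idx])
  if (any(is.na(idx))) {
    warning("no ATC code for: ",
            paste(unique(drug_name[is.na(idx)]), collapse = ", "))
  }
  out
}

#' Merge two reviewers' ADR characterizations
#'
#' Field-wise merge of two independent reviews of the same ADR: agreement
#' keeps the value; divergence is settled by the third (tiebreak) review;
#' divergence without a tiebreak is an error naming the divergent fields.
#'
#' @param a,b,tiebreak lists (or 1-row data.frames) with the same ADR key
#'   (\code{patient_id}, \code{drug_name}, \code{reaction}) and the assessed
#'   fields (\code{severity}, \code{mechanism}, \code{naranjo_score},
#'   \code{naranjo_category}, \code{who_causality}, ...).
#' @return the merged review as a list.
#' @export
merge_reviews <- function(a, b, tiebreak = NULL) {
  a <- as.list(a); b <- as.list(b)
  key <- c("patient_id", "drug_name", "reaction")
  for (f in key) {
    if (!identical(a[[f]], b[[f]])) {
      stop("reviews are not of the same ADR (field '", f, "' differs)")
    }
  }
  fields <- union(names(a), names(b))
  fields <- setdiff(fields, "reviewer_id")
  out <- list()
  divergent <- character(0)
  for (f in fields) {
    if (identical(a[[f]], b[[f]])) {
      out[[f]] <- a[[f]]
    } else if (!is.null(tiebreak)) {
      out[[f]] <- as.list(tiebreak)[[f]]
    } else {
      divergent <- c(divergent, f)
    }
  }
  if (length(divergent)) {
    stop("reviewers diverge without a third review on: ",
         paste(divergent, collapse = ", "))
  }
  out
}

## --- structured assessment notes -------------------------------------------

# The generator documents each embedded ADR as a structured assessment note:
#   ADR|drug=<name>|reaction=<text>|naranjo=<10 chars y/n/u>|sev=<3 chars y/n>
#      |mech=<2 chars y/n>|who=t:<y/n/u>;a:<e/p/u>;d:<p/n/x>;r:<p/n/x>;s:<1/0>
# sev encodes (intervention_required, therapy_change, life_threatening);
# mech encodes (dose_dependent, pharmacologically_predictable).

format_adr_note <- function(drug, reaction, naranjo_answers, severity_facts,
                            mechanism_facts, who_facts) {
  yn <- function(x) ifelse(x, "y", "n")
  paste0("ADR|drug=", drug, "|reaction=", reaction,
         "|naranjo=", paste(substr(naranjo_answers, 1, 1), collapse = ""),
         "|sev=", paste(yn(severity_facts), collapse = ""),
         "|mech=", paste(yn(mechanism_facts), collapse = ""),
         "|who=t:", substr(who_facts$temporal_plausibility, 1, 1),
         ";a:", substr(who_facts$alternative_causes, 1, 1),
         ";d:", ifelse(who_facts$dechallenge == "none", "x",
                       substr(who_facts$dechallenge, 1, 1)),
         ";r:", ifelse(who_facts$rechallenge == "none", "x",
                       substr(who_facts$rechallenge, 1, 1)),
         ";s:", ifelse(isTRUE(who_facts$data_sufficient), "1", "0"))
}

is_adr_note <- function(text) startsWith(text, "ADR|")

parse_adr_note <- function(text) {
  parts <- strsplit(sub("^ADR\\|", "", text), "|", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""),
                   vapply(kv, `[[`, "", 1L))
  expand <- c(y = "yes", n = "no", u = "unknown")
  nar <- expand[strsplit(vals[["naranjo"]], "")[[1L]]]
  sev <- strsplit(vals[["sev"]], "")[[1L]] == "y"
  mech <- strsplit(vals[["mech"]], "")[[1L]] == "y"
  wf <- strsplit(strsplit(vals[["who"]], ";", fixed = TRUE)[[1L]], ":",
                 fixed = TRUE)
  wv <- setNames(vapply(wf, `[[`, "", 2L), vapply(wf, `[[`, "", 1L))
  who <- list(
    temporal_plausibility = c(y = "yes", n = "no", u = "unknown")[[wv[["t"]]]],
    alternative_causes = c(e = "excluded", p = "present",
                           u = "unknown")[[wv[["a"]]]],
    dechallenge = c(p = "positive", n = "negative", x = "none")[[wv[["d"]]]],
    rechallenge = c(p = "positive", n = "negative", x = "none")[[wv[["r"]]]],
    data_sufficient = wv[["s"]] == "1"
  )
  list(drug = vals[["drug"]], reaction = vals[["reaction"]],
       naranjo_answers = unname(nar),
       severity_facts = list(intervention_required = sev[1L],
                             therapy_change = sev[2L],
                             life_threatening_or_prolonging = sev[3L]),
       mechanism_facts = list(dose_dependent = mech[1L],
                              pharmacologically_predictable = mech[2L]),
       who_facts = who)
}

## --- detection linkage ------------------------------------------------------

# Reaction -> clinically relevant triggers, in decreasing specificity. An ADR
# whose reaction matches a pattern is linked to the first listed trigger with
# a hit at the onset day (exact day preferred, then +/- 1 day). Antiemetic
# administration triggers are deliberately not used for linkage; a
# nausea/vomiting ADR links only through a stop of the suspected drug.
reaction_trigger_map <- list(
  list(pattern = "hypoglyc", triggers = "glucose_lt_50"),
  list(pattern = "hypokal", triggers = "potassium_lt_3_0"),
  list(pattern = "hyperkal", triggers = "potassium_gt_5_5"),
  list(pattern = "hyponatr|antidiuretic|siadh", triggers = "sodium_lt_135"),
  list(pattern = "bleed|hemorrhage|haemorrhage|epistaxis|hematuria|melena",
       triggers = c("protamine", "phytomenadione", "inr_gt_3", "ptt_gt_50",
                    "platelets_lt_50000", "hb_ht_drop_25pct")),
  list(pattern = "rash|urticaria|pruritus",
       triggers = c("skin_rash", "hydroxyzine", "diphenhydramine",
                    "dexchlorpheniramine", "loratadine", "promethazine")),
  list(pattern = "renal", triggers = "bun_cr_rise_2x"),
  list(pattern = "thrombocytopen", triggers = "platelets_lt_50000"),
  list(pattern = "consciousness|sedation|somnolence|hypotension",
       triggers = "oversedation_hypotension"),
  list(pattern = "fall", triggers = "patient_fall")
)

# Returns list(detection=, trigger_id=) for one ADR.
link_detection <- function(reaction, drug, onset_day, patient_hits,
                           patient_meds) {
  cand <- character(0)
  for (m in reaction_trigger_map) {
    if (grepl(m$pattern, tolower(reaction))) { cand <- m$triggers; break }
  }
  find_hit <- function(ids, days) {
    h <- patient_hits[patient_hits$trigger_id %in% ids &
                        patient_hits$hospital_day %in% days, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    h <- h[order(match(h$trigger_id, ids), abs(h$hospital_day - onset_day)), ,
           drop = FALSE]
    h$trigger_id[1L]
  }
  for (days in list(onset_day, onset_day + c(-1L, 1L))) {
    if (length(cand)) {
      hit <- find_hit(cand, days)
      if (!is.null(hit)) {
        return(list(detection = "TRIGGER", trigger_id = hit))
      }
    }
  }
  # suspected drug stopped abruptly near onset?
  stops <- patient_hits[patient_hits$trigger_id == "abrupt_medication_stop" &
                          abs(patient_hits$hospital_day - onset_day) <= 1 &
                          grepl(paste0("stop:", drug),
                                patient_hits$evidence, fixed = TRUE), ,
                        drop = FALSE]
  if (nrow(stops) > 0) {
    return(list(detection = "TRIGGER", trigger_id = "abrupt_medication_stop"))
  }
  list(detection = "NON_TRIGGER_REVIEW", trigger_id = NA_character_)
}

#' Adjudicate a cohort's ADRs from structured assessment notes
#'
#' Automated adjudication: finds the structured ADR assessment notes in the
#' record (documented chart-review findings), re-derives all classifications
#' from the recorded facts (Naranjo score and category, WHO-UMC causality,
#' WHO severity, Rawlins-Thompson mechanism, ATC code) and links each ADR to
#' the trigger that detects it -- a clinically relevant trigger firing at the
#' onset day (exact day preferred, then +/- one day) or an abrupt stop of the
#' suspected drug; otherwise the ADR is classed as found by non-trigger
#' review.
#'
#' @param x an \code{icu_cohort}.
#' @param hits trigger hits from \code{\link{scan_cohort}}.
#' @return data.frame of adjudicated ADRs: \code{patient_id, drug_name,
#'   atc_code, reaction, onset_day, detection, trigger_id, severity,
#'   mechanism, naranjo_score, naranjo_category, who_causality}.
#' @export
adjudicate_cohort <- function(x, hits) {
  stopifnot(inherits(x, "icu_cohort"))
  notes <- x$notes[is_adr_note(x$notes$text), , drop = FALSE]
  empty <- data.frame(patient_id = character(0), drug_name = character(0),
                      atc_code = character(0), reaction = character(0),
                      onset_day = integer(0), detection = character(0),
                      trigger_id = character(0), severity = character(0),
                      mechanism = character(0), naranjo_score = integer(0),
                      naranjo_category = character(0),
                      who_causality = character(0), stringsAsFactors = FALSE)
  if (nrow(notes) == 0) return(empty)
  hits_by_pid <- split(hits, hits$patient_id)
  out <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    pid <- notes$patient_id[i]
    p <- x$patients[x$patients$patient_id == pid, , drop = FALSE]
    parsed <- parse_adr_note(notes$text[i])
    onset <- hospital_day(notes$timestamp[i], p$admit_time)
    score <- naranjo_score(parsed$naranjo_answers)
    ph <- hits_by_pid[[pid]]
    if (is.null(ph)) ph <- hits[0, , drop = FALSE]
    link <- link_detection(parsed$reaction, parsed$drug, onset, ph,
                           x$medications[x$medications$patient_id == pid, ,
                                         drop = FALSE])
    out[[i]] <- data.frame(
      patient_id = pid,
      drug_name = parsed$drug,
      atc_code = suppressWarnings(atc_lookup(parsed$drug)),
      reaction = parsed$reaction,
      onset_day = onset,
      detection = link$detection,
      trigger_id = link$trigger_id,
      severity = do.call(classify_severity, parsed$severity_facts),
      mechanism = do.call(classify_mechanism, parsed$mechanism_facts),
      naranjo_score = score,
      naranjo_category = naranjo_category(score),
      who_causality = do.call(who_causality, parsed$who_facts),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
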