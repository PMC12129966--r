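# Shared internal helpers.

# Round half away from zero at `digits` decimals, the convention used for
# the printed one-decimal rates (base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Parse ISO-8601 timestamps ("2020-03-05T08:00:00", with space also accepted,
# date-only rows get 00:00:00). Returns POSIXct in UTC; NA where unparseable.
parse_timestamp <- function(x) {
  x <- as.character(x)
  x <- sub("T", " ", x, fixed = TRUE)
  x <- ifelse(!is.na(x) & nchar(x) == 10, paste(x, "00:00:00"), x)
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
}

format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# 1-based hospital day: the admission calendar day is day 1.
hospital_day <- function(timestamp, admit_time) {
  as.integer(as.Date(timestamp, tz = "UTC") - as.Date(admit_time, tz = "UTC")) + 1L
}

# Canonical drug-name form: lower case, collapsed whitespace, synonym-mapped.
normalize_drug <- function(x) {
  x <- tolower(trimws(gsub("\\s+", " ", as.character(x))))
  syn <- drug_synonyms()
  idx <- match(x, tolower(syn$synonym))
  x[!is.na(idx)] <- tolower(syn$canonical[idx[!is.na(idx)]])
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_df <- function(spec) {
  # spec: named character vector column -> type ("character","numeric",...)
  cols <- lapply(spec, function(t) vector(t, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}
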