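#' Cohort schema
#'
#' The unit of analysis is one participant per row: baseline covariates, the
#' enrollment wave, and the survival outcome (years to dementia, death,
#' loss to follow-up or administrative end, plus event flags). Missing values
#' are `NA` in memory and the empty field on disk; booleans are serialized as
#' `0`/`1` and categorical fields as lowercase tokens.
#'
#' @return A data frame with one row per field: `name`, `type` (one of
#'   `"id"`, `"real"`, `"bool"`, `"cat"`), and `levels` (comma-separated
#'   vocabulary for categorical fields, `NA` otherwise).
#' @export
cohort_schema <- function() {
  f <- function(name, type, levels = NA_character_)
    data.frame(name = name, type = type, levels = levels,
               stringsAsFactors = FALSE)
  rbind(
    f("id", "id"),
    f("wave", "cat", "original,extended"),
    f("age", "real"),
    f("sex", "cat", "female,male"),
    f("education_years", "real"),
    f("sbp", "real"),
    f("bmi", "real"),
    f("total_cholesterol", "real"),
    f("hdl_cholesterol", "real"),
    f("physical_activity_met_hours", "real"),
    f("active_minutes_met4", "real"),
    f("diabetes", "bool"),
    f("stroke", "bool"),
    f("tia", "bool"),
    f("atrial_fibrillation", "bool"),
    f("head_trauma", "bool"),
    f("depressive_symptoms", "bool"),
    f("needs_help_finances_medications", "bool"),
    f("smoking", "cat", "never,former,current"),
    f("alcohol_user", "bool"),
    f("heavy_drinking", "bool"),
    f("social_engagement", "cat", "high,medium_high,medium_low,low"),
    f("living_with_partner", "bool"),
    f("married", "bool"),
    f("lonely", "bool"),
    f("fish_servings_week", "cat", "le_0.25,0.26_2.0,2.1_4.0,ge_4.1"),
    f("uses_antihypertensives", "bool"),
    f("uses_anxiolytics", "bool"),
    f("uses_aspirin", "bool"),
    f("uses_antidepressants", "bool"),
    f("uses_nsaids", "bool"),
    f("calendar_year", "real"),
    f("time", "real"),
    f("event", "cat", "censored,dementia"),
    f("death", "bool"),
    f("ad_subtype", "bool")
  )
}

schema_levels <- function(schema_row) strsplit(schema_row$levels, ",")[[1]]

#' Names of covariate columns (everything that may legitimately be missing)
#'
#' Outcome fields (`time`, `event`, `death`, `ad_subtype`), `id` and `wave`
#' are structural and never treated as imputable covariates. `age` and `sex`
#' are covariates but were completely observed in the emulated study design.
#'
#' @return Character vector of column names.
#' @export
covariate_columns <- function() {
  s <- cohort_schema()
  setdiff(s$name, c("id", "wave", "time", "event", "death", "ad_subtype"))
}

#' Validate a cohort data frame against the schema
#'
#' Checks column presence, in-memory types and categorical vocabularies.
#' Used internally by every entry point that accepts a cohort.
#'
#' @param cohort A data frame.
#' @param require_outcome If `TRUE` (default) the outcome columns must be
#'   present and non-missing.
#' @return `cohort`, invisibly, after passing all checks.
#' @export
validate_cohort <- function(cohort, require_outcome = TRUE) {
  s <- cohort_schema()
  need <- s$name
  if (!require_outcome) {
    s <- s[!s$name %in% c("time", "event", "death", "ad_subtype"), ]
    need <- s$name
  }
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort is missing schema column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(cohort$id))
    stop("duplicate participant id(s): ",
         paste(head(unique(cohort$id[duplicated(cohort$id)]), 5), collapse = ", "))
  for (i in seq_len(nrow(s))) {
    nm <- s$name[i]
    x <- cohort[[nm]]
    switch(s$type[i],
      id = {
        if (any(is.na(x))) stop("missing id")
      },
      real = {
        if (!is.numeric(x)) stop("column '", nm, "' must be numeric")
        if (any(is.infinite(x))) stop("non-finite value in '", nm, "'")
      },
      bool = {
        if (!is.logical(x)) stop("column '", nm, "' must be logical")
      },
      cat = {
        lev <- schema_levels(s[i, ])
        vals <- as.character(x)
        bad <- !is.na(vals) & !vals %in% lev
        if (any(bad))
          stop("column '", nm, "' has value(s) outside its vocabulary: ",
               paste(head(unique(vals[bad]), 5), collapse = ", "))
      })
  }
  if (require_outcome) {
    if (any(is.na(cohort$time)) || any(is.na(cohort$event)))
      stop("outcome fields 'time'/'event' may not be missing")
    if (any(cohort$time <= 0)) stop("follow-up time must be positive")
  }
  invisible(cohort)
}

#' Read a cohort from a delimited text file
#'
#' Parses a comma-delimited UTF-8 file with one header row whose column names
#' are exactly the schema field names. Schema-level problems (unknown or
#' missing columns, duplicate ids) are errors; malformed rows (non-parsable
#' numerics, out-of-vocabulary categories, non-positive follow-up) are
#' rejected one by one and reported in a diagnostics table attached as
#' attribute `"diagnostics"`.
#'
#' @param path Path to the file.
#' @param schema_version Schema label; only `"1"` is defined.
#' @return A validated cohort data frame of the parsed rows, with attribute
#'   `"diagnostics"`: a data frame with columns `row`, `id`, `field`,
#'   `message` (zero rows when the file is clean).
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1"))
    stop("unknown schema version: ", schema_version)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = NULL, fileEncoding = "UTF-8")
  s <- cohort_schema()
  unknown <- setdiff(names(raw), s$name)
  if (length(unknown) > 0)
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  absent <- setdiff(s$name, names(raw))
  if (length(absent) > 0)
    stop("missing column(s): ", paste(absent, collapse = ", "))
  raw <- raw[s$name]

  diags <- list()
  note <- function(row, id, field, message)
    data.frame(row = row, id = id, field = field, message = message,
               stringsAsFactors = FALSE)

  n <- nrow(raw)
  bad_row <- rep(FALSE, n)
  out <- vector("list", nrow(s))
  names(out) <- s$name
  for (i in seq_len(nrow(s))) {
    nm <- s$name[i]
    x <- raw[[nm]]
    x[x == ""] <- NA_character_
    switch(s$type[i],
      id = out[[nm]] <- x,
      real = {
        v <- suppressWarnings(as.numeric(x))
        bad <- !is.na(x) & is.na(v)
        if (any(bad)) {
          for (r in which(bad))
            diags[[length(diags) + 1L]] <-
              note(r, raw$id[r], nm, paste0("non-parsable numeric: '", x[r], "'"))
          bad_row <- bad_row | bad
        }
        out[[nm]] <- v
      },
      bool = {
        v <- rep(NA, n)
        v[!is.na(x) & x == "1"] <- TRUE
        v[!is.na(x) & x == "0"] <- FALSE
        bad <- !is.na(x) & !x %in% c("0", "1")
        if (any(bad)) {
          for (r in which(bad))
            diags[[length(diags) + 1L]] <-
              note(r, raw$id[r], nm, paste0("boolean must be 0/1, got '", x[r], "'"))
          bad_row <- bad_row | bad
        }
        out[[nm]] <- v
      },
      cat = {
        lev <- schema_levels(s[i, ])
        bad <- !is.na(x) & !x %in% lev
        if (any(bad)) {
          for (r in which(bad))
            diags[[length(diags) + 1L]] <-
              note(r, raw$id[r], nm, paste0("value '", x[r],
                   "' not in vocabulary {", paste(lev, collapse = ", "), "}"))
          bad_row <- bad_row | bad
        }
        x[bad] <- NA_character_
        out[[nm]] <- factor(x, levels = lev)
      })
  }
  cohort <- as.data.frame(out, stringsAsFactors = FALSE)

  # outcome sanity per row
  bad_t <- !is.na(cohort$time) & cohort$time <= 0
  for (r in which(bad_t))
    diags[[length(diags) + 1L]] <-
      note(r, cohort$id[r], "time", "follow-up time must be > 0")
  bad_row <- bad_row | bad_t | is.na(cohort$time) | is.na(cohort$event)
  for (r in which(is.na(cohort$time) | is.na(cohort$event)))
    diags[[length(diags) + 1L]] <-
      note(r, cohort$id[r], "time/event", "outcome fields may not be missing")

  cohort <- cohort[!bad_row, , drop = FALSE]
  rownames(cohort) <- NULL
  if (anyDuplicated(cohort$id))
    stop("duplicate participant id(s): ",
         paste(head(unique(cohort$id[duplicated(cohort$id)]), 5), collapse = ", "))
  diagnostics <- if (length(diags) > 0) do.call(rbind, diags) else
    data.frame(row = integer(), id = character(), field = character(),
               message = character(), stringsAsFactors = FALSE)
  validate_cohort(cohort)
  attr(cohort, "diagnostics") <- diagnostics
  cohort
}

#' Write a cohort to a delimited text file
#'
#' Deterministic column order (schema order), missing values as empty
#' fields, booleans as `0`/`1`, categories as lowercase tokens, and numerics
#' at full double precision so that [read_cohort()] round-trips exactly.
#'
#' @param cohort A valid cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  s <- cohort_schema()
  out <- cohort[s$name]
  for (i in seq_len(nrow(s))) {
    nm <- s$name[i]
    x <- out[[nm]]
    chr <- switch(s$type[i],
      id = as.character(x),
      real = ifelse(is.na(x), NA_character_, sprintf("%.17g", x)),
      bool = ifelse(is.na(x), NA_character_, ifelse(x, "1", "0")),
      cat = as.character(x))
    out[[nm]] <- chr
  }
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
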