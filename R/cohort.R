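#' @importFrom stats quantile rexp runif rnorm sd aggregate optim optimHess
#'   kmeans pnorm qnorm complete.cases setNames
#' @importFrom utils read.csv write.csv head
NULL

PRIOR_FLAGS <- c("cvd", "ihd", "pad", "hs", "is", "tia", "af", "neuropathy", "dpa", "hf")
MED_FLAGS   <- c("acarbose", "metformin", "sulfonylureas", "dpp4i", "sglt2i")
SUBJECT_COLS <- c("subject_id", "diagnosis_year", "ddd", "age_at_ddd", "sex", "ethnicity",
                  paste0("prior_", PRIOR_FLAGS), paste0("med_", MED_FLAGS))
HBA1C_RANGE <- c(3, 25)

#' Assemble and validate a cohort
#'
#' A cohort bundles three tables keyed by `subject_id`:
#' * `subjects` — one row per subject: demographics at diagnosis
#'   (`diagnosis_year`, `ddd` date, `age_at_ddd`, `sex`, `ethnicity`),
#'   prior-complication flags `prior_*` and medication flags `med_*`
#'   (0/1, descriptive only).
#' * `measurements` — the longitudinal HbA1c series: `subject_id`,
#'   `t_weeks` (weeks since the date of diabetes diagnosis, non-negative,
#'   strictly increasing within subject) and `hba1c` (%, in \[3, 25\]).
#' * `events` — recurrent-event records: `subject_id`, the observation
#'   window `L_weeks` < `R_weeks`, and one row per hospitalization at
#'   `t_weeks` in (L, R\] (`t_weeks = NA` for a subject with a window but
#'   no events). At most one window per subject.
#'
#' Duplicate measurement times within a subject keep the first occurrence;
#' later duplicates are dropped with a warning. All other invariant
#' violations are collected into a per-row report and raised as an error.
#'
#' @param subjects,measurements,events data frames as described above;
#'   `events` may be `NULL` when no recurrent-event data exist.
#' @param study_span allowed range of `diagnosis_year`.
#' @return A validated object of class `cohort`.
#' @export
cohort <- function(subjects, measurements, events = NULL, study_span = c(1955, 2030)) {
  subjects <- as.data.frame(subjects)
  measurements <- as.data.frame(measurements)
  if (!is.null(events)) events <- as.data.frame(events)
  subjects$subject_id <- as.character(subjects$subject_id)
  measurements$subject_id <- as.character(measurements$subject_id)
  if (!is.null(events)) events$subject_id <- as.character(events$subject_id)

  # deterministic duplicate-time rule: first kept, later dropped
  if (nrow(measurements)) {
    measurements <- measurements[order(match(measurements$subject_id, unique(measurements$subject_id))), , drop = FALSE]
    dup <- duplicated(measurements[, c("subject_id", "t_weeks")])
    if (any(dup)) {
      warning(sprintf("dropped %d duplicate measurement time(s); first occurrence kept", sum(dup)))
      measurements <- measurements[!dup, , drop = FALSE]
    }
  }
  rownames(subjects) <- rownames(measurements) <- NULL
  if (!is.null(events)) rownames(events) <- NULL
  obj <- structure(list(subjects = subjects, measurements = measurements,
                        events = events, study_span = study_span),
                   class = "cohort")
  validate_cohort(obj)
  obj
}

#' Validate a cohort
#'
#' Re-checks every invariant and raises a single error listing the
#' offending rows/subjects, or returns the cohort invisibly.
#'
#' @param x a [cohort()].
#' @return `x`, invisibly.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  problems <- character()
  sub <- x$subjects; mea <- x$measurements; ev <- x$events

  need <- c("subject_id", "diagnosis_year", "age_at_ddd", "sex", "ethnicity")
  miss <- setdiff(need, names(sub))
  if (length(miss)) stop("subjects table missing required column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c("subject_id", "t_weeks", "hba1c"), names(mea))
  if (length(miss)) stop("measurements table missing required column(s): ", paste(miss, collapse = ", "))
  if (!is.null(ev)) {
    miss <- setdiff(c("subject_id", "L_weeks", "R_weeks", "t_weeks"), names(ev))
    if (length(miss)) stop("events table missing required column(s): ", paste(miss, collapse = ", "))
  }

  if (anyDuplicated(sub$subject_id))
    problems <- c(problems, paste0("duplicate subject_id: ",
      paste(unique(sub$subject_id[duplicated(sub$subject_id)]), collapse = ", ")))
  bad <- which(!is.na(sub$age_at_ddd) & sub$age_at_ddd <= 0)
  if (length(bad)) problems <- c(problems, paste0("age_at_ddd <= 0 for subject(s): ",
    paste(sub$subject_id[bad], collapse = ", ")))
  bad <- which(!is.na(sub$diagnosis_year) &
               (sub$diagnosis_year < x$study_span[1] | sub$diagnosis_year > x$study_span[2]))
  if (length(bad)) problems <- c(problems, paste0("diagnosis_year outside study span for subject(s): ",
    paste(sub$subject_id[bad], collapse = ", ")))

  unknown <- setdiff(unique(mea$subject_id), sub$subject_id)
  if (length(unknown)) problems <- c(problems,
    paste0("measurements for unknown subject(s): ", paste(unknown, collapse = ", ")))
  bad <- which(!is.na(mea$t_weeks) & mea$t_weeks < 0)
  if (length(bad)) problems <- c(problems,
    paste0("negative measurement time for subject(s): ",
           paste(unique(mea$subject_id[bad]), collapse = ", ")))
  bad <- which(!is.na(mea$hba1c) & (mea$hba1c < HBA1C_RANGE[1] | mea$hba1c > HBA1C_RANGE[2]))
  if (length(bad)) problems <- c(problems,
    paste0("HbA1c outside [", HBA1C_RANGE[1], ", ", HBA1C_RANGE[2], "] for subject(s): ",
           paste(unique(mea$subject_id[bad]), collapse = ", ")))
  if (nrow(mea)) {
    unsorted <- vapply(split(mea$t_weeks, mea$subject_id), function(t) is.unsorted(t, strictly = TRUE),
                       logical(1))
    if (any(unsorted)) problems <- c(problems,
      paste0("measurement times not strictly increasing for subject(s): ",
             paste(names(unsorted)[unsorted], collapse = ", ")))
  }

  if (!is.null(ev) && nrow(ev)) {
    unknown <- setdiff(unique(ev$subject_id), sub$subject_id)
    if (length(unknown)) problems <- c(problems,
      paste0("events for unknown subject(s): ", paste(unknown, collapse = ", ")))
    win <- unique(ev[, c("subject_id", "L_weeks", "R_weeks")])
    if (anyDuplicated(win$subject_id)) problems <- c(problems,
      paste0("conflicting windows for subject(s): ",
             paste(unique(win$subject_id[duplicated(win$subject_id)]), collapse = ", ")))
    bad <- which(win$L_weeks < 0 | win$R_weeks <= win$L_weeks)
    if (length(bad)) problems <- c(problems,
      paste0("invalid window (need 0 <= L < R) for subject(s): ",
             paste(win$subject_id[bad], collapse = ", ")))
    has_t <- !is.na(ev$t_weeks)
    bad <- which(has_t & (ev$t_weeks <= ev$L_weeks | ev$t_weeks > ev$R_weeks | ev$t_weeks <= 0))
    if (length(bad)) problems <- c(problems,
      paste0("event time outside (L, R] (or <= 0) for subject(s): ",
             paste(unique(ev$subject_id[bad]), collapse = ", ")))
    tt <- ev[has_t, , drop = FALSE]
    if (nrow(tt)) {
      unsorted <- vapply(split(tt$t_weeks, tt$subject_id),
                         function(t) is.unsorted(t, strictly = TRUE), logical(1))
      if (any(unsorted)) problems <- c(problems,
        paste0("event times not strictly increasing for subject(s): ",
               paste(names(unsorted)[unsorted], collapse = ", ")))
    }
  }

  if (length(problems)) stop("cohort validation failed:\n  - ",
                             paste(problems, collapse = "\n  - "))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects, %d HbA1c measurements", nrow(x$subjects), nrow(x$measurements)))
  if (!is.null(x$events)) {
    cat(sprintf(", %d events in %d windows",
                sum(!is.na(x$events$t_weeks)),
                length(unique(x$events$subject_id))))
  }
  cat("\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x a [cohort()].
#' @return integer subject count.
#' @export
n_subjects <- function(x) nrow(x$subjects)

#' Read a cohort from CSV files
#'
#' Reads the three-table CSV layout (comma-separated, UTF-8, header row,
#' ISO-8601 dates) and validates it. Missing required columns raise a
#' schema error naming the column; invariant violations raise a validation
#' error naming the offending subjects.
#'
#' @param subjects_path,measurements_path CSV paths.
#' @param events_path optional events CSV path.
#' @return a validated [cohort()].
#' @export
read_cohort <- function(subjects_path, measurements_path, events_path = NULL) {
  sub <- read.csv(subjects_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  mea <- read.csv(measurements_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  ev <- if (!is.null(events_path)) read.csv(events_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if ("ddd" %in% names(sub)) sub$ddd <- as.Date(sub$ddd)
  cohort(sub, mea, ev)
}

#' Write a cohort to CSV files
#'
#' Writes `subjects.csv`, `measurements.csv` and (when present)
#' `events.csv` into `out_dir`; `read_cohort()` on the written files
#' reproduces the cohort field by field.
#'
#' @param x a [cohort()].
#' @param out_dir output directory, created if needed.
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(x, out_dir) {
  stopifnot(inherits(x, "cohort"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(subjects = file.path(out_dir, "subjects.csv"),
             measurements = file.path(out_dir, "measurements.csv"))
  sub <- x$subjects
  if ("ddd" %in% names(sub)) sub$ddd <- format(sub$ddd)
  write.csv(sub, paths[["subjects"]], row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  write.csv(x$measurements, paths[["measurements"]], row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  if (!is.null(x$events)) {
    paths <- c(paths, events = file.path(out_dir, "events.csv"))
    write.csv(x$events, paths[["events"]], row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(paths)
}

#' Impute the date of diabetes diagnosis (DDD)
#'
#' When the diagnosis year matches the year of the first HbA1c record, the
#' DDD is taken to be that record's date. Otherwise a date is drawn
#' uniformly over the days of the diagnosis year (365 or 366 for leap
#' years), reproducibly under `seed`.
#'
#' @param diagnosis_year calendar year of type 2 diabetes diagnosis.
#' @param first_hba1c_year calendar year of the first HbA1c record.
#' @param first_hba1c_date `Date` of the first HbA1c record (used when the
#'   years match).
#' @param seed integer seed for the uniform draw.
#' @return a `Date`.
#' @export
impute_ddd <- function(diagnosis_year, first_hba1c_year, first_hba1c_date = NULL, seed = NULL) {
  if (diagnosis_year == first_hba1c_year) {
    if (is.null(first_hba1c_date)) stop("first_hba1c_date required when years match")
    return(as.Date(first_hba1c_date))
  }
  start <- as.Date(sprintf("%04d-01-01", diagnosis_year))
  ndays <- as.integer(as.Date(sprintf("%04d-01-01", diagnosis_year + 1)) - start)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  start + sample.int(ndays, 1L) - 1L
}

#' Build a subject's observation window
#'
#' Recurrent-event records are only complete from a truncation date
#' onward, so the left bound of the window on the subject's week axis is 0
#' when the DDD falls after the truncation date and the DDD-to-truncation
#' gap otherwise; the right bound is the end of follow-up. Weeks are
#' day-differences divided by 7, fractional weeks kept.
#'
#' @param subject_ddd `Date` of diabetes diagnosis.
#' @param truncation_date `Date` from which covariates/events are complete.
#' @param followup_end `Date` of the end of follow-up.
#' @return numeric `c(L, R)` in weeks, with `0 <= L < R`.
#' @export
build_observation_window <- function(subject_ddd, truncation_date, followup_end) {
  subject_ddd <- as.Date(subject_ddd); truncation_date <- as.Date(truncation_date)
  followup_end <- as.Date(followup_end)
  if (followup_end <= truncation_date) stop("followup_end must be after truncation_date")
  L <- max(0, as.numeric(truncation_date - subject_ddd) / 7)
  R <- as.numeric(followup_end - subject_ddd) / 7
  if (R <= L) stop("degenerate window: follow-up ends before the observation window opens")
  c(L = L, R = R)
}
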