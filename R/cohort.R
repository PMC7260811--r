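#' Construct a visit cohort
#'
#' A `visit_cohort` is the central data object of the package: a long-format
#' table of subject visits together with a subject-level table giving each
#' individual's follow-up window. Visit times are arbitrary non-negative
#' numbers on a common scale (months, years, ...); the unit is carried as
#' metadata only and never interpreted.
#'
#' The subject table defines the at-risk window used by the censoring
#' adjustment: `entry` is the time the subject came under observation and
#' `end` the administrative closure of their follow-up (dataset closure).
#' Subjects flagged `lost_to_followup` stopped visiting before closure but
#' remain at risk up to `end`. When no subject table is supplied, every
#' subject defaults to `entry = 0` and `end` equal to their last visit time.
#'
#' @param visits data frame with one row per subject-visit. Must contain an
#'   `id` column and a numeric `time` column; any further columns are treated
#'   as per-visit covariates (e.g. an outcome measured at the visit).
#' @param subjects optional data frame with columns `id`, `entry`, `end`,
#'   optionally `lost_to_followup` (logical) and baseline covariate columns.
#'   Subjects present in `visits` but absent here receive the defaults above,
#'   with a warning.
#' @param time_unit label for the time scale, e.g. `"months"`. Metadata only.
#' @param duplicates policy for duplicated `(id, time)` rows: `"error"`
#'   (default) or `"collapse"` (keep one row).
#' @return An object of class `visit_cohort`: a list with elements `visits`
#'   (sorted by id, then time), `subjects`, and `time_unit`.
#' @examples
#' v <- data.frame(id = c("A", "A", "B"), time = c(2, 4, 2))
#' visit_cohort(v)
#' @export
visit_cohort <- function(visits, subjects = NULL, time_unit = "months",
                         duplicates = c("error", "collapse")) {
  duplicates <- match.arg(duplicates)
  if (!is.data.frame(visits)) stop("`visits` must be a data frame", call. = FALSE)
  for (col in c("id", "time")) {
    if (!col %in% names(visits)) {
      stop("`visits` is missing required column '", col, "'", call. = FALSE)
    }
  }
  visits$id <- as.character(visits$id)
  if (!is.numeric(visits$time)) {
    bad <- which(is.na(suppressWarnings(as.numeric(visits$time))))
    stop("non-numeric visit time in rows: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(visits$time)) {
    stop("missing visit time in rows: ",
         paste(utils::head(which(is.na(visits$time)), 5), collapse = ", "), call. = FALSE)
  }
  if (any(visits$time < 0)) {
    bad <- which(visits$time < 0)
    stop("negative visit time in rows: ", paste(utils::head(bad, 5), collapse = ", "),
         " (times must be >= 0)", call. = FALSE)
  }

  visits <- visits[order(visits$id, visits$time), , drop = FALSE]
  rownames(visits) <- NULL

  dup <- duplicated(visits[c("id", "time")])
  if (any(dup)) {
    if (duplicates == "error") {
      d <- visits[dup, , drop = FALSE]
      stop("duplicated (id, time) rows: ",
           paste(sprintf("(%s, %g)", utils::head(d$id, 5), utils::head(d$time, 5)),
                 collapse = ", "),
           "; set duplicates = \"collapse\" to keep one row per (id, time)",
           call. = FALSE)
    }
    visits <- visits[!dup, , drop = FALSE]
  }

  ids <- unique(visits$id)
  last_visit <- tapply(visits$time, factor(visits$id, levels = ids), max)

  if (is.null(subjects)) {
    subjects <- data.frame(id = ids, entry = 0,
                           end = as.numeric(last_visit),
                           lost_to_followup = FALSE,
                           stringsAsFactors = FALSE)
  } else {
    subjects <- as.data.frame(subjects)
    for (col in c("id", "entry", "end")) {
      if (!col %in% names(subjects)) {
        stop("`subjects` is missing required column '", col, "'", call. = FALSE)
      }
    }
    subjects$id <- as.character(subjects$id)
    if (anyDuplicated(subjects$id)) {
      stop("duplicate subject ids in `subjects`: ",
           paste(unique(subjects$id[duplicated(subjects$id)]), collapse = ", "),
           call. = FALSE)
    }
    unknown <- setdiff(subjects$id, ids)
    zero_visit <- character(0)
    if (length(unknown)) {
      # subjects with no visits are allowed but flagged
      zero_visit <- unknown
      warning("subjects with zero visits: ", paste(utils::head(unknown, 5), collapse = ", "),
              call. = FALSE)
    }
    missing_ids <- setdiff(ids, subjects$id)
    if (length(missing_ids)) {
      warning("subjects absent from subject table given default entry = 0, ",
              "end = last visit: ", paste(utils::head(missing_ids, 5), collapse = ", "),
              call. = FALSE)
      subjects <- merge_rows(subjects,
                             data.frame(id = missing_ids, entry = 0,
                                        end = as.numeric(last_visit[missing_ids]),
                                        stringsAsFactors = FALSE))
    }
    if (!"lost_to_followup" %in% names(subjects)) subjects$lost_to_followup <- FALSE
    subjects$lost_to_followup[is.na(subjects$lost_to_followup)] <- FALSE
    if (any(subjects$end < subjects$entry)) {
      bad <- subjects$id[subjects$end < subjects$entry]
      stop("end < entry for subjects: ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  subjects <- subjects[order(subjects$id), , drop = FALSE]
  rownames(subjects) <- NULL

  # window consistency: entry <= first visit, last visit <= end
  first_visit <- tapply(visits$time, factor(visits$id, levels = subjects$id), min)
  lastv <- tapply(visits$time, factor(visits$id, levels = subjects$id), max)
  has_visits <- !is.na(first_visit)
  if (any(has_visits & subjects$entry > first_visit + 1e-12)) {
    bad <- subjects$id[which(has_visits & subjects$entry > first_visit + 1e-12)]
    stop("entry time after first visit for subjects: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(has_visits & subjects$end < lastv - 1e-12)) {
    bad <- subjects$id[which(has_visits & subjects$end < lastv - 1e-12)]
    stop("end of follow-up before last visit for subjects: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  structure(list(visits = visits, subjects = subjects, time_unit = time_unit),
            class = "visit_cohort")
}

# rbind two subject data frames with possibly different columns
merge_rows <- function(a, b) {
  for (col in setdiff(names(a), names(b))) b[[col]] <- NA
  for (col in setdiff(names(b), names(a))) a[[col]] <- NA
  rbind(a, b[names(a)])
}

#' @export
print.visit_cohort <- function(x, ...) {
  nv <- nrow(x$visits)
  ns <- nrow(x$subjects)
  cat("Visit cohort: ", ns, " subjects, ", nv, " visits (time unit: ",
      x$time_unit, ")\n", sep = "")
  per <- table(factor(x$visits$id, levels = x$subjects$id))
  cat("  visits per subject: min ", min(per), ", median ",
      stats::median(per), ", max ", max(per), "\n", sep = "")
  cat("  follow-up window: [", format(min(x$subjects$entry)), ", ",
      format(max(x$subjects$end)), "]\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.visit_cohort <- function(x, ...) x$visits

#' Number of subjects in a cohort
#' @param cohort a [visit_cohort()]
#' @return integer count of subjects (including any with zero visits).
#' @export
n_subjects <- function(cohort) {
  stopifnot(inherits(cohort, "visit_cohort"))
  nrow(cohort$subjects)
}

#' Read a visit table from delimited text
#'
#' Reads a CSV with one row per subject-visit and validates it into a
#' [visit_cohort()]. Times must be numeric and non-negative; calendar dates
#' must be converted by the caller.
#'
#' @param path path to a CSV file.
#' @param id_col,time_col names of the subject-id and visit-time columns.
#' @param covariate_cols optional character vector of per-visit covariate
#'   columns to retain; default keeps all remaining columns.
#' @param duplicates duplicate `(id, time)` policy, see [visit_cohort()].
#' @param time_unit label for the time scale.
#' @return A [visit_cohort()] with default entry/end times (use
#'   [read_subjects()] to supply real follow-up windows).
#' @export
read_visits <- function(path, id_col = "id", time_col = "time",
                        covariate_cols = NULL,
                        duplicates = c("error", "collapse"),
                        time_unit = "months") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(id_col, time_col)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path, call. = FALSE)
    }
  }
  keep <- covariate_cols
  if (is.null(keep)) keep <- setdiff(names(df), c(id_col, time_col))
  missing_cov <- setdiff(keep, names(df))
  if (length(missing_cov)) {
    stop("covariate columns not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  out <- df[c(id_col, time_col, keep)]
  names(out)[1:2] <- c("id", "time")
  if (!is.numeric(out$time)) {
    suppress <- suppressWarnings(as.numeric(out$time))
    if (anyNA(suppress)) {
      stop("non-numeric visit times in rows: ",
           paste(utils::head(which(is.na(suppress)), 5), collapse = ", "),
           call. = FALSE)
    }
    out$time <- suppress
  }
  visit_cohort(out, time_unit = time_unit, duplicates = duplicates)
}

#' Attach subject-level follow-up windows to a cohort
#'
#' Reads a subject table (id, entry time, end of follow-up, optional
#' `lost_to_followup` flag and baseline covariates) and merges it into an
#' existing cohort. Subjects missing from the file keep the defaults
#' `entry = 0`, `end = last visit`, with a warning.
#'
#' @param path path to a CSV file with columns `id`, `entry_time`, `end_time`,
#'   optionally `lost_to_followup` and baseline covariates.
#' @param cohort a [visit_cohort()] whose ids the file refers to.
#' @return The cohort with its subject table replaced.
#' @export
read_subjects <- function(path, cohort) {
  stopifnot(inherits(cohort, "visit_cohort"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("id", "entry_time", "end_time")) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path, call. = FALSE)
    }
  }
  names(df)[names(df) == "entry_time"] <- "entry"
  names(df)[names(df) == "end_time"] <- "end"
  visit_cohort(cohort$visits, subjects = df, time_unit = cohort$time_unit)
}

#' Write a result table to delimited text
#'
#' Writes any of the package's tabular results (bin proportion summaries,
#' bin-width sweeps, intensity-model summaries, weight tables) as CSV with
#' full numeric precision, so that re-reading reproduces the numbers to
#' within 1e-12.
#'
#' @param x the object to write.
#' @param path output file path.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, ...) UseMethod("write_table")

#' @export
write_table.data.frame <- function(x, path, ...) {
  df <- x
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("cannot write to ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @export
write_table.proportion_summary <- function(x, path, ...) {
  write_table(as.data.frame(unclass(x)), path)
}

#' @export
write_table.sweep_result <- function(x, path, ...) {
  write_table(as.data.frame(unclass(x)), path)
}

#' @export
write_table.intensity_model <- function(x, path, ...) {
  write_table(x$coefficients, path)
}
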