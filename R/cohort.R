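#' @keywords internal
"_PACKAGE"

## Assessment schedule: weeks 0, 4, 8 (end of program) and 34 (six-month
## follow-up) relative to program start.
ASSESSMENT_TIMES <- c("T0", "T4", "T8", "T34")

VARIABLE_CLASSES <- c("A", "B", "C")
VARIABLE_SCALES <- c("continuous", "ordinal", "binary")
DIRECTION_HINTS <- c("high_is_positive", "low_is_positive", "unknown")
DROPOUT_STAGES <- c("completed_T34", "lost_after_T8", "lost_in_program")

## Non-predictor columns of the patient table.
CORE_COLUMNS <- c(
  "id", "sex", "age", "bmi",
  paste0("odi_", ASSESSMENT_TIMES), paste0("nprs_", ASSESSMENT_TIMES),
  "dropout_stage"
)

#' I/O dialect for cohort files
#'
#' Delimited-text conventions for [read_cohort()] and [write_cohort()].
#' European clinical sources often print decimal commas (e.g. "72,62");
#' set `decimal = "comma"` (with a non-comma delimiter) to parse them.
#' Internally all values are plain doubles; comma handling is confined
#' to I/O.
#'
#' @param decimal decimal mark, `"point"` or `"comma"`.
#' @param delimiter field separator; defaults to `","` for point decimals
#'   and `";"` for comma decimals.
#' @return a list with elements `decimal`, `delimiter`, `dec` (the
#'   single-character mark).
#' @export
cohort_dialect <- function(decimal = c("point", "comma"), delimiter = NULL) {
  decimal <- match.arg(decimal)
  dec <- if (decimal == "comma") "," else "."
  if (is.null(delimiter)) delimiter <- if (decimal == "comma") ";" else ","
  if (delimiter == dec) {
    stop("delimiter and decimal mark cannot both be '", dec, "'")
  }
  list(decimal = decimal, delimiter = delimiter, dec = dec)
}

#' Construct a patient cohort
#'
#' A cohort bundles one row per patient with a variable dictionary
#' describing every candidate predictor (its class A/B/C, measurement
#' scale, and the direction expected to predict success).  All analysis
#' stages operate on this container.
#'
#' @param patients data.frame with columns `id`, `sex` (`"M"`/`"F"`),
#'   `age`, `bmi`, `odi_T0` ... `nprs_T34`, `dropout_stage`, plus one
#'   column per candidate predictor.  Missing values are `NA`.
#' @param variables data.frame with columns `name`, `class` (`"A"`,
#'   `"B"` or `"C"`), `scale` (`"continuous"`, `"ordinal"`, `"binary"`)
#'   and `direction_hint` (`"high_is_positive"`, `"low_is_positive"`,
#'   `"unknown"`).
#' @param provenance free-text origin note (e.g. simulation seed).
#' @return an object of class `"cohort"`.
#' @export
cohort <- function(patients, variables, provenance = "") {
  stopifnot(is.data.frame(patients), is.data.frame(variables))
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  obj <- structure(
    list(patients = patients, variables = variables,
         provenance = as.character(provenance)[1]),
    class = "cohort"
  )
  validate_cohort(obj)
  obj
}

#' Validate a cohort object
#'
#' Checks structural invariants: required columns, score ranges (ODI in
#' \[0,100\], NPRS in \[0,10\]), the ODI >= 12 eligibility floor at
#' baseline, binary predictors in \{0,1\}, and that every predictor
#' column is declared in the variable dictionary.
#'
#' @param x a `"cohort"`.
#' @return `x`, invisibly; errors describe the offending column/patient.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  p <- x$patients
  v <- x$variables

  required <- c("id", "sex", "age", "bmi", "odi_T0", "nprs_T0", "dropout_stage")
  missing_cols <- setdiff(required, names(p))
  if (length(missing_cols)) {
    stop("malformed cohort: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  dict_required <- c("name", "class", "scale", "direction_hint")
  missing_dict <- setdiff(dict_required, names(v))
  if (length(missing_dict)) {
    stop("malformed variable dictionary: missing column(s) ",
         paste(missing_dict, collapse = ", "))
  }
  if (anyDuplicated(v$name)) {
    stop("variable dictionary: duplicated name(s) ",
         paste(unique(v$name[duplicated(v$name)]), collapse = ", "))
  }
  bad_class <- setdiff(v$class, VARIABLE_CLASSES)
  if (length(bad_class)) {
    stop("unknown variable class: ", paste(bad_class, collapse = ", "))
  }
  bad_scale <- setdiff(v$scale, VARIABLE_SCALES)
  if (length(bad_scale)) {
    stop("unknown variable scale: ", paste(bad_scale, collapse = ", "))
  }
  bad_hint <- setdiff(v$direction_hint, DIRECTION_HINTS)
  if (length(bad_hint)) {
    stop("unknown direction hint: ", paste(bad_hint, collapse = ", "))
  }

  if (nrow(p)) {
    if (anyDuplicated(p$id)) stop("duplicated patient id(s)")
    bad_sex <- setdiff(stats::na.omit(p$sex), c("M", "F"))
    if (length(bad_sex)) stop("sex must be 'M' or 'F'")
    bad_stage <- setdiff(stats::na.omit(p$dropout_stage), DROPOUT_STAGES)
    if (length(bad_stage)) {
      stop("unknown dropout_stage: ", paste(bad_stage, collapse = ", "))
    }
    for (col in grep("^odi_", names(p), value = TRUE)) {
      bad <- which(!is.na(p[[col]]) & (p[[col]] < 0 | p[[col]] > 100))
      if (length(bad)) {
        stop("ODI outside [0,100] in ", col, " for patient ",
             p$id[bad[1]])
      }
    }
    for (col in grep("^nprs_", names(p), value = TRUE)) {
      bad <- which(!is.na(p[[col]]) & (p[[col]] < 0 | p[[col]] > 10))
      if (length(bad)) {
        stop("NPRS outside [0,10] in ", col, " for patient ", p$id[bad[1]])
      }
    }
    bad_floor <- which(!is.na(p$odi_T0) & p$odi_T0 < 12)
    if (length(bad_floor)) {
      stop("odi_T0 below the 12% eligibility floor for patient ",
           p$id[bad_floor[1]])
    }
    if (anyNA(p$odi_T0)) {
      stop("odi_T0 missing for patient ", p$id[which(is.na(p$odi_T0))[1]])
    }
  }

  predictors <- setdiff(names(p), CORE_COLUMNS)
  undeclared <- setdiff(predictors, v$name)
  if (length(undeclared)) {
    stop("predictor column(s) not in variable dictionary: ",
         paste(undeclared, collapse = ", "))
  }
  for (nm in intersect(v$name[v$scale == "binary"], names(p))) {
    vals <- stats::na.omit(p[[nm]])
    if (length(vals) && !all(vals %in% c(0, 1))) {
      stop("binary variable ", nm, " has values outside {0, 1}")
    }
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  p <- x$patients
  cat("<cohort> ", nrow(p), " patients, ",
      nrow(x$variables), " candidate variables\n", sep = "")
  if (nrow(p)) {
    tab <- table(factor(p$dropout_stage, levels = DROPOUT_STAGES))
    cat("  completed T34: ", tab[["completed_T34"]],
        " | lost after T8: ", tab[["lost_after_T8"]],
        " | lost in program: ", tab[["lost_in_program"]], "\n", sep = "")
  }
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Read a cohort from delimited text
#'
#' Expects a patient table and a sidecar variable dictionary (columns
#' `name`, `class`, `scale`, `direction_hint`).  Empty cells become
#' `NA`.  A leading `# provenance:` comment line, as written by
#' [write_cohort()], is recovered.
#'
#' @param path patient-table file.
#' @param dict_path variable-dictionary file.
#' @param dialect a [cohort_dialect()].
#' @return a validated `"cohort"`.
#' @export
read_cohort <- function(path, dict_path, dialect = cohort_dialect()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (!file.exists(dict_path)) stop("dictionary file not found: ", dict_path)

  first <- readLines(path, n = 1L)
  provenance <- if (startsWith(first, "# provenance:")) {
    trimws(sub("^# provenance:", "", first))
  } else ""

  patients <- utils::read.table(
    path, header = TRUE, sep = dialect$delimiter, dec = dialect$dec,
    na.strings = "", comment.char = "#", quote = "\"",
    stringsAsFactors = FALSE, check.names = FALSE,
    colClasses = c(id = "character")
  )
  variables <- utils::read.table(
    dict_path, header = TRUE, sep = dialect$delimiter, dec = dialect$dec,
    na.strings = "", comment.char = "#", quote = "\"",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  # an all-missing score column has no type evidence in the file;
  # scores are integer-valued by construction
  for (col in grep("^(odi|nprs)_", names(patients), value = TRUE)) {
    if (is.logical(patients[[col]])) {
      patients[[col]] <- as.integer(patients[[col]])
    }
  }
  cohort(patients, variables, provenance)
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x))` reproduces
#' `x` exactly, including missing cells (written as empty fields) and
#' the provenance note (a `# provenance:` comment line).
#'
#' @param x a `"cohort"`.
#' @param path patient-table file to write.
#' @param dict_path variable-dictionary file to write.
#' @param dialect a [cohort_dialect()].
#' @return `x`, invisibly.
#' @export
write_cohort <- function(x, path, dict_path, dialect = cohort_dialect()) {
  validate_cohort(x)
  write_one <- function(df, file, comment = NULL) {
    con <- file(file, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(comment)) writeLines(comment, con)
    utils::write.table(df, con, sep = dialect$delimiter, dec = dialect$dec,
                       na = "", quote = FALSE, row.names = FALSE)
  }
  comment <- if (nzchar(x$provenance)) {
    paste0("# provenance: ", x$provenance)
  } else NULL
  write_one(x$patients, path, comment)
  write_one(x$variables, dict_path)
  invisible(x)
}

#' Complete-case subset for an analysis stage
#'
#' Keeps patients with non-missing values for all named variables and
#' for ODI at baseline and at `time`.  Each analysis stage calls this so
#' exclusions are explicit and logged (the paper-style per-table n's —
#' e.g. 110 completers at T8, 100 at T34 — arise from completers with
#' observed outcomes, not from imputation).
#'
#' @param x a `"cohort"`.
#' @param variables character vector of variable names that must be
#'   observed (may be empty).
#' @param time `"T8"` or `"T34"`; the outcome assessment required.
#' @param quiet suppress the exclusion-count message.
#' @return the filtered `"cohort"`; idempotent.
#' @export
complete_case_subset <- function(x, variables = character(), time = "T8",
                                 quiet = FALSE) {
  stopifnot(inherits(x, "cohort"))
  time <- match.arg(time, ASSESSMENT_TIMES)
  unknown <- setdiff(variables, x$variables$name)
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  }
  p <- x$patients
  keep <- !is.na(p$odi_T0)
  ocol <- paste0("odi_", time)
  keep <- keep & if (ocol %in% names(p)) !is.na(p[[ocol]]) else FALSE
  for (nm in variables) {
    keep <- keep & if (nm %in% names(p)) !is.na(p[[nm]]) else FALSE
  }
  removed <- sum(!keep)
  if (!quiet && removed > 0) {
    message("complete_case_subset: removed ", removed, " of ", nrow(p),
            " patients")
  }
  out <- x
  out$patients <- p[keep, , drop = FALSE]
  rownames(out$patients) <- NULL
  out
}

#' Completers at an assessment time
#'
#' Drops patients lost during the program (all derivation analyses use
#' program completers only) and, for `time = "T34"`, those lost between
#' T8 and follow-up.
#'
#' @inheritParams complete_case_subset
#' @return the filtered `"cohort"`.
#' @export
completers <- function(x, time = "T8") {
  stopifnot(inherits(x, "cohort"))
  time <- match.arg(time, ASSESSMENT_TIMES)
  p <- x$patients
  keep <- p$dropout_stage != "lost_in_program"
  if (time == "T34") keep <- keep & p$dropout_stage == "completed_T34"
  out <- x
  out$patients <- p[keep, , drop = FALSE]
  rownames(out$patients) <- NULL
  out
}
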