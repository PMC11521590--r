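#' Construct a cohort object from a data frame
#'
#' Wraps a patient-level data frame in an `sle_cohort` object after checking
#' the column set against the fixed schema. Missing values are represented as
#' `NA`; the missingness mask reported by [missingness_mask()] is derived from
#' them.
#'
#' @param data A data.frame with exactly the columns of the cohort schema
#'   (see [cohort_template()] for names and types).
#' @return An object of class `sle_cohort`.
#' @export
as_sle_cohort <- function(data) {
  cols <- cohort_columns()
  unknown <- setdiff(names(data), cols)
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(cols, names(data))
  if (length(absent)) {
    stop("missing column(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  data <- data[, cols, drop = FALSE]
  data$patient_id <- as.character(data$patient_id)
  rownames(data) <- NULL
  structure(list(data = data), class = "sle_cohort")
}

#' Empty cohort table with the canonical schema
#'
#' @return A zero-row data.frame with the cohort's 42 columns.
#' @export
cohort_template <- function() {
  df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(cohort_columns())),
                    cohort_columns()),
    stringsAsFactors = FALSE
  )
  for (v in c(numeric_variables(), manifestation_variables(),
              "live_birth", "term", "apgar_1min")) {
    df[[v]] <- numeric(0)
  }
  df
}

#' @export
print.sle_cohort <- function(x, ...) {
  n <- nrow(x$data)
  miss <- sum(missingness_mask(x))
  cat(sprintf("sle_cohort: %d patients, %d variables, %d missing cells\n",
              n, ncol(x$data) - 1L, miss))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort An `sle_cohort`.
#' @return Integer patient count.
#' @export
n_patients <- function(cohort) {
  stopifnot(inherits(cohort, "sle_cohort"))
  nrow(cohort$data)
}

#' Patient-level data of a cohort
#' @param cohort An `sle_cohort`.
#' @return The underlying data.frame (one row per patient).
#' @export
cohort_data <- function(cohort) {
  stopifnot(inherits(cohort, "sle_cohort"))
  cohort$data
}

#' Missingness mask of a cohort
#'
#' @param cohort An `sle_cohort`.
#' @return Logical matrix, patients x variables (patient_id excluded),
#'   `TRUE` where a value is missing.
#' @export
missingness_mask <- function(cohort) {
  stopifnot(inherits(cohort, "sle_cohort"))
  m <- is.na(as.matrix(cohort$data[, setdiff(cohort_columns(), "patient_id")]))
  rownames(m) <- cohort$data$patient_id
  m
}

numeric_csv_columns <- function() {
  c(numeric_variables(), manifestation_variables(),
    "live_birth", "term", "apgar_1min")
}

#' Read a cohort table from CSV
#'
#' Reads a patient-per-row CSV with the fixed schema columns. Empty cells
#' denote missing values. Lab labels are normalised case-insensitively to
#' `L/N/H`, delivery types to `CS/FD/ND`, dipstick grades to lower case.
#'
#' @param path Path to a CSV file.
#' @return An `sle_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  unknown <- setdiff(names(raw), cohort_columns())
  if (length(unknown)) {
    stop("unknown column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(cohort_columns(), names(raw))
  if (length(absent)) {
    stop("missing column(s) in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  raw[raw == ""] <- NA

  parse_num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop(sprintf("unparseable numeric cell in column '%s', row %d: '%s'",
                   col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    }
    x
  }
  norm_label <- function(col, levels) {
    x <- toupper(trimws(raw[[col]]))
    bad <- which(!is.na(x) & !(x %in% levels))
    if (length(bad)) {
      stop(sprintf("illegal label in column '%s', row %d: '%s'",
                   col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    }
    x
  }

  df <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  for (v in numeric_csv_columns()) df[[v]] <- parse_num(v)
  grade <- tolower(trimws(raw$urinary_protein_grade))
  bad <- which(!is.na(grade) & !(grade %in% dipstick_grades()))
  if (length(bad)) {
    stop(sprintf("illegal label in column 'urinary_protein_grade', row %d: '%s'",
                 bad[1], raw$urinary_protein_grade[bad[1]]), call. = FALSE)
  }
  df$urinary_protein_grade <- grade
  for (v in lab_variables()) df[[v]] <- norm_label(v, lab_levels())
  df$delivery_type <- norm_label("delivery_type", delivery_levels())
  as_sle_cohort(df)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells, and reading
#' the file back reproduces the cohort exactly (values, labels and mask).
#'
#' @param cohort An `sle_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "sle_cohort"))
  utils::write.csv(cohort$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a cohort against the schema invariants
#'
#' Checks the closed label vocabularies, the Apgar range (0-10), binary
#' indicators, and non-negativity/finiteness of numeric attributes (hard
#' errors), and the obstetric-history consistency rules para <= gravid and
#' live <= gravid (warnings only, since retrospective registries may violate
#' them). The report is ordered deterministically by (row, column).
#'
#' @param cohort An `sle_cohort`.
#' @return A `cohort_validation` object: data.frames `errors` and `warnings`
#'   (columns patient_id, row, column, rule) and a named vector
#'   `missing_counts`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "sle_cohort"))
  df <- cohort$data
  rec <- function(rows, column, rule) {
    if (!length(rows)) return(NULL)
    data.frame(patient_id = df$patient_id[rows], row = rows,
               column = column, rule = rule, stringsAsFactors = FALSE)
  }
  errors <- list()
  warns <- list()

  if (anyDuplicated(df$patient_id)) {
    dup <- which(duplicated(df$patient_id))
    errors[[length(errors) + 1]] <- rec(dup, "patient_id", "duplicate patient_id")
  }
  for (v in lab_variables()) {
    bad <- which(!is.na(df[[v]]) & !(df[[v]] %in% lab_levels()))
    errors[[length(errors) + 1]] <- rec(bad, v, "label not in {L,N,H}")
  }
  bad <- which(!is.na(df$delivery_type) &
                 !(df$delivery_type %in% delivery_levels()))
  errors[[length(errors) + 1]] <- rec(bad, "delivery_type",
                                      "label not in {CS,FD,ND}")
  bad <- which(!is.na(df$urinary_protein_grade) &
                 !(df$urinary_protein_grade %in% dipstick_grades()))
  errors[[length(errors) + 1]] <- rec(bad, "urinary_protein_grade",
                                      "unknown dipstick grade")
  bad <- which(!is.na(df$apgar_1min) &
                 (df$apgar_1min < 0 | df$apgar_1min > 10))
  errors[[length(errors) + 1]] <- rec(bad, "apgar_1min",
                                      "apgar_1min outside [0, 10]")
  for (v in numeric_csv_columns()) {
    bad <- which(!is.na(df[[v]]) & !is.finite(df[[v]]))
    errors[[length(errors) + 1]] <- rec(bad, v, "non-finite numeric value")
  }
  for (v in c("disease_duration_y", "newborn_weight_g", "gestational_age_d",
              "gravid", "para", "abortion", "live")) {
    bad <- which(is.finite(df[[v]]) & df[[v]] < 0)
    errors[[length(errors) + 1]] <- rec(bad, v, "negative value")
  }
  for (v in c(manifestation_variables(), "live_birth", "term")) {
    bad <- which(!is.na(df[[v]]) & !(df[[v]] %in% c(0, 1)))
    errors[[length(errors) + 1]] <- rec(bad, v, "indicator not in {0,1}")
  }
  bad <- which(is.finite(df$para) & is.finite(df$gravid) & df$para > df$gravid)
  warns[[length(warns) + 1]] <- rec(bad, "para", "para > gravid")
  bad <- which(is.finite(df$live) & is.finite(df$gravid) & df$live > df$gravid)
  warns[[length(warns) + 1]] <- rec(bad, "live", "live > gravid")

  bind <- function(lst) {
    lst <- Filter(Negate(is.null), lst)
    if (!length(lst)) {
      return(data.frame(patient_id = character(0), row = integer(0),
                        column = character(0), rule = character(0),
                        stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, lst)
    out <- out[order(out$row, out$column), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  vars <- setdiff(cohort_columns(), "patient_id")
  missing_counts <- vapply(df[vars], function(x) sum(is.na(x)), integer(1))
  structure(list(errors = bind(errors), warnings = bind(warns),
                 missing_counts = missing_counts),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat(sprintf("cohort validation: %d error(s), %d warning(s), %d missing cell(s)\n",
              nrow(x$errors), nrow(x$warnings), sum(x$missing_counts)))
  if (nrow(x$errors)) print(utils::head(x$errors, 10))
  invisible(x)
}
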