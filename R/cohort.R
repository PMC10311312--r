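#' Column schema for a longitudinal visit CSV
#'
#' Describes how the columns of a wide-format visit table map onto the cohort
#' model: one row per patient-visit, with per-patient demographics repeated on
#' every row.  The diagnosis vocabulary is configurable so that cohort-specific
#' subtype labels (for example `"LMCI"`/`"EMCI"`) can be collapsed onto the
#' canonical `CN`/`MCI`/`AD` states.
#'
#' @param patient_id,visit_month,age,diagnosis Column names in the CSV.
#'   `visit_month` (months from baseline) is optional in the file; when the
#'   column is absent, visits are kept in file order within each patient.
#' @param features Character vector of longitudinal feature column names, or
#'   `NULL` to auto-detect every numeric column not otherwise claimed.
#' @param demographics Named character vector mapping the canonical demographic
#'   fields (`gender`, `race`, `ethnicity`, `education`, `apoe4`) to column
#'   names.  Missing columns are tolerated (the cohort then has no
#'   demographics for that field).
#' @param diagnosis_map Named character vector mapping raw diagnosis strings to
#'   canonical states (`"CN"`, `"MCI"`, `"AD"`).  Raw values not in the map
#'   are rejected at load time.
#' @return A `cohort_schema` list.
#' @export
cohort_schema <- function(patient_id = "patient_id",
                          visit_month = "visit_month",
                          age = "age",
                          diagnosis = "diagnosis",
                          features = NULL,
                          demographics = c(gender = "gender", race = "race",
                                           ethnicity = "ethnicity",
                                           education = "education",
                                           apoe4 = "apoe4"),
                          diagnosis_map = c(CN = "CN", MCI = "MCI", AD = "AD",
                                            EMCI = "MCI", LMCI = "MCI")) {
  if (!all(diagnosis_map %in% c("CN", "MCI", "AD"))) {
    stop("`diagnosis_map` values must be CN, MCI or AD", call. = FALSE)
  }
  structure(list(patient_id = patient_id, visit_month = visit_month,
                 age = age, diagnosis = diagnosis, features = features,
                 demographics = demographics, diagnosis_map = diagnosis_map),
            class = "cohort_schema")
}

DEMOGRAPHIC_FIELDS <- c("gender", "race", "ethnicity", "education", "apoe4")

new_cohort <- function(visits, demographics, feature_names) {
  stopifnot(is.data.frame(visits), is.data.frame(demographics),
            is.character(feature_names))
  structure(list(visits = visits, demographics = demographics,
                 feature_names = feature_names),
            class = "mci_cohort")
}

#' Validate the internal consistency of a cohort
#'
#' Checks that every feature column exists, visit indices are unique and
#' consecutive within patient, diagnoses are canonical, and demographics cover
#' exactly the patients present in the visit table.
#'
#' @param cohort An `mci_cohort`.
#' @return The cohort, invisibly; errors describe the first violated invariant.
#' @export
validate_cohort <- function(cohort) {
  v <- cohort$visits
  needed <- c("patient_id", "visit_index", "age", "diagnosis", cohort$feature_names)
  miss <- setdiff(needed, names(v))
  if (length(miss)) {
    stop("cohort visits table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(v[c("patient_id", "visit_index")])) {
    stop("duplicate (patient_id, visit_index) rows", call. = FALSE)
  }
  bad <- !v$diagnosis %in% c("CN", "MCI", "AD")
  if (any(bad)) {
    stop("non-canonical diagnosis values: ",
         paste(unique(v$diagnosis[bad]), collapse = ", "), call. = FALSE)
  }
  if (!setequal(unique(v$patient_id), cohort$demographics$patient_id)) {
    stop("demographics and visits cover different patient sets", call. = FALSE)
  }
  invisible(cohort)
}

#' Number of patients in a cohort
#' @param cohort An `mci_cohort`.
#' @return Integer patient count.
#' @export
n_patients <- function(cohort) length(unique(cohort$visits$patient_id))

#' @export
print.mci_cohort <- function(x, ...) {
  v <- x$visits
  cat(sprintf("<mci_cohort> %d patients, %d visits, %d longitudinal features\n",
              n_patients(x), nrow(v), length(x$feature_names)))
  if (nrow(v)) {
    tab <- table(v$diagnosis)
    cat("  visit diagnoses:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    fm <- vapply(x$feature_names,
                 function(f) mean(is.na(v[[f]])), numeric(1))
    cat(sprintf("  missing feature cells: %.1f%%\n", 100 * mean(fm)))
  }
  invisible(x)
}

#' Load a longitudinal cohort from a wide-format visit CSV
#'
#' Reads one row per patient-visit, groups rows by patient, orders visits by
#' the visit-month column when present (file order otherwise), assigns a
#' 1-based `visit_index` per patient, and extracts per-patient demographics
#' from the first row of each patient.  Empty cells and `"NA"` both parse as
#' missing values; missing feature cells are preserved as `NA`, never zero.
#'
#' @param path CSV file path.
#' @param schema A [cohort_schema()] describing the columns.
#' @return An `mci_cohort`: list with `visits` (data.frame of
#'   `patient_id`, `visit_index`, `visit_month`, `age`, `diagnosis` and one
#'   column per feature), `demographics` (one row per patient) and
#'   `feature_names`.
#' @export
load_cohort <- function(path, schema = cohort_schema()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  for (col in c("patient_id", "diagnosis", "age")) {
    if (!schema[[col]] %in% names(raw)) {
      stop(sprintf("schema error: required column '%s' not found", schema[[col]]),
           call. = FALSE)
    }
  }
  pid <- as.character(raw[[schema$patient_id]])
  dx_raw <- as.character(raw[[schema$diagnosis]])
  unknown <- stats::na.omit(setdiff(unique(dx_raw), names(schema$diagnosis_map)))
  if (length(unknown)) {
    stop("integrity error: diagnosis value(s) not in schema diagnosis_map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dx <- unname(schema$diagnosis_map[dx_raw])

  has_month <- schema$visit_month %in% names(raw)
  month <- if (has_month) as.numeric(raw[[schema$visit_month]]) else NA_real_
  if (has_month && anyDuplicated(data.frame(pid, month))) {
    stop("integrity error: duplicate (patient, visit_month) rows", call. = FALSE)
  }

  demo_cols <- schema$demographics[schema$demographics %in% names(raw)]
  feat_names <- schema$features
  if (is.null(feat_names)) {
    claimed <- c(schema$patient_id, schema$visit_month, schema$age,
                 schema$diagnosis, demo_cols)
    feat_names <- setdiff(names(raw)[vapply(raw, is.numeric, logical(1))], claimed)
  } else {
    miss <- setdiff(feat_names, names(raw))
    if (length(miss)) {
      stop("schema error: feature column(s) not found: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }

  # order by patient (first appearance), then visit month / file order
  ord_pid <- factor(pid, levels = unique(pid))
  ord <- if (has_month) order(ord_pid, month) else order(ord_pid)
  visits <- data.frame(patient_id = pid[ord],
                       visit_index = stats::ave(seq_along(ord), pid[ord],
                                                FUN = seq_along),
                       visit_month = if (has_month) month[ord] else NA_real_,
                       age = as.numeric(raw[[schema$age]])[ord],
                       diagnosis = dx[ord],
                       stringsAsFactors = FALSE)
  for (f in feat_names) visits[[f]] <- as.numeric(raw[[f]])[ord]

  first <- !duplicated(visits$patient_id)
  demographics <- data.frame(patient_id = visits$patient_id[first],
                             stringsAsFactors = FALSE)
  for (field in names(demo_cols)) {
    demographics[[field]] <- raw[[demo_cols[[field]]]][ord][first]
  }
  rownames(visits) <- rownames(demographics) <- NULL
  validate_cohort(new_cohort(visits, demographics, feat_names))
}

#' Write a cohort back to a wide-format visit CSV
#'
#' Inverse of [load_cohort()]: one row per visit with the patient's
#' demographics repeated on every row, and missing values serialised as empty
#' cells.  `load_cohort(write_cohort(cohort, path))` reproduces the cohort up
#' to column order and floating-point text round-trip.
#'
#' @param cohort An `mci_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  v <- cohort$visits
  out <- v[c("patient_id", "visit_month", "age", "diagnosis", cohort$feature_names)]
  demo_fields <- setdiff(names(cohort$demographics), "patient_id")
  if (nrow(v)) {
    idx <- match(v$patient_id, cohort$demographics$patient_id)
    for (field in demo_fields) out[[field]] <- cohort$demographics[[field]][idx]
  } else {
    for (field in demo_fields) out[[field]] <- cohort$demographics[[field]][0]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
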