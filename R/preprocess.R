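#' @title ESAS preprocessing: from raw assessments to a modeling dataset
#' @name preprocess
#' @description
#' The preprocessing pipeline turns an assessment-level table of nine ESAS
#' item scores into a per-patient longitudinal series of Box-Cox transformed
#' total symptom distress scores (TSDS) with time measured in months since
#' diagnosis, applying the assessment- and patient-level inclusion rules:
#' imputation of the TSDS when at most half the items are missing, exclusion
#' of assessments with more than half missing, resolution of same-day
#' duplicate assessments in favour of the higher TSDS, and exclusion of
#' patients with fewer than three surviving assessments, all-zero item
#' scores, or a missing income quintile.
NULL

# Days per month used for the months-since-diagnosis time axis (365.25/12).
MONTH_DAYS <- 30.4375

#' Names of the nine ESAS symptom items
#'
#' Pain, tiredness, drowsiness, nausea, lack of appetite, shortness of
#' breath, depression, anxiety, and wellbeing, each self-scored 0-10
#' (0 = absent / best, 10 = worst).  Wellbeing is summed as scored, without
#' reversal.
#'
#' @return character vector of nine column names.
#' @export
esas_items <- function() {
  c("pain", "tiredness", "drowsiness", "nausea", "appetite",
    "dyspnea", "depression", "anxiety", "wellbeing")
}

# Validate the nine item columns of an assessment table: integer 0-10 or NA.
check_item_scores <- function(assessments) {
  items <- esas_items()
  missing_cols <- setdiff(items, names(assessments))
  if (length(missing_cols)) {
    stop("assessment table lacks item columns: ",
         paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(assessments[items])
  bad <- !is.na(m) & (m < 0 | m > 10 | m != round(m))
  if (any(bad)) {
    stop("item scores must be integers in 0-10 or NA; ",
         sum(bad), " offending value(s), first: ", m[which(bad)[1]])
  }
  invisible(m)
}

#' Compute the total symptom distress score for each assessment
#'
#' The TSDS is the sum of the nine ESAS item scores (0-90).  Assessments
#' with 1-4 missing items (at most 50%) are imputed as the mean of the
#' present scores times nine, which keeps the imputed score on the 0-90
#' summative scale; assessments with five or more missing items (more than
#' 50%) are marked excluded.
#'
#' @param assessments data frame with at least `patient_id`, `date`, and the
#'   nine columns named by [esas_items()], scores integer 0-10 or `NA`.
#' @return the input with two added columns: `tsds_raw` (numeric, `NA` when
#'   excluded) and `tsds_excluded` (logical).
#' @export
compute_tsds <- function(assessments) {
  m <- check_item_scores(assessments)
  n_miss <- rowSums(is.na(m))
  excluded <- n_miss > ncol(m) / 2
  tsds <- ifelse(n_miss == 0,
                 rowSums(m),
                 rowMeans(m, na.rm = TRUE) * ncol(m))
  tsds[excluded] <- NA_real_
  assessments$tsds_raw <- tsds
  assessments$tsds_excluded <- excluded
  assessments
}

#' Resolve same-day duplicate assessments
#'
#' When a patient has two or more assessments on the same calendar day, the
#' one with the higher raw (possibly imputed) TSDS is kept.  Ties keep the
#' first record in input order, which is deterministic and leaves the
#' downstream TSDS series unchanged relative to any other tie choice.
#' Assessments already marked excluded are dropped first.
#'
#' @param assessments output of [compute_tsds()].
#' @return assessment table with at most one row per patient-day.
#' @export
dedupe_same_day <- function(assessments) {
  if (is.null(assessments$tsds_raw)) {
    stop("run compute_tsds() before dedupe_same_day()")
  }
  a <- assessments[!assessments$tsds_excluded, , drop = FALSE]
  if (!nrow(a)) return(a)
  key <- paste(a$patient_id, a$date, sep = "\r")
  # stable within-key order => which.max keeps the first of tied maxima
  keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(idx) {
    idx[which.max(a$tsds_raw[idx])]
  }), use.names = FALSE)
  a[sort(keep), , drop = FALSE]
}

#' Apply patient-level exclusion rules
#'
#' Removes, in order: (a) patients with fewer than three surviving
#' assessments, (b) patients whose every recorded item score on every
#' assessment is zero (treated as data error), and (c) patients with a
#' missing neighbourhood income quintile.  A patient is logged under the
#' first rule that removes them.
#'
#' @param assessments assessment table after [compute_tsds()] and
#'   [dedupe_same_day()].
#' @param patients patient-level table with `patient_id` and
#'   `income_quintile` (plus any other baseline covariates).
#' @return list with `assessments` and `patients` restricted to retained
#'   patients, and `exclusion_log`, a data frame of `patient_id` and
#'   `reason` in `c("under_3", "all_zero", "missing_income")`.
#' @export
apply_patient_filters <- function(assessments, patients) {
  items <- esas_items()
  log_id <- character(0)
  log_reason <- character(0)

  n_per <- table(assessments$patient_id)
  under3 <- names(n_per)[n_per < 3]
  # patients present in the patient table but with 0 surviving assessments
  under3 <- union(under3,
                  setdiff(as.character(patients$patient_id),
                          as.character(assessments$patient_id)))
  log_id <- c(log_id, under3)
  log_reason <- c(log_reason, rep("under_3", length(under3)))
  assessments <- assessments[!assessments$patient_id %in% under3, , drop = FALSE]

  m <- as.matrix(assessments[items])
  allzero_row <- rowSums(m != 0, na.rm = TRUE) == 0
  by_patient <- tapply(allzero_row, assessments$patient_id, all)
  allzero <- names(by_patient)[by_patient]
  log_id <- c(log_id, allzero)
  log_reason <- c(log_reason, rep("all_zero", length(allzero)))
  assessments <- assessments[!assessments$patient_id %in% allzero, , drop = FALSE]

  keep_ids <- as.character(patients$patient_id)
  no_income <- keep_ids[is.na(patients$income_quintile) &
                          keep_ids %in% assessments$patient_id]
  log_id <- c(log_id, no_income)
  log_reason <- c(log_reason, rep("missing_income", length(no_income)))
  assessments <- assessments[!assessments$patient_id %in% no_income, , drop = FALSE]

  patients <- patients[patients$patient_id %in% assessments$patient_id, , drop = FALSE]
  list(assessments = assessments,
       patients = patients,
       exclusion_log = data.frame(patient_id = log_id, reason = log_reason,
                                  stringsAsFactors = FALSE))
}

#' Flag services received in the week before each assessment
#'
#' A time-varying covariate flag is true when the corresponding service
#' (chemotherapy, radiotherapy, home care, palliative care) occurred 0-7
#' days before the assessment, read as the closed interval
#' `[date - 7, date]` so that a service on the assessment day itself counts.
#'
#' @param assessments assessment table with `patient_id` and `date`.
#' @param services data frame with `patient_id`, `service`, `date`; service
#'   names must be among [service_types()].
#' @param window_days lookback length in days (default 7).
#' @return logical matrix, one row per assessment, one column per service
#'   type.
#' @export
service_window_flags <- function(assessments, services, window_days = 7) {
  types <- service_types()
  flags <- matrix(FALSE, nrow(assessments), length(types),
                  dimnames = list(NULL, types))
  if (is.null(services) || !nrow(services)) return(flags)
  bad <- setdiff(unique(services$service), types)
  if (length(bad)) stop("unknown service type(s): ", paste(bad, collapse = ", "))
  sv <- split(services, services$patient_id)
  for (i in seq_len(nrow(assessments))) {
    s <- sv[[as.character(assessments$patient_id[i])]]
    if (is.null(s)) next
    d <- as.numeric(assessments$date[i] - s$date)
    hit <- d >= 0 & d <= window_days
    if (any(hit)) flags[i, unique(s$service[hit])] <- TRUE
  }
  flags
}

#' Time-varying covariate names
#'
#' @return character vector of the four treatment/supportive-care flags.
#' @export
service_types <- function() {
  c("chemotherapy", "radiotherapy", "home_care", "palliative_care")
}

#' Build the longitudinal modeling dataset
#'
#' Converts filtered assessments into the per-patient series consumed by
#' [fit_gbtm()]: time in months since diagnosis (days / 30.4375), the raw
#' and Box-Cox transformed TSDS, and the four binary time-varying service
#' flags.  Only each patient's first `max_assessments` assessments (by date)
#' are retained.
#'
#' @param assessments assessment table after the assessment- and
#'   patient-level filters, with `tsds_raw` computed.
#' @param patients patient-level table with `patient_id`, `diagnosis_date`
#'   and baseline covariates.
#' @param services optional service-event table for [service_window_flags()].
#'   If `NULL` and the assessment table already carries the four flag
#'   columns they are used as-is; otherwise the flags are all zero.
#' @param max_assessments per-patient cap on the number of assessments
#'   (default 30, earliest first).
#' @return an object of class `symtraj_data`: a list with `obs` (one row per
#'   retained assessment: `patient_id`, `months`, `tsds_raw`,
#'   `tsds_transformed`, four 0/1 flag columns) and `patients` (baseline
#'   table of retained patients).
#' @export
build_longitudinal_dataset <- function(assessments, patients, services = NULL,
                                       max_assessments = 30) {
  if (is.null(assessments$tsds_raw)) {
    stop("run compute_tsds() before build_longitudinal_dataset()")
  }
  diag_date <- patients$diagnosis_date[match(assessments$patient_id,
                                             patients$patient_id)]
  if (anyNA(diag_date)) {
    stop("assessments present for patients missing from the patient table")
  }
  days <- as.numeric(assessments$date - diag_date)
  if (any(days < 0)) {
    stop(sum(days < 0), " assessment(s) dated before diagnosis")
  }

  types <- service_types()
  if (!is.null(services)) {
    flags <- service_window_flags(assessments, services)
  } else if (all(types %in% names(assessments))) {
    flags <- as.matrix(assessments[types]) > 0
  } else {
    flags <- matrix(FALSE, nrow(assessments), length(types),
                    dimnames = list(NULL, types))
  }

  obs <- data.frame(patient_id = assessments$patient_id,
                    months = days / MONTH_DAYS,
                    tsds_raw = assessments$tsds_raw,
                    stringsAsFactors = FALSE)
  obs$tsds_transformed <- tsds_transform(obs$tsds_raw)
  obs <- cbind(obs, as.data.frame(flags + 0L))

  ord <- order(obs$patient_id, obs$months)
  obs <- obs[ord, , drop = FALSE]
  seq_in_patient <- stats::ave(obs$months, obs$patient_id,
                               FUN = seq_along)
  obs <- obs[seq_in_patient <= max_assessments, , drop = FALSE]
  rownames(obs) <- NULL

  structure(list(obs = obs,
                 patients = patients[patients$patient_id %in% obs$patient_id,
                                     , drop = FALSE]),
            class = "symtraj_data")
}

#' @export
print.symtraj_data <- function(x, ...) {
  cat("Longitudinal symptom-burden dataset\n")
  cat("  patients:    ", nrow(x$patients), "\n")
  cat("  assessments: ", nrow(x$obs), "\n")
  cat("  time range:  ", sprintf("%.2f", min(x$obs$months)), "-",
      sprintf("%.2f", max(x$obs$months)), "months since diagnosis\n")
  invisible(x)
}

#' Run the full preprocessing pipeline
#'
#' Convenience wrapper: [compute_tsds()], [dedupe_same_day()],
#' [apply_patient_filters()], [build_longitudinal_dataset()].
#'
#' @inheritParams build_longitudinal_dataset
#' @param assessments raw assessment table (nine item columns).
#' @return list with the `symtraj_data` object (`data`) and the
#'   patient-level `exclusion_log`.
#' @export
preprocess_cohort <- function(assessments, patients, services = NULL,
                              max_assessments = 30) {
  a <- dedupe_same_day(compute_tsds(assessments))
  f <- apply_patient_filters(a, patients)
  list(data = build_longitudinal_dataset(f$assessments, f$patients, services,
                                         max_assessments),
       exclusion_log = f$exclusion_log)
}
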