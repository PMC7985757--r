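#' Write and read the modeling dataset as delimited text
#'
#' The longitudinal dataset is persisted as two tab-separated files,
#' `modeling_obs.tsv` (one row per assessment) and `modeling_patients.tsv`
#' (one row per patient), so fits can be run from the command line or
#' another session.
#'
#' @param data a `symtraj_data`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_modeling_data <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data$obs, file.path(dir, "modeling_obs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data$patients, file.path(dir, "modeling_patients.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_modeling_data
#' @export
read_modeling_data <- function(dir) {
  obs <- utils::read.delim(file.path(dir, "modeling_obs.tsv"),
                           stringsAsFactors = FALSE)
  patients <- utils::read.delim(file.path(dir, "modeling_patients.tsv"),
                                stringsAsFactors = FALSE)
  obs$patient_id <- as.character(obs$patient_id)
  patients$patient_id <- as.character(patients$patient_id)
  structure(list(obs = obs, patients = patients), class = "symtraj_data")
}

#' Serialize a fit summary to delimited text
#'
#' Writes the coefficient table, group probabilities, fit statistics and
#' adequacy diagnostics of a fitted model as tab-separated text files under
#' `dir`.
#'
#' @param fit a `gbtm_fit`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_fit_summary <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(coef_table(fit), file.path(dir, "coefficients.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  stats_df <- data.frame(
    statistic = c("loglik", "bic", "n_patients", "n_obs", "n_params",
                  "sigma", paste0("pi_", seq_along(fit$pi))),
    value = c(fit$loglik, bic_score(fit), fit$n_patients, fit$n_obs,
              fit$n_params, fit$params$sigma, fit$pi))
  utils::write.table(stats_df, file.path(dir, "fit_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(adequacy_diagnostics(fit)),
                     file.path(dir, "adequacy.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
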