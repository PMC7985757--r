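# Shared fixtures built in code.

# Wrap a bare observation table into the modeling-dataset container.
make_dataset <- function(patient_id, months, y, flags = NULL) {
  obs <- data.frame(patient_id = patient_id, months = months,
                    tsds_raw = tsds_inverse(y), tsds_transformed = y,
                    stringsAsFactors = FALSE)
  for (tv in service_types()) {
    obs[[tv]] <- if (is.null(flags)) 0L else flags[[tv]]
  }
  structure(list(obs = obs,
                 patients = data.frame(patient_id = unique(patient_id))),
            class = "symtraj_data")
}

# An assessment table row with given item scores (recycled to nine).
make_assessment <- function(patient_id, date, scores) {
  scores <- rep_len(scores, 9)
  df <- data.frame(patient_id = patient_id, date = as.Date(date))
  df[esas_items()] <- as.list(scores)
  df
}

# Simulation config for a flat well-separated design with no artifacts.
flat_config <- function(n_patients, means, probs, sd = 0.5,
                        n_obs = 10, seed = 1,
                        death = rep(0, length(means)),
                        followup = 100) {
  J <- length(means)
  coefs <- cbind(means, 0, 0, 0, 0)
  cm <- list(probs = matrix(0, J, 4, dimnames = list(NULL, service_types())),
             effects = matrix(0, J, 4, dimnames = list(NULL, service_types())))
  simulation_config(n_patients = n_patients, group_probs = probs,
                    group_coefficients = coefs, residual_sd = sd,
                    assessments_per_patient = list(mean = n_obs, max = n_obs),
                    covariate_model = cm, item_missing_rate = 0,
                    dup_rate = 0, frac_under3 = 0, frac_allzero = 0,
                    frac_missing_income = 0, death_model = death,
                    followup_months = followup, seed = seed)
}

# Generate + preprocess a clean cohort from a config.
clean_dataset <- function(cfg) {
  co <- generate_cohort(cfg)
  preprocess_cohort(co$assessments, co$patients, co$services)$data
}

# Independent brute-force mixture log-likelihood: enumerates the J mixture
# terms per patient directly, no shared code with cnorm_loglik.
brute_force_loglik <- function(y_by_patient, t_by_patient, pi, beta, sigma,
                               time_scale = 10) {
  total <- 0
  for (i in seq_along(y_by_patient)) {
    y <- y_by_patient[[i]]
    u <- t_by_patient[[i]] / time_scale
    terms <- vapply(seq_along(pi), function(j) {
      mu <- vapply(u, function(ui)
        sum(beta[[j]] * ui^(seq_along(beta[[j]]) - 1)), numeric(1))
      pi[j] * prod(stats::dnorm(y, mu, sigma))
    }, numeric(1))
    total <- total + log(sum(terms))
  }
  total
}
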