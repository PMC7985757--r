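#' Configuration for the synthetic symptom-burden cohort
#'
#' Builds and validates the parameter set for [generate_cohort()].  The
#' defaults emulate a population cohort of metastatic breast cancer
#' patients assessed with the ESAS at ambulatory visits: six latent
#' trajectory groups (three changing quartic groups with lower symptom
#' burden, three flat groups with higher burden), roughly a thousand
#' patients averaging sixteen assessments each, diagnosis dates spread
#' over five calendar years with administrative censoring at the end of
#' the sixth, group-dependent monthly death hazards, and the data
#' pathologies the preprocessing rules target (missing items, same-day
#' duplicates, patients with under three assessments, all-zero patients,
#' missing income quintile).
#'
#' @param n_patients number of patients.
#' @param group_probs probability vector over the J latent groups; must sum
#'   to 1.
#' @param group_coefficients J x 5 matrix (or list of length-5 vectors) of
#'   polynomial coefficients (intercept, linear, ..., quartic) for the mean
#'   transformed TSDS; the polynomial is evaluated in scaled time
#'   `months / 10`, the same axis [fit_gbtm()] reports on.
#' @param residual_sd within-group residual SD on the transformed scale.
#' @param assessments_per_patient list with `mean` and `max`: visit counts
#'   are drawn as `3 + Poisson(mean - 3)` capped at `max`, before any
#'   truncation by death or censoring.
#' @param visit_spacing mean months between successive visits; gaps are
#'   exponential, rounded to 0.25-month resolution with a 0.25 floor, and
#'   the first visit falls on the diagnosis date.
#' @param covariate_model list with `probs` and `effects`, each a J x 4
#'   matrix (columns [service_types()]): per-visit Bernoulli probability of
#'   each service flag, and its additive effect on the group mean
#'   (transformed-scale units).
#' @param item_missing_rate per-item probability of a missing score
#'   (applied by [inject_artifacts()]).
#' @param dup_rate per-assessment probability of a same-day duplicate.
#' @param frac_under3 fraction of patients truncated to fewer than three
#'   assessments.
#' @param frac_allzero fraction of patients whose item scores are all set
#'   to zero.
#' @param frac_missing_income fraction of patients with a missing income
#'   quintile.
#' @param death_model per-group constant monthly hazard of death.
#' @param followup_months administrative censoring horizon in months after
#'   the earliest diagnosis date.
#' @param seed integer seed for the single random stream all generation
#'   steps consume.
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(n_patients = 995,
                              group_probs = c(0.115, 0.099, 0.121,
                                              0.246, 0.265, 0.154),
                              group_coefficients = default_group_coefficients(),
                              residual_sd = 1.0,
                              assessments_per_patient = list(mean = 16, max = 40),
                              visit_spacing = 1.5,
                              covariate_model = default_covariate_model(
                                if (is.matrix(group_coefficients))
                                  nrow(group_coefficients)
                                else length(group_coefficients)),
                              item_missing_rate = 0.01,
                              dup_rate = 0.037,
                              frac_under3 = 0.20,
                              frac_allzero = 0.005,
                              frac_missing_income = 0.003,
                              death_model = c(0.012, 0.005, 0.005,
                                              0.015, 0.018, 0.022),
                              followup_months = 72,
                              seed = 1L) {
  if (is.list(group_coefficients) && !is.matrix(group_coefficients)) {
    group_coefficients <- do.call(rbind, group_coefficients)
  }
  group_probs <- group_probs / 1  # keep as given; validated below
  cfg <- list(n_patients = n_patients,
              group_probs = group_probs,
              group_coefficients = group_coefficients,
              residual_sd = residual_sd,
              assessments_per_patient = assessments_per_patient,
              visit_spacing = visit_spacing,
              covariate_model = covariate_model,
              item_missing_rate = item_missing_rate,
              dup_rate = dup_rate,
              frac_under3 = frac_under3,
              frac_allzero = frac_allzero,
              frac_missing_income = frac_missing_income,
              death_model = death_model,
              followup_months = followup_months,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default per-group trajectory coefficients
#'
#' Three quartic groups with lower, changing symptom burden and three flat
#' groups with higher, sustained burden, on the transformed TSDS scale
#' (0 to about 8.35) with scaled time `months / 10`.
#'
#' @return 6 x 5 coefficient matrix.
#' @export
default_group_coefficients <- function() {
  rbind(c(3.2, -1.50,  0.45, -0.055,  0.0020),   # low, improving
        c(2.2,  1.10, -0.35,  0.045, -0.0018),   # low, rising then easing
        c(4.5, -1.80,  0.55, -0.065,  0.0025),   # moderate, most improvement
        c(5.2,  0, 0, 0, 0),                     # high, flat
        c(6.0,  0, 0, 0, 0),                     # higher, flat
        c(6.8,  0, 0, 0, 0))                     # highest, flat
}

#' Default time-varying covariate model
#'
#' Per-visit service probabilities shared across groups and additive mean
#' effects on the transformed scale, in the order [service_types()].
#'
#' @param J number of groups.
#' @return list with `probs` and `effects`, each a `J x 4` matrix.
#' @export
default_covariate_model <- function(J) {
  probs <- matrix(rep(c(0.35, 0.10, 0.25, 0.30), each = J), J, 4,
                  dimnames = list(NULL, service_types()))
  effects <- matrix(rep(c(-0.10, 0.35, 0.15, 0.25), each = J), J, 4,
                    dimnames = list(NULL, service_types()))
  list(probs = probs, effects = effects)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid simulation config field '", field, "': ", msg,
                  call. = FALSE)
  }
  chk(is.numeric(cfg$n_patients) && cfg$n_patients >= 1, "n_patients",
      "must be a positive count")
  p <- cfg$group_probs
  chk(all(p >= 0), "group_probs", "entries must be non-negative")
  chk(abs(sum(p) - 1) <= 1e-12, "group_probs", "must sum to 1 within 1e-12")
  J <- length(p)
  chk(is.matrix(cfg$group_coefficients) &&
        nrow(cfg$group_coefficients) == J &&
        ncol(cfg$group_coefficients) == 5,
      "group_coefficients", "must be a J x 5 matrix (intercept..quartic)")
  chk(cfg$residual_sd >= 0, "residual_sd", "must be >= 0")
  app <- cfg$assessments_per_patient
  chk(is.list(app) && app$mean >= 3 && app$max >= app$mean,
      "assessments_per_patient", "needs mean >= 3 and max >= mean")
  chk(cfg$visit_spacing > 0, "visit_spacing", "must be > 0")
  cm <- cfg$covariate_model
  chk(is.list(cm) && all(dim(cm$probs) == c(J, 4)) &&
        all(dim(cm$effects) == c(J, 4)),
      "covariate_model", "probs and effects must be J x 4 matrices")
  chk(all(cm$probs >= 0 & cm$probs <= 1), "covariate_model",
      "probs must lie in [0,1]")
  for (f in c("item_missing_rate", "dup_rate", "frac_under3", "frac_allzero",
              "frac_missing_income")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must lie in [0,1]")
  }
  chk(length(cfg$death_model) == J && all(cfg$death_model >= 0),
      "death_model", "must be J non-negative monthly hazards")
  chk(cfg$followup_months > 0, "followup_months", "must be > 0")
  invisible(cfg)
}

# Split an integer TSDS target (0-90) across nine items capped at 10 each.
# Multinomial split, then overflow above 10 is reallocated to items with
# remaining capacity.  Only the sum is meaningful downstream.
allocate_items <- function(target) {
  stopifnot(target >= 0, target <= 90)
  if (target == 0) return(integer(9))
  x <- as.integer(stats::rmultinom(1, target, rep(1 / 9, 9)))
  while (any(x > 10)) {
    excess <- sum(x[x > 10] - 10L)
    x[x > 10] <- 10L
    room <- which(x < 10)
    add <- room[sample.int(length(room), min(excess, length(room)))]
    x[add] <- x[add] + 1L
    # loop handles excess > number of items with room
    if (excess > length(room)) next else break
  }
  while (sum(x) < target) {           # top up any residual shortfall
    room <- which(x < 10)
    i <- room[sample.int(length(room), 1)]
    x[i] <- x[i] + 1L
  }
  x
}

#' Generate a synthetic cohort of ESAS assessments
#'
#' Draws each patient's latent trajectory group, visit schedule, death or
#' censoring time, per-visit service flags and transformed TSDS (group
#' polynomial plus covariate effects plus normal noise), then back-transforms
#' to an integer 0-90 raw score and splits it across the nine items.  The
#' output is clean: artifact injection (missing items, duplicates, under-3
#' and all-zero patients) is a separate step, [inject_artifacts()].
#'
#' @param config a [simulation_config()].
#' @param seed optional override of `config$seed`.
#' @return list of four data frames: `assessments` (patient_id, date, nine
#'   item columns, the `latent` transformed trajectory value each score was
#'   generated from, and an `artifact` provenance column, empty here),
#'   `patients`
#'   (diagnosis/death dates, baseline covariates, ED counts, observation
#'   months), `services` (patient_id, service, date events backing the
#'   0-7-day flags), and `truth` (patient_id, true_group, death_month).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  J <- length(config$group_probs)
  n <- as.integer(config$n_patients)
  study_start <- as.Date("2010-01-01")
  study_end <- study_start + round(config$followup_months * MONTH_DAYS)

  ids <- sprintf("P%04d", seq_len(n))
  grp <- sample.int(J, n, replace = TRUE, prob = config$group_probs)
  diagnosis <- study_start + sample.int(
    max(1L, as.integer(round((config$followup_months - 12) * MONTH_DAYS))),
    n, replace = TRUE) - 1L
  horizon <- as.numeric(study_end - diagnosis) / MONTH_DAYS

  hz <- config$death_model[grp]
  death_month <- ifelse(hz > 0, stats::rexp(n, rate = pmax(hz, 1e-12)), Inf)
  death_month[death_month > horizon] <- Inf
  end_month <- pmin(death_month, horizon)

  n_target <- pmin(3 + stats::rpois(n, config$assessments_per_patient$mean - 3),
                   config$assessments_per_patient$max)

  rows <- vector("list", n)
  svc_rows <- vector("list", n)
  types <- service_types()
  tmax <- tsds_transformed_max()
  for (i in seq_len(n)) {
    gaps <- pmax(0.25, round(stats::rexp(n_target[i] - 1,
                                         1 / config$visit_spacing) * 4) / 4)
    tt <- cumsum(c(0, gaps))
    tt <- tt[tt <= end_month[i]]
    if (!length(tt)) tt <- 0
    k <- length(tt)
    u <- tt / 10
    Xp <- cbind(1, u, u^2, u^3, u^4)
    w <- matrix(stats::runif(k * 4) <
                  rep(config$covariate_model$probs[grp[i], ], each = k), k, 4)
    mu <- drop(Xp %*% config$group_coefficients[grp[i], ]) +
      drop(w %*% config$covariate_model$effects[grp[i], ])
    y <- mu + stats::rnorm(k, 0, config$residual_sd)
    y <- pmin(pmax(y, 0), tmax)
    raw <- pmin(pmax(round(tsds_inverse(y)), 0), 90)
    items <- t(vapply(raw, allocate_items, integer(9)))
    colnames(items) <- esas_items()
    dates <- diagnosis[i] + round(tt * MONTH_DAYS)
    rows[[i]] <- data.frame(patient_id = ids[i], date = dates,
                            items, latent = y, artifact = "",
                            stringsAsFactors = FALSE)
    on <- which(w, arr.ind = TRUE)
    if (nrow(on)) {
      svc_rows[[i]] <- data.frame(
        patient_id = ids[i],
        service = types[on[, 2]],
        date = dates[on[, 1]] - sample.int(8, nrow(on), replace = TRUE) + 1L,
        stringsAsFactors = FALSE)
    }
  }
  assessments <- do.call(rbind, rows)
  rownames(assessments) <- NULL
  services <- do.call(rbind, svc_rows)
  rownames(services) <- NULL

  age_levels <- c("18-39", "40-49", "50-59", "60-69", "70-79", "80-99")
  age_probs <- c(0.071, 0.173, 0.255, 0.242, 0.171, 0.087)
  income <- sample.int(5, n, replace = TRUE)
  income[sample.int(n, round(config$frac_missing_income * n))] <- NA
  death_date <- as.Date(ifelse(is.finite(death_month),
                               diagnosis + round(death_month * MONTH_DAYS),
                               NA), origin = "1970-01-01")
  obs_months <- end_month
  patients <- data.frame(
    patient_id = ids,
    diagnosis_date = diagnosis,
    death_date = death_date,
    age_group = sample(age_levels, n, replace = TRUE, prob = age_probs),
    income_quintile = income,
    rurality = sample(c("urban", "rural"), n, replace = TRUE,
                      prob = c(0.884, 0.116)),
    diagnosis_year = as.integer(format(diagnosis, "%Y")),
    charlson = sample(c("0", "1-3"), n, replace = TRUE, prob = c(0.954, 0.046)),
    ed_visits = stats::rpois(n, 0.12 * obs_months),
    observation_months = obs_months,
    stringsAsFactors = FALSE)

  truth <- data.frame(patient_id = ids, true_group = grp,
                      death_month = ifelse(is.finite(death_month),
                                           death_month, NA),
                      stringsAsFactors = FALSE)
  list(assessments = assessments, patients = patients,
       services = services, truth = truth)
}

#' Inject data pathologies into a clean assessment table
#'
#' Applies, in order: truncation of a configured fraction of patients to
#' fewer than three assessments, all-zero item scores for a configured
#' fraction, same-day duplicate assessments (the duplicate has item scores
#' binomially thinned from the original, so its TSDS never exceeds the
#' original's), and item-level missingness.  Every touched row is tagged in
#' the `artifact` provenance column so filter behaviour can be audited.
#'
#' @param assessments assessment table from [generate_cohort()].
#' @param config the same [simulation_config()].
#' @param seed optional override; defaults to a fixed offset of
#'   `config$seed` so generation and injection use distinct streams.
#' @return the modified assessment table.
#' @export
inject_artifacts <- function(assessments, config,
                             seed = config$seed + 500009L) {
  validate_sim_config(config)
  set.seed(seed)
  items <- esas_items()
  a <- assessments
  tag <- function(old, t) ifelse(old == "", t, paste(old, t, sep = ";"))
  ids <- unique(a$patient_id)

  n_u3 <- round(config$frac_under3 * length(ids))
  if (n_u3 > 0) {
    u3 <- sample(ids, n_u3)
    keep_n <- sample(1:2, n_u3, replace = TRUE)
    drop <- logical(nrow(a))
    for (k in seq_along(u3)) {
      idx <- which(a$patient_id == u3[k])
      idx <- idx[order(a$date[idx])]
      if (length(idx) > keep_n[k]) drop[idx[-seq_len(keep_n[k])]] <- TRUE
      a$artifact[idx] <- tag(a$artifact[idx], "under3")
    }
    a <- a[!drop, , drop = FALSE]
  } else {
    u3 <- character(0)
  }

  n_az <- round(config$frac_allzero * length(ids))
  if (n_az > 0) {
    az <- sample(setdiff(ids, u3), n_az)
    sel <- a$patient_id %in% az
    a[sel, items] <- 0L
    a$artifact[sel] <- tag(a$artifact[sel], "allzero")
  }

  if (config$dup_rate > 0) {
    sel <- which(stats::runif(nrow(a)) < config$dup_rate)
    if (length(sel)) {
      dups <- a[sel, , drop = FALSE]
      m <- as.matrix(dups[items])
      m[] <- stats::rbinom(length(m), as.integer(m), 0.5)
      dups[items] <- m
      dups$artifact <- tag(dups$artifact, "dup")
      a$artifact[sel] <- tag(a$artifact[sel], "dup_orig")
      a <- rbind(a, dups)
      a <- a[order(a$patient_id, a$date), , drop = FALSE]
    }
  }

  if (config$item_missing_rate > 0) {
    m <- as.matrix(a[items])
    miss <- matrix(stats::runif(length(m)) < config$item_missing_rate,
                   nrow(m), ncol(m))
    m[miss] <- NA_integer_
    a[items] <- m
    hit <- rowSums(miss) > 0
    a$artifact[hit] <- tag(a$artifact[hit], "miss")
  }
  rownames(a) <- NULL
  a
}

#' Simulate a full study cohort with pathologies
#'
#' [generate_cohort()] followed by [inject_artifacts()].
#'
#' @inheritParams generate_cohort
#' @return same structure as [generate_cohort()], with artifacts injected
#'   into `assessments`.
#' @export
simulate_study_cohort <- function(config = simulation_config(),
                                  seed = config$seed) {
  cohort <- generate_cohort(config, seed = seed)
  cohort$assessments <- inject_artifacts(cohort$assessments, config,
                                         seed = seed + 500009L)
  cohort
}
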