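#' @title Group profiles, sensitivity analyses and figures
#' @name reporting
NULL

# half-up rounding to `digits` decimals (table formatting convention;
# base round() is half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pearson chi-square test of independence
#'
#' Textbook Pearson statistic without continuity correction, as used for
#' the group-by-covariate comparisons and the baseline-median sensitivity
#' analysis.
#'
#' @param tab contingency table (matrix of counts).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("degenerate margin: zero expected count")
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Patient characteristics by trajectory group
#'
#' Cross-tabulates each baseline covariate against assigned trajectory
#' group, reporting counts and within-group percentages (half-up, 2
#' decimals) plus a Pearson chi-square test per covariate.  When any
#' expected cell count falls below `merge_threshold`, adjacent groups are
#' merged (smallest neighbouring pair first) until all expected counts
#' clear the threshold; the merge is recorded per covariate.
#'
#' @param patients baseline covariate table, one row per patient.
#' @param assignments integer group per patient (same order), e.g.
#'   `fit$assigned_group`.
#' @param covariates character vector of covariate column names; defaults
#'   to all columns except `patient_id` and date columns.
#' @param merge_threshold minimum expected cell count (default 5).
#' @return list of class `group_profile`: per covariate a list with
#'   `counts`, `percents`, `test` (statistic, df, p_value or a skip note)
#'   and `merge_map` (group labels used for the test).
#' @export
characteristics_table <- function(patients, assignments,
                                  covariates = NULL, merge_threshold = 5) {
  if (nrow(patients) != length(assignments)) {
    stop("assignments must cover all patients")
  }
  if (is.null(covariates)) {
    drop <- c("patient_id", grep("date", names(patients), value = TRUE),
              "observation_months", "ed_visits")
    covariates <- setdiff(names(patients), drop)
  }
  J <- max(assignments)
  out <- list()
  for (cv in covariates) {
    v <- patients[[cv]]
    tab <- table(factor(v), factor(assignments, levels = seq_len(J)))
    pct <- sweep(tab, 2, colSums(tab), "/") * 100
    pct[] <- round_half_up(pct, 2)
    entry <- list(counts = unclass(tab), percents = unclass(pct))
    if (nrow(tab) < 2) {
      entry$test <- list(skipped = TRUE,
                         note = "single level; test skipped")
      entry$merge_map <- colnames(tab)
    } else {
      merged <- merge_small_groups(unclass(tab), merge_threshold)
      entry$test <- pearson_chisq(merged$tab)
      entry$test$skipped <- FALSE
      entry$merge_map <- merged$labels
      entry$merged_counts <- merged$tab
      entry$merged_percents <- round_half_up(
        sweep(merged$tab, 2, colSums(merged$tab), "/") * 100, 2)
    }
    out[[cv]] <- entry
  }
  structure(out, class = "group_profile")
}

# merge adjacent group columns until every expected count clears the
# threshold (or only two columns remain)
merge_small_groups <- function(tab, threshold) {
  labels <- colnames(tab)
  groups <- as.list(seq_len(ncol(tab)))
  repeat {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expected >= threshold) || ncol(tab) <= 2) break
    # merge the column holding the smallest expected cell with its
    # smaller-total neighbour
    j <- which(expected == min(expected), arr.ind = TRUE)[1, 2]
    nb <- if (j == 1) 2 else if (j == ncol(tab)) j - 1 else {
      if (sum(tab[, j - 1]) <= sum(tab[, j + 1])) j - 1 else j + 1
    }
    lo <- min(j, nb); hi <- max(j, nb)
    tab[, lo] <- tab[, lo] + tab[, hi]
    groups[[lo]] <- c(groups[[lo]], groups[[hi]])
    tab <- tab[, -hi, drop = FALSE]
    groups[[hi]] <- NULL
  }
  colnames(tab) <- vapply(groups, function(g)
    paste(sort(unlist(g)), collapse = "+"), character(1))
  list(tab = tab, labels = colnames(tab))
}

#' @export
print.group_profile <- function(x, ...) {
  for (cv in names(x)) {
    cat("==", cv, "==\n")
    m <- x[[cv]]
    show <- matrix(paste0(m$counts, " (", format(m$percents, nsmall = 2),
                          "%)"),
                   nrow(m$counts), dimnames = dimnames(m$counts))
    print(show, quote = FALSE)
    if (isTRUE(m$test$skipped)) {
      cat(" ", m$test$note, "\n")
    } else {
      cat(sprintf("  chi-square %.2f, df %d, p %.4g", m$test$statistic,
                  m$test$df, m$test$p_value))
      if (length(m$merge_map) < ncol(m$counts)) {
        cat("  [groups merged:", paste(m$merge_map, collapse = " | "), "]")
      }
      cat("\n")
    }
  }
  invisible(x)
}

#' Per-patient service receipt flags
#'
#' A patient "received" a service if any of their modeled assessments
#' carries the corresponding 0-7-day flag.
#'
#' @param data a `symtraj_data`.
#' @return data frame with `patient_id` and one logical column per
#'   [service_types()] entry.
#' @export
service_receipt_flags <- function(data) {
  obs <- data$obs
  out <- data.frame(patient_id = unique(obs$patient_id),
                    stringsAsFactors = FALSE)
  for (tv in service_types()) {
    got <- tapply(obs[[tv]] > 0, obs$patient_id, any)
    out[[tv]] <- as.logical(got[out$patient_id])
  }
  out
}

#' Cohort summary table
#'
#' Whole-cohort counts and percentages for each baseline covariate,
#' service receipt over the modeled assessments, the mean (SD, range) of
#' the baseline raw TSDS, and the ED-visit rate per person-month.
#'
#' @param data a `symtraj_data`.
#' @param patients baseline table with the covariates to summarize (plus
#'   `ed_visits` and `observation_months` if the ED rate is wanted).
#' @param covariates covariate columns to tabulate; defaults as in
#'   [characteristics_table()].
#' @return list with `covariates` (named list of count/percent data
#'   frames), `services`, `baseline_tsds` and (if available) `ed_rate`.
#' @export
cohort_summary <- function(data, patients, covariates = NULL) {
  if (is.null(covariates)) {
    drop <- c("patient_id", grep("date", names(patients), value = TRUE),
              "observation_months", "ed_visits")
    covariates <- setdiff(names(patients), drop)
  }
  n <- nrow(patients)
  tab_one <- function(v) {
    t <- table(v, useNA = "no")
    data.frame(level = names(t), n = as.integer(t),
               pct = round_half_up(100 * as.integer(t) / n, 2))
  }
  cov_tabs <- lapply(patients[covariates], tab_one)
  svc <- service_receipt_flags(data)
  svc_tab <- data.frame(
    service = service_types(),
    n = vapply(service_types(), function(s) sum(svc[[s]]), integer(1)))
  svc_tab$pct <- round_half_up(100 * svc_tab$n / nrow(svc), 2)
  first <- !duplicated(data$obs$patient_id)
  base <- data$obs$tsds_raw[first]
  out <- list(n_patients = n,
              n_assessments = nrow(data$obs),
              covariates = cov_tabs,
              services = svc_tab,
              baseline_tsds = c(mean = mean(base), sd = stats::sd(base),
                                min = min(base), max = max(base)))
  if (all(c("ed_visits", "observation_months") %in% names(patients))) {
    out$ed_rate <- ed_visit_rate(patients$ed_visits,
                                 patients$observation_months)
  }
  out
}

#' Clinical parameters by trajectory group
#'
#' Per-group percentages of patients receiving each service, each
#' pairwise service combination, all four services, and (when death
#' months are supplied) death within and beyond three years of
#' diagnosis.
#'
#' @param data a `symtraj_data`.
#' @param assignments assigned group per patient in dataset order.
#' @param deaths optional data frame with `patient_id` and `death_month`.
#' @return data frame: one row per parameter, one column per group, in
#'   percent (half-up, 2 decimals).
#' @export
clinical_parameters_table <- function(data, assignments, deaths = NULL) {
  svc <- service_receipt_flags(data)
  J <- max(assignments)
  flags <- list()
  for (s in service_types()) flags[[s]] <- svc[[s]]
  combos <- utils::combn(service_types(), 2, simplify = FALSE)
  for (cb in combos) {
    flags[[paste(cb, collapse = " + ")]] <- svc[[cb[1]]] & svc[[cb[2]]]
  }
  flags[["all four services"]] <-
    Reduce(`&`, lapply(service_types(), function(s) svc[[s]]))
  if (!is.null(deaths)) {
    dm <- deaths$death_month[match(svc$patient_id, deaths$patient_id)]
    flags[["death within 3 years"]] <- !is.na(dm) & dm <= 36
    flags[["death after 3 years"]] <- !is.na(dm) & dm > 36
  }
  rows <- lapply(names(flags), function(nm) {
    pct <- vapply(seq_len(J), function(j) {
      idx <- assignments == j
      round_half_up(100 * mean(flags[[nm]][idx]), 2)
    }, numeric(1))
    stats::setNames(data.frame(parameter = nm, t(pct)),
                    c("parameter", paste0("group_", seq_len(J))))
  })
  do.call(rbind, rows)
}

#' Baseline-median sensitivity analysis
#'
#' Dichotomizes patients at the cohort median of the baseline (first
#' assessment) raw TSDS, with ties at the median assigned to the high
#' side, and cross-tabulates high/low baseline against membership in the
#' designated high-burden groups, returning the Pearson chi-square with
#' df = 1.
#'
#' @param data a `symtraj_data`.
#' @param assignments assigned group per patient, in `data` patient order
#'   (e.g. `fit$assigned_group`).
#' @param high_groups indices of the high-burden trajectory groups.
#' @return list of class `sensitivity_result` with the 2x2 `table`,
#'   `statistic`, `df`, `p_value` and `n`.
#' @export
baseline_median_sensitivity <- function(data, assignments, high_groups) {
  obs <- data$obs
  first_idx <- !duplicated(obs$patient_id)
  baseline <- obs$tsds_raw[first_idx]
  ids <- obs$patient_id[first_idx]
  if (length(baseline) != length(assignments)) {
    stop("assignments must have one entry per patient")
  }
  med <- stats::median(baseline)
  high_base <- baseline >= med
  in_high <- assignments %in% high_groups
  if (all(high_base) || !any(high_base)) {
    stop("degenerate margin: every patient on one side of the median")
  }
  tab <- table(baseline = factor(high_base, c(FALSE, TRUE),
                                 c("below_median", "at_or_above_median")),
               group = factor(in_high, c(FALSE, TRUE),
                              c("low_groups", "high_groups")))
  ts <- pearson_chisq(tab)
  structure(list(table = unclass(tab), statistic = ts$statistic,
                 df = ts$df, p_value = ts$p_value, n = sum(tab),
                 median_baseline = med, patient_ids = ids),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Sensitivity analysis\n")
  if (!is.null(x$table)) print(x$table)
  if (!is.null(x$statistic)) {
    cat(sprintf("chi-square (%d, N = %d) = %.2f, p = %.4g\n",
                x$df, x$n, x$statistic, x$p_value))
  }
  if (!is.null(x$max_abs_shift)) {
    cat("max |trajectory shift| by group:\n")
    print(round(x$max_abs_shift, 4))
    if (!is.null(x$note)) cat(x$note, "\n")
  }
  invisible(x)
}

#' Death-imputation sensitivity analysis
#'
#' Re-fits the selected trajectory model after assigning patients who died
#' during follow-up the maximum transformed TSDS at the assessments they
#' would otherwise have contributed: monthly pseudo-visits from the death
#' month to the end of follow-up, capped so no patient exceeds
#' `max_assessments` total.  Reports, per group, the maximum absolute
#' difference between base and re-fitted mean trajectories on a shared
#' time grid.  The input dataset is not modified.
#'
#' @param data the base `symtraj_data`.
#' @param fit the base `gbtm_fit` whose spec is re-fitted.
#' @param deaths data frame with `patient_id` and `death_month` (months
#'   since diagnosis; `NA` for patients who did not die).
#' @param followup_months end of follow-up for the pseudo-visit grid;
#'   default the latest observed assessment time.
#' @param max_assessments per-patient cap including pseudo-visits
#'   (default 30).
#' @param n_starts,seed passed to the re-fit.
#' @return list of class `sensitivity_result` with `refit`,
#'   `max_abs_shift` (per base group), `grid` and `n_imputed`.
#' @export
death_imputation_sensitivity <- function(data, fit, deaths,
                                         followup_months = NULL,
                                         max_assessments = 30,
                                         n_starts = 2, seed = 1L) {
  obs <- data$obs
  if (is.null(followup_months)) followup_months <- max(obs$months)
  dm <- deaths$death_month[match(unique(obs$patient_id), deaths$patient_id)]
  ids <- unique(obs$patient_id)
  ymax <- tsds_transformed_max()
  extra <- list()
  for (i in seq_along(ids)) {
    if (is.na(dm[i]) || dm[i] > followup_months) next
    have <- sum(obs$patient_id == ids[i])
    slots <- max_assessments - have
    if (slots <= 0) next
    start <- ceiling(dm[i])
    if (start > followup_months) next
    tt <- utils::head(seq(start, followup_months, by = 1), slots)
    if (!length(tt)) next
    row <- obs[obs$patient_id == ids[i], ][1, ]
    add <- row[rep(1, length(tt)), , drop = FALSE]
    add$months <- tt
    add$tsds_raw <- 90
    add$tsds_transformed <- ymax
    add[service_types()] <- 0L
    extra[[length(extra) + 1]] <- add
  }
  n_imputed <- if (length(extra)) sum(vapply(extra, nrow, integer(1))) else 0L
  if (!n_imputed) {
    grid <- seq(min(obs$months), followup_months, length.out = 50)
    return(structure(list(refit = fit,
                          max_abs_shift = stats::setNames(
                            numeric(fit$spec$n_groups),
                            seq_len(fit$spec$n_groups)),
                          grid = grid, n_imputed = 0L,
                          note = "no deaths within follow-up; base fit unchanged"),
                     class = "sensitivity_result"))
  }
  obs2 <- rbind(obs, do.call(rbind, extra))
  obs2 <- obs2[order(match(obs2$patient_id, ids), obs2$months), ]
  rownames(obs2) <- NULL
  data2 <- structure(list(obs = obs2, patients = data$patients),
                     class = "symtraj_data")
  spec2 <- fit$spec
  spec2$cnorm_min <- NULL  # bounds re-derived from the augmented data range
  spec2$cnorm_max <- NULL
  refit <- fit_gbtm(data2, spec2, n_starts = n_starts, seed = seed)

  grid <- seq(min(obs$months), followup_months, length.out = 50)
  shift <- vapply(seq_len(fit$spec$n_groups), function(j) {
    base <- suppressWarnings(predict_trajectory(fit, j, grid)$mean)
    new <- suppressWarnings(predict_trajectory(refit, j, grid)$mean)
    max(abs(new - base))
  }, numeric(1))
  structure(list(refit = refit,
                 max_abs_shift = stats::setNames(shift,
                                                 seq_len(fit$spec$n_groups)),
                 grid = grid, n_imputed = n_imputed),
            class = "sensitivity_result")
}

#' Emergency-department visit rate per person-month
#'
#' Total events over total person-months, with standard error and 95%
#' confidence interval from an intercept-only Poisson regression of event
#' counts with a log person-month offset.
#'
#' @param ed_counts integer vector of ED visit counts per patient.
#' @param person_months observation months per patient (all > 0).
#' @param level confidence level (default 0.95).
#' @return list with `rate`, `se`, `lower`, `upper`, `total_events`,
#'   `total_person_months`.
#' @export
ed_visit_rate <- function(ed_counts, person_months, level = 0.95) {
  if (sum(person_months) <= 0) stop("total person-months must be > 0")
  if (any(person_months <= 0)) stop("each patient needs positive exposure")
  fit <- stats::glm(ed_counts ~ 1 + offset(log(person_months)),
                    family = stats::poisson())
  est <- stats::coef(fit)[[1]]
  se_log <- sqrt(stats::vcov(fit)[1, 1])
  zq <- stats::qnorm(1 - (1 - level) / 2)
  rate <- exp(est)
  list(rate = rate,
       se = rate * se_log,   # delta method on the log scale
       lower = exp(est - zq * se_log),
       upper = exp(est + zq * se_log),
       total_events = sum(ed_counts),
       total_person_months = sum(person_months))
}

#' Trajectory profile plot
#'
#' One mean trajectory per group on the transformed-TSDS scale against
#' months since diagnosis, with pointwise 95% confidence bands and group
#' membership percentages in the legend.
#'
#' @param fit a `gbtm_fit`.
#' @param data optional `symtraj_data`; used only for the time grid range
#'   (defaults to the fitted range).
#' @param n_grid number of grid points (default 100).
#' @param covariate_profile passed to [predict_trajectory()].
#' @return a `ggplot` object.
#' @export
plot_trajectories <- function(fit, data = NULL, n_grid = 100,
                              covariate_profile = NULL) {
  rng <- if (!is.null(data)) range(data$obs$months) else fit$months_range
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  pct <- 100 * tabulate(fit$assigned_group, fit$spec$n_groups) /
    fit$n_patients
  curves <- do.call(rbind, lapply(seq_len(fit$spec$n_groups), function(j) {
    d <- predict_trajectory(fit, j, grid, covariate_profile)
    d$group <- sprintf("Group %d (%.1f%%)", j, pct[j])
    d
  }))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$months, y = .data$mean,
                               colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "Months since diagnosis",
                  y = "Transformed total symptom distress score",
                  colour = "Trajectory group", fill = "Trajectory group") +
    ggplot2::theme_minimal()
}

#' Export the trajectory figure to a file
#'
#' @param fit a `gbtm_fit`.
#' @param out output path (extension selects the device, e.g. `.png`,
#'   `.pdf`).
#' @param ... passed to [plot_trajectories()].
#' @param width,height,dpi figure dimensions.
#' @return `out`, invisibly.
#' @export
export_trajectory_plot <- function(fit, out, ..., width = 8, height = 5,
                                   dpi = 150) {
  p <- plot_trajectories(fit, ...)
  ggplot2::ggsave(out, p, width = width, height = height, dpi = dpi)
  invisible(out)
}
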