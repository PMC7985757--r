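test_that("percentages are count over group total, rounded half-up", {
  # Group 1 chemotherapy 77/89 and merged-group Charlson 329/338
  patients <- data.frame(
    chemo = rep(c("Yes", "No"), c(77, 12)),
    stringsAsFactors = FALSE)
  tab <- characteristics_table(patients, rep(1, 89), covariates = "chemo")
  expect_equal(tab$chemo$counts["Yes", "1"], 77)
  expect_equal(tab$chemo$percents["Yes", "1"], 86.52)
  expect_equal(tab$chemo$percents["No", "1"], 13.48)

  p2 <- data.frame(charlson = rep(c("0", "1-3"), c(329, 9)))
  t2 <- characteristics_table(p2, rep(1, 338), covariates = "charlson")
  expect_equal(t2$charlson$percents["0", "1"], 97.34)

  # half-up convention: 1/16 = 6.25 stays, 0.125 rounds up at 2 dp
  expect_equal(symtraj:::round_half_up(0.125, 2), 0.13)
  expect_equal(symtraj:::round_half_up(86.515, 2), 86.52)
})

test_that("profile chi-square agrees with the stats oracle and merges cells", {
  set.seed(81)
  patients <- data.frame(
    rural = sample(c("urban", "rural"), 300, TRUE, prob = c(0.8, 0.2)))
  groups <- sample(1:4, 300, TRUE, prob = c(0.05, 0.3, 0.3, 0.35))
  tab <- characteristics_table(patients, groups, covariates = "rural",
                               merge_threshold = 5)
  ct <- tab$rural$test
  oracle <- suppressWarnings(chisq.test(table(patients$rural,
                                              factor(groups, 1:4)),
                                        correct = FALSE))
  # counts per covariate sum to group totals
  expect_equal(colSums(tab$rural$counts), unname(table(factor(groups, 1:4))),
               ignore_attr = TRUE)
  expect_true(all(abs(colSums(tab$rural$percents) - 100) < 0.02))
  if (length(tab$rural$merge_map) == 4) {
    expect_equal(ct$statistic, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(ct$df, unname(oracle$parameter))
  } else {
    # merged table still matches the oracle computed on the merged counts
    om <- suppressWarnings(chisq.test(tab$rural$merged_counts,
                                      correct = FALSE))
    expect_equal(ct$statistic, unname(om$statistic), tolerance = 1e-10)
  }

  # identical group proportions give statistic 0, p 1
  even <- matrix(c(10, 20, 10, 20), 2)
  expect_equal(pearson_chisq(even)$statistic, 0)
  expect_equal(pearson_chisq(even)$p_value, 1)

  # single-level covariate: test skipped with a note
  p1 <- data.frame(constant = rep("x", 20))
  t1 <- characteristics_table(p1, rep(1:2, 10), covariates = "constant")
  expect_true(t1$constant$test$skipped)
})

test_that("pearson chi-square matches stats::chisq.test on random tables", {
  set.seed(82)
  for (r in 1:20) {
    tab <- matrix(rpois(6, 30) + 1, 2, 3)
    got <- pearson_chisq(tab)
    want <- chisq.test(tab, correct = FALSE)
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, unname(want$p.value), tolerance = 1e-10)
    expect_equal(got$df, unname(want$parameter))
  }
})

test_that("baseline median split computes the df-1 chi-square", {
  # hand fixture engineered to the 2x2 table ((30,10),(10,30))
  n <- 80
  ids <- sprintf("p%02d", 1:n)
  baseline_raw <- c(rep(5, 40), rep(60, 40))   # median 32.5; 40 high, 40 low
  y <- tsds_transform(baseline_raw)
  d <- make_dataset(rep(ids, each = 2), months = rep(c(0, 1), n),
                    y = rep(y, each = 2))
  assignments <- c(rep(1, 30), rep(2, 10), rep(1, 10), rep(2, 30))
  res <- baseline_median_sensitivity(d, assignments, high_groups = 2)
  expect_equal(unname(res$table), matrix(c(30, 10, 10, 30), 2))
  expect_equal(res$statistic, 20)   # expected counts all 20
  expect_equal(res$df, 1)
  expect_equal(res$n, 80)

  expect_error(baseline_median_sensitivity(d, assignments, high_groups = NULL),
               "degenerate|one side")
})

test_that("median split keeps nominal error under independence and power under dependence", {
  set.seed(83)
  n <- 200
  ids <- sprintf("p%03d", 1:n)
  reject_null <- logical(60)
  reject_alt <- logical(20)
  base <- sample(0:90, n, replace = TRUE)
  d <- make_dataset(rep(ids, each = 2), months = rep(c(0, 1), n),
                    y = rep(tsds_transform(base), each = 2))
  for (r in seq_along(reject_null)) {
    g <- sample(1:2, n, replace = TRUE)        # independent of baseline
    reject_null[r] <- baseline_median_sensitivity(d, g, 2)$p_value < 0.05
  }
  expect_lt(abs(mean(reject_null) - 0.05), 0.07)
  for (r in seq_along(reject_alt)) {
    p_high <- ifelse(base >= median(base), 0.85, 0.15)
    g <- 1 + rbinom(n, 1, p_high)
    if (length(unique(g)) < 2) g[1:2] <- 1:2
    reject_alt[r] <- baseline_median_sensitivity(d, g, 2)$p_value < 0.001
  }
  expect_gte(mean(reject_alt), 0.95)
})

test_that("ED visit rate matches arithmetic and the exact Poisson interval", {
  expect_lt(suppressWarnings(ed_visit_rate(rep(0, 10), rep(10, 10))$rate),
            1e-6)
  r <- ed_visit_rate(c(5, 7), c(40, 60))
  expect_equal(r$rate, 0.12)
  expect_equal(r$total_events, 12)

  # 500 events over 4000 person-months vs exact Poisson interval
  set.seed(84)
  counts <- rmultinom(1, 500, rep(1, 100))[, 1]
  r2 <- ed_visit_rate(counts, rep(40, 100))
  exact <- poisson.test(500)$conf.int / 4000
  width_glm <- r2$upper - r2$lower
  width_exact <- exact[2] - exact[1]
  expect_lt(abs(width_glm - width_exact) / width_exact, 0.05)
  expect_error(ed_visit_rate(c(1, 2), c(0, 10)), "positive exposure")
})

test_that("cohort summary and clinical parameter tables report percentages per group", {
  cfg <- flat_config(80, means = c(2, 6), probs = c(0.5, 0.5), sd = 0.5,
                     n_obs = 5, seed = 87)
  cfg$covariate_model$probs[1, ] <- c(0.5, 0.2, 0.3, 0.4)
  co <- generate_cohort(cfg)
  pp <- preprocess_cohort(co$assessments, co$patients, co$services)
  cs <- cohort_summary(pp$data, pp$data$patients)
  expect_equal(cs$n_patients, nrow(pp$data$patients))
  expect_equal(sum(cs$covariates$rurality$n), cs$n_patients)
  expect_true(all(abs(vapply(cs$covariates, function(t) sum(t$pct),
                             numeric(1)) - 100) < 0.05))
  expect_true(all(cs$services$pct >= 0 & cs$services$pct <= 100))
  expect_equal(unname(cs$baseline_tsds["min"]),
               min(pp$data$obs$tsds_raw[!duplicated(pp$data$obs$patient_id)]))

  ids <- unique(pp$data$obs$patient_id)
  truth <- co$truth$true_group[match(ids, co$truth$patient_id)]
  cp <- clinical_parameters_table(pp$data, truth,
                                  deaths = co$truth[, c("patient_id",
                                                        "death_month")])
  expect_equal(ncol(cp), 3)
  expect_true(all(as.matrix(cp[-1]) >= 0 & as.matrix(cp[-1]) <= 100))
  # combination receipt can never exceed either component's receipt
  chemo <- cp[cp$parameter == "chemotherapy", -1]
  combo <- cp[cp$parameter == "chemotherapy + radiotherapy", -1]
  expect_true(all(combo <= chemo))
  # group 1 was configured with more frequent chemotherapy visits
  expect_gte(cp[cp$parameter == "chemotherapy", "group_1"],
             cp[cp$parameter == "chemotherapy", "group_2"])
})

test_that("death imputation with no deaths returns the base fit unchanged", {
  cfg <- flat_config(60, means = c(2, 6), probs = c(0.5, 0.5), sd = 0.5,
                     n_obs = 5, seed = 85)
  d <- clean_dataset(cfg)
  fit <- fit_gbtm(d, trajectory_spec(2, 0), n_starts = 2, seed = 2)
  deaths <- data.frame(patient_id = d$patients$patient_id,
                       death_month = NA_real_)
  res <- death_imputation_sensitivity(d, fit, deaths)
  expect_equal(unname(res$max_abs_shift), c(0, 0))
  expect_equal(res$n_imputed, 0L)
})

test_that("universal early death drags late trajectories to the scale maximum", {
  cfg <- flat_config(50, means = 3, probs = 1, sd = 0.4, n_obs = 4,
                     seed = 86, followup = 24)
  d <- clean_dataset(cfg)
  d$obs <- d$obs[d$obs$months <= 1.01, ]   # keep only near-baseline visits
  d$patients <- d$patients[d$patients$patient_id %in% d$obs$patient_id, ,
                           drop = FALSE]
  fit <- fit_gbtm(d, trajectory_spec(1, 0), n_starts = 2, seed = 2)
  deaths <- data.frame(patient_id = unique(d$obs$patient_id), death_month = 1)
  before <- nrow(d$obs)
  res <- death_imputation_sensitivity(d, fit, deaths, followup_months = 24,
                                      seed = 3)
  expect_equal(nrow(d$obs), before)        # base dataset untouched
  late <- predict_trajectory(res$refit, res$refit$spec$n_groups, 24)
  expect_gt(late$mean, 0.9 * tsds_transformed_max())
})
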