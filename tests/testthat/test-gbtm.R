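test_that("mixture log-likelihood matches brute-force enumeration", {
  # 2 patients x 2 timepoints, 2 groups, hand-set parameters
  d <- make_dataset(patient_id = c("a", "a", "b", "b"),
                    months = c(0, 6, 0, 12),
                    y = c(2.1, 2.6, 6.9, 7.4))
  spec <- trajectory_spec(2, orders = 1, cnorm_min = -Inf, cnorm_max = Inf)
  params <- list(theta = matrix(log(0.35 / 0.65), 1, 1),
                 beta = list(c(2.0, 0.5), c(7.0, -0.25)),
                 alpha = matrix(0, 2, 0), sigma = 0.6)
  got <- cnorm_loglik(params, d, spec)
  want <- brute_force_loglik(
    y_by_patient = list(c(2.1, 2.6), c(6.9, 7.4)),
    t_by_patient = list(c(0, 6), c(0, 12)),
    pi = c(0.35, 0.65),
    beta = list(c(2.0, 0.5), c(7.0, -0.25)), sigma = 0.6)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("single-component likelihood reduces to the pooled normal", {
  set.seed(3)
  y <- rnorm(40, 5, 1)
  d <- make_dataset(rep(letters[1:8], each = 5),
                    months = rep(seq(0, 8, 2), 8), y = y)
  spec <- trajectory_spec(1, 0, cnorm_min = -Inf, cnorm_max = Inf)
  params <- list(theta = matrix(0, 0, 1), beta = list(4.8),
                 alpha = matrix(0, 1, 0), sigma = 1.1)
  expect_equal(cnorm_loglik(params, d, spec),
               sum(dnorm(y, 4.8, 1.1, log = TRUE)), tolerance = 1e-12)
})

test_that("censoring bounds outside the data range are inactive", {
  set.seed(4)
  d <- make_dataset(rep(letters[1:6], each = 4),
                    months = rep(0:3, 6), y = runif(24, 1, 7))
  params <- list(theta = matrix(0.4, 1, 1),
                 beta = list(c(2, 0.3), c(6, -0.1)),
                 alpha = matrix(0, 2, 0), sigma = 0.8)
  ll_wide <- cnorm_loglik(params, d,
                          trajectory_spec(2, 1, cnorm_min = 0.5,
                                          cnorm_max = 7.5))
  ll_inf <- cnorm_loglik(params, d,
                         trajectory_spec(2, 1, cnorm_min = -Inf,
                                         cnorm_max = Inf))
  expect_equal(ll_wide, ll_inf, tolerance = 1e-12)
})

test_that("active censoring replaces the density with tail mass", {
  d <- make_dataset(c("a", "a", "b", "b"), months = c(0, 1, 0, 1),
                    y = c(0.5, 2.0, 3.0, 5.0))
  spec <- trajectory_spec(1, 0, cnorm_min = 1, cnorm_max = 4)
  params <- list(theta = matrix(0, 0, 1), beta = list(2.5),
                 alpha = matrix(0, 1, 0), sigma = 1)
  got <- cnorm_loglik(params, d, spec)
  want <- pnorm(1, 2.5, 1, log.p = TRUE) +
    dnorm(2, 2.5, 1, log = TRUE) + dnorm(3, 2.5, 1, log = TRUE) +
    pnorm(4, 2.5, 1, lower.tail = FALSE, log.p = TRUE)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("likelihood is invariant to permuting group labels", {
  set.seed(5)
  d <- make_dataset(rep(letters[1:10], each = 3),
                    months = rep(c(0, 3, 6), 10), y = runif(30, 0, 8))
  spec <- trajectory_spec(3, c(1, 2, 0), cnorm_min = -Inf, cnorm_max = Inf)
  pi <- c(0.2, 0.5, 0.3)
  beta <- list(c(2, 0.1), c(5, -0.2, 0.05), 7)
  base <- list(theta = matrix(log(pi[1:2] / pi[3]), 2, 1),
               beta = beta, alpha = matrix(0, 3, 0), sigma = 0.7)
  ll1 <- cnorm_loglik(base, d, spec)
  perm <- c(3, 1, 2)
  spec2 <- trajectory_spec(3, c(0, 1, 2), cnorm_min = -Inf, cnorm_max = Inf)
  pi2 <- pi[perm]
  perm_params <- list(theta = matrix(log(pi2[1:2] / pi2[3]), 2, 1),
                      beta = beta[perm], alpha = matrix(0, 3, 0), sigma = 0.7)
  expect_equal(cnorm_loglik(perm_params, d, spec2), ll1, tolerance = 1e-10)
})

test_that("loglik validates inputs", {
  d <- make_dataset("a", 0, 3)
  spec <- trajectory_spec(1, 0)
  expect_error(cnorm_loglik(list(theta = matrix(0, 0, 1), beta = list(c(1, 2)),
                                 alpha = matrix(0, 1, 0), sigma = 1), d, spec),
               "length")
  expect_error(cnorm_loglik(list(theta = matrix(0, 0, 1), beta = list(1),
                                 alpha = matrix(0, 1, 0), sigma = -1), d, spec),
               "sigma")
  empty <- structure(list(obs = d$obs[0, ], patients = d$patients),
                     class = "symtraj_data")
  expect_error(cnorm_loglik(list(theta = matrix(0, 0, 1), beta = list(1),
                                 alpha = matrix(0, 1, 0), sigma = 1),
                            empty, spec), "empty")
})

test_that("one-group flat fit recovers the closed-form normal MLE", {
  set.seed(6)
  y <- rnorm(60, 4, 0.9)
  d <- make_dataset(rep(sprintf("p%02d", 1:12), each = 5),
                    months = rep(seq(0, 12, 3), 12), y = y)
  fit <- fit_gbtm(d, trajectory_spec(1, 0), n_starts = 2, seed = 1)
  expect_equal(fit$params$beta[[1]][1], mean(y), tolerance = 1e-4)
  expect_equal(fit$params$sigma, sqrt(mean((y - mean(y))^2)),
               tolerance = 1e-4)
  expect_true(fit$converged)
  expect_equal(fit$n_params, 2)
})

test_that("two well-separated flat groups are recovered", {
  cfg <- flat_config(200, means = c(2, 8), probs = c(0.4, 0.6), sd = 0.5,
                     n_obs = 10, seed = 1)
  d <- clean_dataset(cfg)
  fit <- fit_gbtm(d, trajectory_spec(2, 0, cnorm_min = 0,
                                     cnorm_max = tsds_transformed_max()),
                  n_starts = 3, seed = 5)
  expect_lt(abs(fit$params$beta[[1]][1] - 2), 0.1)
  expect_lt(abs(fit$params$beta[[2]][1] - 8), 0.1)
  expect_lt(max(abs(fit$pi - c(0.4, 0.6))), 0.05)
  expect_lt(abs(fit$params$sigma - 0.5), 0.05)

  # MLE optimality: fitted loglik beats the generating truth on this data
  truth <- list(theta = matrix(log(0.4 / 0.6), 1, 1),
                beta = list(2, 8), alpha = matrix(0, 2, 0), sigma = 0.5)
  ll_truth <- cnorm_loglik(truth, d,
                           trajectory_spec(2, 0, cnorm_min = 0,
                                           cnorm_max = tsds_transformed_max()))
  expect_gte(fit$loglik, ll_truth)

  # separation implies near-certain classification
  expect_gt(mean(apply(fit$posterior, 1, max)), 0.99)

  # groups relabeled in ascending trajectory level
  expect_lt(fit$params$beta[[1]][1], fit$params$beta[[2]][1])
})

test_that("posterior rows sum to one and collapse to pi under symmetry", {
  set.seed(8)
  d <- make_dataset(rep(sprintf("p%d", 1:15), each = 2),
                    months = rep(c(0, 5), 15), y = runif(30, 1, 7))
  spec <- trajectory_spec(2, 0, cnorm_min = -Inf, cnorm_max = Inf)
  fit <- fit_gbtm(d, spec, n_starts = 2, seed = 2, compute_se = FALSE)
  expect_equal(unname(rowSums(fit$posterior)), rep(1, 15),
               tolerance = 1e-10)
  expect_equal(fit$assigned_group,
               unname(apply(fit$posterior, 1, which.max)))

  # identical group parameters: posterior equals pi in every row
  same <- list(theta = matrix(log(0.3 / 0.7), 1, 1), beta = list(4, 4),
               alpha = matrix(0, 2, 0), sigma = 1)
  fake <- fit
  fake$params <- same
  fake$bounds <- c(-Inf, Inf)
  post <- posterior_matrix(fake, d)
  expect_equal(post, matrix(rep(c(0.3, 0.7), each = 15), 15, 2),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("reported objective improves monotonically across iterations", {
  cfg <- flat_config(80, means = c(2, 6), probs = c(0.5, 0.5), sd = 0.8,
                     n_obs = 6, seed = 3)
  d <- clean_dataset(cfg)
  fit <- fit_gbtm(d, trajectory_spec(2, 1), n_starts = 2, seed = 4,
                  compute_se = FALSE)
  expect_true(all(diff(fit$trace) >= -1e-8))
})

test_that("time-varying covariate effects are recovered", {
  cfg <- flat_config(250, means = c(2.5, 6), probs = c(0.5, 0.5), sd = 0.5,
                     n_obs = 8, seed = 10)
  cfg$covariate_model$probs[, "radiotherapy"] <- 0.4
  cfg$covariate_model$effects[, "radiotherapy"] <- 0.6
  d <- clean_dataset(cfg)
  fit <- fit_gbtm(d, trajectory_spec(2, 0, tv_covariates = "radiotherapy"),
                  n_starts = 2, seed = 6)
  expect_lt(max(abs(fit$params$alpha[, "radiotherapy"] - 0.6)), 0.15)
  # Wald z for a strong true effect is large
  tab <- coef_table(fit)
  z <- tab$z[tab$term == "radiotherapy"]
  expect_true(all(abs(z) > 3))
})

test_that("adding a null covariate leaves trajectory shapes unchanged", {
  cfg <- flat_config(150, means = c(2.5, 6), probs = c(0.5, 0.5), sd = 0.6,
                     n_obs = 8, seed = 12)
  cfg$covariate_model$probs[, "home_care"] <- 0.3   # flag present, effect 0
  d <- clean_dataset(cfg)
  f0 <- fit_gbtm(d, trajectory_spec(2, 0), n_starts = 2, seed = 7,
                 compute_se = FALSE)
  f1 <- fit_gbtm(d, trajectory_spec(2, 0, tv_covariates = "home_care"),
                 n_starts = 2, seed = 7, compute_se = FALSE)
  expect_lt(max(abs(unlist(f1$params$beta) - unlist(f0$params$beta))), 0.1)
})

test_that("prediction handles flat groups, covariate profiles and extrapolation", {
  cfg <- flat_config(100, means = c(2, 6), probs = c(0.5, 0.5), sd = 0.5,
                     n_obs = 6, seed = 14)
  cfg$covariate_model$probs[, "chemotherapy"] <- 0.3  # flag varies, effect 0
  d <- clean_dataset(cfg)
  fit <- fit_gbtm(d, trajectory_spec(2, 0), n_starts = 2, seed = 3)
  grid <- seq(0, 4, 1)
  p <- predict_trajectory(fit, 1, grid)
  expect_true(all(abs(p$mean - p$mean[1]) < 1e-12))    # flat line
  expect_true(all(p$lower <= p$mean & p$mean <= p$upper))
  expect_error(predict_trajectory(fit, 3, grid), "group")
  expect_warning(predict_trajectory(fit, 1, max(d$obs$months) + 5),
                 "extrapolat")
  # all-zero covariate profile equals the pure polynomial
  fitc <- fit_gbtm(d, trajectory_spec(2, 0, tv_covariates = "chemotherapy"),
                   n_starts = 2, seed = 3)
  p0 <- predict_trajectory(fitc, 2, grid)
  pz <- predict_trajectory(fitc, 2, grid,
                           covariate_profile = c(chemotherapy = 0))
  expect_equal(p0$mean, pz$mean)
})

test_that("group count larger than patient count is rejected", {
  d <- make_dataset(c("a", "b"), c(0, 0), c(2, 6))
  expect_error(fit_gbtm(d, trajectory_spec(3, 0)), "exceeds patient count")
})
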