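#' @title Censored-normal group-based trajectory model
#' @name gbtm
#' @description
#' A finite mixture of polynomial mean trajectories for a continuous
#' longitudinal outcome.  Each latent group j has membership probability
#' `pi_j` (multinomial logit, last group reference), a polynomial mean in
#' scaled time, optional additive time-varying covariate effects, and a
#' shared residual SD.  The outcome density is censored normal (CNORM):
#' normal between the censoring bounds, with probability mass
#' `Phi((ymin - mu)/sigma)` at or below the lower bound and the mirrored
#' upper-tail mass at or above the upper bound.  With bounds outside the
#' observed range (the default) the censoring terms are inactive and the
#' model is an ordinary normal mixture.  Estimation is by direct
#' maximization of the observed-data log-likelihood with multiple random
#' starts.
NULL

# Internal time scaling: months are divided by this before powering, so
# quartic terms stay well conditioned over multi-year follow-up.
# Coefficients are reported on the scaled axis; the fit records the scale.
TIME_SCALE <- 10

#' Specify a trajectory model
#'
#' @param n_groups number of latent groups J (>= 1).
#' @param orders integer vector of per-group polynomial orders in 0..4; a
#'   single value is recycled to all groups.
#' @param cnorm_min,cnorm_max censoring bounds on the transformed outcome
#'   scale; `NULL` (default) resolves at fit time to 1 unit outside the
#'   observed data range, making the censoring inactive.
#' @param tv_covariates names of time-varying covariate columns included as
#'   per-group additive mean shifters (subset of [service_types()] or any
#'   columns of the dataset).
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_groups, orders, cnorm_min = NULL,
                            cnorm_max = NULL, tv_covariates = character(0)) {
  n_groups <- as.integer(n_groups)
  if (n_groups < 1) stop("n_groups must be >= 1")
  if (length(orders) == 1) orders <- rep(orders, n_groups)
  orders <- as.integer(orders)
  if (length(orders) != n_groups) {
    stop("length(orders) must equal n_groups")
  }
  if (any(orders < 0 | orders > 4)) stop("orders must lie in 0..4")
  if (!is.null(cnorm_min) && !is.null(cnorm_max) && cnorm_min >= cnorm_max) {
    stop("cnorm_min must be < cnorm_max")
  }
  structure(list(n_groups = n_groups, orders = orders,
                 cnorm_min = cnorm_min, cnorm_max = cnorm_max,
                 tv_covariates = as.character(tv_covariates)),
            class = "trajectory_spec")
}

#' @export
format.trajectory_spec <- function(x, ...) {
  paste0(x$n_groups, " group(s), orders ",
         paste(x$orders, collapse = ""),
         if (length(x$tv_covariates))
           paste0(", covariates: ", paste(x$tv_covariates, collapse = ", ")))
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat("Trajectory spec:", format(x), "\n")
  invisible(x)
}

# ---- internal data/parameter plumbing ---------------------------------------

# Compile a symtraj_data + spec into flat structures for likelihood work.
gbtm_env <- function(data, spec, x_membership = NULL) {
  if (!inherits(data, "symtraj_data")) stop("data must be a symtraj_data")
  obs <- data$obs
  if (!nrow(obs)) stop("dataset is empty")
  pid <- factor(obs$patient_id, levels = unique(obs$patient_id))
  n <- nlevels(pid)
  if (spec$n_groups > n) {
    stop("n_groups (", spec$n_groups, ") exceeds patient count (", n, ")")
  }
  u <- obs$months / TIME_SCALE
  U <- cbind(1, u, u^2, u^3, u^4)
  ncov <- length(spec$tv_covariates)
  W <- if (ncov) {
    miss <- setdiff(spec$tv_covariates, names(obs))
    if (length(miss)) stop("covariates not in dataset: ",
                           paste(miss, collapse = ", "))
    as.matrix(obs[spec$tv_covariates])
  } else matrix(0, nrow(obs), 0)
  ymin <- spec$cnorm_min
  ymax <- spec$cnorm_max
  y <- obs$tsds_transformed
  if (is.null(ymin)) ymin <- min(y) - 1
  if (is.null(ymax)) ymax <- max(y) + 1
  Xm <- cbind(intercept = rep(1, n))
  if (!is.null(x_membership)) {
    x_membership <- as.matrix(x_membership)
    if (nrow(x_membership) != n) {
      stop("x_membership must have one row per patient")
    }
    Xm <- cbind(Xm, x_membership)
  }
  list(y = y, pidx = as.integer(pid), patient_ids = levels(pid), n = n,
       U = U, W = W, ncov = ncov, J = spec$n_groups, orders = spec$orders,
       ymin = ymin, ymax = ymax, Xm = Xm, pm = ncol(Xm),
       lo = y <= ymin, hi = y >= ymax)
}

n_gbtm_params <- function(env) {
  (env$J - 1) * env$pm + sum(env$orders + 1) + env$J * env$ncov + 1
}

pack_params <- function(params, env) {
  th <- params$theta
  if (env$J > 1 && is.null(dim(th))) th <- matrix(th, ncol = 1)
  c(if (env$J > 1) as.numeric(t(th)),
    unlist(params$beta, use.names = FALSE),
    if (env$ncov) as.numeric(t(params$alpha)),
    log(params$sigma))
}

unpack_params <- function(par, env) {
  J <- env$J
  k <- 0
  theta <- if (J > 1) {
    m <- matrix(par[seq_len((J - 1) * env$pm)], J - 1, env$pm, byrow = TRUE)
    k <- (J - 1) * env$pm
    m
  } else matrix(0, 0, env$pm)
  beta <- vector("list", J)
  for (j in seq_len(J)) {
    nb <- env$orders[j] + 1
    beta[[j]] <- par[k + seq_len(nb)]
    k <- k + nb
  }
  alpha <- if (env$ncov) {
    m <- matrix(par[k + seq_len(J * env$ncov)], J, env$ncov, byrow = TRUE)
    k <- k + J * env$ncov
    dimnames(m) <- list(NULL, colnames(env$W))
    m
  } else matrix(0, J, 0)
  sigma <- exp(par[k + 1])
  list(theta = theta, beta = beta, alpha = alpha, sigma = sigma)
}

# log membership probabilities, n x J (rows identical without membership
# covariates)
log_pi_matrix <- function(params, env) {
  logits <- cbind(env$Xm %*% t(params$theta), 0)  # n x J, reference last
  logits - apply(logits, 1, logsumexp)
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# per-observation log density matrix (n_obs x J) under the CNORM model
cnorm_logdens <- function(params, env) {
  J <- env$J
  out <- matrix(0, length(env$y), J)
  for (j in seq_len(J)) {
    mu <- drop(env$U[, seq_len(env$orders[j] + 1), drop = FALSE] %*%
                 params$beta[[j]])
    if (env$ncov) mu <- mu + drop(env$W %*% params$alpha[j, ])
    ld <- stats::dnorm(env$y, mu, params$sigma, log = TRUE)
    if (any(env$lo)) {
      ld[env$lo] <- stats::pnorm(env$ymin, mu[env$lo], params$sigma,
                                 log.p = TRUE)
    }
    if (any(env$hi)) {
      ld[env$hi] <- stats::pnorm(env$ymax, mu[env$hi], params$sigma,
                                 lower.tail = FALSE, log.p = TRUE)
    }
    out[, j] <- ld
  }
  out
}

# patient-level conditional log-likelihood matrix (n x J)
patient_loglik_matrix <- function(params, env) {
  ld <- cnorm_logdens(params, env)
  rowsum(ld, env$pidx, reorder = TRUE)
}

gbtm_loglik_env <- function(params, env) {
  lmat <- log_pi_matrix(params, env) + patient_loglik_matrix(params, env)
  sum(apply(lmat, 1, logsumexp))
}

#' Censored-normal mixture log-likelihood
#'
#' Evaluates the observed-data log-likelihood
#' `sum_i log sum_j pi_j prod_t f_j(y_it)` where `f_j` is the censored
#' normal density of group j at the patient's observation.
#'
#' @param params list with `theta` (membership logit matrix, `(J-1) x 1`
#'   without membership covariates; a plain vector is accepted), `beta`
#'   (list of J polynomial coefficient vectors on the `months/10` axis),
#'   `alpha` (`J x n_cov` covariate effect matrix, may be empty), and
#'   `sigma` (residual SD > 0).
#' @param data a `symtraj_data` object.
#' @param spec a [trajectory_spec()] dimensionally consistent with `params`.
#' @return the log-likelihood (scalar).
#' @export
cnorm_loglik <- function(params, data, spec) {
  env <- gbtm_env(data, spec)
  for (j in seq_len(env$J)) {
    if (length(params$beta[[j]]) != env$orders[j] + 1) {
      stop("beta[[", j, "]] must have length order + 1 = ", env$orders[j] + 1)
    }
  }
  if (params$sigma <= 0) stop("sigma must be > 0")
  if (is.null(params$alpha)) params$alpha <- matrix(0, env$J, env$ncov)
  ll <- gbtm_loglik_env(params, env)
  if (!is.finite(ll)) {
    stop("non-finite log-likelihood (sigma = ", params$sigma,
         ", bounds [", env$ymin, ", ", env$ymax, "])")
  }
  ll
}

# ---- fitting ----------------------------------------------------------------

# k-means style initialization on per-patient mean outcome, perturbed per
# start.  Returns a packed parameter vector.
init_start <- function(env, start_index) {
  ybar <- tapply(env$y, env$pidx, mean)
  J <- env$J
  if (J == 1) {
    centers <- mean(env$y)
    assign <- rep(1L, env$n)
  } else {
    km <- suppressWarnings(
      stats::kmeans(ybar, centers = J, nstart = 5, iter.max = 50))
    ord <- order(km$centers)
    centers <- as.numeric(km$centers[ord])
    assign <- match(km$cluster, ord)
  }
  if (start_index > 1) {
    spread <- max(stats::sd(ybar), 0.25)
    centers <- centers + stats::rnorm(J, 0, spread / 2)
    flip <- stats::runif(env$n) < 0.1
    assign[flip] <- sample.int(J, sum(flip), replace = TRUE)
  }
  prop <- pmax(tabulate(assign, J) / env$n, 1 / (4 * env$n))
  prop <- prop / sum(prop)
  theta <- matrix(0, J - 1, env$pm)
  if (J > 1) theta[, 1] <- log(prop[-J] / prop[J])
  beta <- lapply(seq_len(J), function(j) {
    b <- numeric(env$orders[j] + 1)
    b[1] <- centers[j]
    b
  })
  resid <- env$y - centers[assign][env$pidx]
  sigma <- max(stats::sd(resid), 0.05)
  pack_params(list(theta = theta, beta = beta,
                   alpha = matrix(0, J, env$ncov), sigma = sigma), env)
}

# Log-likelihood and analytic score of the packed parameter vector.
# Gradient pieces: with r_ij the posterior and d_jt = dlogf/dmu,
#   d ll / d beta_j  = sum_i r_ij sum_t d_jt x_t
#   d ll / d theta_j = sum_i (r_ij - pi_ij) x_mi        (reference group last)
#   d ll / d logsig  = sum_i sum_j r_ij sum_t dlogf/dlogsigma
# where for interior points d = (y-mu)/sigma^2 and dlogf/dlogsigma = z^2-1,
# and for censored points the normal density is replaced by the tail mass,
# giving inverse-Mills-ratio terms.
gbtm_loglik_grad <- function(par, env) {
  params <- unpack_params(par, env)
  J <- env$J
  sigma <- params$sigma
  nobs <- length(env$y)
  dmu <- matrix(0, nobs, J)      # dlogf/dmu
  dls <- matrix(0, nobs, J)      # dlogf/dlog sigma
  logf <- matrix(0, nobs, J)
  mid <- !(env$lo | env$hi)
  for (j in seq_len(J)) {
    mu <- drop(env$U[, seq_len(env$orders[j] + 1), drop = FALSE] %*%
                 params$beta[[j]])
    if (env$ncov) mu <- mu + drop(env$W %*% params$alpha[j, ])
    z <- (env$y - mu) / sigma
    logf[, j] <- stats::dnorm(env$y, mu, sigma, log = TRUE)
    dmu[, j] <- z / sigma
    dls[, j] <- z^2 - 1
    if (any(env$lo)) {
      zl <- (env$ymin - mu[env$lo]) / sigma
      lp <- stats::pnorm(zl, log.p = TRUE)
      mills <- exp(stats::dnorm(zl, log = TRUE) - lp)
      logf[env$lo, j] <- lp
      dmu[env$lo, j] <- -mills / sigma
      dls[env$lo, j] <- -zl * mills
    }
    if (any(env$hi)) {
      zh <- (env$ymax - mu[env$hi]) / sigma
      lp <- stats::pnorm(zh, lower.tail = FALSE, log.p = TRUE)
      mills <- exp(stats::dnorm(zh, log = TRUE) - lp)
      logf[env$hi, j] <- lp
      dmu[env$hi, j] <- mills / sigma
      dls[env$hi, j] <- zh * mills
    }
  }
  Lmat <- rowsum(logf, env$pidx, reorder = TRUE)     # n x J
  lpi <- log_pi_matrix(params, env)
  s <- lpi + Lmat
  smax <- apply(s, 1, max)
  ll <- sum(smax + log(rowSums(exp(s - smax))))
  r <- exp(s - smax)
  r <- r / rowSums(r)                                # posteriors, n x J
  robs <- r[env$pidx, , drop = FALSE]                # expanded to obs

  grad <- numeric(length(par))
  k <- 0
  if (J > 1) {
    resid <- r - exp(lpi)                            # n x J
    for (j in seq_len(J - 1)) {
      grad[k + seq_len(env$pm)] <- colSums(resid[, j] * env$Xm)
      k <- k + env$pm
    }
  }
  for (j in seq_len(J)) {
    wgt <- robs[, j] * dmu[, j]
    nb <- env$orders[j] + 1
    grad[k + seq_len(nb)] <- colSums(wgt * env$U[, seq_len(nb), drop = FALSE])
    k <- k + nb
  }
  if (env$ncov) {
    for (j in seq_len(J)) {
      grad[k + seq_len(env$ncov)] <- colSums(robs[, j] * dmu[, j] * env$W)
      k <- k + env$ncov
    }
  }
  grad[k + 1] <- sum(robs * dls)
  list(loglik = ll, grad = grad)
}

# One quasi-Newton run from a packed start.  BFGS in chunks so the
# improvement path of the reported objective can be recorded.
optimize_start <- function(par, env, tol, max_iter, chunk = 50) {
  negll <- function(p) {
    v <- tryCatch(-gbtm_loglik_env(unpack_params(p, env), env),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  neggr <- function(p) {
    g <- tryCatch(-gbtm_loglik_grad(p, env)$grad, error = function(e) NULL)
    if (is.null(g) || !all(is.finite(g))) numeric(length(p)) else g
  }
  trace <- -negll(par)
  used <- 0
  converged <- FALSE
  while (used < max_iter) {
    res <- tryCatch(
      stats::optim(par, negll, gr = neggr, method = "BFGS",
                   control = list(maxit = min(chunk, max_iter - used),
                                  reltol = tol)),
      error = function(e) NULL)
    if (is.null(res)) break
    par <- res$par
    ll <- -res$value
    used <- used + min(chunk, max_iter - used)
    trace <- c(trace, ll)
    prev <- trace[length(trace) - 1]
    if (res$convergence == 0 || abs(ll - prev) < tol * (abs(ll) + 0.1)) {
      converged <- TRUE
      break
    }
  }
  list(par = par, loglik = trace[length(trace)], trace = trace,
       converged = converged, iterations = used)
}

#' Fit a group-based trajectory model
#'
#' Maximizes the censored-normal mixture log-likelihood by quasi-Newton
#' (BFGS) iteration from `n_starts` initializations (a k-means split of
#' per-patient mean outcome, perturbed per start), keeping the best local
#' optimum.  Groups are then relabeled in ascending order of time-averaged
#' fitted trajectory, so group 1 is the lowest-burden group.  Standard
#' errors come from the observed information (numerical Hessian) at the
#' optimum.
#'
#' @param data a `symtraj_data` object from [build_longitudinal_dataset()].
#' @param spec a [trajectory_spec()].
#' @param n_starts number of random starts (default 10).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum BFGS iterations per start (default 500).
#' @param seed master seed; per-start seeds are derived from it.
#' @param x_membership optional numeric matrix (one row per patient, in
#'   dataset patient order) of baseline covariates entered into the
#'   membership logits for joint estimation (stage-3 modeling).
#' @param compute_se compute the numerical Hessian and standard errors
#'   (default TRUE; disable for speed in large ladders).
#' @return object of class `gbtm_fit`; see [posterior_matrix()],
#'   [predict_trajectory()], [adequacy_diagnostics()], [bic_score()].
#' @export
fit_gbtm <- function(data, spec, n_starts = 10, tol = 1e-6, max_iter = 500,
                     seed = 1L, x_membership = NULL, compute_se = TRUE) {
  env <- gbtm_env(data, spec, x_membership)
  best <- NULL
  diagnostics <- list()
  n_used <- 0
  for (s in seq_len(n_starts)) {
    set.seed(seed + s)
    par0 <- init_start(env, s)
    res <- optimize_start(par0, env, tol, max_iter)
    diagnostics[[s]] <- list(start = s, loglik = res$loglik,
                             converged = res$converged)
    n_used <- s
    if (is.finite(res$loglik) &&
        (is.null(best) || res$loglik > best$loglik)) {
      best <- res
    }
    # well-separated problems converge to the same optimum repeatedly;
    # stop early once three starts agree to within tol
    lls <- vapply(diagnostics, `[[`, numeric(1), "loglik")
    top <- max(lls[is.finite(lls)])
    if (sum(abs(lls - top) < 1e-4 * (abs(top) + 1)) >= 3) break
  }
  if (is.null(best) || !is.finite(best$loglik)) {
    stop("all ", n_starts, " starts failed to produce a finite optimum; ",
         "per-start log-likelihoods: ",
         paste(vapply(diagnostics, function(d)
       format(d$loglik, digits = 6), character(1)), collapse = ", "))
  }

  params <- unpack_params(best$par, env)
  perm <- trajectory_order(params, env)
  params <- permute_params(params, perm, env)
  spec$orders <- spec$orders[perm]
  env$orders <- env$orders[perm]
  par_hat <- pack_params(params, env)

  vcov <- se <- NULL
  if (compute_se) {
    H <- tryCatch(
      stats::optimHess(par_hat, function(p)
        -gbtm_loglik_env(unpack_params(p, env), env)),
      error = function(e) NULL)
    singular <- FALSE
    if (!is.null(H)) {
      vcov <- tryCatch(solve(H), error = function(e) NULL)
      if (is.null(vcov)) {
        # near-singular information (e.g. collinear high-order terms in an
        # over-parameterized candidate): fall back to the Moore-Penrose
        # generalized inverse so Wald screening still has (wide) SEs
        sv <- svd(H)
        keep <- sv$d > max(sv$d) * 1e-10
        if (any(keep)) {
          vcov <- sv$v[, keep, drop = FALSE] %*%
            (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
          singular <- TRUE
        }
      }
      if (!is.null(vcov)) {
        d <- diag(vcov)
        se <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
      }
    }
    if (is.null(vcov)) {
      warning("observed information not invertible; standard errors unavailable")
    }
  }

  log_pi <- log_pi_matrix(params, env)
  post <- exp(log_pi + patient_loglik_matrix(params, env))
  post <- post / rowSums(post)
  dimnames(post) <- list(env$patient_ids, NULL)
  assigned <- max.col(post, ties.method = "first")
  pi_hat <- colMeans(exp(log_pi))

  fit <- structure(list(
    spec = spec,
    params = params,
    pi = pi_hat,
    loglik = best$loglik,
    n_patients = env$n,
    n_obs = length(env$y),
    n_params = n_gbtm_params(env),
    posterior = post,
    assigned_group = assigned,
    patient_ids = env$patient_ids,
    se = if (!is.null(se)) unpack_se(se, env) else NULL,
    vcov = vcov,
    par = par_hat,
    converged = best$converged,
    n_starts_used = n_used,
    start_diagnostics = diagnostics,
    trace = best$trace,
    time_scale = TIME_SCALE,
    months_range = range(data$obs$months),
    bounds = c(env$ymin, env$ymax),
    has_membership_covariates = env$pm > 1),
    class = "gbtm_fit")
  fit
}

# ascending time-averaged trajectory level over the observed time points
trajectory_order <- function(params, env) {
  levels <- vapply(seq_len(env$J), function(j) {
    mean(env$U[, seq_len(env$orders[j] + 1), drop = FALSE] %*%
           params$beta[[j]])
  }, numeric(1))
  order(levels)
}

permute_params <- function(params, perm, env) {
  J <- env$J
  gamma_full <- rbind(params$theta, 0)            # J x pm, reference last
  gf <- gamma_full[perm, , drop = FALSE]
  theta <- sweep(gf[-J, , drop = FALSE], 2, gf[J, ], "-")
  list(theta = theta,
       beta = params$beta[perm],
       alpha = params$alpha[perm, , drop = FALSE],
       sigma = params$sigma)
}

unpack_se <- function(se, env) {
  u <- unpack_params(se, env)
  u$sigma <- se[length(se)]  # SE of log(sigma); delta applied on report
  u
}

#' @export
print.gbtm_fit <- function(x, ...) {
  cat("Censored-normal group-based trajectory model\n")
  cat("  ", format(x$spec), "\n", sep = "")
  cat("  patients: ", x$n_patients, ", observations: ", x$n_obs, "\n", sep = "")
  cat("  log-likelihood: ", format(x$loglik, digits = 8),
      "  (", x$n_params, " parameters)\n", sep = "")
  cat("  group probabilities:",
      paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("  residual SD:", sprintf("%.4f", x$params$sigma), "\n")
  if (!x$converged) cat("  WARNING: optimizer did not meet tolerance\n")
  invisible(x)
}

#' @export
summary.gbtm_fit <- function(object, ...) {
  tab <- coef_table(object)
  cat("Group-based trajectory model (", format(object$spec), ")\n", sep = "")
  cat("log-likelihood ", format(object$loglik, digits = 8),
      ", BIC ", format(bic_score(object), digits = 8), "\n\n", sep = "")
  print(tab, row.names = FALSE, digits = 4)
  invisible(tab)
}

#' Coefficient table for a fitted trajectory model
#'
#' One row per estimated polynomial or covariate coefficient with standard
#' error, Wald z statistic and two-sided p-value, in the style of trajectory
#' model parameter tables.
#'
#' @param fit a `gbtm_fit`.
#' @return data frame with columns `group`, `term`, `estimate`, `se`,
#'   `z`, `p_value`.
#' @export
coef_table <- function(fit) {
  poly_names <- c("intercept", "linear", "quadratic", "cubic", "quartic")
  rows <- list()
  for (j in seq_len(fit$spec$n_groups)) {
    nb <- fit$spec$orders[j] + 1
    rows[[length(rows) + 1]] <- data.frame(
      group = j, term = poly_names[seq_len(nb)],
      estimate = fit$params$beta[[j]],
      se = if (!is.null(fit$se)) fit$se$beta[[j]] else NA_real_)
    if (ncol(fit$params$alpha)) {
      rows[[length(rows) + 1]] <- data.frame(
        group = j, term = colnames(fit$params$alpha),
        estimate = fit$params$alpha[j, ],
        se = if (!is.null(fit$se)) fit$se$alpha[j, ] else NA_real_)
    }
  }
  tab <- do.call(rbind, rows)
  tab$z <- tab$estimate / tab$se
  tab$p_value <- 2 * stats::pnorm(-abs(tab$z))
  rownames(tab) <- NULL
  tab
}

#' Posterior group-membership probabilities
#'
#' Entry (i, j) is `pi_j L_ij / sum_k pi_k L_ik`, the posterior probability
#' that patient i belongs to group j given their observed series; rows sum
#' to 1.
#'
#' @param fit a `gbtm_fit`.
#' @param data optional `symtraj_data` to score; defaults to the posterior
#'   computed on the training data at fit time.
#' @return `n_patients x J` matrix.
#' @export
posterior_matrix <- function(fit, data = NULL) {
  if (is.null(data)) return(fit$posterior)
  if (fit$has_membership_covariates) {
    stop("scoring new data is not supported for fits with membership covariates")
  }
  spec <- fit$spec
  spec$cnorm_min <- fit$bounds[1]
  spec$cnorm_max <- fit$bounds[2]
  env <- gbtm_env(data, spec)
  post <- exp(log_pi_matrix(fit$params, env) +
                patient_loglik_matrix(fit$params, env))
  post <- post / rowSums(post)
  dimnames(post) <- list(env$patient_ids, NULL)
  post
}

#' Predicted mean trajectory with pointwise confidence band
#'
#' Evaluates a group's mean transformed-TSDS trajectory on a time grid for
#' a given covariate profile, with a delta-method pointwise 95% confidence
#' interval from the coefficient covariance.
#'
#' @param fit a `gbtm_fit` (fitted with `compute_se = TRUE` for the CI).
#' @param group group index in 1..J.
#' @param months numeric vector of months since diagnosis.
#' @param covariate_profile named 0/1 vector over the fitted time-varying
#'   covariates; default all zero (the pure polynomial).
#' @param level confidence level (default 0.95).
#' @return data frame with `months`, `mean`, `se`, `lower`, `upper`.
#' @export
predict_trajectory <- function(fit, group, months,
                               covariate_profile = NULL, level = 0.95) {
  J <- fit$spec$n_groups
  if (group < 1 || group > J) stop("group must lie in 1..", J)
  if (any(months < fit$months_range[1] - 1e-9 |
            months > fit$months_range[2] + 1e-9)) {
    warning("extrapolating outside the fitted time range [",
            sprintf("%.2f", fit$months_range[1]), ", ",
            sprintf("%.2f", fit$months_range[2]), "] months")
  }
  u <- months / fit$time_scale
  nb <- fit$spec$orders[group] + 1
  X <- outer(u, 0:(nb - 1), `^`)
  ncov <- ncol(fit$params$alpha)
  w <- numeric(ncov)
  if (!is.null(covariate_profile) && ncov) {
    nm <- colnames(fit$params$alpha)
    w <- as.numeric(covariate_profile[nm])
    w[is.na(w)] <- 0
  }
  mu <- drop(X %*% fit$params$beta[[group]]) +
    if (ncov) sum(w * fit$params$alpha[group, ]) else 0

  se <- rep(NA_real_, length(months))
  if (!is.null(fit$vcov)) {
    idx <- param_index(fit, group)
    V <- fit$vcov[c(idx$beta, idx$alpha), c(idx$beta, idx$alpha), drop = FALSE]
    G <- if (ncov) {
      cbind(X, matrix(rep(w, each = length(months)), ncol = ncov))
    } else X
    se <- sqrt(pmax(rowSums((G %*% V) * G), 0))
  }
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(months = months, mean = mu, se = se,
             lower = mu - zq * se, upper = mu + zq * se)
}

# positions of group j's beta and alpha entries in the packed parameter
# vector (and thus in vcov)
param_index <- function(fit, group) {
  env_orders <- fit$spec$orders
  J <- fit$spec$n_groups
  pm <- if (fit$has_membership_covariates)
    (length(fit$par) - sum(env_orders + 1) -
       J * ncol(fit$params$alpha) - 1) / (J - 1) else 1
  k <- (J - 1) * pm
  beta_start <- k + c(0, cumsum(env_orders + 1))[group]
  beta_idx <- beta_start + seq_len(env_orders[group] + 1)
  k <- k + sum(env_orders + 1)
  ncov <- ncol(fit$params$alpha)
  alpha_idx <- if (ncov) k + (group - 1) * ncov + seq_len(ncov) else integer(0)
  list(beta = beta_idx, alpha = alpha_idx)
}
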