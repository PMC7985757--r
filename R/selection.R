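#' @title Model selection and adequacy diagnostics
#' @name model_selection
#' @description
#' The iterative search over the number of trajectory groups and per-group
#' polynomial orders: grow the number of groups (all quartic) while the log
#' Bayes factor against the previous model exceeds 10, then step each
#' group's order down while its highest-order coefficient is
#' non-significant, and finally check classification adequacy (AvePP, OCC,
#' agreement of estimated probabilities with assigned proportions).
NULL

#' Bayesian information criterion of a trajectory fit
#'
#' Uses the trajectory-modeling convention `BIC = loglik - (k/2) log(N)`
#' with N the number of patients, so *higher* BIC indicates better fit and
#' twice a BIC difference approximates the log Bayes factor.
#'
#' @param fit a converged `gbtm_fit`.
#' @return scalar BIC.
#' @export
bic_score <- function(fit) {
  if (!isTRUE(fit$converged)) {
    stop("BIC requested for a non-converged fit")
  }
  fit$loglik - 0.5 * fit$n_params * log(fit$n_patients)
}

#' Log Bayes factor approximated from two BIC values
#'
#' `2 * (bic_complex - bic_simple)` on the higher-is-better BIC convention;
#' values above 10 are conventionally strong evidence for the more complex
#' model.
#'
#' @param bic_simple BIC of the simpler (fewer-parameter) model.
#' @param bic_complex BIC of the more complex model.
#' @return scalar approximation to `2 log B`.
#' @export
log_bayes_factor <- function(bic_simple, bic_complex) {
  2 * (bic_complex - bic_simple)
}

#' Classification adequacy diagnostics
#'
#' For each group: the average posterior probability (AvePP) among patients
#' assigned to the group, the odds of correct classification
#' `OCC_j = [AvePP_j / (1 - AvePP_j)] / [pi_j / (1 - pi_j)]`, the estimated
#' membership probability `pi_j`, the assigned proportion `P_j`, and
#' `|pi_j - P_j|`.  Conventional adequacy thresholds are AvePP > 0.7 and
#' OCC > 5 with `|pi - P|` near zero.
#'
#' @param fit a `gbtm_fit`.
#' @param avepp_threshold,occ_threshold pass/fail thresholds (defaults 0.7
#'   and 5).
#' @return data frame of class `adequacy_report`, one row per group, with
#'   columns `group`, `n_assigned`, `membership_pct`, `avepp`, `occ`,
#'   `pi_hat`, `p_assigned`, `abs_diff`, `pass_avepp`, `pass_occ`.  Empty
#'   groups get `NA` AvePP/OCC.
#' @export
adequacy_diagnostics <- function(fit, avepp_threshold = 0.7,
                                 occ_threshold = 5) {
  J <- fit$spec$n_groups
  post <- fit$posterior
  assigned <- fit$assigned_group
  n <- fit$n_patients
  out <- data.frame(group = seq_len(J))
  out$n_assigned <- tabulate(assigned, J)
  out$membership_pct <- 100 * out$n_assigned / n
  out$avepp <- vapply(seq_len(J), function(j) {
    idx <- assigned == j
    if (!any(idx)) NA_real_ else mean(post[idx, j])
  }, numeric(1))
  out$pi_hat <- fit$pi
  odds <- function(p) p / (1 - p)
  out$occ <- odds(out$avepp) / odds(out$pi_hat)
  out$p_assigned <- out$n_assigned / n
  out$abs_diff <- abs(out$pi_hat - out$p_assigned)
  out$pass_avepp <- !is.na(out$avepp) & out$avepp > avepp_threshold
  out$pass_occ <- !is.na(out$occ) & out$occ > occ_threshold
  class(out) <- c("adequacy_report", "data.frame")
  out
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat("Classification adequacy\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# Wald p-value of a group's highest-order polynomial coefficient.
highest_order_p <- function(fit, group) {
  if (is.null(fit$se)) return(NA_real_)
  b <- fit$params$beta[[group]]
  s <- fit$se$beta[[group]]
  k <- length(b)
  2 * stats::pnorm(-abs(b[k] / s[k]))
}

#' Iterative group-number and polynomial-order selection
#'
#' Stage 1 grows the number of groups from 1, all groups quartic, while the
#' log Bayes factor of J groups against J - 1 exceeds 10 (and `max_groups`
#' is not exceeded).  Stage 2 holds the selected group count and repeatedly
#' sweeps groups left to right, reducing a group's polynomial order by one
#' whenever its highest-order coefficient is non-significant at `alpha`
#' (Wald test), until a full sweep makes no change.  Every candidate fit is
#' recorded with its BIC and log Bayes factor; secondary criteria (group
#' membership at least 5%, adequacy thresholds) are reported as notes, not
#' used for automatic rejection.
#'
#' @param data a `symtraj_data`.
#' @param max_groups largest group count to consider.
#' @param max_order starting polynomial order for every group (default 4).
#' @param alpha significance level for the order step-down Wald tests.
#' @param n_starts,tol,max_iter passed to [fit_gbtm()].
#' @param seed master seed; candidate fits derive their multi-start seeds
#'   from it, so the whole search is deterministic given data and seed.
#' @param tv_covariates time-varying covariates carried in every candidate.
#' @param min_membership_pct advisory minimum group share in percent.
#' @return object of class `model_ladder`: list with `candidates` (data
#'   frame: stage, n_groups, orders, loglik, n_params, bic,
#'   log_bayes_factor), `fits` (list of `gbtm_fit`s), `selected` (index
#'   into candidates), `fit` (the selected fit) and `notes`.
#' @export
select_model <- function(data, max_groups = 6, max_order = 4, alpha = 0.05,
                         n_starts = 4, tol = 1e-6, max_iter = 500,
                         seed = 1L, tv_covariates = character(0),
                         min_membership_pct = 5) {
  candidates <- list()
  fits <- list()
  notes <- character(0)
  add_candidate <- function(stage, fit, lbf) {
    candidates[[length(candidates) + 1]] <<- data.frame(
      stage = stage, n_groups = fit$spec$n_groups,
      orders = paste(fit$spec$orders, collapse = ""),
      loglik = fit$loglik, n_params = fit$n_params,
      bic = bic_score(fit), log_bayes_factor = lbf)
    fits[[length(fits) + 1]] <<- fit
  }

  # a candidate "fails" if it errors or does not meet tolerance
  fit_candidate <- function(spec, seed) {
    tryCatch({
      f <- fit_gbtm(data, spec, n_starts = n_starts, tol = tol,
                    max_iter = max_iter, seed = seed)
      if (!f$converged) stop("did not converge within max_iter")
      f
    }, error = function(e) e)
  }

  # stage 1: grow J with all orders at max_order
  prev_bic <- NULL
  chosen <- NULL
  for (J in seq_len(max_groups)) {
    fit <- fit_candidate(trajectory_spec(J, max_order,
                                         tv_covariates = tv_covariates),
                         seed + 97L * J)
    if (inherits(fit, "error")) {
      notes <- c(notes, paste0("fit failure at J=", J, ": ",
                               conditionMessage(fit)))
      warning("candidate fit failed at J = ", J, "; ladder continues")
      break
    }
    lbf <- if (is.null(prev_bic)) NA_real_
           else log_bayes_factor(prev_bic, bic_score(fit))
    add_candidate("groups", fit, lbf)
    if (!is.null(prev_bic) && lbf <= 10) {
      notes <- c(notes, paste0("stopped growing at J=", J,
                               " (log Bayes factor ", sprintf("%.2f", lbf),
                               " <= 10); keeping J=", J - 1))
      break
    }
    chosen <- fit
    prev_bic <- bic_score(fit)
  }
  if (is.null(chosen)) stop("no candidate model could be fitted")

  # stage 2: step down polynomial orders
  current <- chosen
  repeat {
    changed <- FALSE
    for (j in seq_len(current$spec$n_groups)) {
      while (current$spec$orders[j] > 0) {
        p <- highest_order_p(current, j)
        if (is.na(p) || p < alpha) break
        orders_new <- current$spec$orders
        orders_new[j] <- orders_new[j] - 1
        cand <- fit_candidate(
          trajectory_spec(current$spec$n_groups, orders_new,
                          tv_covariates = tv_covariates),
          seed + 977L + 31L * j + sum(orders_new))
        if (inherits(cand, "error")) {
          notes <- c(notes, paste0("step-down fit failure at orders ",
                                   paste(orders_new, collapse = ""), ": ",
                                   conditionMessage(cand)))
          break
        }
        add_candidate("orders", cand,
                      log_bayes_factor(bic_score(current), bic_score(cand)))
        current <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  adequacy <- adequacy_diagnostics(current)
  if (any(adequacy$membership_pct < min_membership_pct)) {
    notes <- c(notes, paste0("group(s) ",
                             paste(which(adequacy$membership_pct <
                                           min_membership_pct), collapse = ","),
                             " below ", min_membership_pct, "% membership"))
  }
  if (!all(adequacy$pass_avepp & adequacy$pass_occ)) {
    notes <- c(notes, "one or more groups fail AvePP/OCC adequacy thresholds")
  }

  cand_df <- do.call(rbind, candidates)
  selected <- which(cand_df$n_groups == current$spec$n_groups &
                      cand_df$orders == paste(current$spec$orders,
                                              collapse = ""))
  selected <- selected[length(selected)]
  structure(list(candidates = cand_df, fits = fits, selected = selected,
                 fit = current, adequacy = adequacy, notes = notes),
            class = "model_ladder")
}

#' @export
print.model_ladder <- function(x, ...) {
  cat("Trajectory model selection ladder\n")
  print.data.frame(x$candidates, row.names = FALSE, digits = 8)
  sel <- x$candidates[x$selected, ]
  cat("selected:", sel$n_groups, "group(s), orders", sel$orders, "\n")
  if (length(x$notes)) cat("notes:\n", paste(" -", x$notes, collapse = "\n"),
                           "\n")
  invisible(x)
}
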