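#' Multinomial regression of trajectory group on baseline covariates
#'
#' Stage-2 membership modeling: regresses assigned trajectory group on
#' time-fixed baseline covariates with a multinomial logit (group 1 as the
#' reference outcome) and reports Wald tests per coefficient.  The fitted
#' coefficients can subsequently be entered into joint estimation via the
#' `x_membership` argument of [fit_gbtm()] (stage 3).
#'
#' @param groups integer vector of assigned groups (or a `gbtm_fit`, from
#'   which assignments are taken).
#' @param covariates data frame of baseline covariates, one row per patient
#'   in the same order.
#' @return list of class `membership_fit` with `model` (the underlying
#'   multinomial fit), `coefficients` (data frame: group, term, estimate,
#'   se, z, p_value) and `fitted_probs`.
#' @export
membership_model <- function(groups, covariates) {
  if (inherits(groups, "gbtm_fit")) groups <- groups$assigned_group
  groups <- as.integer(groups)
  if (length(unique(groups)) < 2) {
    stop("membership model needs at least 2 groups present")
  }
  if (is.null(covariates)) covariates <- data.frame(row.names =
                                                      seq_along(groups))
  if (nrow(covariates) != length(groups)) {
    stop("covariates must have one row per patient")
  }
  df <- cbind(data.frame(.group = factor(groups)), covariates)
  # single-level covariates make the design degenerate; name the culprit
  for (nm in names(covariates)) {
    if (length(unique(stats::na.omit(covariates[[nm]]))) < 2) {
      stop("covariate '", nm, "' has a single level; drop it")
    }
  }
  form <- if (ncol(covariates)) .group ~ . else .group ~ 1
  fit <- nnet::multinom(form, data = df, trace = FALSE, maxit = 500)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, 1, dimnames = list(
    levels(df$.group)[2], names(cf)))
  se <- tryCatch({
    s <- summary(fit)$standard.errors
    if (is.null(dim(s))) matrix(s, 1, dimnames = dimnames(cf)) else s
  }, error = function(e) cf * NA)
  big <- abs(cf) > 15 | se > 100
  if (any(big, na.rm = TRUE)) {
    culprit <- colnames(cf)[which(apply(big, 2, any))[1]]
    stop("apparent separation or degenerate design involving '",
         culprit, "'")
  }
  tab <- data.frame(group = rep(rownames(cf), ncol(cf)),
                    term = rep(colnames(cf), each = nrow(cf)),
                    estimate = as.vector(cf), se = as.vector(se))
  tab$z <- tab$estimate / tab$se
  tab$p_value <- 2 * stats::pnorm(-abs(tab$z))
  structure(list(model = fit, coefficients = tab,
                 fitted_probs = stats::fitted(fit)),
            class = "membership_fit")
}

#' @export
print.membership_fit <- function(x, ...) {
  cat("Multinomial membership model\n")
  print.data.frame(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}
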