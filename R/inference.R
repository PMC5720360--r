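#' Fit a network meta-analysis model
#'
#' Estimates the variance components by the chosen method, then
#' estimates the basic parameters (average effects of every treatment
#' relative to the network reference) by generalized least squares with
#' the estimated total covariance plugged in.  The weights are treated
#' as fixed and known at this stage, so confidence intervals use normal
#' quantiles.  A table of all pairwise treatment comparisons is
#' derived from the basic parameters and their covariance matrix.
#'
#' @param net An [assemble_network()] result.
#' @param method `"pm"`, `"dl"`, `"reml"`, or `"ml"`.
#' @param model `"full"` (random inconsistency effects) or
#'   `"consistency"` (no inconsistency, tau_omega^2 = 0).
#' @param level Confidence level for Wald intervals.
#' @return An object of class `"nma_fit"` with components `est` (the
#'   variance-component estimation result), `gls` (the plug-in GLS
#'   fit), `basic` (data frame of basic parameters), `pairwise` (data
#'   frame over all ordered treatment pairs), and `q` (the Q
#'   decomposition of the data).
#' @examples
#' blocks <- list(
#'   contrast_block("s1", "A", "B", 0.4, 0.04),
#'   contrast_block("s2", "A", "B", 0.1, 0.09),
#'   contrast_block("s3", "B", "C", 0.3, 0.05),
#'   contrast_block("s4", "B", "C", -0.2, 0.07))
#' net <- assemble_network(blocks)
#' fit <- fit_network(net, method = "pm", model = "full")
#' fit
#' @export
fit_network <- function(net, method = c("pm", "dl", "reml", "ml"),
                        model = c("full", "consistency"), level = 0.95) {
  stopifnot(inherits(net, "nma_network"))
  method <- match.arg(method)
  model <- match.arg(model)
  stopifnot(level > 0, level < 1)
  est <- switch(method,
    pm = if (model == "full") estimate_pm_full(net) else
      estimate_pm_consistency(net),
    dl = estimate_dl(net, model),
    reml = estimate_reml(net, model, "reml"),
    ml = estimate_reml(net, model, "ml"))
  vc <- est$vc
  gls <- gls_fit(net$Y, net$X,
                 total_covariance(net, vc$tau_beta_sq, vc$tau_omega_sq))
  z <- stats::qnorm(1 - (1 - level) / 2)
  basic <- data.frame(
    treatment = names(gls$delta_hat),
    estimate = unname(gls$delta_hat),
    se = sqrt(diag(gls$cov_delta)),
    stringsAsFactors = FALSE)
  basic$lower <- basic$estimate - z * basic$se
  basic$upper <- basic$estimate + z * basic$se

  pairwise <- pairwise_table(net, gls, level)

  structure(
    list(est = est, gls = gls, basic = basic, pairwise = pairwise,
         q = q_decompose(net), reference = net$reference,
         treatments = net$treatments, level = level, net = net),
    class = "nma_fit")
}

# All ordered treatment pairs (I, J), I < J, with estimates
# delta^{AJ} - delta^{AI} and standard errors from the covariance of
# the basic parameters (the reference has estimate 0, variance 0).
pairwise_table <- function(net, gls, level) {
  trts <- net$treatments
  cT <- length(trts)
  full_est <- stats::setNames(numeric(cT), trts)
  full_cov <- matrix(0, cT, cT, dimnames = list(trts, trts))
  nonref <- names(gls$delta_hat)
  full_est[nonref] <- gls$delta_hat
  full_cov[nonref, nonref] <- gls$cov_delta
  z <- stats::qnorm(1 - (1 - level) / 2)
  pairs <- utils::combn(trts, 2)
  est <- full_est[pairs[2, ]] - full_est[pairs[1, ]]
  se <- sqrt(pmax(0,
    diag(full_cov)[pairs[1, ]] + diag(full_cov)[pairs[2, ]] -
      2 * full_cov[cbind(pairs[1, ], pairs[2, ])]))
  ref <- net$reference
  param <- ifelse(
    pairs[1, ] == ref,
    paste0("d(", ref, ",", pairs[2, ], ")"),
    paste0("d(", ref, ",", pairs[2, ], ") - d(", ref, ",", pairs[1, ],
           ")"))
  data.frame(
    treat1 = pairs[1, ], treat2 = pairs[2, ], parameters = param,
    estimate = unname(est), se = unname(se),
    lower = unname(est - z * se), upper = unname(est + z * se),
    stringsAsFactors = FALSE)
}

#' @export
print.nma_fit <- function(x, digits = 2, ...) {
  cat("Network meta-analysis fit (", x$est$method, ", ",
      x$est$model, " model)\n\n", sep = "")
  print(x$est$vc)
  cat("\nBasic parameters (relative to ", x$reference, ", ",
      format(100 * x$level), "% CI):\n", sep = "")
  b <- x$basic
  b[-1] <- lapply(b[-1], round, digits = digits)
  print(b, row.names = FALSE)
  invisible(x)
}

#' @export
summary.nma_fit <- function(object, digits = 2, ...) {
  print(object, digits = digits)
  cat("\nAll pairwise comparisons:\n")
  p <- object$pairwise
  p[c("estimate", "se", "lower", "upper")] <-
    lapply(p[c("estimate", "se", "lower", "upper")], round,
           digits = digits)
  print(p, row.names = FALSE)
  cat("\n")
  print(object$q)
  invisible(object)
}

#' Q-profile confidence interval for the heterogeneity variance under
#' the consistency model
#'
#' Inverts the chi-squared distribution of the monotone network Q pivot
#' under the consistency model: the interval bounds are the values of
#' tau_beta^2 at which the pivot crosses the upper and lower chi-squared
#' quantiles with n - c degrees of freedom.  Crossings below zero are
#' truncated to zero; if the pivot at zero is already below the lower
#' quantile, the degenerate interval [0, 0] is returned and flagged.
#'
#' @param net An [assemble_network()] result.
#' @param level Confidence level.
#' @return An object of class `"nma_vc_ci"` with `lower`, `upper`,
#'   `level`, `parameter`, `method`, and a `degenerate` flag.
#' @export
q_profile_ci_consistency <- function(net, level = 0.95) {
  stopifnot(inherits(net, "nma_network"))
  stopifnot(level > 0, level < 1)
  df <- net$n - net$c
  pivot <- spectral_pivot(net$Y, net$X, net$S, net$M1)
  alpha <- 1 - level
  q_hi <- stats::qchisq(1 - alpha / 2, df)
  q_lo <- stats::qchisq(alpha / 2, df)
  upper0 <- 1 + max(diag(net$S))
  # pivot decreasing: crossing the upper quantile gives the lower bound.
  lo <- solve_monotone(pivot, q_hi, upper0)
  hi <- solve_monotone(pivot, q_lo, upper0)
  structure(
    list(parameter = "tau_beta_sq", lower = lo$root, upper = hi$root,
         level = level, method = "q_profile_consistency",
         degenerate = hi$truncated),
    class = "nma_vc_ci")
}

#' Profile-likelihood confidence interval for a variance component
#'
#' Computes a restricted-likelihood profile interval for one variance
#' component of the full model, maximizing the restricted log-likelihood
#' over the other component at each candidate value.  The bounds are
#' where twice the drop from the maximized restricted log-likelihood
#' crosses the chi-squared(1) quantile; the lower bound is truncated at
#' zero.  If the upper crossing is not found below the search cap the
#' interval is flagged open-ended.
#'
#' @param net An [assemble_network()] result.
#' @param parameter `"tau_beta_sq"` or `"tau_omega_sq"`.
#' @param level Confidence level.
#' @param fit Optionally, a precomputed [estimate_reml()] result.
#' @return An object of class `"nma_vc_ci"`.
#' @export
profile_likelihood_ci <- function(net,
                                  parameter = c("tau_beta_sq",
                                                "tau_omega_sq"),
                                  level = 0.95, fit = NULL) {
  stopifnot(inherits(net, "nma_network"))
  parameter <- match.arg(parameter)
  stopifnot(level > 0, level < 1)
  if (is.null(fit)) fit <- estimate_reml(net, "full")
  ll_max <- fit$diagnostics$loglik
  est <- if (parameter == "tau_beta_sq") fit$vc$tau_beta_sq else
    fit$vc$tau_omega_sq
  B <- 10 * (max(fit$vc$tau_beta_sq, fit$vc$tau_omega_sq) + 1)
  crit <- stats::qchisq(level, 1)

  profile_ll <- function(val) {
    opt <- stats::optimize(function(other) {
      if (parameter == "tau_beta_sq")
        restricted_loglik(net, val, other)
      else
        restricted_loglik(net, other, val)
    }, interval = c(0, B), maximum = TRUE, tol = 1e-8)
    opt$objective
  }
  drop2 <- function(val) 2 * (ll_max - profile_ll(val)) - crit

  # Lower bound.
  lower <- 0
  if (est > 0 && drop2(0) > 0) {
    lower <- stats::uniroot(drop2, c(0, est), tol = 1e-8)$root
  }
  # Upper bound: expand from the estimate until the drop exceeds the
  # critical value, capped at B.
  open_ended <- FALSE
  hi <- max(est, 1e-3)
  while (drop2(hi) < 0 && hi < B) hi <- hi * 2
  if (hi >= B && drop2(min(hi, B)) < 0) {
    upper <- B
    open_ended <- TRUE
  } else {
    upper <- stats::uniroot(drop2, c(est, min(hi, B)), tol = 1e-8)$root
  }
  structure(
    list(parameter = parameter, lower = lower, upper = upper,
         level = level, method = "profile_likelihood",
         open_ended = open_ended, estimate = est),
    class = "nma_vc_ci")
}

#' @export
print.nma_vc_ci <- function(x, digits = 4, ...) {
  cat(sprintf("%s %.0f%% CI (%s): [%.*g, %.*g]%s\n",
              x$parameter, 100 * x$level, x$method,
              digits, x$lower, digits, x$upper,
              if (isTRUE(x$degenerate)) " (degenerate)"
              else if (isTRUE(x$open_ended)) " (upper bound open-ended)"
              else ""))
  invisible(x)
}
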