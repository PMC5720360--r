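#' Solve a monotone estimating equation for a variance component
#'
#' Finds the unique nonnegative root of `pivot(tau) = target_df` for a
#' continuous, strictly decreasing pivot function that decays to zero.
#' If `pivot(0) <= target_df` the estimate is truncated to zero.
#' Otherwise the root is bracketed by doubling an upper bound and then
#' refined by bisection until the equation residual satisfies
#' `|pivot(root) - target_df| <= 1e-10 * (1 + target_df)` (or the
#' bracket collapses below 1e-12).
#'
#' @param pivot A decreasing scalar function of a nonnegative variance.
#' @param target_df The degrees of freedom to match.
#' @param upper Initial upper bracket (doubled as needed).
#' @return A list with `root`, `truncated`, `iterations`, and
#'   `residual` (pivot(root) - target_df).
#' @export
solve_monotone <- function(pivot, target_df, upper = 1) {
  f0 <- pivot(0)
  if (!is.finite(f0))
    stop("pivot evaluation at 0 is not finite", call. = FALSE)
  if (f0 <= target_df)
    return(list(root = 0, truncated = TRUE, iterations = 0L,
                residual = f0 - target_df))
  lo <- 0
  hi <- max(upper, 1e-8)
  it <- 0L
  fhi <- pivot(hi)
  while (fhi > target_df) {
    lo <- hi
    hi <- hi * 2
    fhi <- pivot(hi)
    it <- it + 1L
    if (!is.finite(fhi)) stop("pivot evaluation is not finite",
                              call. = FALSE)
    if (it > 200L) stop("failed to bracket the estimating equation root",
                        call. = FALSE)
  }
  tol_f <- 1e-10 * (1 + abs(target_df))
  root <- hi
  fr <- fhi
  while (it < 500L) {
    mid <- (lo + hi) / 2
    fm <- pivot(mid)
    it <- it + 1L
    if (abs(fm - target_df) < abs(fr - target_df)) {
      root <- mid
      fr <- fm
    }
    # Bisect to absolute 1e-12 on the variance; the equation residual
    # alone can leave the root imprecise where the pivot is flat.
    if ((hi - lo) < 1e-12 ||
        (abs(fm - target_df) <= tol_f && (hi - lo) < 1e-10)) break
    if (fm > target_df) lo <- mid else hi <- mid
  }
  list(root = root, truncated = FALSE, iterations = it,
       residual = fr - target_df)
}

# Container for an estimation result.
estimation_result <- function(vc, method, model, diagnostics = list()) {
  structure(list(vc = vc, method = method, model = model,
                 diagnostics = diagnostics),
            class = "nma_est")
}

#' @export
print.nma_est <- function(x, ...) {
  cat("Variance component estimation (", x$method, ", ", x$model,
      " model)\n", sep = "")
  print(x$vc)
  if (!is.null(x$diagnostics$warning))
    cat("warning:", x$diagnostics$warning, "\n")
  invisible(x)
}

# Shared guard for full-model estimation.
check_full_model <- function(net) {
  if (length(net$designs) < 2L)
    stop("the full model is not identifiable with a single design: ",
         "the design mean and its inconsistency effect are aliased; ",
         "use the consistency model", call. = FALSE)
}

# Between-design (inconsistency) degrees of freedom:
# (n - c) - sum_d (n_d - 1) c_d = sum_d c_d - c.  When zero, the
# design means saturate the basic parameters and the inconsistency
# variance is not identifiable.
df_inconsistency <- function(net) {
  net$n - net$c -
    sum(vapply(net$designs, `[[`, numeric(1), "df_het"))
}

msg_no_inc_df <- paste(
  "the design means saturate the basic parameters (no between-design",
  "degrees of freedom), so the inconsistency variance is not",
  "identifiable; tau_omega^2 was set to 0")

#' Paule-Mandel estimation under the full model
#'
#' Estimates the between-study heterogeneity variance by matching the
#' sum over designs of the heterogeneity Q pivots, each weighted by the
#' total within-design precision at the candidate variance, to its
#' degrees of freedom `sum_d (n_d - 1) c_d`.  The resulting estimate is
#' then held fixed while the inconsistency variance is estimated by
#' matching the network Q pivot, weighted by the full total precision,
#' to `n - c`.  Both equations have unique roots because the pivots are
#' continuous, strictly decreasing and decay to zero; estimates at or
#' below the boundary are truncated to zero.
#'
#' @param net An [assemble_network()] result with at least two designs.
#' @return An object of class `"nma_est"`.
#' @export
estimate_pm_full <- function(net) {
  stopifnot(inherits(net, "nma_network"))
  check_full_model(net)
  df_het <- sum(vapply(net$designs, `[[`, numeric(1), "df_het"))
  upper <- 1 + max(diag(net$S))
  diag <- list()
  if (df_het == 0) {
    sol_b <- list(root = 0, truncated = TRUE, iterations = 0L,
                  residual = 0)
    diag$warning <- paste(
      "no design has replicate studies, so the full-model heterogeneity",
      "variance is not identifiable; tau_beta^2 was set to 0")
    warning(diag$warning, call. = FALSE)
  } else {
    sol_b <- solve_monotone(het_pivot_function(net), df_het, upper)
  }
  if (df_inconsistency(net) == 0) {
    sol_w <- list(root = 0, truncated = TRUE, iterations = 0L,
                  residual = 0)
    diag$warning <- paste(c(diag$warning, msg_no_inc_df),
                          collapse = "; ")
    warning(msg_no_inc_df, call. = FALSE)
  } else {
    pivot_w <- spectral_pivot(net$Y, net$X,
                              net$S + sol_b$root * net$M1, net$M2)
    sol_w <- solve_monotone(pivot_w, net$n - net$c, upper)
  }
  diag$iterations <- c(beta = sol_b$iterations, omega = sol_w$iterations)
  diag$residuals <- c(beta = sol_b$residual, omega = sol_w$residual)
  estimation_result(
    variance_components(sol_b$root, sol_w$root,
                        sol_b$truncated, sol_w$truncated),
    "PM", "full", diag)
}

#' Paule-Mandel estimation under the consistency model
#'
#' Estimates the between-study heterogeneity variance assuming no
#' inconsistency (tau_omega^2 = 0) by matching the network Q pivot,
#' weighted by (tau_beta^2 M1 + S)^{-1}, to its degrees of freedom
#' n - c.  Truncated to zero when the pivot at zero does not exceed
#' n - c.
#'
#' @param net An [assemble_network()] result.
#' @return An object of class `"nma_est"`.
#' @export
estimate_pm_consistency <- function(net) {
  stopifnot(inherits(net, "nma_network"))
  pivot <- spectral_pivot(net$Y, net$X, net$S, net$M1)
  sol <- solve_monotone(pivot, net$n - net$c, 1 + max(diag(net$S)))
  estimation_result(
    variance_components(sol$root, 0, sol$truncated, FALSE),
    "PM", "consistency",
    list(iterations = c(beta = sol$iterations),
         residuals = c(beta = sol$residual)))
}

#' Moment-matching coefficients for the DerSimonian-Laird estimator
#'
#' Under the model, the expectation of the fixed-effect network Q
#' statistic is linear in the two variance components:
#' `E[Q_net] = (n - c) + a1 * tau_beta^2 + a2 * tau_omega^2` with
#' `a_j = tr((W - W H) M_j)` for W = S^{-1} and the hat matrix
#' H = X (X'WX)^{-1} X'W.  The summed within-design heterogeneity
#' statistic has expectation
#' `sum_d (n_d-1) c_d + b1 * tau_beta^2` with
#' `b1 = sum_d tr((W_d - W_d H_d) M_d)` (the inconsistency component
#' drops out exactly because design-level effects are absorbed by the
#' design means).
#'
#' @param net An [assemble_network()] result.
#' @return A list with `a0` (= n - c), `a1`, `a2`, `b0`
#'   (= sum (n_d-1) c_d), and `b1`.
#' @export
dl_moment_coefficients <- function(net) {
  stopifnot(inherits(net, "nma_network"))
  tr_wh <- function(Y, X, S, M) {
    U <- chol(S)
    W <- chol2inv(U)
    WX <- W %*% X
    XtWX <- crossprod(X, WX)
    # tr(W M) - tr((X'WX)^{-1} (X'W M W X))
    sum(W * M) - sum(diag(solve(XtWX, crossprod(WX, M %*% WX))))
  }
  a1 <- tr_wh(net$Y, net$X, net$S, net$M1)
  a2 <- tr_wh(net$Y, net$X, net$S, net$M2)
  b1 <- sum(vapply(net$designs, function(d) {
    if (d$n_d == 1L) return(0)
    tr_wh(d$Y_d, d$X_d, d$S_d, d$M_d)
  }, numeric(1)))
  list(a0 = net$n - net$c, a1 = a1, a2 = a2,
       b0 = sum(vapply(net$designs, `[[`, numeric(1), "df_het")),
       b1 = b1)
}

#' DerSimonian-Laird moment estimation
#'
#' Closed-form method-of-moments estimation.  Under the full model, the
#' heterogeneity variance solves the moment equation for the summed
#' within-design Q statistic and is then substituted into the moment
#' equation for the network Q statistic to estimate the inconsistency
#' variance.  Under the consistency model the network moment equation is
#' solved for the heterogeneity variance alone.  Negative solutions are
#' truncated to zero.
#'
#' @param net An [assemble_network()] result.
#' @param model `"full"` or `"consistency"`.
#' @return An object of class `"nma_est"`.
#' @export
estimate_dl <- function(net, model = c("full", "consistency")) {
  stopifnot(inherits(net, "nma_network"))
  model <- match.arg(model)
  co <- dl_moment_coefficients(net)
  q_net <- q_pivot_net(net, 0, 0)$value
  diag <- list(coefficients = co)
  if (model == "consistency") {
    tb_raw <- (q_net - co$a0) / co$a1
    vc <- variance_components(max(0, tb_raw), 0, tb_raw <= 0, FALSE)
    return(estimation_result(vc, "DL", "consistency", diag))
  }
  check_full_model(net)
  q_het <- sum(vapply(net$designs, function(d) q_pivot_het(d, 0)$value,
                      numeric(1)))
  if (co$b0 == 0 || co$b1 == 0) {
    tb <- 0
    tb_trunc <- TRUE
    diag$warning <- paste(
      "no design has replicate studies, so the full-model heterogeneity",
      "variance is not identifiable; tau_beta^2 was set to 0")
    warning(diag$warning, call. = FALSE)
  } else {
    tb_raw <- (q_het - co$b0) / co$b1
    tb <- max(0, tb_raw)
    tb_trunc <- tb_raw <= 0
  }
  if (df_inconsistency(net) == 0 || co$a2 <= 1e-12) {
    diag$warning <- paste(c(diag$warning, msg_no_inc_df),
                          collapse = "; ")
    warning(msg_no_inc_df, call. = FALSE)
    tw_raw <- 0
  } else {
    tw_raw <- (q_net - co$a0 - co$a1 * tb) / co$a2
  }
  estimation_result(
    variance_components(tb, max(0, tw_raw), tb_trunc, tw_raw <= 0),
    "DL", "full", diag)
}

#' Restricted (or profile) log-likelihood of the variance components
#'
#' Evaluates the restricted log-likelihood of the stacked model at the
#' given variance components, with the basic parameters eliminated:
#' `-0.5 * (log det V + log det X'V^{-1}X + r'V^{-1}r)` where
#' `r = Y - X delta_hat(V)`; additive constants are dropped.  The
#' `"ml"` variant omits the `log det X'V^{-1}X` term, giving the profile
#' log-likelihood maximized over the basic parameters.
#'
#' @param net An [assemble_network()] result.
#' @param tau_beta_sq,tau_omega_sq Nonnegative variance components.
#' @param kind `"reml"` or `"ml"`.
#' @return The log-likelihood value (a scalar).
#' @export
restricted_loglik <- function(net, tau_beta_sq, tau_omega_sq = 0,
                              kind = c("reml", "ml")) {
  kind <- match.arg(kind)
  fit <- gls_fit(net$Y, net$X,
                 total_covariance(net, tau_beta_sq, tau_omega_sq))
  ll <- -0.5 * (fit$logdet_V + fit$q)
  if (kind == "reml") ll <- ll - 0.5 * fit$logdet_XtVinvX
  ll
}

# Objective and analytic gradient for (restricted) ML, used by the
# optimizer.  theta = (tau_beta_sq, tau_omega_sq); for the consistency
# model theta = tau_beta_sq only.
reml_obj_grad <- function(Y, X, S, M1, M2, kind, model) {
  Ms <- if (model == "full") list(M1, M2) else list(M1)
  function(theta) {
    V <- S + theta[1] * M1 +
      (if (model == "full") theta[2] else 0) * M2
    U <- chol(V)
    Vinv <- chol2inv(U)
    VinvX <- Vinv %*% X
    XtVX <- crossprod(X, VinvX)
    Uc <- chol(XtVX)
    Cinv <- chol2inv(Uc)
    delta <- Cinv %*% crossprod(VinvX, Y)
    r <- Y - X %*% delta
    Vr <- Vinv %*% r
    ll <- -0.5 * (2 * sum(log(diag(U))) + sum(r * Vr))
    if (kind == "reml") ll <- ll - sum(log(diag(Uc)))
    grad <- vapply(Ms, function(M) {
      tr1 <- sum(Vinv * M)
      tr2 <- if (kind == "reml")
        sum(Cinv * crossprod(VinvX, M %*% VinvX)) else 0
      -0.5 * (tr1 - tr2 - sum(Vr * (M %*% Vr)))
    }, numeric(1))
    list(value = ll, gradient = grad)
  }
}

#' Likelihood-based estimation of the variance components
#'
#' Maximizes the restricted (REML) or ordinary (ML) log-likelihood over
#' the nonnegative quadrant of (tau_beta^2, tau_omega^2) (or over
#' tau_beta^2 alone under the consistency model) by bounded
#' quasi-Newton search with analytic gradients.  Several starting
#' values are tried (the origin and the moment and Paule-Mandel
#' estimates) and the best converged solution is returned; the
#' convergence flag of every start is reported in the diagnostics.
#' REML is the recommended default; ML is provided for completeness but
#' is biased downwards in small samples.
#'
#' @param net An [assemble_network()] result.
#' @param model `"full"` or `"consistency"`.
#' @param kind `"reml"` or `"ml"` (for [estimate_reml()] /
#'   [estimate_ml()]).
#' @return An object of class `"nma_est"` carrying the maximized
#'   log-likelihood in its diagnostics.
#' @export
estimate_reml <- function(net, model = c("full", "consistency"),
                          kind = c("reml", "ml")) {
  stopifnot(inherits(net, "nma_network"))
  model <- match.arg(model)
  kind <- match.arg(kind)
  if (model == "full") check_full_model(net)

  pm <- suppressWarnings(
    if (model == "full") estimate_pm_full(net) else
      estimate_pm_consistency(net))
  dl <- suppressWarnings(estimate_dl(net, model))
  B <- 10 * (max(pm$vc$tau_beta_sq, pm$vc$tau_omega_sq,
                 dl$vc$tau_beta_sq, dl$vc$tau_omega_sq) + 1)

  starts <- list(c(0, 0),
                 c(dl$vc$tau_beta_sq, dl$vc$tau_omega_sq),
                 c(pm$vc$tau_beta_sq, pm$vc$tau_omega_sq))
  npar <- if (model == "full") 2L else 1L
  starts <- lapply(starts, function(s) pmin(s[seq_len(npar)], B))
  starts <- unique(lapply(starts, round, digits = 10))

  og <- reml_obj_grad(net$Y, net$X, net$S, net$M1, net$M2, kind, model)
  runs <- lapply(starts, function(s) {
    tryCatch(
      stats::optim(par = s,
                   fn = function(th) -og(th)$value,
                   gr = function(th) -og(th)$gradient,
                   method = "L-BFGS-B", lower = rep(0, npar),
                   upper = rep(B, npar),
                   control = list(factr = 1e-8 / .Machine$double.eps,
                                  maxit = 200L)),
      error = function(e) list(value = Inf, convergence = 99L,
                               par = s, message = conditionMessage(e)))
  })
  conv <- vapply(runs, function(r) r$convergence == 0L, logical(1))
  vals <- vapply(runs, function(r) -r$value, numeric(1))
  if (!any(conv)) {
    best <- which.max(vals)
    stop("likelihood optimization failed to converge from all starts; ",
         "best point found: (",
         paste(signif(runs[[best]]$par, 6), collapse = ", "),
         ")", call. = FALSE)
  }
  best <- which(conv)[which.max(vals[conv])]
  par <- runs[[best]]$par
  par[par < 1e-10] <- 0                 # snap boundary solutions
  tb <- par[1]
  tw <- if (model == "full") par[2] else 0
  estimation_result(
    variance_components(tb, tw, truncated_beta = tb == 0,
                        truncated_omega = model == "full" && tw == 0),
    toupper(kind), model,
    list(loglik = vals[best], starts = starts,
         converged = conv, convergence = TRUE,
         counts = runs[[best]]$counts))
}

#' @rdname estimate_reml
#' @export
estimate_ml <- function(net, model = c("full", "consistency")) {
  estimate_reml(net, model, kind = "ml")
}
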