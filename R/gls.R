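#' Generalized least squares fit with a known covariance matrix
#'
#' Computes the weighted regression of Y on X with weight matrix
#' V^{-1}, via Cholesky solves (V is never inverted explicitly and no
#' regularization is added: a non-positive-definite V fails loudly).
#'
#' @param Y Outcome vector (length n).
#' @param X Design matrix (n x c, full column rank).
#' @param V Positive-definite n x n covariance matrix.
#' @return An object of class `"gls_fit"` with `delta_hat`
#'   (coefficients), `cov_delta` (their covariance, `(X'V^{-1}X)^{-1}`),
#'   `fitted`, `residuals`, and `q` (the weighted residual sum of
#'   squares `r'V^{-1}r`).
#' @export
gls_fit <- function(Y, X, V) {
  X <- as.matrix(X)
  n <- length(Y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n)
    stop("dimension mismatch between Y, X and V", call. = FALSE)
  U <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is not positive definite: ",
         conditionMessage(e), call. = FALSE))
  # Whitened system: Z = U^{-T} Y, W = U^{-T} X, then OLS.
  Z <- backsolve(U, Y, transpose = TRUE)
  W <- backsolve(U, X, transpose = TRUE)
  XtVX <- crossprod(W)
  Uc <- tryCatch(chol(XtVX), error = function(e)
    stop("X'V^{-1}X is not positive definite: design matrix is rank ",
         "deficient", call. = FALSE))
  if (min(diag(Uc)) < 1e-7 * max(diag(Uc)))
    stop("X'V^{-1}X is numerically singular: design matrix is rank ",
         "deficient", call. = FALSE)
  delta <- backsolve(Uc, backsolve(Uc, crossprod(W, Z), transpose = TRUE))
  delta <- as.numeric(delta)
  names(delta) <- colnames(X)
  cov_delta <- chol2inv(Uc)
  dimnames(cov_delta) <- list(colnames(X), colnames(X))
  fitted <- as.numeric(X %*% delta)
  res <- Y - fitted
  rz <- Z - W %*% delta
  structure(
    list(delta_hat = delta, cov_delta = cov_delta, fitted = fitted,
         residuals = res, q = sum(rz^2), logdet_V = 2 * sum(log(diag(U))),
         logdet_XtVinvX = 2 * sum(log(diag(Uc)))),
    class = "gls_fit")
}

# Variance components container.
variance_components <- function(tau_beta_sq, tau_omega_sq = 0,
                                truncated_beta = FALSE,
                                truncated_omega = FALSE) {
  stopifnot(tau_beta_sq >= 0, tau_omega_sq >= 0)
  structure(list(tau_beta_sq = tau_beta_sq, tau_omega_sq = tau_omega_sq,
                 truncated_beta = truncated_beta,
                 truncated_omega = truncated_omega),
            class = "nma_vc")
}

#' @export
print.nma_vc <- function(x, ...) {
  cat(sprintf("tau_beta^2  = %.6g%s\n", x$tau_beta_sq,
              if (x$truncated_beta) " (truncated)" else ""))
  cat(sprintf("tau_omega^2 = %.6g%s\n", x$tau_omega_sq,
              if (x$truncated_omega) " (truncated)" else ""))
  invisible(x)
}

# Total covariance of the stacked model at the given components.
total_covariance <- function(net, tau_beta_sq, tau_omega_sq = 0) {
  net$S + tau_beta_sq * net$M1 + tau_omega_sq * net$M2
}

#' Network Q pivot
#'
#' Evaluates the network quadratic form at variance components
#' (tau_beta_sq, tau_omega_sq): the GLS residuals of Y on X weighted by
#' the total precision (tau_beta_sq*M1 + tau_omega_sq*M2 + S)^{-1},
#' where the same weight is used for fitting.  Under the model at the
#' true components this quantity is chi-squared with n - c degrees of
#' freedom; evaluated at (0, 0) it is the familiar fixed-effect network
#' Q statistic.
#'
#' @param net An [assemble_network()] result.
#' @param tau_beta_sq,tau_omega_sq Nonnegative variance components.
#' @return A list with `value`, `df` (= n - c), and `at` (the components
#'   used).
#' @export
q_pivot_net <- function(net, tau_beta_sq, tau_omega_sq = 0) {
  stopifnot(inherits(net, "nma_network"))
  fit <- gls_fit(net$Y, net$X, total_covariance(net, tau_beta_sq,
                                                tau_omega_sq))
  list(value = fit$q, df = net$n - net$c,
       at = variance_components(tau_beta_sq, tau_omega_sq))
}

#' Single-design heterogeneity Q pivot
#'
#' Evaluates the heterogeneity quadratic form of one design at
#' tau_beta_sq: the GLS residuals of the design's stacked contrasts
#' about the design mean, weighted by (tau_beta_sq*M_d + S_d)^{-1}.
#' Under the single-design submodel it is chi-squared with
#' (n_d - 1) * c_d degrees of freedom.  A design with a single study has
#' value 0 and df 0.
#'
#' @param design An element of `net$designs` (see [split_by_design()]).
#' @param tau_beta_sq Nonnegative heterogeneity variance.
#' @return A list with `value`, `df`, and `at`.
#' @export
q_pivot_het <- function(design, tau_beta_sq) {
  stopifnot(inherits(design, "nma_design"))
  if (design$n_d == 1L)
    return(list(value = 0, df = 0L,
                at = variance_components(tau_beta_sq)))
  fit <- gls_fit(design$Y_d, design$X_d,
                 tau_beta_sq * design$M_d + design$S_d)
  list(value = fit$q, df = design$df_het,
       at = variance_components(tau_beta_sq))
}

#' Decompose the network Q statistic
#'
#' Splits the fixed-effect network Q statistic into within-design
#' heterogeneity contributions and a between-design inconsistency
#' remainder: `Q_net = sum_d Q_het_d + Q_inc`, all evaluated at zero
#' variance components (within-study weights only).
#'
#' @param net An [assemble_network()] result.
#' @return An object of class `"q_decomposition"` with `q_net`,
#'   `q_het_by_design` (named vector), `q_het` (their sum), `q_inc`, and
#'   the associated degrees of freedom.
#' @export
q_decompose <- function(net) {
  stopifnot(inherits(net, "nma_network"))
  qn <- q_pivot_net(net, 0, 0)
  qd <- vapply(net$designs, function(d) q_pivot_het(d, 0)$value,
               numeric(1))
  df_het <- vapply(net$designs, `[[`, numeric(1), "df_het")
  structure(
    list(q_net = qn$value, q_het_by_design = qd, q_het = sum(qd),
         q_inc = qn$value - sum(qd),
         df_net = qn$df, df_het_by_design = df_het,
         df_het = sum(df_het), df_inc = qn$df - sum(df_het)),
    class = "q_decomposition")
}

#' @export
print.q_decomposition <- function(x, digits = 4, ...) {
  cat("Q decomposition (within-study weights):\n")
  tab <- data.frame(
    component = c(paste0("heterogeneity [", names(x$q_het_by_design), "]"),
                  "heterogeneity (total)", "inconsistency", "network"),
    Q = round(c(x$q_het_by_design, x$q_het, x$q_inc, x$q_net), digits),
    df = c(x$df_het_by_design, x$df_het, x$df_inc, x$df_net))
  print(tab, row.names = FALSE)
  invisible(x)
}

# ---- spectral pivot machinery ------------------------------------------
#
# Every Q pivot used for estimation has the form
#   Q(tau) = r(tau)' (base + tau * M)^{-1} r(tau)
# with r the GLS residual under the same weight.  Writing base = U'U and
# A = U^{-T} M U^{-1} = E L E', the weight becomes diagonal in the
# rotated frame, so Q(tau) is a weighted least-squares RSS with weights
# 1/(1 + tau * lambda_i).  One eigendecomposition then makes every
# subsequent evaluation O(n c^2), which root-finding and interval
# inversion exploit heavily.

spectral_basis <- function(X, base, M) {
  X <- as.matrix(X)
  U <- tryCatch(chol(base), error = function(e)
    stop("base covariance matrix is not positive definite", call. = FALSE))
  K <- backsolve(U, M, transpose = TRUE)        # U^{-T} M
  A <- t(backsolve(U, t(K), transpose = TRUE))  # U^{-T} M U^{-1}
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  list(U = U, E = eg$vectors, lam = pmax(eg$values, 0),
       W = crossprod(eg$vectors, backsolve(U, X, transpose = TRUE)))
}

pivot_from_basis <- function(basis, Y) {
  Z <- crossprod(basis$E, backsolve(basis$U, Y, transpose = TRUE))
  W <- basis$W
  lam <- basis$lam
  function(tau) {
    w <- 1 / (1 + tau * lam)
    Ww <- W * w
    delta <- solve(crossprod(Ww, W), crossprod(Ww, Z))
    r <- Z - W %*% delta
    sum(w * r^2)
  }
}

spectral_pivot <- function(Y, X, base, M) {
  pivot_from_basis(spectral_basis(X, base, M), Y)
}

# Fast evaluator for the summed heterogeneity pivot over all designs.
het_pivot_function <- function(net) {
  pivots <- lapply(net$designs, function(d) {
    if (d$n_d == 1L) return(NULL)
    spectral_pivot(d$Y_d, d$X_d, d$S_d, d$M_d)
  })
  pivots <- Filter(Negate(is.null), pivots)
  function(tau) sum(vapply(pivots, function(p) p(tau), numeric(1)))
}
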