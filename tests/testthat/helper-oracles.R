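# Independent oracles, deliberately written with brute-force methods so
# they share no code path with the package internals.

# Univariate Paule-Mandel estimate by coarse-to-fine grid scan of the
# weighted Q function (no root finder).
uni_pm_gridscan <- function(y, v, target = length(y) - 1) {
  qfun <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    sum(w * (y - mu)^2)
  }
  if (qfun(0) <= target) return(0)
  lo <- 0
  hi <- 1
  while (qfun(hi) > target) hi <- hi * 2
  for (step in c(1e-2, 1e-4, 1e-6, 1e-8)) {
    taus <- seq(lo, hi, by = step)
    qs <- vapply(taus, qfun, numeric(1))
    i <- max(which(qs > target))
    lo <- taus[i]
    hi <- taus[min(i + 1L, length(taus))]
  }
  (lo + hi) / 2
}

# Classical univariate DerSimonian-Laird estimate.
uni_dl_closed <- function(y, v) {
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2)
  max(0, (q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

# Univariate Q-profile confidence interval by grid scan.
uni_qprofile <- function(y, v, level = 0.95) {
  k <- length(y)
  qfun <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    sum(w * (y - mu)^2)
  }
  alpha <- 1 - level
  solve_q <- function(target) {
    if (qfun(0) <= target) return(0)
    hi <- 1
    while (qfun(hi) > target) hi <- hi * 2
    stats::uniroot(function(t) qfun(t) - target, c(0, hi),
                   tol = 1e-12)$root
  }
  c(lower = solve_q(stats::qchisq(1 - alpha / 2, k - 1)),
    upper = solve_q(stats::qchisq(alpha / 2, k - 1)))
}

# A univariate meta-analysis expressed as a one-design network: k
# two-arm studies of the same pair of treatments.
univariate_network <- function(y, v, trts = c("A", "B")) {
  blocks <- lapply(seq_along(y), function(i)
    contrast_block(sprintf("s%02d", i), trts[1], trts[2], y[i], v[i]))
  assemble_network(blocks)
}

# Random small connected network with simulated outcomes; used by the
# property-style tests.
random_network <- function(seed, n_studies = NULL, n_treatments = NULL,
                           tau_beta_sq = 0.3, tau_omega_sq = 0.15) {
  set.seed(seed)
  if (is.null(n_treatments)) n_treatments <- sample(3:5, 1)
  if (is.null(n_studies))
    n_studies <- sample((n_treatments + 2):(n_treatments + 8), 1)
  n3 <- min(sample(0:2, 1), n_studies - (n_treatments - 1))
  mix <- c("2" = n_studies - n3)
  if (n3 > 0) mix <- c(mix, "3" = n3)
  layout <- synthetic_layout(n_studies = n_studies,
                             n_treatments = n_treatments,
                             design_mix = mix, seed = seed)
  sim <- simulate_dataset(layout, tau_beta_sq, tau_omega_sq,
                          seed = seed + 1L)
  set_outcome(layout, sim$Y)
}

# Dense direct evaluation of a Q pivot (explicit inversion), used to
# cross-check the package's factorization-based evaluations.
q_direct <- function(Y, X, V) {
  Vi <- solve(V)
  delta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% Y)
  r <- Y - X %*% delta
  as.numeric(t(r) %*% Vi %*% r)
}
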