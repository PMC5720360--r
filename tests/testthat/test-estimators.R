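test_that("solve_monotone truncates at the boundary and finds closed-form roots", {
  sol <- solve_monotone(function(tau) 3 / (1 + tau), 5)
  expect_equal(sol$root, 0)
  expect_true(sol$truncated)
  # Boundary equality also truncates.
  expect_true(solve_monotone(function(tau) 5 / (1 + tau), 5)$truncated)

  sol <- solve_monotone(function(tau) 4 / (1 + tau), 2)
  expect_false(sol$truncated)
  expect_equal(sol$root, 1, tolerance = 1e-8)
  expect_lte(abs(sol$residual), 1e-10 * 3)
})

test_that("solve_monotone matches the univariate grid-scan oracle", {
  y <- c(0, 1, 2)
  v <- c(1, 1, 1)
  pivot <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    sum(w * (y - mu)^2)
  }
  sol <- solve_monotone(pivot, 2)
  expect_equal(sol$root, uni_pm_gridscan(y, v), tolerance = 1e-6)
})

test_that("PM consistency estimation reduces to the univariate estimator", {
  cases <- list(
    list(y = c(-0.5, 0.2, 0.9, 1.4), v = c(0.2, 0.5, 0.3, 1.1)),
    list(y = c(0, 1, 2), v = c(1, 1, 1)),
    list(y = c(0.1, 0.15, 0.05), v = c(2, 3, 4)))   # homogeneous
  for (cs in cases) {
    net <- univariate_network(cs$y, cs$v)
    est <- estimate_pm_consistency(net)
    expect_equal(est$vc$tau_beta_sq, uni_pm_gridscan(cs$y, cs$v),
                 tolerance = 1e-6)
  }
  exact <- univariate_network(c(1, 1, 1), c(1, 2, 1))
  est <- estimate_pm_consistency(exact)
  expect_equal(est$vc$tau_beta_sq, 0)
  expect_true(est$vc$truncated_beta)
})

test_that("PM full-model estimates satisfy their estimating equations", {
  for (seed in 1:12) {
    net <- random_network(seed + 400)
    est <- suppressWarnings(estimate_pm_full(net))
    df_het <- sum(vapply(net$designs, `[[`, numeric(1), "df_het"))
    if (!est$vc$truncated_beta) {
      got <- sum(vapply(net$designs, function(d)
        q_pivot_het(d, est$vc$tau_beta_sq)$value, numeric(1)))
      expect_lte(abs(got - df_het), 1e-10 * (1 + df_het))
    }
    if (!est$vc$truncated_omega) {
      got <- q_pivot_net(net, est$vc$tau_beta_sq,
                         est$vc$tau_omega_sq)$value
      expect_lte(abs(got - (net$n - net$c)),
                 1e-10 * (1 + net$n - net$c))
    }
  }
})

test_that("PM full model truncates both components on noise-free consistent data", {
  delta <- c(B = 0.5, C = -0.3)
  blocks <- list(
    contrast_block("s1", "A", "B", delta["B"], 1),
    contrast_block("s2", "A", "B", delta["B"], 2),
    contrast_block("s3", "A", "C", delta["C"], 1),
    contrast_block("s4", "A", "C", delta["C"], 1),
    contrast_block("s5", "B", "C", delta["C"] - delta["B"], 1))
  net <- assemble_network(blocks)
  est <- estimate_pm_full(net)
  expect_equal(est$vc$tau_beta_sq, 0)
  expect_equal(est$vc$tau_omega_sq, 0)
  expect_true(est$vc$truncated_beta)
  expect_true(est$vc$truncated_omega)
})

test_that("full-model estimation guards identifiability", {
  single_design <- univariate_network(c(0, 1, 2), c(1, 1, 1))
  expect_error(estimate_pm_full(single_design), "aliased")
  expect_error(estimate_dl(single_design), "aliased")
  # Two designs but no replication anywhere: warned, tau_beta^2 = 0.
  net <- assemble_network(list(
    contrast_block("s1", "A", "B", 0.4, 1),
    contrast_block("s2", "A", "C", -0.2, 1),
    contrast_block("s3", "B", "C", 0.9, 1)))
  expect_warning(est <- estimate_pm_full(net), "replicate")
  expect_equal(est$vc$tau_beta_sq, 0)
  expect_warning(dl <- estimate_dl(net), "replicate")
  expect_equal(dl$vc$tau_beta_sq, 0)

  # Design means that saturate the basic parameters leave no
  # between-design df: tau_omega^2 is unidentified and reported 0.
  sat <- assemble_network(list(
    contrast_block("s1", "A", "B", 0.2, 1),
    contrast_block("s2", "A", "B", 0.9, 1),
    contrast_block("s3", "A", "C", -0.4, 1),
    contrast_block("s4", "A", "C", 0.5, 1)))
  expect_equal(nmari:::df_inconsistency(sat), 0)
  expect_warning(pm_sat <- estimate_pm_full(sat), "saturate")
  expect_equal(pm_sat$vc$tau_omega_sq, 0)
  expect_true(pm_sat$vc$truncated_omega)
  expect_warning(dl_sat <- estimate_dl(sat), "saturate")
  expect_equal(dl_sat$vc$tau_omega_sq, 0)
  # And the Q decomposition is exact there: no inconsistency part.
  expect_equal(q_decompose(sat)$q_inc, 0, tolerance = 1e-10)
})

test_that("moment coefficients obey their structural identities", {
  # Univariate equal variances: a1 = sum(w) - sum(w^2)/sum(w) = (k-1)/v.
  k <- 5
  v <- 2
  net <- univariate_network(stats::rnorm(k), rep(v, k))
  co <- dl_moment_coefficients(net)
  expect_equal(co$a1, (k - 1) / v, tolerance = 1e-10)
  expect_equal(co$a0, net$n - net$c)

  for (seed in 1:6) {
    rnet <- random_network(seed + 500)
    co <- dl_moment_coefficients(rnet)
    expect_equal(co$a0, rnet$n - rnet$c)
    expect_gte(co$a2, 0)
    expect_gte(co$a1, 0)
    # tr((W - WH) S) = n - c, computed independently.
    W <- solve(rnet$S)
    H <- rnet$X %*% solve(t(rnet$X) %*% W %*% rnet$X,
                          t(rnet$X) %*% W)
    expect_equal(sum(diag((W - W %*% H) %*% rnet$S)),
                 rnet$n - rnet$c, tolerance = 1e-8)
    # And the coefficients match the dense-trace route.
    expect_equal(co$a1, sum(diag((W - W %*% H) %*% rnet$M1)),
                 tolerance = 1e-8)
    expect_equal(co$a2, sum(diag((W - W %*% H) %*% rnet$M2)),
                 tolerance = 1e-8)
  }
})

test_that("DL estimation reduces to the classical univariate formula", {
  y <- c(-0.2, 0.4, 1.1, 0.8)
  v <- c(0.3, 0.6, 0.4, 1.0)
  net <- univariate_network(y, v)
  est <- estimate_dl(net, model = "consistency")
  expect_equal(est$vc$tau_beta_sq, uni_dl_closed(y, v),
               tolerance = 1e-10)

  # Full model on an AB-replicated + BC-singleton network: tau_beta^2
  # comes from the replicated design alone.
  blocks <- c(lapply(seq_along(y), function(i)
    contrast_block(sprintf("s%d", i), "A", "B", y[i], v[i])),
    list(contrast_block("x1", "B", "C", 0.3, 0.5)))
  net2 <- assemble_network(blocks)
  # No between-design df here, so the tau_omega^2 warning is expected.
  est2 <- suppressWarnings(estimate_dl(net2))
  expect_equal(est2$vc$tau_beta_sq, uni_dl_closed(y, v),
               tolerance = 1e-10)
  # PM full model likewise reduces to univariate PM.
  pm2 <- suppressWarnings(estimate_pm_full(net2))
  expect_equal(pm2$vc$tau_beta_sq, uni_pm_gridscan(y, v, 3),
               tolerance = 1e-6)

  exact <- univariate_network(c(1, 1, 1, 1), c(1, 2, 1, 3))
  expect_equal(estimate_dl(exact, "consistency")$vc$tau_beta_sq, 0)
})

test_that("DL moment equations are satisfied exactly by the returned estimates", {
  for (seed in 1:8) {
    net <- random_network(seed + 600)
    est <- suppressWarnings(estimate_dl(net))
    co <- est$diagnostics$coefficients
    q_net <- q_pivot_net(net, 0, 0)$value
    q_het <- sum(vapply(net$designs, function(d)
      q_pivot_het(d, 0)$value, numeric(1)))
    if (!est$vc$truncated_beta)
      expect_equal(co$b0 + co$b1 * est$vc$tau_beta_sq, q_het,
                   tolerance = 1e-10)
    if (!est$vc$truncated_omega)
      expect_equal(co$a0 + co$a1 * est$vc$tau_beta_sq +
                     co$a2 * est$vc$tau_omega_sq, q_net,
                   tolerance = 1e-10)
  }
})

test_that("the restricted likelihood is location invariant and matches a closed form", {
  net <- random_network(777)
  shifted <- set_outcome(net, net$Y + net$X %*% rep(2.5, net$c))
  for (vc in list(c(0.1, 0.05), c(0.6, 0.3))) {
    expect_equal(restricted_loglik(net, vc[1], vc[2]),
                 restricted_loglik(shifted, vc[1], vc[2]),
                 tolerance = 1e-10)
  }

  # Univariate equal-variance closed form: with w = 1/(v + tau2),
  # ll = -0.5 * (k log(v+tau2) + log(k w) + w * sum((y - ybar)^2)).
  y <- c(0.2, 0.8, -0.4, 1.1)
  v <- 0.7
  net_u <- univariate_network(y, rep(v, length(y)))
  for (tau2 in c(0, 0.3, 1.2)) {
    k <- length(y)
    w <- 1 / (v + tau2)
    ll_hand <- -0.5 * (k * log(v + tau2) + log(k * w) +
                         w * sum((y - mean(y))^2))
    expect_equal(restricted_loglik(net_u, tau2, 0), ll_hand,
                 tolerance = 1e-10)
  }
})

test_that("REML attains at least the restricted likelihood of the moment estimates", {
  for (seed in 1:5) {
    net <- random_network(seed + 700)
    reml <- suppressWarnings(estimate_reml(net))
    ll_reml <- reml$diagnostics$loglik
    for (other in list(suppressWarnings(estimate_pm_full(net)),
                       suppressWarnings(estimate_dl(net)))) {
      ll_other <- restricted_loglik(net, other$vc$tau_beta_sq,
                                    other$vc$tau_omega_sq)
      expect_gte(ll_reml, ll_other - 1e-6)
    }
  }
})

test_that("REML agrees with an independent mixed-model implementation", {
  library(metafor)
  for (seed in c(3, 9)) {
    net <- random_network(seed + 800, n_treatments = 4,
                          tau_beta_sq = 0.4, tau_omega_sq = 0.2)
    est <- estimate_reml(net)
    dat <- data.frame(y = net$Y, study = net$row_map$study,
                      design = net$row_map$design,
                      comp = net$row_map$comparison)
    X <- net$X
    mf <- metafor::rma.mv(
      y, V = net$S, mods = ~ X - 1,
      random = list(~ comp | study, ~ comp | design),
      struct = c("CS", "CS"), rho = 0.5, phi = 0.5, data = dat)
    expect_equal(est$vc$tau_beta_sq, unname(mf$tau2),
                 tolerance = 5e-3)
    expect_equal(est$vc$tau_omega_sq, unname(mf$gamma2),
                 tolerance = 5e-3)
    fit <- gls_fit(net$Y, net$X,
                   nmari:::total_covariance(net, est$vc$tau_beta_sq,
                                            est$vc$tau_omega_sq))
    expect_equal(unname(fit$delta_hat), unname(coef(mf)),
                 tolerance = 1e-3)
  }
})

test_that("ML and REML differ in the expected direction on small samples", {
  net <- random_network(901, tau_beta_sq = 0.5, tau_omega_sq = 0.2)
  reml <- suppressWarnings(estimate_reml(net))
  ml <- suppressWarnings(estimate_ml(net))
  # ML profiles out no location parameters, so it never exceeds REML's
  # variance estimates by much; typically it is smaller.
  expect_lte(ml$vc$tau_beta_sq + ml$vc$tau_omega_sq,
             reml$vc$tau_beta_sq + reml$vc$tau_omega_sq + 1e-6)
})

test_that("variance estimates are invariant to the reference treatment", {
  net_a <- random_network(1001, n_treatments = 4)
  for (ref in c("B", "D")) {
    net_r <- assemble_network(net_a$blocks, reference = ref)
    for (f in list(function(n) suppressWarnings(estimate_pm_full(n)),
                   function(n) suppressWarnings(estimate_dl(n)),
                   estimate_pm_consistency,
                   function(n) suppressWarnings(estimate_reml(n)))) {
      e_a <- f(net_a)
      e_r <- f(net_r)
      tol <- if (e_a$method %in% c("PM", "DL")) 1e-8 else 1e-5
      expect_equal(e_a$vc$tau_beta_sq, e_r$vc$tau_beta_sq,
                   tolerance = tol)
      expect_equal(e_a$vc$tau_omega_sq, e_r$vc$tau_omega_sq,
                   tolerance = tol)
    }
  }
})
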