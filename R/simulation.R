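#' Generate a synthetic network layout
#'
#' Builds a synthetic network meta-analysis layout (treatments, designs,
#' within-study covariance matrices) for simulation studies, emulating
#' the structure of real cognitive-enhancer networks: mostly two-arm
#' studies with a few multi-arm studies, a dominant reference treatment,
#' and highly variable within-study variances.
#'
#' Per-arm variances are drawn from a log-normal distribution whose
#' parameters are calibrated so that the two-arm within-study variance
#' (the sum of two arm variances) has mean 0.53 and median 0.29.  In
#' multi-arm studies the covariance between contrasts is the baseline
#' arm's variance, as implied by the shared baseline arm.  Connectivity
#' is guaranteed by assigning a spanning set of comparisons to the first
#' studies.  The outcome vector of the returned network is identically
#' zero; it is a template whose Y is replaced by [simulate_dataset()].
#'
#' @param n_studies Total number of studies.
#' @param n_treatments Number of treatments (labelled A, B, C, ...).
#' @param design_mix Named integer vector giving the number of studies
#'   by arm count.  Must sum to `n_studies`.  The default emulates the
#'   two-arm-dominated mix of real networks: with the default
#'   `n_studies = 41` and `n_treatments = 9` it is
#'   `c("2" = 37, "3" = 3, "4" = 1)`; for smaller networks the
#'   multi-arm studies are dropped as needed.
#' @param prob_reference Probability that a non-spanning two-arm study
#'   includes the reference treatment.
#' @param log_var_mean,log_var_sd Parameters of the log-normal arm
#'   variance distribution (defaults are the calibrated values).
#' @param seed Integer seed making the layout reproducible.
#' @return An [assemble_network()] object with `Y = 0`.
#' @export
synthetic_layout <- function(n_studies = 41, n_treatments = 9,
                             design_mix = default_design_mix(n_studies,
                                                             n_treatments),
                             prob_reference = 0.5,
                             log_var_mean = -2.2712,
                             log_var_sd = 1.3735,
                             seed = 1) {
  stopifnot(n_treatments >= 2, n_studies >= 1)
  if (sum(design_mix) != n_studies)
    stop("'design_mix' must sum to 'n_studies'", call. = FALSE)
  arm_counts <- rep(as.integer(names(design_mix)), design_mix)
  if (any(arm_counts < 2) || any(arm_counts > n_treatments))
    stop("arm counts must lie in [2, n_treatments]", call. = FALSE)
  treatments <- make_treatment_labels(n_treatments)
  ref <- treatments[1L]

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  arm_counts <- sample(arm_counts)    # shuffle multi-arm positions
  # Spanning tree first: study i connects treatment i+1 to a treatment
  # already in the network, guaranteeing connectivity.
  n_span <- n_treatments - 1L
  if (n_studies < n_span)
    stop("need at least n_treatments - 1 studies to connect the ",
         "network", call. = FALSE)
  sets <- vector("list", n_studies)
  for (i in seq_len(n_studies)) {
    k <- arm_counts[i]
    if (i <= n_span) {
      new_t <- treatments[i + 1L]
      anchor <- sample(treatments[seq_len(i)], 1L)
      extra <- if (k > 2)
        sample(setdiff(treatments, c(new_t, anchor)), k - 2L) else
          character(0)
      sets[[i]] <- c(anchor, new_t, extra)
    } else if (k == 2 && stats::runif(1) < prob_reference) {
      sets[[i]] <- c(ref, sample(treatments[-1L], 1L))
    } else {
      sets[[i]] <- sample(treatments, k)
    }
  }

  blocks <- vector("list", n_studies)
  for (i in seq_len(n_studies)) {
    trts <- sort(sets[[i]])
    k <- length(trts)
    v_arm <- exp(stats::rnorm(k, log_var_mean, log_var_sd))
    S <- matrix(v_arm[1L], k - 1L, k - 1L)
    diag(S) <- v_arm[1L] + v_arm[-1L]
    blocks[[i]] <- contrast_block(sprintf("study%02d", i), trts[1L],
                                  trts[-1L], rep(0, k - 1L), S)
  }
  assemble_network(blocks, reference = ref)
}

default_design_mix <- function(n_studies, n_treatments) {
  n4 <- if (n_treatments >= 4 && n_studies >= 10) 1L else 0L
  n3 <- if (n_treatments >= 3)
    max(0L, min(3L, n_studies - n4 - (n_treatments - 1L))) else 0L
  mix <- c("2" = n_studies - n3 - n4)
  if (n3 > 0) mix <- c(mix, "3" = n3)
  if (n4 > 0) mix <- c(mix, "4" = n4)
  mix
}

make_treatment_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else
    sprintf("T%03d", seq_len(n))
}

# Deterministic substream seed for (grid point, replicate).  The affine
# map is injective over the index ranges used, so distinct
# (grid, rep) pairs get distinct seeds below 2^31.
substream_seed <- function(seed, grid_index, rep_index) {
  m <- 2147483563
  as.integer((as.numeric(seed %% m) * 40014 +
                grid_index * 1014003 + rep_index) %% m) + 1L
}

# Matrix square roots of the random-effect structures, reusable across
# replicates on a fixed layout.
sim_factors <- function(net) {
  sqrtm <- function(M) {
    eg <- eigen(M, symmetric = TRUE)
    eg$vectors %*% (t(eg$vectors) * sqrt(pmax(eg$values, 0)))
  }
  list(R1 = sqrtm(net$M1), R2 = sqrtm(net$M2), RS = t(chol(net$S)))
}

#' Simulate a dataset from the stacked model
#'
#' Draws an outcome vector from the multivariate normal with mean
#' `X delta` and covariance `tau_beta_sq*M1 + tau_omega_sq*M2 + S` on a
#' fixed network layout, by simulating the three random components
#' (heterogeneity, inconsistency, within-study error) separately so
#' that the latent draws can be retained for diagnostics.
#'
#' @param net A network layout (see [synthetic_layout()]).
#' @param tau_beta_sq,tau_omega_sq True variance components.
#' @param delta Basic-parameter vector (default all zero; the
#'   estimation of the variance components is location invariant).
#' @param seed Optional integer seed (set just before the draws).
#' @param keep_latent If `TRUE` the three latent component draws are
#'   returned alongside Y.
#' @param factors Precomputed matrix square roots from an earlier call
#'   (internal reuse across replicates).
#' @return A list with `Y` and, if requested, `latent` (components
#'   `heterogeneity`, `inconsistency`, `error` with
#'   `Y = X delta + heterogeneity + inconsistency + error`).
#' @export
simulate_dataset <- function(net, tau_beta_sq, tau_omega_sq,
                             delta = NULL, seed = NULL,
                             keep_latent = FALSE, factors = NULL) {
  stopifnot(inherits(net, "nma_network"),
            tau_beta_sq >= 0, tau_omega_sq >= 0)
  if (is.null(factors)) factors <- sim_factors(net)
  if (is.null(delta)) delta <- rep(0, net$c)
  stopifnot(length(delta) == net$c)
  if (!is.null(seed)) set.seed(seed)
  n <- net$n
  bdraw <- sqrt(tau_beta_sq) * as.numeric(factors$R1 %*% stats::rnorm(n))
  wdraw <- sqrt(tau_omega_sq) * as.numeric(factors$R2 %*% stats::rnorm(n))
  edraw <- as.numeric(factors$RS %*% stats::rnorm(n))
  Y <- as.numeric(net$X %*% delta) + bdraw + wdraw + edraw
  out <- list(Y = Y)
  if (keep_latent)
    out$latent <- list(heterogeneity = bdraw, inconsistency = wdraw,
                       error = edraw)
  out
}

# ---- fast per-replicate fitting ----------------------------------------
#
# All layout-dependent, Y-independent work is done once per layout:
# spectral bases for the heterogeneity pivots, the fixed-weight
# projection matrices behind the moment estimator, and the moment
# coefficients.  Each replicate then costs a handful of small solves.

sim_fit_context <- function(net) {
  ctx <- list(net = net)
  ctx$df_het <- sum(vapply(net$designs, `[[`, numeric(1), "df_het"))
  ctx$df_inc <- net$n - net$c - ctx$df_het
  ctx$upper <- 1 + max(diag(net$S))
  ctx$het_bases <- lapply(net$designs, function(d) {
    if (d$n_d == 1L) return(NULL)
    c(spectral_basis(d$X_d, d$S_d, d$M_d), list(rows = d$rows))
  })
  ctx$het_bases <- Filter(Negate(is.null), ctx$het_bases)
  # Fixed-weight quadratic forms: Q = Y' (W - W H) Y at V = S.
  proj <- function(X, S) {
    W <- chol2inv(chol(S))
    WX <- W %*% X
    A <- W - WX %*% solve(crossprod(X, WX), t(WX))
    (A + t(A)) / 2
  }
  ctx$A_net <- proj(net$X, net$S)
  ctx$A_het <- lapply(net$designs, function(d) {
    if (d$n_d == 1L) return(NULL)
    list(rows = d$rows, A = proj(d$X_d, d$S_d))
  })
  ctx$A_het <- Filter(Negate(is.null), ctx$A_het)
  ctx$dl <- dl_moment_coefficients(net)
  ctx
}

# Fit PM, DL and REML (full model) to one outcome vector using the
# precomputed context.  Returns per-method variance components plus the
# plug-in GLS basic-parameter estimates and standard errors.
sim_fit_methods <- function(ctx, Y, methods = c("pm", "dl", "reml"),
                            level = 0.95) {
  net <- ctx$net
  q_net0 <- as.numeric(Y %*% ctx$A_net %*% Y)
  q_het0 <- sum(vapply(ctx$A_het, function(a) {
    y <- Y[a$rows]
    as.numeric(y %*% a$A %*% y)
  }, numeric(1)))

  vcs <- list()
  if ("pm" %in% methods || "reml" %in% methods) {
    if (q_het0 <= ctx$df_het) {
      tb <- 0; tb_tr <- TRUE
    } else {
      pivots <- lapply(ctx$het_bases, function(b)
        pivot_from_basis(b, Y[b$rows]))
      sol <- solve_monotone(function(tau)
        sum(vapply(pivots, function(p) p(tau), numeric(1))),
        ctx$df_het, ctx$upper)
      tb <- sol$root; tb_tr <- sol$truncated
    }
    if (ctx$df_inc == 0) {
      solw <- list(root = 0, truncated = TRUE)
    } else {
      pw <- spectral_pivot(Y, net$X, net$S + tb * net$M1, net$M2)
      solw <- solve_monotone(pw, net$n - net$c, ctx$upper)
    }
    vcs$pm <- variance_components(tb, solw$root, tb_tr, solw$truncated)
  }
  if ("dl" %in% methods || "reml" %in% methods) {
    co <- ctx$dl
    tb_raw <- if (co$b1 > 0) (q_het0 - co$b0) / co$b1 else 0
    tb <- max(0, tb_raw)
    tw_raw <- if (ctx$df_inc == 0 || co$a2 <= 1e-12) 0 else
      (q_net0 - co$a0 - co$a1 * tb) / co$a2
    vcs$dl <- variance_components(tb, max(0, tw_raw),
                                  tb_raw <= 0, tw_raw <= 0)
  }
  if ("reml" %in% methods) {
    og <- reml_obj_grad(Y, net$X, net$S, net$M1, net$M2, "reml", "full")
    B <- 10 * (max(vcs$pm$tau_beta_sq, vcs$pm$tau_omega_sq,
                   vcs$dl$tau_beta_sq, vcs$dl$tau_omega_sq) + 1)
    starts <- unique(lapply(list(
      c(0, 0),
      c(vcs$dl$tau_beta_sq, vcs$dl$tau_omega_sq),
      c(vcs$pm$tau_beta_sq, vcs$pm$tau_omega_sq)),
      function(s) round(pmin(s, B), 10)))
    runs <- lapply(starts, function(s) {
      tryCatch(
        stats::optim(s, fn = function(th) -og(th)$value,
                     gr = function(th) -og(th)$gradient,
                     method = "L-BFGS-B", lower = c(0, 0),
                     upper = c(B, B),
                     control = list(factr = 1e-8 / .Machine$double.eps,
                                    maxit = 200L)),
        error = function(e) list(value = Inf, convergence = 99L))
    })
    conv <- vapply(runs, function(r) r$convergence == 0L, logical(1))
    if (any(conv)) {
      vals <- vapply(runs, function(r) -r$value, numeric(1))
      best <- which(conv)[which.max(vals[conv])]
      p <- runs[[best]]$par
      p[p < 1e-10] <- 0
      vcs$reml <- variance_components(p[1], p[2], p[1] == 0, p[2] == 0)
    } else {
      vcs$reml <- NULL                 # counted as a failure
    }
  }

  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list()
  for (m in intersect(methods, names(vcs))) {
    vc <- vcs[[m]]
    if (is.null(vc)) next
    fit <- gls_fit(Y, net$X,
                   total_covariance(net, vc$tau_beta_sq,
                                    vc$tau_omega_sq))
    se <- sqrt(diag(fit$cov_delta))
    out[[m]] <- list(
      vc = vc, delta = fit$delta_hat, se = se,
      lower = fit$delta_hat - z * se, upper = fit$delta_hat + z * se)
  }
  out
}

#' Run a Monte-Carlo grid over variance-component settings
#'
#' Simulates `reps` datasets at each (tau_beta^2, tau_omega^2) grid
#' point on a fixed layout, fits every requested method to each
#' replicate (all methods see identical data), and summarizes: mean and
#' empirical SD of each estimated variance component, coverage of the
#' nominal Wald confidence intervals for the basic parameters (pooled
#' across parameters and replicates), the product-moment correlations
#' between each pair of methods' estimates, and the number of
#' likelihood-fit failures.  Failed likelihood replicates are excluded
#' from that method's summaries and counted.
#'
#' @param layout A network layout, e.g. from [synthetic_layout()].
#' @param grid Data frame with columns `tau_beta_sq` and
#'   `tau_omega_sq`; defaults to the 15-point grid
#'   tau_beta^2 in \{0, 0.25, 0.5, 0.75, 1\} x
#'   tau_omega^2 in \{0, 0.25, 0.5\}.
#' @param reps Replicates per grid point.
#' @param seed Master seed; replicate (g, r) uses a deterministic
#'   substream so runs are reproducible and extensible.
#' @param methods Subset of `c("pm", "dl", "reml")`.
#' @param delta True basic parameters (default all zero).
#' @param level Nominal confidence level for the coverage computation.
#' @return An object of class `"nma_sim"`: a list with `summary` (one
#'   row per grid point and method), `correlations` (rho triples per
#'   grid point, ordered (PM-DL, PM-REML, DL-REML)), and `estimates`
#'   (per-replicate long data frame).
#' @export
run_grid <- function(layout,
                     grid = expand.grid(
                       tau_beta_sq = c(0, 0.25, 0.5, 0.75, 1),
                       tau_omega_sq = c(0, 0.25, 0.5)),
                     reps = 1000, seed = 1,
                     methods = c("pm", "dl", "reml"),
                     delta = NULL, level = 0.95) {
  stopifnot(inherits(layout, "nma_network"), reps >= 1)
  methods <- match.arg(methods, c("pm", "dl", "reml"), several.ok = TRUE)
  if (is.null(delta)) delta <- rep(0, layout$c)
  ctx <- sim_fit_context(layout)
  factors <- sim_factors(layout)
  grid <- as.data.frame(grid)

  est_rows <- vector("list", nrow(grid) * reps)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    tb <- grid$tau_beta_sq[g]
    tw <- grid$tau_omega_sq[g]
    for (r in seq_len(reps)) {
      sim <- simulate_dataset(layout, tb, tw, delta = delta,
                              seed = substream_seed(seed, g, r),
                              factors = factors)
      fits <- sim_fit_methods(ctx, sim$Y, methods, level)
      k <- k + 1L
      est_rows[[k]] <- data.frame(
        grid = g, rep = r, tau_beta_sq = tb, tau_omega_sq = tw,
        method = methods,
        est_beta = vapply(methods, function(m)
          if (is.null(fits[[m]])) NA_real_ else
            fits[[m]]$vc$tau_beta_sq, numeric(1)),
        est_omega = vapply(methods, function(m)
          if (is.null(fits[[m]])) NA_real_ else
            fits[[m]]$vc$tau_omega_sq, numeric(1)),
        covered = vapply(methods, function(m)
          if (is.null(fits[[m]])) NA_real_ else
            mean(delta >= fits[[m]]$lower & delta <= fits[[m]]$upper),
          numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  est <- do.call(rbind, est_rows)

  summ <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    do.call(rbind, lapply(methods, function(m) {
      e <- est[est$grid == g & est$method == m, ]
      ok <- !is.na(e$est_beta)
      data.frame(
        tau_beta_sq = grid$tau_beta_sq[g],
        tau_omega_sq = grid$tau_omega_sq[g], method = m,
        mean_beta = mean(e$est_beta[ok]),
        sd_beta = stats::sd(e$est_beta[ok]),
        mean_omega = mean(e$est_omega[ok]),
        sd_omega = stats::sd(e$est_omega[ok]),
        coverage = mean(e$covered[ok]),
        failures = sum(!ok), n_used = sum(ok),
        stringsAsFactors = FALSE)
    }))
  }))

  correlations <- NULL
  pairs <- list(c("pm", "dl"), c("pm", "reml"), c("dl", "reml"))
  pairs <- Filter(function(p) all(p %in% methods), pairs)
  if (length(pairs)) {
    correlations <- do.call(rbind, lapply(seq_len(nrow(grid)),
                                          function(g) {
      e <- est[est$grid == g, ]
      wide_b <- stats::reshape(
        e[c("rep", "method", "est_beta")], idvar = "rep",
        timevar = "method", direction = "wide")
      wide_w <- stats::reshape(
        e[c("rep", "method", "est_omega")], idvar = "rep",
        timevar = "method", direction = "wide")
      row <- data.frame(tau_beta_sq = grid$tau_beta_sq[g],
                        tau_omega_sq = grid$tau_omega_sq[g])
      for (p in pairs) {
        nm <- paste0("rho_beta_", p[1], "_", p[2])
        row[[nm]] <- safe_cor(wide_b[[paste0("est_beta.", p[1])]],
                              wide_b[[paste0("est_beta.", p[2])]])
        nm <- paste0("rho_omega_", p[1], "_", p[2])
        row[[nm]] <- safe_cor(wide_w[[paste0("est_omega.", p[1])]],
                              wide_w[[paste0("est_omega.", p[2])]])
      }
      row
    }))
  }

  structure(list(summary = summ, correlations = correlations,
                 estimates = est, grid = grid, reps = reps,
                 seed = seed, methods = methods, level = level),
            class = "nma_sim")
}

safe_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' @export
print.nma_sim <- function(x, digits = 3, ...) {
  cat("Monte-Carlo grid:", nrow(x$grid), "settings x", x$reps,
      "replicates; methods:", paste(x$methods, collapse = ", "), "\n")
  s <- x$summary
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], round, digits = digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Generate a synthetic arm-level dataset
#'
#' Produces an arm-level continuous-outcome study table (columns
#' `study, treatment, mean, sd, n`) on a randomly generated connected
#' layout, for use as a file-based fixture or demonstration input.
#' True effects are drawn from the stacked model at the given variance
#' components.
#'
#' @inheritParams synthetic_layout
#' @param tau_beta_sq,tau_omega_sq Variance components used to perturb
#'   the arm means.
#' @return A data frame in the continuous arm-level schema.
#' @export
synthetic_arm_table <- function(n_studies = 12, n_treatments = 4,
                                design_mix = c("2" = n_studies - 1,
                                               "3" = 1),
                                tau_beta_sq = 0.1, tau_omega_sq = 0.05,
                                seed = 1) {
  layout <- synthetic_layout(n_studies, n_treatments, design_mix,
                             seed = seed)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed + 1L)
  sim <- simulate_dataset(layout, tau_beta_sq, tau_omega_sq)
  rows <- list()
  pos <- 0L
  for (b in layout$blocks) {
    k <- length(b$comparators)
    y <- sim$Y[pos + seq_len(k)]
    pos <- pos + k
    # Recover arm-level summaries consistent with the block covariance:
    # the off-diagonal of S is the baseline arm variance.
    v_base <- if (k > 1) b$S[1L, 2L] else b$S[1L, 1L] / 2
    v_comp <- diag(b$S) - v_base
    n_arm <- pmax(2L, round(stats::runif(k + 1L, 20, 200)))
    base_mean <- stats::rnorm(1)
    rows[[length(rows) + 1L]] <- data.frame(
      study = b$study_id,
      treatment = c(b$baseline, b$comparators),
      mean = c(base_mean, base_mean + y),
      sd = sqrt(c(v_base, v_comp) * n_arm),
      n = n_arm, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
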