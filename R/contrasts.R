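#' Compound-symmetry correlation matrix with correlation one half
#'
#' Returns the k x k matrix with ones on the main diagonal and halves
#' everywhere else.  This is the correlation structure shared by the
#' random effects acting on the contrasts of a multi-arm study: all
#' contrasts are measured against a common baseline arm, so their
#' random-effect perturbations are exchangeable with correlation 1/2.
#'
#' @param k Dimension (number of contrasts); a positive integer.
#' @return A k x k symmetric positive-definite matrix.
#' @examples
#' p_matrix(3)
#' @export
p_matrix <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != round(k))
    stop("'k' must be a single integer >= 1", call. = FALSE)
  k <- as.integer(k)
  m <- matrix(0.5, k, k)
  diag(m) <- 1
  m
}

#' Construct a contrast block
#'
#' A contrast block holds one study's vector of estimated relative
#' treatment effects against a study-specific baseline arm, together
#' with its within-study covariance matrix.  Most users will create
#' blocks with [contrasts_from_binary()] or [contrasts_from_continuous()]
#' rather than calling this constructor directly; it is exported for
#' contrast-level data where effects and covariances are supplied
#' externally.
#'
#' @param study_id Study label.
#' @param baseline Baseline treatment label.
#' @param comparators Character vector of comparator treatment labels.
#' @param y Numeric vector of relative effects (comparator minus
#'   baseline on the modelling scale), one per comparator.
#' @param S Within-study covariance matrix of `y` (a scalar variance is
#'   accepted for two-arm studies).
#' @return An object of class `"contrast_block"`.
#' @export
contrast_block <- function(study_id, baseline, comparators, y, S) {
  study_id <- as.character(study_id)
  baseline <- as.character(baseline)
  comparators <- as.character(comparators)
  y <- as.numeric(y)
  S <- as.matrix(S)
  k <- length(comparators)
  if (k < 1L)
    stop("a contrast block needs at least one comparator", call. = FALSE)
  if (anyDuplicated(c(baseline, comparators)))
    stop("treatments within a study must be distinct", call. = FALSE)
  if (length(y) != k)
    stop("'y' must have one entry per comparator", call. = FALSE)
  if (!all(dim(S) == c(k, k)))
    stop("'S' must be a ", k, " x ", k, " matrix", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8 * (1 + max(abs(S))))
    stop("'S' must be symmetric", call. = FALSE)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("within-study covariance matrix is not positive definite ",
         "(study ", study_id, ")", call. = FALSE)
  structure(
    list(study_id = study_id, baseline = baseline,
         comparators = comparators, y = y, S = S,
         design_id = design_id(c(baseline, comparators))),
    class = "contrast_block")
}

#' @export
print.contrast_block <- function(x, ...) {
  cat("Contrast block: study", x$study_id,
      "| design", x$design_id, "| baseline", x$baseline, "\n")
  tab <- data.frame(comparator = x$comparators, y = x$y,
                    var = diag(x$S))
  print(tab, row.names = FALSE)
  invisible(x)
}

# Canonical design label: the sorted treatment set.
design_id <- function(treatments) {
  paste(sort(unique(as.character(treatments))), collapse = ":")
}

#' Log-odds-ratio contrasts from binary arm-level data
#'
#' Computes a study's log odds ratios of each comparator arm against the
#' baseline arm, with the within-study covariance implied by the shared
#' baseline arm: diagonal entries are the sum of the two arms' log-odds
#' variances (1/events + 1/non-events per arm) and off-diagonal entries
#' are the baseline arm's log-odds variance.
#'
#' If any cell (events or non-events) of any arm in the study is zero, a
#' continuity correction adds 0.5 to every cell of every arm of that
#' study before effects and variances are computed.
#'
#' @param arms A data frame with columns `study`, `treatment`, `events`,
#'   `total` for a single study (at least two rows).
#' @param baseline Baseline treatment label; defaults to the
#'   lexicographically smallest treatment in the study.
#' @return A [contrast_block()].
#' @export
contrasts_from_binary <- function(arms, baseline = NULL) {
  arms <- validate_arms(arms, c("study", "treatment", "events", "total"))
  if (any(arms$events < 0) || any(arms$total < 1) ||
      any(arms$events > arms$total))
    stop("binary arms require 0 <= events <= total and total >= 1",
         call. = FALSE)
  trt <- as.character(arms$treatment)
  if (is.null(baseline)) baseline <- min(trt)
  baseline <- as.character(baseline)
  if (!baseline %in% trt)
    stop("baseline '", baseline, "' not among the study's treatments",
         call. = FALSE)
  a <- as.numeric(arms$events)
  n <- as.numeric(arms$total)
  b <- n - a
  if (any(a == 0) || any(b == 0)) {      # continuity correction, whole study
    a <- a + 0.5
    b <- b + 0.5
  }
  if (any(a <= 0) || any(b <= 0))
    stop("degenerate study: an arm has no information even after ",
         "continuity correction (study ", arms$study[1L], ")", call. = FALSE)
  lo <- log(a / b)
  v <- 1 / a + 1 / b
  ib <- match(baseline, trt)
  comp <- sort(trt[-ib])
  ic <- match(comp, trt)
  y <- lo[ic] - lo[ib]
  S <- matrix(v[ib], length(comp), length(comp))
  diag(S) <- v[ib] + v[ic]
  contrast_block(arms$study[1L], baseline, comp, y, S)
}

#' Mean-difference contrasts from continuous arm-level data
#'
#' Computes a study's mean differences of each comparator arm against
#' the baseline arm.  No common-standard-deviation assumption is made:
#' the variance of each contrast is `sd_j^2/n_j + sd_b^2/n_b` and the
#' covariance between two contrasts of a multi-arm study is the baseline
#' arm's variance `sd_b^2/n_b`.
#'
#' @param arms A data frame with columns `study`, `treatment`, `mean`,
#'   `sd`, `n` for a single study (at least two rows).
#' @param baseline Baseline treatment label; defaults to the
#'   lexicographically smallest treatment in the study.
#' @return A [contrast_block()].
#' @export
contrasts_from_continuous <- function(arms, baseline = NULL) {
  arms <- validate_arms(arms, c("study", "treatment", "mean", "sd", "n"))
  if (any(arms$sd <= 0))
    stop("continuous arms require sd > 0", call. = FALSE)
  if (any(arms$n < 2))
    stop("continuous arms require n >= 2", call. = FALSE)
  trt <- as.character(arms$treatment)
  if (is.null(baseline)) baseline <- min(trt)
  baseline <- as.character(baseline)
  if (!baseline %in% trt)
    stop("baseline '", baseline, "' not among the study's treatments",
         call. = FALSE)
  v <- as.numeric(arms$sd)^2 / as.numeric(arms$n)
  ib <- match(baseline, trt)
  comp <- sort(trt[-ib])
  ic <- match(comp, trt)
  y <- as.numeric(arms$mean)[ic] - as.numeric(arms$mean)[ib]
  S <- matrix(v[ib], length(comp), length(comp))
  diag(S) <- v[ib] + v[ic]
  contrast_block(arms$study[1L], baseline, comp, y, S)
}

# Shared arm-table validation for a single study.
validate_arms <- function(arms, cols) {
  arms <- as.data.frame(arms)
  missing_cols <- setdiff(cols, names(arms))
  if (length(missing_cols))
    stop("arm table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(arms) < 2L)
    stop("a study needs at least two arms", call. = FALSE)
  if (length(unique(as.character(arms$study))) != 1L)
    stop("contrast construction expects arms from a single study",
         call. = FALSE)
  if (anyDuplicated(as.character(arms$treatment)))
    stop("duplicated treatment within study ", arms$study[1L], call. = FALSE)
  arms
}

# Re-express a contrast block relative to a different baseline treatment
# in the same design.  The linear map is exact: effects subtract the new
# baseline's effect, and the covariance transforms accordingly.
rebaseline_block <- function(block, new_baseline) {
  if (identical(block$baseline, new_baseline)) return(block)
  trts <- c(block$baseline, block$comparators)
  if (!new_baseline %in% trts)
    stop("'", new_baseline, "' is not a treatment of study ",
         block$study_id, call. = FALSE)
  new_comp <- sort(setdiff(trts, new_baseline))
  k <- length(new_comp)
  # Transformation rows: theta_t - theta_nb where theta_baseline = 0.
  TT <- matrix(0, k, length(block$comparators))
  j_nb <- match(new_baseline, block$comparators)
  for (i in seq_len(k)) {
    t_i <- new_comp[i]
    if (t_i != block$baseline)
      TT[i, match(t_i, block$comparators)] <- 1
    TT[i, j_nb] <- TT[i, j_nb] - 1
  }
  contrast_block(block$study_id, new_baseline, new_comp,
                 as.numeric(TT %*% block$y),
                 TT %*% block$S %*% t(TT))
}
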