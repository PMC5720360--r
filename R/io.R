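#' Read an arm-level CSV file
#'
#' Reads and validates arm-level study data.  Binary data use the
#' schema `study,treatment,events,total`; continuous data use
#' `study,treatment,mean,sd,n`.  Malformed rows are reported with their
#' line numbers.
#'
#' @param path Path to a comma-separated file with a header row.
#' @param kind `"binary"` or `"continuous"`.
#' @return A validated data frame of arm records with class
#'   `"arm_table"` and attribute `kind`.
#' @export
read_arm_csv <- function(path, kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- if (kind == "binary")
    c("study", "treatment", "events", "total") else
      c("study", "treatment", "mean", "sd", "n")
  missing_cols <- setdiff(cols, names(dat))
  if (length(missing_cols))
    stop("schema mismatch in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dat <- dat[cols]
  bad <- if (kind == "binary") {
    with(dat, !is.finite(events) | !is.finite(total) | events < 0 |
           total < 1 | events > total | events != round(events) |
           total != round(total))
  } else {
    with(dat, !is.finite(mean) | !is.finite(sd) | sd <= 0 |
           !is.finite(n) | n < 2)
  }
  if (any(bad))
    stop("invalid arm record(s) in ", path, " at line(s) ",
         paste(which(bad) + 1L, collapse = ", "),
         " (line numbers include the header)", call. = FALSE)
  key <- paste(dat$study, dat$treatment)
  if (anyDuplicated(key))
    stop("duplicated (study, treatment) pair(s) in ", path, ": ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  structure(dat, class = c("arm_table", "data.frame"), kind = kind)
}

#' Convert an arm-level table to contrast blocks
#'
#' Splits an arm table by study and computes each study's contrasts
#' against its (lexicographically smallest) baseline treatment.
#'
#' @param arms A data frame as returned by [read_arm_csv()], or any
#'   data frame in one of the two arm-level schemas.
#' @param kind `"binary"` or `"continuous"`; taken from the table's
#'   attribute when present.
#' @return A list of [contrast_block()] objects.
#' @export
arms_to_blocks <- function(arms, kind = attr(arms, "kind")) {
  kind <- match.arg(kind, c("binary", "continuous"))
  f <- if (kind == "binary") contrasts_from_binary else
    contrasts_from_continuous
  unname(lapply(split(as.data.frame(arms), as.character(arms$study)), f))
}

#' Read contrast-level CSV files
#'
#' Reads per-study relative effects from a long-format CSV with columns
#' `study,design,baseline,comparator,estimate` together with a
#' companion within-study covariance CSV with columns
#' `study,row,col,value` (row/col index the study's comparators in
#' their file order; only the lower or upper triangle need be given).
#'
#' @param path Path to the estimates CSV.
#' @param cov_path Path to the covariance CSV.
#' @return A list of [contrast_block()] objects.
#' @export
read_contrast_csv <- function(path, cov_path) {
  for (p in c(path, cov_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  est <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study", "design", "baseline", "comparator", "estimate")
  if (length(setdiff(need, names(est))))
    stop("schema mismatch in ", path, ": missing column(s) ",
         paste(setdiff(need, names(est)), collapse = ", "),
         call. = FALSE)
  cv <- utils::read.csv(cov_path, stringsAsFactors = FALSE)
  if (length(setdiff(c("study", "row", "col", "value"), names(cv))))
    stop("schema mismatch in ", cov_path, call. = FALSE)
  lapply(unique(est$study), function(s) {
    e <- est[est$study == s, ]
    k <- nrow(e)
    S <- matrix(NA_real_, k, k)
    cvs <- cv[cv$study == s, ]
    for (i in seq_len(nrow(cvs))) {
      S[cvs$row[i], cvs$col[i]] <- cvs$value[i]
      S[cvs$col[i], cvs$row[i]] <- cvs$value[i]
    }
    if (anyNA(S))
      stop("incomplete covariance for study ", s, call. = FALSE)
    contrast_block(s, e$baseline[1L], e$comparator, e$estimate, S)
  })
}

#' Write fit results to files
#'
#' Writes `variance_components.json` (estimates, truncation flags,
#' method, model, and diagnostics, full precision),
#' `pairwise.csv` (all pairwise comparisons with estimates, standard
#' errors, and confidence bounds), and `qdecomp.csv` (the Q
#' decomposition) into a directory.
#'
#' @param fit An [fit_network()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "nma_fit"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  vc_path <- file.path(dir, "variance_components.json")
  vc <- fit$est$vc
  jsonlite::write_json(
    list(method = fit$est$method, model = fit$est$model,
         reference = fit$reference,
         tau_beta_sq = vc$tau_beta_sq,
         tau_omega_sq = vc$tau_omega_sq,
         truncated_beta = vc$truncated_beta,
         truncated_omega = vc$truncated_omega,
         level = fit$level),
    vc_path, auto_unbox = TRUE, digits = NA)
  pw_path <- file.path(dir, "pairwise.csv")
  utils::write.csv(fit$pairwise, pw_path, row.names = FALSE)
  q_path <- file.path(dir, "qdecomp.csv")
  q <- fit$q
  utils::write.csv(
    data.frame(component = c(names(q$q_het_by_design),
                             "heterogeneity_total", "inconsistency",
                             "network"),
               Q = c(q$q_het_by_design, q$q_het, q$q_inc, q$q_net),
               df = c(q$df_het_by_design, q$df_het, q$df_inc,
                      q$df_net)),
    q_path, row.names = FALSE)
  invisible(c(vc_path, pw_path, q_path))
}

#' Dump the stacked model matrices to CSV files
#'
#' Writes Y, X, S, M1, M2 and the row map of an assembled network into
#' a directory, for external audit.
#'
#' @param net An [assemble_network()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
dump_matrices <- function(net, dir) {
  stopifnot(inherits(net, "nma_network"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(data.frame(Y = net$Y), "Y")
  wr(as.data.frame(net$X), "X")
  wr(as.data.frame(net$S), "S")
  wr(as.data.frame(net$M1), "M1")
  wr(as.data.frame(net$M2), "M2")
  wr(net$row_map, "row_map")
  invisible(paths)
}
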