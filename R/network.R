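#' Assemble the stacked network meta-analysis model
#'
#' Stacks per-study contrast blocks into the matrices of the
#' design-by-treatment interaction model with random inconsistency
#' effects: the outcome vector Y, the design matrix X mapping the basic
#' parameters (effects of each treatment relative to the network
#' reference) to the study-level contrasts, the block-diagonal
#' within-study covariance S, and the two random-effect structure
#' matrices M1 (between-study heterogeneity, blocks by study) and M2
#' (inconsistency, blocks by design).
#'
#' Rows are ordered by design, then study, then comparator, and every
#' block is re-expressed against its design's baseline treatment (the
#' lexicographically smallest treatment of the design) so that studies
#' of the same design share comparisons.
#'
#' @param blocks A list of [contrast_block()] objects, one per study.
#' @param reference Network reference treatment; defaults to the
#'   lexicographically smallest treatment label in the network.
#' @return An object of class `"nma_network"` with components `Y`, `X`,
#'   `S`, `M1`, `M2`, `row_map` (a data frame mapping each row to its
#'   design, study and comparison), `treatments`, `reference`, `c`, `n`,
#'   and `designs` (see [split_by_design()]).
#' @export
assemble_network <- function(blocks, reference = NULL) {
  if (inherits(blocks, "contrast_block")) blocks <- list(blocks)
  if (!length(blocks))
    stop("'blocks' must be a nonempty list of contrast blocks",
         call. = FALSE)
  ok <- vapply(blocks, inherits, logical(1), "contrast_block")
  if (!all(ok))
    stop("all elements of 'blocks' must be contrast_block objects",
         call. = FALSE)

  studies <- vapply(blocks, `[[`, character(1), "study_id")
  if (anyDuplicated(studies))
    stop("duplicate study id(s): ",
         paste(unique(studies[duplicated(studies)]), collapse = ", "),
         call. = FALSE)

  treatments <- sort(unique(unlist(lapply(blocks, function(b)
    c(b$baseline, b$comparators)))))
  if (is.null(reference)) reference <- treatments[1L]
  reference <- as.character(reference)
  if (!reference %in% treatments)
    stop("reference treatment '", reference, "' does not occur in the ",
         "network", call. = FALSE)

  check_connected(blocks, treatments)

  # Design baseline = smallest treatment in the design; re-express all
  # blocks accordingly so same-design studies share comparisons.
  blocks <- lapply(blocks, function(b) {
    trts <- sort(c(b$baseline, b$comparators))
    rebaseline_block(b, trts[1L])
  })

  dids <- vapply(blocks, `[[`, character(1), "design_id")
  ord <- order(dids, vapply(blocks, `[[`, character(1), "study_id"))
  blocks <- blocks[ord]
  dids <- dids[ord]

  nonref <- setdiff(treatments, reference)
  cc <- length(nonref)

  Y <- numeric(0)
  row_design <- row_study <- row_base <- row_comp <- character(0)
  for (b in blocks) {
    Y <- c(Y, b$y)
    k <- length(b$comparators)
    row_design <- c(row_design, rep(b$design_id, k))
    row_study <- c(row_study, rep(b$study_id, k))
    row_base <- c(row_base, rep(b$baseline, k))
    row_comp <- c(row_comp, b$comparators)
  }
  n <- length(Y)
  row_map <- data.frame(design = row_design, study = row_study,
                        baseline = row_base, comparator = row_comp,
                        comparison = paste(row_base, row_comp, sep = "-"),
                        stringsAsFactors = FALSE)

  # Design matrix over the basic parameters (non-reference treatments):
  # each row encodes comparator-minus-baseline.
  X <- matrix(0, n, cc, dimnames = list(NULL, nonref))
  for (i in seq_len(n)) {
    if (row_comp[i] != reference) X[i, row_comp[i]] <- 1
    if (row_base[i] != reference) X[i, row_base[i]] <- -1
  }
  if (qr(X)$rank < cc)
    stop("design matrix is rank deficient: the network does not ",
         "identify all basic parameters", call. = FALSE)

  S <- matrix(0, n, n)
  pos <- 0L
  for (b in blocks) {
    k <- length(b$comparators)
    idx <- pos + seq_len(k)
    S[idx, idx] <- b$S
    pos <- pos + k
  }

  same_study <- outer(row_study, row_study, "==")
  M1 <- ifelse(same_study, 0.5, 0)
  diag(M1) <- 1
  same_design <- outer(row_design, row_design, "==")
  same_comp <- outer(row_map$comparison, row_map$comparison, "==")
  M2 <- ifelse(same_design & same_comp, 1, ifelse(same_design, 0.5, 0))
  diag(M2) <- 1

  net <- structure(
    list(Y = Y, X = X, S = S, M1 = M1, M2 = M2, row_map = row_map,
         treatments = treatments, reference = reference,
         c = cc, n = n, blocks = blocks),
    class = "nma_network")
  net$designs <- split_by_design(net)
  net
}

# Connectivity of the treatment graph (edge iff co-occurring in a
# design), by label propagation; errors naming the components.
check_connected <- function(blocks, treatments) {
  comp <- stats::setNames(seq_along(treatments), treatments)
  repeat {
    changed <- FALSE
    for (b in blocks) {
      trts <- c(b$baseline, b$comparators)
      m <- min(comp[trts])
      if (any(comp[trts] != m)) {
        comp[trts] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1L) {
    groups <- split(names(comp), comp)
    stop("network is disconnected; components: ",
         paste(vapply(groups, paste, character(1), collapse = ","),
               collapse = " | "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Split an assembled network into its single-design submodels
#'
#' For each design d the submodel stacks that design's studies: Y_d, the
#' block-diagonal S_d, the design matrix X_d (a stack of identity
#' matrices, since each study of the design estimates the same design
#' mean), and the heterogeneity structure M_d, block diagonal with the
#' compound-symmetry block [p_matrix()] per study.  The heterogeneity
#' degrees of freedom of design d are (n_d - 1) * c_d.
#'
#' @param net An [assemble_network()] result.
#' @return A list of objects of class `"nma_design"`.
#' @export
split_by_design <- function(net) {
  stopifnot(inherits(net, "nma_network"))
  out <- list()
  for (d in unique(net$row_map$design)) {
    idx <- which(net$row_map$design == d)
    studies <- unique(net$row_map$study[idx])
    n_d <- length(studies)
    c_d <- length(idx) / n_d
    X_d <- do.call(rbind, rep(list(diag(c_d)), n_d))
    M_d <- kronecker(diag(n_d), p_matrix(c_d))
    out[[d]] <- structure(
      list(design_id = d, n_d = n_d, c_d = c_d,
           Y_d = net$Y[idx], X_d = X_d,
           S_d = net$S[idx, idx, drop = FALSE], M_d = M_d,
           rows = idx, df_het = (n_d - 1) * c_d),
      class = "nma_design")
  }
  out
}

#' Replace the outcome vector of an assembled network
#'
#' Returns a copy of the network with a new stacked outcome vector,
#' keeping the layout (X, S, M1, M2, row map) fixed and updating the
#' per-design submodels consistently.  Used when simulating outcomes on
#' a fixed layout.
#'
#' @param net An [assemble_network()] result.
#' @param Y Numeric vector of length `net$n`.
#' @return The updated `"nma_network"` object.
#' @export
set_outcome <- function(net, Y) {
  stopifnot(inherits(net, "nma_network"), length(Y) == net$n)
  net$Y <- as.numeric(Y)
  for (d in names(net$designs))
    net$designs[[d]]$Y_d <- net$Y[net$designs[[d]]$rows]
  pos <- 0L
  for (i in seq_along(net$blocks)) {
    k <- length(net$blocks[[i]]$comparators)
    net$blocks[[i]]$y <- net$Y[pos + seq_len(k)]
    pos <- pos + k
  }
  net
}

#' @export
print.nma_network <- function(x, ...) {
  nd <- length(x$designs)
  cat("Network meta-analysis data:",
      length(unique(x$row_map$study)), "studies,",
      length(x$treatments), "treatments,", nd,
      if (nd == 1L) "design," else "designs,",
      x$n, "contrasts\n")
  cat("  treatments:", paste(x$treatments, collapse = ", "), "\n")
  cat("  reference: ", x$reference, "\n", sep = "")
  df_het <- sum(vapply(x$designs, `[[`, numeric(1), "df_het"))
  cat("  heterogeneity df:", df_het,
      "| network residual df:", x$n - x$c, "\n")
  invisible(x)
}
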