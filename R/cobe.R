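# ---------------------------------------------------------------------------
# Multi-run containers
# ---------------------------------------------------------------------------

#' Bundle one subject's runs into a multi-run stack
#'
#' A stack is the multi-block input to COBE: an ordered list of
#' regions x timepoints matrices, one per resting-state run, all sharing the
#' same region dimension. Timepoint counts may differ between runs.
#'
#' @param subject_id Identifier (coerced to character).
#' @param runs List of numeric matrices, regions x timepoints. Names are
#'   ignored; order defines `run_index` 1..N unless `run_index` is given.
#' @param run_index Optional integer vector of unique run indices.
#' @return An object of class `multi_run_stack` with elements `subject_id`,
#'   `runs` (list of matrices) and `run_index`.
#' @examples
#' st <- multi_run_stack("s1", list(matrix(rnorm(40), 4), matrix(rnorm(40), 4)))
#' @export
multi_run_stack <- function(subject_id, runs, run_index = seq_along(runs)) {
  if (!is.list(runs) || length(runs) < 2L)
    stop("a multi-run stack needs at least 2 runs")
  runs <- lapply(runs, as.matrix)
  P <- vapply(runs, nrow, integer(1))
  if (length(unique(P)) != 1L)
    stop("all runs of a subject must have the same number of regions")
  if (P[1] < 2L) stop("need at least 2 regions")
  if (any(vapply(runs, ncol, integer(1)) < 2L))
    stop("each run needs at least 2 timepoints")
  if (!all(vapply(runs, function(m) all(is.finite(m)), logical(1))))
    stop("run matrices must be finite")
  run_index <- as.integer(run_index)
  if (anyDuplicated(run_index)) stop("run_index values must be unique")
  structure(list(subject_id = as.character(subject_id),
                 runs = runs, run_index = run_index),
            class = "multi_run_stack")
}

#' @export
print.multi_run_stack <- function(x, ...) {
  cat(sprintf("<multi_run_stack> subject %s: %d runs, %d regions, T = %s\n",
              x$subject_id, length(x$runs), nrow(x$runs[[1]]),
              paste(vapply(x$runs, ncol, integer(1)), collapse = "/")))
  invisible(x)
}

#' COBE configuration
#'
#' @param n_components Number of common components C (>= 1).
#' @param rank_policy Per-block rank policy: `list(energy = f)` keeps the
#'   smallest rank whose singular values carry at least fraction `f` of the
#'   total squared singular values, or `list(fixed = r)` for a fixed rank.
#'   The default `energy = 0.99` keeps band-limited structure while
#'   excluding most isotropic noise directions; a full-rank block would make
#'   the common subspace degenerate, so some truncation is mandatory.
#' @param tol Numerical tolerance used for rank decisions and tie detection.
#' @param max_iter Iteration cap, kept for interface compatibility; the
#'   solver used here is a dense symmetric eigendecomposition and does not
#'   iterate.
#' @param sign_rule Sign convention label. `"max_abs_positive"` (default)
#'   flips each weight column so its largest-magnitude entry is positive,
#'   which makes between-subject component correlations comparable;
#'   `"none"` leaves the eigen-solver's signs.
#' @param demean_rows Remove each region's temporal mean before the basis
#'   is computed (default `TRUE`): components should reflect covariation,
#'   not baseline offsets.
#' @return An object of class `cobe_config`.
#' @export
cobe_config <- function(n_components = 1L,
                        rank_policy = list(energy = 0.99),
                        tol = 1e-8,
                        max_iter = 100L,
                        sign_rule = c("max_abs_positive", "none"),
                        demean_rows = TRUE) {
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be >= 1")
  validate_rank_policy(rank_policy)
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  sign_rule <- match.arg(sign_rule)
  structure(list(n_components = n_components, rank_policy = rank_policy,
                 tol = tol, max_iter = max_iter, sign_rule = sign_rule,
                 demean_rows = isTRUE(demean_rows)),
            class = "cobe_config")
}

validate_rank_policy <- function(rank_policy) {
  if (!is.list(rank_policy) || length(rank_policy) != 1L ||
      !(names(rank_policy) %in% c("energy", "fixed")))
    stop("rank_policy must be list(energy = f) or list(fixed = r)")
  if (names(rank_policy) == "energy") {
    f <- rank_policy$energy
    if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
      stop("energy fraction must lie in (0, 1]")
  } else {
    r <- rank_policy$fixed
    if (!is.numeric(r) || length(r) != 1L || r < 1 || r != round(r))
      stop("fixed rank must be a positive integer")
  }
  invisible(rank_policy)
}

# ---------------------------------------------------------------------------
# Block bases
# ---------------------------------------------------------------------------

#' Orthonormal basis of a run's leading column space
#'
#' Computes, by singular value decomposition of the (optionally
#' row-demeaned) run matrix, an orthonormal basis of the leading
#' r-dimensional column space, with r set by the rank policy.
#'
#' @param run Numeric matrix, regions x timepoints.
#' @param rank_policy See [cobe_config()].
#' @param demean_rows Remove each row's mean first.
#' @return A regions x r matrix with orthonormal columns.
#' @export
orthonormal_block_basis <- function(run, rank_policy = list(energy = 0.99),
                                    demean_rows = TRUE) {
  run <- as.matrix(run)
  validate_rank_policy(rank_policy)
  if (demean_rows) run <- run - rowMeans(run)
  total <- sum(run^2)
  if (total <= 0)
    stop("degenerate input: run matrix is all-zero after demeaning")
  if (names(rank_policy) == "fixed" &&
      rank_policy$fixed > min(dim(run)))
    stop(sprintf("invalid config: fixed rank %d exceeds min(P, T) = %d",
                 rank_policy$fixed, min(dim(run))))
  sv <- svd(run, nu = min(dim(run)), nv = 0)
  d2 <- sv$d^2
  numerical_rank <- sum(d2 > d2[1] * 1e-12)
  r <- if (names(rank_policy) == "fixed") {
    as.integer(rank_policy$fixed)
  } else {
    min(which(cumsum(d2) / sum(d2) >= rank_policy$energy * (1 - 1e-12)))
  }
  r <- max(1L, min(r, numerical_rank))
  sv$u[, seq_len(r), drop = FALSE]
}

# ---------------------------------------------------------------------------
# Common component extraction
# ---------------------------------------------------------------------------

#' Extract the common component(s) of a subject's runs (COBE)
#'
#' Models each run as the sum of a common subspace shared by all runs and a
#' run-specific subspace. The common weight columns are found
#' deterministically as the leading eigenvectors of
#' \eqn{M = \sum_n Q_n Q_n^\top}, where \eqn{Q_n} is the orthonormal basis
#' of run n's retained column space: the c-th column maximizes the summed
#' squared projection onto all blocks among unit vectors orthogonal to the
#' earlier columns. Fit scores are the eigenvalues divided by the number of
#' runs and lie in \[0, 1\]; a score of 1 means the direction lies exactly
#' inside every block's retained subspace.
#'
#' @param stack A [multi_run_stack()].
#' @param config A [cobe_config()].
#' @return An object of class `common_component` with elements
#'   `subject_id`, `weights` (P x C, orthonormal columns), `run_timecourses`
#'   (per run, T x C, the least-squares coefficients \eqn{R_n^\top \bar A}),
#'   `fit_scores` (length C, non-increasing), `eigen_gap_tied` (logical:
#'   eigenvalue C is numerically tied with eigenvalue C+1) and `config`.
#' @examples
#' a <- c(1, 1, 1, 1) / 2
#' st <- multi_run_stack("s", list(a %o% rnorm(20), a %o% rnorm(20)))
#' cc <- extract_common_components(st, cobe_config(1))
#' cc$fit_scores  # 1: the direction lies in both runs
#' @export
extract_common_components <- function(stack, config = cobe_config()) {
  stopifnot(inherits(stack, "multi_run_stack"), inherits(config, "cobe_config"))
  P <- nrow(stack$runs[[1]])
  C <- config$n_components
  if (C > P) stop("n_components cannot exceed the number of regions")
  Q <- lapply(stack$runs, orthonormal_block_basis,
              rank_policy = config$rank_policy,
              demean_rows = config$demean_rows)
  M <- matrix(0, P, P)
  for (q in Q) M <- M + tcrossprod(q)
  eig <- eigen(M, symmetric = TRUE)
  achievable <- sum(eig$values > config$tol)
  if (C > achievable)
    stop(sprintf(
      "n_components = %d exceeds the rank of the summed projector (achievable maximum: %d)",
      C, achievable))
  W <- eig$vectors[, seq_len(C), drop = FALSE]
  fit <- eig$values[seq_len(C)] / length(Q)
  fit <- pmin(pmax(fit, 0), 1)
  tied <- C < P &&
    (eig$values[C] - eig$values[C + 1L]) < config$tol
  if (config$sign_rule == "max_abs_positive") {
    for (j in seq_len(C)) {
      k <- which.max(abs(W[, j]))
      if (W[k, j] < 0) W[, j] <- -W[, j]
    }
  }
  tc <- lapply(stack$runs, function(R) crossprod(R, W))
  structure(list(subject_id = stack$subject_id,
                 weights = W,
                 run_timecourses = tc,
                 fit_scores = fit,
                 eigen_gap_tied = tied,
                 config = config),
            class = "common_component")
}

#' @export
print.common_component <- function(x, ...) {
  cat(sprintf("<common_component> subject %s: P = %d, C = %d, fit = %s%s\n",
              x$subject_id, nrow(x$weights), ncol(x$weights),
              paste(sprintf("%.3f", x$fit_scores), collapse = ", "),
              if (x$eigen_gap_tied) " [eigenvalue tie]" else ""))
  invisible(x)
}

#' Run-specific residuals after removing the common subspace
#'
#' Projects each run onto the orthogonal complement of the common weights:
#' `residual_n = R_n - W (W' R_n)`. Adding the common part back
#' reconstructs the run exactly, and the squared Frobenius norms satisfy
#' the Pythagorean identity.
#'
#' @param stack A [multi_run_stack()].
#' @param comp The [extract_common_components()] result for that stack.
#' @return List of P x T residual matrices, one per run, in run order.
#' @export
run_specific_residual <- function(stack, comp) {
  stopifnot(inherits(stack, "multi_run_stack"),
            inherits(comp, "common_component"))
  if (nrow(comp$weights) != nrow(stack$runs[[1]]))
    stop("dimension mismatch between stack and component weights")
  W <- comp$weights
  lapply(stack$runs, function(R) R - W %*% crossprod(W, R))
}

#' Deflate a stack by a set of common directions
#'
#' Replaces each run by its run-specific residual, yielding the stack on
#' which a further (sequential) common-component extraction operates. Used
#' to realize the sequential-extraction property: extracting C = 1 twice
#' with deflation in between matches a single C = 2 extraction.
#'
#' @inheritParams run_specific_residual
#' @return A new `multi_run_stack` of residual runs.
#' @export
deflate_stack <- function(stack, comp) {
  res <- run_specific_residual(stack, comp)
  multi_run_stack(stack$subject_id, res, stack$run_index)
}
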