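# ---------------------------------------------------------------------------
# Common-correlation matrix and maximal-dissimilarity (MCD) selection
# ---------------------------------------------------------------------------

#' Collect per-subject first common components into a component matrix
#'
#' @param weights P x S numeric matrix, one unit-norm column per subject.
#' @param subject_ids Character vector of length S, unique.
#' @return An object of class `component_matrix`.
#' @export
component_matrix <- function(weights, subject_ids = colnames(weights)) {
  weights <- as.matrix(weights)
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(ncol(weights)))
  subject_ids <- as.character(subject_ids)
  if (ncol(weights) < 2L) stop("need at least 2 subjects")
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (length(subject_ids) != ncol(weights))
    stop("one id per column required")
  colnames(weights) <- subject_ids
  structure(list(subject_ids = subject_ids, weights = weights),
            class = "component_matrix")
}

#' Subject-by-subject Pearson correlation of common components
#'
#' @param components A [component_matrix()].
#' @return Object of class `common_correlation` holding `subject_ids` and
#'   the S x S symmetric correlation matrix `r` with unit diagonal.
#' @export
common_correlation_matrix <- function(components) {
  stopifnot(inherits(components, "component_matrix"))
  W <- components$weights
  if (nrow(W) < 3L) stop("need at least 3 regions for Pearson correlation")
  sds <- apply(W, 2, stats::sd)
  if (any(sds == 0))
    stop("constant component column for subject(s): ",
         paste(components$subject_ids[sds == 0], collapse = ", "))
  r <- stats::cor(W)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(components$subject_ids, components$subject_ids)
  structure(list(subject_ids = components$subject_ids, r = r),
            class = "common_correlation")
}

#' Wrap an existing correlation matrix
#'
#' Convenience constructor used by tests and the threshold sweep when the
#' matrix comes from disk rather than from [common_correlation_matrix()].
#' @param r Square symmetric numeric matrix with unit diagonal.
#' @param subject_ids Ids; default from dimnames or 1..S.
#' @export
common_correlation <- function(r, subject_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(r)))
  if (nrow(r) != ncol(r)) stop("correlation matrix must be square")
  if (max(abs(r - t(r))) > 1e-12) stop("correlation matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-12) stop("diagonal must be 1")
  if (max(abs(r)) > 1 + 1e-12) stop("entries must lie in [-1, 1]")
  dimnames(r) <- list(subject_ids, subject_ids)
  structure(list(subject_ids = as.character(subject_ids), r = r),
            class = "common_correlation")
}

#' MCD selection configuration
#'
#' @param threshold Absolute-correlation threshold tau in (0, 1); a pair may
#'   coexist in the dissimilar set only if |r| is strictly below it.
#' @param n_restarts Number of independent randomized growths.
#' @param seed Integer seed driving one RNG stream for all restarts.
#' @param tie_break Label of the tie-break policy between equally good
#'   restarts: smaller within-set max |r|, then larger set, then
#'   lexicographically smallest sorted id list.
#' @export
mcd_config <- function(threshold = 0.75, n_restarts = 1000L, seed = 1L,
                       tie_break = "maxr_size_lex") {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  n_restarts <- as.integer(n_restarts)
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  structure(list(threshold = threshold, n_restarts = n_restarts,
                 seed = as.integer(seed), tie_break = tie_break),
            class = "mcd_config")
}

#' Grow one maximal dissimilar set
#'
#' Seeds the set with a uniformly drawn pair whose |r| is strictly below
#' `threshold`, then repeatedly adds a uniformly drawn subject whose |r|
#' with every current member is strictly below `threshold`, stopping when
#' no subject qualifies. Uses the ambient R RNG stream; seed it with
#' `set.seed()` for reproducibility (done by [select_mcd()]).
#'
#' @param corr A `common_correlation`.
#' @param threshold Tau in (0, 1).
#' @return Integer vector of member indices (sorted), or `integer(0)` when
#'   no pair is below the threshold.
#' @export
grow_dissimilar_set <- function(corr, threshold = 0.75) {
  stopifnot(inherits(corr, "common_correlation"))
  a <- abs(corr$r)
  S <- nrow(a)
  ok <- a < threshold
  diag(ok) <- FALSE
  pairs <- which(ok & upper.tri(ok), arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(integer(0))
  p <- pairs[sample.int(nrow(pairs), 1L), ]
  members <- c(p[[1]], p[[2]])
  # candidates: qualify against every current member
  cand <- which(ok[, members[1]] & ok[, members[2]])
  cand <- setdiff(cand, members)
  while (length(cand) > 0L) {
    nxt <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    members <- c(members, nxt)
    cand <- cand[ok[cand, nxt]]
    cand <- setdiff(cand, nxt)
  }
  sort(members)
}

max_abs_within <- function(a, members) {
  sub <- a[members, members]
  max(sub[upper.tri(sub)])
}

#' Select the maximal-COBE-dissimilarity (MCD) group
#'
#' Runs `n_restarts` randomized maximal-set growths and keeps the set with
#' the smallest within-set maximum absolute correlation. Ties go to the
#' larger set, then to the lexicographically smallest sorted id list. The
#' complement forms the COBE-similarity (CS) group. The previous RNG state
#' is restored on exit, so identical config and seed give identical
#' results regardless of the ambient RNG.
#'
#' @param corr A `common_correlation`.
#' @param config An [mcd_config()].
#' @return Object of class `mcd_result`: `mcd_ids`, `cs_ids`,
#'   `max_abs_corr_within`, `restart_log` (data.frame restart/size/max_abs_r),
#'   `config`.
#' @export
select_mcd <- function(corr, config = mcd_config()) {
  stopifnot(inherits(corr, "common_correlation"),
            inherits(config, "mcd_config"))
  a <- abs(corr$r)
  diag(a) <- 0
  if (!any(a[upper.tri(a)] < config$threshold))
    stop("no pair below threshold")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  best <- NULL
  best_val <- Inf
  log_size <- integer(config$n_restarts)
  log_maxr <- numeric(config$n_restarts)
  for (k in seq_len(config$n_restarts)) {
    m <- grow_dissimilar_set(corr, config$threshold)
    if (length(m) < 2L) {
      log_size[k] <- length(m); log_maxr[k] <- NA_real_
      next
    }
    v <- max_abs_within(a, m)
    log_size[k] <- length(m); log_maxr[k] <- v
    if (is.null(best)) {
      best <- m; best_val <- v
    } else if (v < best_val ||
               (v == best_val && length(m) > length(best)) ||
               (v == best_val && length(m) == length(best) &&
                lex_less(corr$subject_ids[m], corr$subject_ids[best]))) {
      best <- m; best_val <- v
    }
  }
  if (is.null(best)) stop("no pair below threshold")
  ids <- corr$subject_ids
  structure(list(mcd_ids = ids[best],
                 cs_ids = setdiff(ids, ids[best]),
                 max_abs_corr_within = best_val,
                 restart_log = data.frame(restart = seq_len(config$n_restarts),
                                          size = log_size,
                                          max_abs_r = log_maxr),
                 config = config),
            class = "mcd_result")
}

# strict lexicographic comparison of sorted id vectors
lex_less <- function(x, y) {
  x <- sort(x); y <- sort(y)
  n <- min(length(x), length(y))
  for (i in seq_len(n)) {
    if (x[i] < y[i]) return(TRUE)
    if (x[i] > y[i]) return(FALSE)
  }
  length(x) < length(y)
}

#' @export
print.mcd_result <- function(x, ...) {
  cat(sprintf(
    "<mcd_result> MCD n = %d (max |r| = %.3f), CS n = %d, %d restarts, tau = %.2f\n",
    length(x$mcd_ids), x$max_abs_corr_within, length(x$cs_ids),
    x$config$n_restarts, x$config$threshold))
  invisible(x)
}

#' Mean absolute correlation of one subject with all others
#'
#' A per-subject dissimilarity summary: low values mean the subject's
#' common component is unlike everyone else's. Used for the auxiliary
#' dissimilarity-versus-behavior correlations.
#'
#' @param corr A `common_correlation`.
#' @param subject_id One id present in the matrix.
#' @return Mean of |r| with the other S - 1 subjects, in \[0, 1\].
#' @export
subject_dissimilarity_score <- function(corr, subject_id) {
  stopifnot(inherits(corr, "common_correlation"))
  if (length(corr$subject_ids) < 2L) stop("need at least 2 subjects")
  i <- match(as.character(subject_id), corr$subject_ids)
  if (is.na(i)) stop("unknown subject id: ", subject_id)
  mean(abs(corr$r[i, -i]))
}
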