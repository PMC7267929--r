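# Independent oracles and small fixture builders shared across test files.
# Oracles deliberately take a different computational route than the
# package code they check.

# Leading common directions via SVD of the horizontally concatenated block
# bases (left singular vectors of [Q_1 ... Q_N]; squared singular values
# equal the eigenvalues of sum Q_n Q_n').
oracle_common_directions <- function(Q_list, C) {
  sv <- svd(do.call(cbind, Q_list), nu = C, nv = 0)
  list(vectors = sv$u, values = sv$d[seq_len(C)]^2,
       all_values = sv$d^2)
}

# Textbook Pearson correlation
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Welch two-sample t statistic, df and two-sided p from the closed form
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pearson chi-square from the definition sum (O - E)^2 / E
oracle_chisq2x2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# All maximal tau-dissimilar subject sets of a correlation matrix by
# exhaustive enumeration (S <= 12); returns list of sorted index vectors.
oracle_maximal_sets <- function(r, tau) {
  S <- nrow(r)
  a <- abs(r); diag(a) <- 0
  ok <- a < tau
  feasible <- function(members) {
    if (length(members) < 2) return(FALSE)
    sub <- ok[members, members]
    all(sub[upper.tri(sub)])
  }
  sets <- list()
  for (mask in seq_len(2^S - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(S) - 1)) > 0)
    if (!feasible(members)) next
    outside <- setdiff(seq_len(S), members)
    maximal <- !any(vapply(outside, function(o)
      all(ok[o, members]), logical(1)))
    if (maximal) sets[[length(sets) + 1L]] <- members
  }
  sets
}

# Global min over maximal sets of the within-set max |r|
oracle_minmax_value <- function(r, tau) {
  sets <- oracle_maximal_sets(r, tau)
  if (!length(sets)) return(NA_real_)
  a <- abs(r)
  min(vapply(sets, function(m) {
    sub <- a[m, m]; max(sub[upper.tri(sub)])
  }, numeric(1)))
}

# Multi-run stack with a planted C-dimensional common subspace (shared by
# every block), k block-specific components and light noise: the setting
# in which the sequential-extraction property holds. Component amplitudes
# are graded so the common directions have distinct block energies.
planted_stack <- function(P = 10, T_len = 25, n_runs = 3, C = 2, k = 2,
                          noise = 0.005, id = "planted") {
  A <- qr.Q(qr(matrix(rnorm(P * C), P)))   # orthonormal common directions
  runs <- lapply(seq_len(n_runs), function(n) {
    Y <- matrix(rnorm(C * T_len), C) * (C:1)   # graded energies
    R <- A %*% Y
    for (j in seq_len(k)) {
      b <- rnorm(P); b <- as.numeric(b - A %*% crossprod(A, b))
      R <- R + 0.5 * (b / sqrt(sum(b^2))) %o% rnorm(T_len)
    }
    R + noise * matrix(rnorm(P * T_len), P)
  })
  list(stack = multi_run_stack(id, runs), A = A)
}

# Random multi-run stack whose blocks share no planted structure
random_stack <- function(P = 10, T_len = 20, n_runs = 3, id = "rnd") {
  multi_run_stack(id, lapply(seq_len(n_runs),
                             function(i) matrix(rnorm(P * T_len), P)))
}

# Random correlation-like matrix from low-dimensional random unit columns
random_corr <- function(S = 8, dim = 4) {
  X <- matrix(rnorm(dim * S), dim)
  r <- cor(X)
  common_correlation((r + t(r)) / 2 - diag(diag((r + t(r)) / 2)) + diag(S),
                     sprintf("s%02d", seq_len(S)))
}

abs_cos <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))

# Small behavior table built by hand
tiny_behaviors <- function(n = 10, seed = 1) {
  set.seed(seed)
  behavior_table(sprintf("s%02d", 1:n),
                 rep(c("male", "female"), length.out = n),
                 data.frame(m1 = rnorm(n), m2 = rnorm(n)),
                 categories = c(m1 = "cognition", m2 = "emotion"))
}
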