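# Common orthogonal basis extraction: block bases, common components,
# run-specific residuals, and the algebraic properties of the decomposition.

test_that("orthonormal_block_basis recovers simple column spaces", {
  # rank-1 matrix a y': single basis column = +/- a / ||a||
  a <- c(3, 0, 4, 0)
  y <- rnorm(20); y <- y - mean(y)
  B <- orthonormal_block_basis(a %o% y, list(energy = 0.99),
                               demean_rows = FALSE)
  expect_equal(ncol(B), 1L)
  expect_equal(abs_cos(B[, 1], a / 5), 1, tolerance = 1e-10)

  # diag(2, 1, 0, 0), fixed r = 2: basis spans e1, e2
  B2 <- orthonormal_block_basis(diag(c(2, 1, 0, 0)), list(fixed = 2),
                                demean_rows = FALSE)
  expect_equal(dim(B2), c(4L, 2L))
  expect_equal(colSums(B2[3:4, ]^2), c(0, 0), tolerance = 1e-20)
  expect_equal(crossprod(B2), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("energy policy captures the stated fraction (full-SVD oracle)", {
  set.seed(42)
  for (i in 1:5) {
    X <- matrix(rnorm(200), 10, 20)
    B <- orthonormal_block_basis(X, list(energy = 0.99), demean_rows = TRUE)
    Xd <- X - rowMeans(X)
    captured <- sum((B %*% crossprod(B, Xd))^2) / sum(Xd^2)
    expect_gte(captured, 0.99)
    # oracle: smallest r by cumulative squared singular values
    d2 <- svd(Xd)$d^2
    r_star <- min(which(cumsum(d2) / sum(d2) >= 0.99))
    expect_identical(ncol(B), r_star)
  }
})

test_that("degenerate and invalid block inputs error", {
  expect_error(orthonormal_block_basis(matrix(0, 4, 6)), "degenerate")
  # constant rows become zero after demeaning
  expect_error(orthonormal_block_basis(matrix(1, 4, 6), demean_rows = TRUE),
               "degenerate")
  expect_error(orthonormal_block_basis(matrix(rnorm(24), 4, 6),
                                       list(fixed = 5)),
               "invalid config")
})

test_that("shared rank-1 and subspace-intersection cases are exact", {
  a <- c(1, 1, 1, 1) / 2
  y1 <- rnorm(20); y1 <- y1 - mean(y1)
  y2 <- rnorm(20); y2 <- y2 - mean(y2)
  st <- multi_run_stack("s", list(a %o% y1, a %o% y2))
  cc <- extract_common_components(st, cobe_config(1, demean_rows = FALSE))
  expect_equal(abs_cos(cc$weights[, 1], a), 1, tolerance = 1e-10)
  expect_equal(cc$fit_scores, 1, tolerance = 1e-10)

  # run 1 spans {e1}, run 2 spans {e1, e2}: common = e1 with fit 1
  e <- diag(4)
  r1 <- e[, 1] %o% c(-1, 1, -2, 2, 0)
  r2 <- e[, 1:2] %*% matrix(c(1, 0, 2, 1, 0, 2, 1, -1, 2, -2), 2, 5)
  st2 <- multi_run_stack("s2", list(r1, r2))
  cc2 <- extract_common_components(
    st2, cobe_config(1, rank_policy = list(energy = 1), demean_rows = FALSE))
  expect_equal(abs_cos(cc2$weights[, 1], e[, 1]), 1, tolerance = 1e-8)
  expect_equal(cc2$fit_scores, 1, tolerance = 1e-10)
})

test_that("components match the concatenated-basis SVD oracle", {
  set.seed(7)
  for (i in 1:5) {
    st <- random_stack(P = 10, T_len = 20, n_runs = 3)
    cfg <- cobe_config(2, rank_policy = list(fixed = 4), demean_rows = TRUE)
    cc <- extract_common_components(st, cfg)
    Q <- lapply(st$runs, orthonormal_block_basis,
                rank_policy = list(fixed = 4), demean_rows = TRUE)
    or <- oracle_common_directions(Q, 2)
    gaps <- c(or$all_values[1] - or$all_values[2],
              or$all_values[2] - or$all_values[3])
    for (j in 1:2) {
      if (gaps[j] > 1e-6)
        expect_gt(abs_cos(cc$weights[, j], or$vectors[, j]), 1 - 1e-6)
    }
    expect_equal(cc$fit_scores, or$values / 3, tolerance = 1e-10)
  }
})

test_that("component invariants hold: orthonormality, sign rule, fit range", {
  set.seed(8)
  st <- random_stack(P = 12, T_len = 30, n_runs = 4)
  cc <- extract_common_components(st, cobe_config(3))
  G <- crossprod(cc$weights)
  expect_equal(G, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(cc$fit_scores) <= 1e-12))
  expect_true(all(cc$fit_scores >= 0 & cc$fit_scores <= 1))
  for (j in 1:3)
    expect_gt(cc$weights[which.max(abs(cc$weights[, j])), j], 0)
  # timecourses are the least-squares coefficients R' W
  expect_equal(cc$run_timecourses[[2]], crossprod(st$runs[[2]], cc$weights),
               tolerance = 1e-12)
})

test_that("over-asking for components errors with achievable maximum", {
  a <- c(1, 0, 0, 0)
  y1 <- rnorm(10); y2 <- rnorm(10)
  st <- multi_run_stack("s", list(a %o% y1, a %o% y2))
  expect_error(
    extract_common_components(
      st, cobe_config(3, rank_policy = list(energy = 1),
                      demean_rows = FALSE)),
    "achievable maximum: 1")
  expect_error(extract_common_components(st, cobe_config(5)),
               "regions")
})

test_that("sequential C=1 extraction with deflation matches C=2 at once", {
  set.seed(21)
  for (i in 1:5) {
    ps <- planted_stack(P = 10, T_len = 25, n_runs = 3, C = 2, k = 2)
    st <- ps$stack
    cfg1 <- cobe_config(1, rank_policy = list(fixed = 4))
    both <- extract_common_components(
      st, cobe_config(2, rank_policy = list(fixed = 4)))
    first <- extract_common_components(st, cfg1)
    second <- extract_common_components(deflate_stack(st, first), cfg1)
    expect_gt(abs_cos(first$weights[, 1], both$weights[, 1]), 1 - 1e-4)
    expect_gt(abs_cos(second$weights[, 1], both$weights[, 2]), 1 - 1e-4)
    # and both routes recover the planted common subspace
    proj <- crossprod(ps$A, cbind(first$weights, second$weights))
    expect_equal(colSums(proj^2), c(1, 1), tolerance = 1e-2,
                 ignore_attr = TRUE)
  }
})

test_that("run order and per-run scaling do not change the solution", {
  set.seed(31)
  st <- random_stack(P = 8, T_len = 20, n_runs = 3)
  cfg <- cobe_config(2, rank_policy = list(fixed = 3))
  cc <- extract_common_components(st, cfg)
  # permutation invariance
  stp <- multi_run_stack(st$subject_id, st$runs[c(3, 1, 2)])
  ccp <- extract_common_components(stp, cfg)
  for (j in 1:2)
    expect_gt(abs_cos(cc$weights[, j], ccp$weights[, j]), 1 - 1e-8)
  expect_equal(cc$fit_scores, ccp$fit_scores, tolerance = 1e-10)
  # scale invariance (column space unchanged)
  sts <- multi_run_stack(st$subject_id,
                         list(st$runs[[1]] * -17.3, st$runs[[2]],
                              st$runs[[3]] * 0.01))
  ccs <- extract_common_components(sts, cfg)
  for (j in 1:2)
    expect_gt(abs_cos(cc$weights[, j], ccs$weights[, j]), 1 - 1e-8)
})

test_that("run-specific residuals decompose the runs exactly", {
  set.seed(41)
  st <- random_stack(P = 10, T_len = 20, n_runs = 3)
  cc <- extract_common_components(st, cobe_config(2))
  res <- run_specific_residual(st, cc)
  W <- cc$weights
  for (n in 1:3) {
    R <- st$runs[[n]]
    # exact reconstruction
    expect_equal(res[[n]] + W %*% crossprod(W, R), R, tolerance = 1e-10)
    # residual orthogonal to the common span
    expect_lt(max(abs(crossprod(W, res[[n]]))), 1e-8 * max(abs(res[[n]])))
    # Pythagoras
    expect_equal(sum(R^2),
                 sum((W %*% crossprod(W, R))^2) + sum(res[[n]]^2),
                 tolerance = 1e-8)
  }
  # runs entirely inside span(W): zero residuals
  inside <- lapply(1:2, function(i) W %*% matrix(rnorm(2 * 15), 2))
  st_in <- multi_run_stack("in", inside)
  res_in <- run_specific_residual(st_in, cc)
  expect_lt(max(abs(res_in[[1]])), 1e-10)
  # component orthogonal to a run: residual equals the run
  ortho_run <- (diag(10) - tcrossprod(W)) %*% matrix(rnorm(10 * 15), 10)
  st_o <- multi_run_stack("o", list(ortho_run, ortho_run))
  res_o <- run_specific_residual(st_o, cc)
  expect_equal(res_o[[1]], ortho_run, tolerance = 1e-10)
  # dimension mismatch
  st_bad <- random_stack(P = 7, T_len = 12, n_runs = 2)
  expect_error(run_specific_residual(st_bad, cc), "mismatch")
})

test_that("stack construction enforces its invariants", {
  expect_error(multi_run_stack("s", list(matrix(1:6, 2))), "at least 2 runs")
  expect_error(multi_run_stack("s", list(matrix(rnorm(6), 2),
                                         matrix(rnorm(9), 3))),
               "same number of regions")
  expect_error(multi_run_stack("s", list(matrix(c(1, NA, 3, 4), 2),
                                         matrix(rnorm(4), 2))), "finite")
  expect_error(multi_run_stack("s", list(matrix(rnorm(4), 2),
                                         matrix(rnorm(4), 2)),
                               run_index = c(1, 1)), "unique")
})
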