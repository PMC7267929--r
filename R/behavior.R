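# ---------------------------------------------------------------------------
# Behavioral battery, sex composition, and sex-matched control
# ---------------------------------------------------------------------------

#' Assemble a behavior table
#'
#' @param subject_ids Unique ids matching the imaging cohort.
#' @param sex Character vector, `"male"`/`"female"`, one per subject.
#' @param measures data.frame of numeric measure columns (ordinal codings
#'   allowed), one row per subject. Missing values are rejected: the
#'   pipeline mirrors a complete-case contract.
#' @param categories Named character vector mapping measure name ->
#'   category (e.g. substance use, cognition, physiological).
#' @return Object of class `behavior_table`.
#' @export
behavior_table <- function(subject_ids, sex, measures, categories = NULL) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (length(sex) != length(subject_ids))
    stop("one sex entry per subject required")
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  measures <- as.data.frame(measures)
  if (nrow(measures) != length(subject_ids))
    stop("one measure row per subject required")
  if (!all(vapply(measures, is.numeric, logical(1))))
    stop("all measure columns must be numeric")
  if (anyNA(measures))
    stop("missing values in measures; the battery is complete-case only")
  if (is.null(categories))
    categories <- setNames(rep("uncategorized", ncol(measures)),
                           names(measures))
  structure(list(subject_ids = subject_ids, sex = sex,
                 measures = measures, categories = categories),
            class = "behavior_table")
}

#' Compare the behavior battery between two groups
#'
#' Per measure, a two-sided Welch two-sample t test with Bonferroni
#' correction over the number of measures tested (69 with the default
#' battery: a raw p is flagged when below `alpha / m`).
#'
#' @param behaviors A [behavior_table()].
#' @param groups List with id vectors `mcd` and `cs`.
#' @param alpha Familywise level (default 0.05).
#' @param measure_subset Optional character vector restricting the battery.
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @return data.frame of class `behavior_comparison`: measure, category,
#'   group means/SEMs, statistic, raw p, `significant`. Attributes
#'   `family_size`, `alpha`.
#' @export
compare_behaviors <- function(behaviors, groups, alpha = 0.05,
                              measure_subset = NULL,
                              method = c("welch", "wilcoxon")) {
  stopifnot(inherits(behaviors, "behavior_table"))
  method <- match.arg(method)
  meas <- names(behaviors$measures)
  if (!is.null(measure_subset)) {
    missing <- setdiff(measure_subset, meas)
    if (length(missing)) stop("unknown measures: ",
                              paste(missing, collapse = ", "))
    meas <- intersect(meas, measure_subset)
  }
  if (length(meas) == 0L) stop("empty measure set")
  i1 <- match(groups$mcd, behaviors$subject_ids)
  i2 <- match(groups$cs, behaviors$subject_ids)
  if (anyNA(i1) || anyNA(i2)) stop("group ids not found in behavior table")
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each group needs at least 2 subjects")
  out <- do.call(rbind, lapply(meas, function(mn) {
    x <- behaviors$measures[i1, mn]; y <- behaviors$measures[i2, mn]
    w <- if (method == "welch") welch_row(x, y) else {
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      list(statistic = unname(wt$statistic), p = wt$p.value,
           degenerate = FALSE)
    }
    data.frame(measure = mn,
               category = unname(behaviors$categories[mn]),
               mean_mcd = mean(x), sem_mcd = sem(x),
               mean_cs = mean(y), sem_cs = sem(y),
               statistic = w$statistic, p_raw = w$p,
               degenerate = w$degenerate)
  }))
  m <- length(meas)
  out$significant <- out$p_raw < alpha / m
  if (any(out$degenerate))
    warning("constant measure(s) in both groups: ",
            paste(out$measure[out$degenerate], collapse = ", "))
  attr(out, "family_size") <- m
  attr(out, "alpha") <- alpha
  class(out) <- c("behavior_comparison", "data.frame")
  out
}

#' Pearson chi-square test of sex composition
#'
#' 2x2 group x sex contingency test without continuity correction
#' (expected counts are large in the intended use).
#'
#' @param groups List with id vectors `mcd` and `cs`.
#' @param sex Named character vector id -> "male"/"female" (or a
#'   [behavior_table()], from which ids and sex are taken).
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List of class `sex_composition`: `counts` (2x2 matrix),
#'   `statistic`, `df`, `p`.
#' @export
sex_composition_test <- function(groups, sex, correct = FALSE) {
  if (inherits(sex, "behavior_table"))
    sex <- setNames(sex$sex, sex$subject_ids)
  tab <- rbind(mcd = table(factor(sex[groups$mcd], c("male", "female"))),
               cs = table(factor(sex[groups$cs], c("male", "female"))))
  sex_composition_from_counts(tab, correct = correct)
}

#' Chi-square test from explicit 2x2 counts
#'
#' @param counts 2x2 matrix of non-negative integer counts (rows: groups,
#'   columns: sexes).
#' @param correct Yates continuity correction (default FALSE).
#' @export
sex_composition_from_counts <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("a margin of the contingency table is all zero")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  structure(list(counts = counts,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value),
            class = "sex_composition")
}

#' @export
print.sex_composition <- function(x, ...) {
  cat(sprintf("<sex_composition> X^2 = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p))
  print(x$counts)
  invisible(x)
}

#' Draw a random sex-matched (RSSM) subset of the CS group
#'
#' Uniform draw without replacement of exactly `target_counts["male"]`
#' males and `target_counts["female"]` females from the CS ids, typically
#' matching the MCD group's sex composition. Deterministic under
#' `set.seed()`; the previous RNG state is restored.
#'
#' @param cs_ids Character vector of CS subject ids.
#' @param sex Named character vector id -> sex, or a [behavior_table()].
#' @param target_counts Named integer vector `c(male = ..., female = ...)`.
#' @param seed Integer seed.
#' @return Character vector of drawn ids (sorted).
#' @export
draw_rssm <- function(cs_ids, sex, target_counts, seed = 1L) {
  if (inherits(sex, "behavior_table"))
    sex <- setNames(sex$sex, sex$subject_ids)
  males <- cs_ids[sex[cs_ids] == "male"]
  females <- cs_ids[sex[cs_ids] == "female"]
  tm <- as.integer(target_counts[["male"]])
  tf <- as.integer(target_counts[["female"]])
  if (length(males) < tm)
    stop(sprintf("CS group short of males: need %d, have %d (shortfall %d)",
                 tm, length(males), tm - length(males)))
  if (length(females) < tf)
    stop(sprintf("CS group short of females: need %d, have %d (shortfall %d)",
                 tf, length(females), tf - length(females)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  sort(c(sample(males, tm), sample(females, tf)))
}

#' Re-test MCD against a sex-matched CS subset
#'
#' Reruns the behavioral comparison on a subset of measures (by default
#' the measures flagged in the full MCD-versus-CS comparison) and the
#' network-weight comparison on the given label(s), with the RSSM subset
#' standing in for CS.
#'
#' @param behaviors A [behavior_table()].
#' @param network_table A `network_weight_table`.
#' @param mcd_ids,rssm_ids Disjoint id vectors.
#' @param alpha Familywise level.
#' @param measure_subset Measures to test (required non-empty).
#' @param labels Network labels to test (default `"DefaultA"`).
#' @return List with `behavior` (a `behavior_comparison`) and `network`
#'   (a `group_weight_comparison` restricted to `labels`).
#' @export
compare_mcd_vs_rssm <- function(behaviors, network_table, mcd_ids, rssm_ids,
                                alpha = 0.05, measure_subset,
                                labels = "DefaultA") {
  if (length(intersect(mcd_ids, rssm_ids)))
    stop("MCD and RSSM id sets must be disjoint")
  if (missing(measure_subset) || length(measure_subset) == 0L)
    stop("empty measure subset")
  groups <- list(mcd = mcd_ids, cs = rssm_ids)
  beh <- compare_behaviors(behaviors, groups, alpha = alpha,
                           measure_subset = measure_subset)
  net <- NULL
  if (!is.null(network_table)) {
    sub <- network_table
    keep <- sub$labels %in% labels
    if (!any(keep)) stop("labels not found in network table: ",
                         paste(labels, collapse = ", "))
    sub$labels <- sub$labels[keep]
    sub$values <- sub$values[, keep, drop = FALSE]
    net <- compare_network_weights(sub, groups, alpha = alpha)
  }
  list(behavior = beh, network = net)
}

#' Correlate per-subject dissimilarity with behavioral measures
#'
#' Pearson correlation, with two-sided p, of a per-subject dissimilarity
#' score (see [subject_dissimilarity_score()]) against each requested
#' measure. Stands in for the variation-versus-behavior auxiliary
#' analysis; the dissimilarity score is this package's documented proxy.
#'
#' @param scores Named numeric vector id -> dissimilarity score.
#' @param behaviors A [behavior_table()].
#' @param measure_subset Measures to correlate (default: all).
#' @return data.frame measure, r, p.
#' @export
correlate_dissimilarity_with_behaviors <- function(scores, behaviors,
                                                   measure_subset = NULL) {
  stopifnot(inherits(behaviors, "behavior_table"))
  ids <- intersect(names(scores), behaviors$subject_ids)
  if (length(ids) < 3L) stop("need at least 3 subjects with scores")
  s <- scores[ids]
  if (stats::sd(s) == 0) stop("constant dissimilarity score vector")
  meas <- if (is.null(measure_subset)) names(behaviors$measures)
          else measure_subset
  idx <- match(ids, behaviors$subject_ids)
  do.call(rbind, lapply(meas, function(mn) {
    x <- behaviors$measures[idx, mn]
    if (stats::sd(x) == 0)
      return(data.frame(measure = mn, r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(s, x)
    data.frame(measure = mn, r = unname(ct$estimate), p = ct$p.value)
  }))
}
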