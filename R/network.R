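# ---------------------------------------------------------------------------
# Network-level weight summaries and group contrasts
# ---------------------------------------------------------------------------

#' Validate a parcellation lookup
#'
#' A lookup maps every region index 1..P to a region name, a label (one of
#' the 17 cortical network names or a subcortical ROI name) and a
#' hemisphere (`left`, `right` or `none`). Cortical labels carry no
#' hemisphere suffix, so left and right parcels of a network are merged
#' when weights are averaged per label.
#'
#' @param lookup data.frame with columns `region_index`, `region_name`,
#'   `label`, `hemisphere`.
#' @return The validated data.frame (ordered by region_index), classed
#'   `parcellation_lookup`.
#' @export
parcellation_lookup <- function(lookup) {
  need <- c("region_index", "region_name", "label", "hemisphere")
  if (!all(need %in% names(lookup)))
    stop("lookup needs columns ", paste(need, collapse = ", "))
  lookup <- lookup[order(lookup$region_index), , drop = FALSE]
  P <- nrow(lookup)
  if (!identical(as.integer(lookup$region_index), seq_len(P)))
    stop("region_index must cover 1..P exactly once")
  if (!all(lookup$hemisphere %in% c("left", "right", "none")))
    stop("hemisphere must be left, right or none")
  rownames(lookup) <- NULL
  class(lookup) <- c("parcellation_lookup", "data.frame")
  lookup
}

#' Average component weights within parcellation labels
#'
#' @param components A [component_matrix()] (P x S).
#' @param lookup A [parcellation_lookup()] covering all P regions.
#' @return Object of class `network_weight_table`: `subject_ids`, `labels`
#'   and `values`, a subjects x labels matrix of arithmetic means. Labels
#'   appear in order of first occurrence in the lookup.
#' @export
summarize_weights_by_network <- function(components, lookup) {
  stopifnot(inherits(components, "component_matrix"))
  lookup <- parcellation_lookup(lookup)
  W <- components$weights
  if (nrow(lookup) != nrow(W))
    stop("lookup covers ", nrow(lookup), " regions but components have ",
         nrow(W))
  if (anyNA(lookup$label) || any(lookup$label == "")) {
    bad <- lookup$region_index[is.na(lookup$label) | lookup$label == ""]
    stop("regions without a label: ", paste(bad, collapse = ", "))
  }
  labels <- unique(lookup$label)
  V <- vapply(labels, function(l) {
    colMeans(W[lookup$label == l, , drop = FALSE])
  }, numeric(ncol(W)))
  # V: subjects x labels
  V <- matrix(V, nrow = ncol(W), dimnames = list(components$subject_ids, labels))
  structure(list(subject_ids = components$subject_ids,
                 labels = labels, values = V),
            class = "network_weight_table")
}

# Welch two-sample comparison used by both the network and behavior
# batteries. Degenerate case (both groups constant with equal means) gets
# statistic 0, p = 1 and a warning flag rather than an error.
welch_row <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, p = 1, degenerate = TRUE))
    return(list(statistic = Inf * sign(mean(x) - mean(y)), p = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Compare network-averaged weights between two groups
#'
#' Per label, a two-sided Welch two-sample t test of MCD versus CS mean
#' weights, with Bonferroni familywise correction over the number of
#' labels present (36 with the default 17 cortical + 19 subcortical
#' template).
#'
#' @param table A `network_weight_table`.
#' @param groups List with character vectors `mcd` and `cs` of subject ids.
#' @param alpha Familywise significance level (default 0.05).
#' @param method `"welch"` (default) or `"wilcoxon"` (Mann-Whitney) for
#'   ordinal purists.
#' @return data.frame of class `group_weight_comparison` with one row per
#'   label: group means and standard errors, statistic, raw p, and
#'   `significant = p_raw < alpha / m`. Attributes `family_size` and
#'   `alpha`.
#' @export
compare_network_weights <- function(table, groups, alpha = 0.05,
                                    method = c("welch", "wilcoxon")) {
  stopifnot(inherits(table, "network_weight_table"))
  method <- match.arg(method)
  i1 <- match(groups$mcd, table$subject_ids)
  i2 <- match(groups$cs, table$subject_ids)
  if (anyNA(i1) || anyNA(i2)) stop("group ids not found in table")
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each group needs at least 2 subjects")
  out <- do.call(rbind, lapply(table$labels, function(l) {
    x <- table$values[i1, l]; y <- table$values[i2, l]
    w <- if (method == "welch") welch_row(x, y) else {
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      list(statistic = unname(wt$statistic), p = wt$p.value,
           degenerate = FALSE)
    }
    data.frame(label = l,
               mean_mcd = mean(x), sem_mcd = sem(x),
               mean_cs = mean(y), sem_cs = sem(y),
               statistic = w$statistic, p_raw = w$p,
               degenerate = w$degenerate)
  }))
  m <- length(table$labels)
  out$significant <- out$p_raw < alpha / m
  if (any(out$degenerate))
    warning("degenerate (constant) labels: ",
            paste(out$label[out$degenerate], collapse = ", "))
  attr(out, "family_size") <- m
  attr(out, "alpha") <- alpha
  class(out) <- c("group_weight_comparison", "data.frame")
  out
}
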