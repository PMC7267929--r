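# Behavioral battery, sex composition, RSSM control, and dissimilarity
# correlations.

test_that("battery flags follow the Bonferroni rule", {
  spec <- default_behavior_spec()
  expect_identical(nrow(spec), 69L)
  # per-test threshold at m = 69, alpha = 0.05
  expect_equal(0.05 / 69, 7.246377e-4, tolerance = 1e-6)
  set.seed(1)
  cfg <- simulation_config(seed = 1)
  labels <- c(rep("subgroup", 20), rep("majority", 100))
  beh <- generate_behaviors(labels, cfg)
  grp <- list(mcd = beh$subject_ids[labels == "subgroup"],
              cs = beh$subject_ids[labels == "majority"])
  cmp <- compare_behaviors(beh, grp)
  expect_identical(attr(cmp, "family_size"), 69L)
  expect_identical(cmp$significant, cmp$p_raw < 0.05 / 69)
  expect_identical(nrow(cmp), 69L)
})

test_that("global null yields zero flags; identical groups give p = 1", {
  n <- 40
  ids <- sprintf("s%02d", 1:n)
  set.seed(2)
  vals <- rnorm(n / 2)
  beh <- behavior_table(ids, rep(c("male", "female"), n / 2),
                        data.frame(m1 = c(vals, vals), m2 = rep(1:5, 8)))
  grp <- list(mcd = ids[1:(n / 2)], cs = ids[(n / 2 + 1):n])
  cmp <- compare_behaviors(beh, grp)
  expect_equal(cmp$statistic[cmp$measure == "m1"], 0, tolerance = 1e-12)
  expect_equal(cmp$p_raw[cmp$measure == "m1"], 1, tolerance = 1e-12)
  expect_false(any(cmp$significant))
})

test_that("battery output is invariant to column and subject order", {
  beh0 <- tiny_behaviors(n = 12)
  ids <- beh0$subject_ids
  grp <- list(mcd = ids[1:6], cs = ids[7:12])
  cmp <- compare_behaviors(beh0, grp)
  perm <- sample(12)
  beh1 <- behavior_table(ids[perm], beh0$sex[perm],
                         beh0$measures[perm, c("m2", "m1")],
                         beh0$categories)
  cmp1 <- compare_behaviors(beh1, grp)
  for (m in c("m1", "m2")) {
    expect_equal(cmp$p_raw[cmp$measure == m], cmp1$p_raw[cmp1$measure == m],
                 tolerance = 1e-12)
    expect_equal(cmp$statistic[cmp$measure == m],
                 cmp1$statistic[cmp1$measure == m], tolerance = 1e-12)
  }
})

test_that("planted effects are flagged and nulls are not (50 replicates)", {
  planted <- planted_measures()
  all5 <- 0L; clean <- 0L
  for (s in 1:50) {
    cfg <- simulation_config(seed = s)
    set.seed(1000 + s)
    labels <- c(rep("subgroup", 16), rep("majority", 104))
    beh <- generate_behaviors(labels, cfg)
    grp <- list(mcd = beh$subject_ids[labels == "subgroup"],
                cs = beh$subject_ids[labels == "majority"])
    cmp <- compare_behaviors(beh, grp)
    flags <- cmp$measure[cmp$significant]
    if (all(planted %in% flags)) all5 <- all5 + 1L
    if (!any(setdiff(cmp$measure, planted) %in% flags)) clean <- clean + 1L
  }
  expect_gte(all5, 45L)
  expect_gte(clean, 45L)
})

test_that("chi-square matches closed forms and the hand oracle", {
  # identical proportions
  r0 <- sex_composition_from_counts(rbind(c(50, 50), c(50, 50)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # maximal association: all expected counts 5, statistic exactly 20
  r1 <- sex_composition_from_counts(rbind(c(10, 0), c(0, 10)))
  expect_equal(r1$statistic, 20, tolerance = 1e-12)
  expect_identical(r1$df, 1L)
  # published-style table vs sum (O-E)^2/E oracle
  tab <- rbind(c(74, 33), c(323, 358))
  r2 <- sex_composition_from_counts(tab)
  expect_equal(r2$statistic, oracle_chisq2x2(tab), tolerance = 1e-10)
  expect_equal(r2$statistic, 17.5, tolerance = 0.15)
  # transpose invariance
  r3 <- sex_composition_from_counts(t(tab))
  expect_equal(r2$statistic, r3$statistic, tolerance = 1e-12)
  # degenerate margin
  expect_error(sex_composition_from_counts(rbind(c(0, 0), c(3, 4))),
               "margin")
})

test_that("sex_composition_test builds the table from ids", {
  ids <- sprintf("s%02d", 1:8)
  sex <- setNames(rep(c("male", "female"), 4), ids)
  res <- sex_composition_test(list(mcd = ids[1:4], cs = ids[5:8]), sex)
  expect_equal(unname(res$counts["mcd", ]), c(2, 2))
  expect_equal(res$statistic, 0)
})

test_that("RSSM draws are exact, constrained and deterministic", {
  ids <- sprintf("c%02d", 1:10)
  sex <- setNames(rep(c("male", "female"), each = 5), ids)
  # forced draw: targets equal the full composition
  full <- draw_rssm(ids, sex, c(male = 5, female = 5), seed = 3)
  expect_setequal(full, ids)
  # constraint satisfaction across seeds
  for (s in 1:25) {
    d <- draw_rssm(ids, sex, c(male = 2, female = 1), seed = s)
    expect_length(d, 3)
    expect_identical(sum(sex[d] == "male"), 2L)
    expect_identical(sum(sex[d] == "female"), 1L)
  }
  # determinism
  expect_identical(draw_rssm(ids, sex, c(male = 2, female = 1), seed = 9),
                   draw_rssm(ids, sex, c(male = 2, female = 1), seed = 9))
  expect_error(draw_rssm(ids, sex, c(male = 6, female = 0), seed = 1),
               "shortfall")
})

test_that("MCD vs RSSM: identical columns give zero flags", {
  ids <- sprintf("s%02d", 1:12)
  set.seed(4)
  vals <- rnorm(6)
  beh <- behavior_table(ids, rep("male", 12),
                        data.frame(m1 = c(vals, vals), m2 = rnorm(12)))
  res <- compare_mcd_vs_rssm(beh, NULL, ids[1:6], ids[7:12],
                             measure_subset = "m1")
  expect_false(any(res$behavior$significant))
  expect_error(compare_mcd_vs_rssm(beh, NULL, ids[1:6], ids[5:10],
                                   measure_subset = "m1"), "disjoint")
  expect_error(compare_mcd_vs_rssm(beh, NULL, ids[1:6], ids[7:12],
                                   measure_subset = character(0)), "empty")
})

test_that("sex matching removes a sex-confounded effect but keeps a real one", {
  # alcohol-analog differs between groups only through sex composition;
  # marijuana-analog carries a genuine group effect
  spec <- default_behavior_spec()
  i_alc <- spec$measure == "Total_Drinks_7_Days"
  spec$mean_subgroup[i_alc] <- spec$mean_majority[i_alc]
  spec$sex_delta[i_alc] <- 6
  cfg <- simulation_config(S = 300, subgroup_size = 40,
                           behavior_spec = spec,
                           p_male_subgroup = 0.9, p_male_majority = 0.3,
                           seed = 1)
  set.seed(99)
  labels <- c(rep("subgroup", 40), rep("majority", 260))
  beh <- generate_behaviors(labels, cfg)
  mcd_ids <- beh$subject_ids[labels == "subgroup"]
  cs_ids <- beh$subject_ids[labels == "majority"]
  # confounded effect is visible against unmatched CS
  full <- compare_behaviors(beh, list(mcd = mcd_ids, cs = cs_ids))
  expect_true(full$significant[full$measure == "Total_Drinks_7_Days"])
  expect_true(full$significant[full$measure == "SSAGA_Mj_Times_Used"])
  sex <- setNames(beh$sex, beh$subject_ids)
  target <- c(male = sum(sex[mcd_ids] == "male"),
              female = sum(sex[mcd_ids] == "female"))
  flags <- sapply(1:50, function(d) {
    rssm <- draw_rssm(cs_ids, sex, target, seed = d)
    res <- compare_mcd_vs_rssm(beh, NULL, mcd_ids, rssm,
                               measure_subset = c("Total_Drinks_7_Days",
                                                  "SSAGA_Mj_Times_Used"))
    res$behavior$significant[match(c("Total_Drinks_7_Days",
                                     "SSAGA_Mj_Times_Used"),
                                   res$behavior$measure)]
  })
  alc_rate <- mean(flags[1, ]); mj_rate <- mean(flags[2, ])
  expect_gte(mj_rate, 0.9)
  expect_lt(alc_rate, mj_rate / 2)
})

test_that("null RSSM draws leave planted-null measures unflagged", {
  spec <- default_behavior_spec()
  spec$mean_subgroup <- spec$mean_majority   # full behavioral null
  cfg <- simulation_config(S = 200, subgroup_size = 30,
                           behavior_spec = spec, seed = 2)
  set.seed(11)
  labels <- c(rep("subgroup", 30), rep("majority", 170))
  beh <- generate_behaviors(labels, cfg)
  mcd_ids <- beh$subject_ids[labels == "subgroup"]
  cs_ids <- beh$subject_ids[labels == "majority"]
  sex <- setNames(beh$sex, beh$subject_ids)
  target <- c(male = sum(sex[mcd_ids] == "male"),
              female = sum(sex[mcd_ids] == "female"))
  unflagged <- sapply(1:20, function(d) {
    rssm <- draw_rssm(cs_ids, sex, target, seed = 100 + d)
    res <- compare_mcd_vs_rssm(beh, NULL, mcd_ids, rssm,
                               measure_subset = planted_measures())
    !any(res$behavior$significant)
  })
  expect_gte(mean(unflagged), 0.95)
})

test_that("dissimilarity-behavior correlation matches the hand oracle", {
  ids <- c("a", "b", "c", "d", "e")
  scores <- setNames(c(0.1, 0.3, 0.2, 0.5, 0.4), ids)
  m <- data.frame(equal = unname(scores),
                  pairs = c(2.0, 1.0, 4.0, 3.0, 5.0))
  beh <- behavior_table(ids, rep("male", 5), m)
  res <- correlate_dissimilarity_with_behaviors(scores, beh)
  expect_equal(res$r[res$measure == "equal"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$measure == "pairs"],
               oracle_pearson(unname(scores), m$pairs), tolerance = 1e-12)
  expect_error(
    correlate_dissimilarity_with_behaviors(setNames(rep(0.2, 5), ids), beh),
    "constant")
})

test_that("independent behaviors stay weakly correlated at n = 200", {
  ok <- sapply(1:20, function(s) {
    set.seed(s)
    ids <- sprintf("s%03d", 1:200)
    scores <- setNames(runif(200), ids)
    beh <- behavior_table(ids, rep("female", 200),
                          data.frame(x = rnorm(200)))
    res <- correlate_dissimilarity_with_behaviors(scores, beh)
    abs(res$r) < 0.2
  })
  expect_gte(mean(ok), 0.95)
})

test_that("behavior table enforces the complete-case contract", {
  expect_error(behavior_table(c("a", "b"), c("male", "female"),
                              data.frame(m = c(1, NA))),
               "complete-case")
  expect_error(behavior_table(c("a", "a"), c("male", "male"),
                              data.frame(m = c(1, 2))), "unique")
  expect_error(behavior_table(c("a", "b"), c("m", "f"),
                              data.frame(m = c(1, 2))), "male")
})
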