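# ---------------------------------------------------------------------------
# Synthetic multi-run datasets with a planted common component, a planted
# dissimilar subgroup, planted behavioral effects and sex imbalance
# ---------------------------------------------------------------------------

#' Synthetic parcellation lookup
#'
#' Builds a SYNTHETIC stand-in for a 17-network cortical parcellation plus
#' 19 subcortical ROIs (the real region-to-network assignment is not
#' shipped). Cortical parcels are split evenly across the 17 network
#' labels with alternating hemispheres; the 19 subcortical labels are the
#' usual bilateral structures plus the brainstem. With `P = 100` there are
#' 81 cortical parcels; with `P = 419`, 400, mirroring the dimensionality
#' of a Schaefer-400-style template.
#'
#' @param P Total number of regions (cortical + 19 subcortical), >= 36.
#' @return A [parcellation_lookup()] with 36 distinct labels.
#' @export
synthetic_parcellation <- function(P = 100L) {
  P <- as.integer(P)
  networks <- c("DefaultA", "DefaultB", "DefaultC",
                "ContA", "ContB", "ContC",
                "SalVentAttnA", "SalVentAttnB",
                "DorsAttnA", "DorsAttnB",
                "LimbicA", "LimbicB",
                "SomMotA", "SomMotB",
                "VisCent", "VisPeri", "TempPar")
  sub_structs <- c("Accumbens", "Amygdala", "Caudate", "Cerebellum",
                   "Diencephalon", "Hippocampus", "Pallidum", "Putamen",
                   "Thalamus")
  n_sub <- 2L * length(sub_structs) + 1L  # bilateral + brainstem = 19
  n_cort <- P - n_sub
  if (n_cort < length(networks))
    stop("P too small: need at least one parcel per cortical network")
  # even allocation, leftovers to the first networks
  sizes <- rep(n_cort %/% 17L, 17L)
  extra <- n_cort %% 17L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  cort_label <- rep(networks, times = sizes)
  cort_hemi <- rep(c("left", "right"), length.out = n_cort)
  # 19 separate subcortical labels: bilateral structures keep their
  # hemisphere in the label so each ROI is its own comparison unit
  sub_label <- c(paste0(rep(sub_structs, each = 2L), c("-L", "-R")),
                 "Brainstem")
  sub_hemi <- c(rep(c("left", "right"), length(sub_structs)), "none")
  lab <- c(cort_label, sub_label)
  hemi <- c(cort_hemi, sub_hemi)
  parcellation_lookup(data.frame(
    region_index = seq_len(P),
    region_name = paste0(ifelse(seq_len(P) <= n_cort, "Parcel_", "ROI_"),
                         lab, "_", seq_len(P)),
    label = lab,
    hemisphere = hemi,
    stringsAsFactors = FALSE))
}

#' Default behavior battery specification (69 measures)
#'
#' One row per measure: category, majority and subgroup means, common
#' standard deviation, whether negative draws are clipped at zero
#' (count-like measures), and an optional additive male shift
#' (`sex_delta`) for building sex-confounded scenarios. The five planted
#' measures carry the substance-use and antisocial group means reported
#' for similarity/dissimilarity subgroups in large healthy cohorts
#' (alcohol 4.84 vs 10.11, tobacco 5.97 vs 18.05, marijuana 1.35 vs 4.59,
#' illicit 0.53 vs 2.19, plus a small antisocial-score shift); their
#' standard deviations are set so the effects are detectable at the
#' default desk-scale cohort (120 subjects), not at the original cohort
#' scale. All other 64 measures have equal group means.
#'
#' @return data.frame with columns `measure`, `category`, `mean_majority`,
#'   `mean_subgroup`, `sd`, `clip0`, `sex_delta`.
#' @export
default_behavior_spec <- function() {
  row <- function(measure, category, m1, m2, sd, clip0 = FALSE, sexd = 0)
    data.frame(measure = measure, category = category, mean_majority = m1,
               mean_subgroup = m2, sd = sd, clip0 = clip0, sex_delta = sexd,
               stringsAsFactors = FALSE)
  null_block <- function(names, category, m, s, clip0 = FALSE)
    do.call(rbind, lapply(names, row, category = category, m1 = m, m2 = m,
                          sd = s, clip0 = clip0))
  spec <- rbind(
    # --- planted effects ---------------------------------------------------
    row("Total_Drinks_7_Days", "substance use", 4.84, 10.11, 2.0, TRUE),
    row("Total_Any_Tobacco_7_Days", "substance use", 5.97, 18.05, 4.5, TRUE),
    row("SSAGA_Mj_Times_Used", "substance use", 1.35, 4.59, 1.2, TRUE),
    row("SSAGA_Times_Used_Illicits", "substance use", 0.53, 2.19, 0.6, TRUE),
    row("DSM_Antis_Pct", "psychiatric & life function", 53, 58, 2.0),
    # --- null measures -----------------------------------------------------
    null_block(c("PicSeq_AgeAdj", "CardSort_AgeAdj", "Flanker_AgeAdj",
                 "PMAT24_A_CR", "ReadEng_AgeAdj", "PicVocab_AgeAdj",
                 "ProcSpeed_AgeAdj", "DDisc_AUC_40K", "VSPLOT_TC",
                 "SCPT_SEN", "SCPT_SPEC", "IWRD_TOT", "ListSort_AgeAdj",
                 "WM_Task_Acc"), "cognition", 100, 15),
    null_block(c("MMSE_Score", "PSQI_Score"), "alertness", 15, 4),
    null_block(c("ER40_CR", "AngAffect_Unadj", "AngHostil_Unadj",
                 "AngAggr_Unadj", "FearAffect_Unadj", "FearSomat_Unadj",
                 "Sadness_Unadj", "LifeSatisf_Unadj", "MeanPurp_Unadj",
                 "PosAffect_Unadj", "Friendship_Unadj", "Loneliness_Unadj",
                 "PercHostil_Unadj", "PercReject_Unadj", "PercStress_Unadj"),
               "emotion", 50, 10),
    null_block(c("NEOFAC_A", "NEOFAC_O", "NEOFAC_C", "NEOFAC_N",
                 "NEOFAC_E"), "personality", 30, 6),
    null_block(c("Odor_Unadj", "Taste_Unadj", "PainInterf_Tsum",
                 "Mars_Log_Score", "Noise_Comp"), "sensory", 100, 12),
    null_block(c("SSAGA_Educ", "SSAGA_Income", "FamHist_Fath_Alc",
                 "FamHist_Moth_Dep", "Handedness"),
               "health/family history", 10, 3),
    null_block(c("ASR_Anxd_Pct", "ASR_Witd_Pct", "ASR_Intn_T", "ASR_Extn_T",
                 "ASR_Attn_Pct", "ASR_Aggr_Pct", "ASR_Rule_Pct",
                 "ASR_Intr_Pct", "DSM_Depr_Pct", "DSM_Anxi_Pct",
                 "DSM_Adh_Pct"), "psychiatric & life function", 55, 8),
    null_block(c("SSAGA_Alc_Age_1st_Use", "SSAGA_TB_Age_1st_Cig",
                 "SSAGA_Mj_Age_1st_Use", "SSAGA_Alc_12_Drinks_Per_Day"),
               "substance use", 17, 3),
    null_block(c("BPSystolic", "BPDiastolic", "BMI"), "physiological",
               110, 12))
  stopifnot(nrow(spec) == 69L, !anyDuplicated(spec$measure))
  rownames(spec) <- NULL
  spec
}

#' Names of the five planted behavioral measures
#' @export
planted_measures <- function() {
  c("Total_Drinks_7_Days", "Total_Any_Tobacco_7_Days",
    "SSAGA_Mj_Times_Used", "SSAGA_Times_Used_Illicits", "DSM_Antis_Pct")
}

#' Simulation configuration
#'
#' The stated world: a majority of subjects share (up to jitter) one
#' default-mode-concentrated spatial map; a small subgroup has its
#' DMN-A-analog weights reduced by `dmn_reduction` and carries large
#' idiosyncratic perturbations (`subgroup_scatter`) making the subgroup
#' maps mutually dissimilar. Each run of a subject is that subject's map
#' times an AR(1) time course, plus `k_individual` run-specific spatial
#' components with their own AR(1) time courses, plus white noise.
#'
#' @param P Regions (default 100; use 419 for full-scale dimensionality).
#' @param S Subjects (default 120).
#' @param subgroup_size Planted dissimilar subgroup size (default 16; 0
#'   gives a null dataset with no subgroup).
#' @param n_runs Runs per subject (default 4).
#' @param T_len Timepoints per run (default 300).
#' @param k_individual Run-specific components per run (default 5).
#' @param noise_sd White-noise standard deviation sigma (default 0.5).
#' @param map_jitter Within-majority map variability (default 0.1).
#' @param dmn_reduction Delta subtracted from the unit template's
#'   DMN-A-analog weights in the subgroup (default 0.15).
#' @param subgroup_scatter Scale of the subgroup's idiosyncratic map
#'   perturbation (default 0.5).
#' @param ar_coefficient AR(1) coefficient phi of all time courses
#'   (default 0.9), emulating band-limited BOLD smoothness.
#' @param behavior_spec See [default_behavior_spec()].
#' @param p_male_subgroup,p_male_majority Group-conditional male
#'   probabilities (defaults 74/107 and 323/681, the sex fractions
#'   reported for the dissimilar and similar groups).
#' @param seed Integer master seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(P = 100L, S = 120L, subgroup_size = 16L,
                              n_runs = 4L, T_len = 300L, k_individual = 5L,
                              noise_sd = 0.5, map_jitter = 0.1,
                              dmn_reduction = 0.15, subgroup_scatter = 0.5,
                              ar_coefficient = 0.9,
                              behavior_spec = default_behavior_spec(),
                              p_male_subgroup = 74 / 107,
                              p_male_majority = 323 / 681,
                              seed = 1L) {
  stopifnot(subgroup_size < S, dmn_reduction >= 0, noise_sd >= 0,
            map_jitter >= 0, subgroup_scatter >= 0,
            ar_coefficient >= 0, ar_coefficient < 1,
            p_male_subgroup >= 0, p_male_subgroup <= 1,
            p_male_majority >= 0, p_male_majority <= 1,
            n_runs >= 2, T_len >= 2, k_individual >= 0)
  structure(list(P = as.integer(P), S = as.integer(S),
                 subgroup_size = as.integer(subgroup_size),
                 n_runs = as.integer(n_runs), T_len = as.integer(T_len),
                 k_individual = as.integer(k_individual),
                 noise_sd = noise_sd, map_jitter = map_jitter,
                 dmn_reduction = dmn_reduction,
                 subgroup_scatter = subgroup_scatter,
                 ar_coefficient = ar_coefficient,
                 behavior_spec = behavior_spec,
                 p_male_subgroup = p_male_subgroup,
                 p_male_majority = p_male_majority,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# derive a stage/unit-specific sub-seed, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 2654435761 + offset) %% 2147483647)
}

#' Base spatial template of the common component
#'
#' Unit-norm map with elevated default-mode weights: height `h` on the
#' DMN-A-analog regions, 1.4x the baseline on DMN-B/C, baseline `b`
#' elsewhere. The DMN-A height is calibrated to the default effect
#' geometry (reduction 0.15, scatter 0.5, jitter 0.1) so that the norm a
#' subgroup map loses to the DMN-A reduction equals the norm it gains
#' from its idiosyncratic scatter: both groups then renormalize by the
#' same expected factor and the planted contrast stays confined to DMN-A
#' instead of leaking into every label's mean. The template is fixed per
#' parcellation; it does not track configuration changes.
#'
#' @param lookup A [parcellation_lookup()].
#' @return Unit-norm numeric vector of length P.
#' @export
base_template <- function(lookup) {
  delta0 <- 0.15; scatter0 <- 0.5; jitter0 <- 0.1
  P <- nrow(lookup)
  n_a <- sum(lookup$label == "DefaultA")
  n_bc <- sum(lookup$label %in% c("DefaultB", "DefaultC"))
  # 2 delta n_a h - n_a delta^2 = scatter^2 - jitter^2
  h <- ((scatter0^2 - jitter0^2) / n_a + delta0^2) / (2 * delta0)
  b <- sqrt((1 - n_a * h^2) / (1.4^2 * n_bc + P - n_a - n_bc))
  w <- rep(b, P)
  w[lookup$label %in% c("DefaultB", "DefaultC")] <- 1.4 * b
  w[lookup$label == "DefaultA"] <- h
  w / sqrt(sum(w^2))
}

# random direction with expected norm `scale`
perturbation <- function(P, scale) scale * stats::rnorm(P) / sqrt(P)

#' Generate one subject's true spatial map
#'
#' Majority subjects: template plus jitter, renormalized. Subgroup
#' subjects: template with DMN-A-analog weights reduced by
#' `dmn_reduction`, plus a `subgroup_scatter`-scaled idiosyncratic
#' perturbation, renormalized. Uses the ambient RNG.
#'
#' @param config A [simulation_config()].
#' @param group_label `"majority"` or `"subgroup"`.
#' @param lookup Optional precomputed lookup (defaults to
#'   `synthetic_parcellation(config$P)`).
#' @param template Optional precomputed [base_template()].
#' @return Unit-norm numeric vector of length P.
#' @export
generate_subject_map <- function(config, group_label = c("majority", "subgroup"),
                                 lookup = NULL, template = NULL) {
  group_label <- match.arg(group_label)
  if (is.null(lookup)) lookup <- synthetic_parcellation(config$P)
  if (is.null(template)) template <- base_template(lookup)
  m <- template
  if (group_label == "subgroup") {
    m[lookup$label == "DefaultA"] <-
      m[lookup$label == "DefaultA"] - config$dmn_reduction
    m <- m + perturbation(config$P, config$subgroup_scatter)
  } else {
    m <- m + perturbation(config$P, config$map_jitter)
  }
  m / sqrt(sum(m^2))
}

# zero-mean AR(1) time course with unit marginal sd before demeaning
ar1_course <- function(T_len, phi) {
  x <- as.numeric(
    stats::filter(stats::rnorm(T_len, sd = sqrt(1 - phi^2)), phi,
                  method = "recursive",
                  init = stats::rnorm(1)))
  x - mean(x)
}

#' Generate a subject's multi-run stack around a true map
#'
#' Each run is `sqrt(P) * a y' + sum_j sqrt(P) * b_j u_j' + sigma * E`:
#' the shared unit map `a` with a zero-mean AR(1) time course, plus
#' `k_individual` run-specific random unit spatial components
#' (orthogonalized against `a`) with their own AR(1) courses, plus white
#' noise. The `sqrt(P)` amplitude gives component matrices entries of
#' order one, so `sigma` is directly the noise-to-component entry ratio.
#' Uses the ambient RNG.
#'
#' @param true_map Unit-norm numeric vector (length P).
#' @param config A [simulation_config()].
#' @param subject_id Identifier for the resulting stack.
#' @return A [multi_run_stack()] with `n_runs` runs.
#' @export
generate_runs <- function(true_map, config, subject_id = "sim") {
  P <- length(true_map)
  amp <- sqrt(P)
  runs <- lapply(seq_len(config$n_runs), function(n) {
    R <- amp * true_map %o% ar1_course(config$T_len, config$ar_coefficient)
    if (config$k_individual > 0) {
      for (j in seq_len(config$k_individual)) {
        b <- stats::rnorm(P)
        b <- b - sum(b * true_map) * true_map
        b <- b / sqrt(sum(b^2))
        R <- R + amp * b %o% ar1_course(config$T_len, config$ar_coefficient)
      }
    }
    if (config$noise_sd > 0)
      R <- R + config$noise_sd * matrix(stats::rnorm(P * config$T_len), P)
    R
  })
  multi_run_stack(subject_id, runs)
}

#' Generate the behavior table for a labeled cohort
#'
#' Each measure is drawn per subject from a normal with the group's
#' configured mean (plus `sex_delta` for males) and sd; count-like
#' measures (`clip0`) are clipped at zero. Sex is drawn per the
#' group-conditional male probabilities. Uses the ambient RNG.
#'
#' @param true_labels Character vector of `"majority"`/`"subgroup"`.
#' @param config A [simulation_config()].
#' @param subject_ids Ids (default sub001...).
#' @return A [behavior_table()].
#' @export
generate_behaviors <- function(true_labels, config,
                               subject_ids = sprintf("sub%03d", seq_along(true_labels))) {
  S <- length(true_labels)
  spec <- config$behavior_spec
  is_sub <- true_labels == "subgroup"
  p_male <- ifelse(is_sub, config$p_male_subgroup, config$p_male_majority)
  sex <- ifelse(stats::runif(S) < p_male, "male", "female")
  vals <- lapply(seq_len(nrow(spec)), function(i) {
    mu <- ifelse(is_sub, spec$mean_subgroup[i], spec$mean_majority[i]) +
      spec$sex_delta[i] * (sex == "male")
    x <- stats::rnorm(S, mean = mu, sd = spec$sd[i])
    if (spec$clip0[i]) x <- pmax(x, 0)
    x
  })
  measures <- as.data.frame(setNames(vals, spec$measure))
  behavior_table(subject_ids, sex, measures,
                 categories = setNames(spec$category, spec$measure))
}

#' Generate a complete synthetic dataset
#'
#' Composes the map, run and behavior generators under one master seed.
#' Each subject's map and runs are drawn from subject-specific derived
#' seeds, so a subject's data does not depend on cohort size or order.
#' The previous RNG state is restored on exit.
#'
#' @param config A [simulation_config()].
#' @return Object of class `synthetic_dataset`: `stacks` (list of
#'   [multi_run_stack()]), `true_maps` (P x S), `true_labels`,
#'   `behaviors`, `lookup`, `config`.
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  lookup <- synthetic_parcellation(config$P)
  template <- base_template(lookup)
  S <- config$S
  ids <- sprintf("sub%03d", seq_len(S))
  true_labels <- c(rep("subgroup", config$subgroup_size),
                   rep("majority", S - config$subgroup_size))
  true_maps <- matrix(NA_real_, config$P, S, dimnames = list(NULL, ids))
  stacks <- vector("list", S)
  names(stacks) <- ids
  for (i in seq_len(S)) {
    set.seed(derive_seed(config$seed, 1e6 + i))
    true_maps[, i] <- generate_subject_map(config, true_labels[i],
                                           lookup, template)
    set.seed(derive_seed(config$seed, 2e6 + i))
    stacks[[i]] <- generate_runs(true_maps[, i], config, subject_id = ids[i])
  }
  set.seed(derive_seed(config$seed, 3e6))
  behaviors <- generate_behaviors(true_labels, config, subject_ids = ids)
  structure(list(stacks = stacks, true_maps = true_maps,
                 true_labels = setNames(true_labels, ids),
                 behaviors = behaviors, lookup = lookup, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> S = %d (%d subgroup), P = %d, %d runs x %d timepoints\n",
    x$config$S, x$config$subgroup_size, x$config$P, x$config$n_runs,
    x$config$T_len))
  invisible(x)
}
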