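# ---------------------------------------------------------------------------
# Pipeline orchestration: simulate/load -> decompose -> correlate -> select
# -> summarize -> compare -> rssm, with per-stage artifacts and a run report
# ---------------------------------------------------------------------------

#' Extract first common components for a whole cohort
#'
#' Applies [extract_common_components()] with C = 1 to every stack and
#' collects the unit-norm weight columns.
#'
#' @param stacks Named list of [multi_run_stack()] objects.
#' @param config A [cobe_config()] (C forced to 1 for the component
#'   matrix).
#' @return A [component_matrix()], P x S.
#' @export
decompose_cohort <- function(stacks, config = cobe_config()) {
  config$n_components <- 1L
  W <- vapply(stacks,
              function(st) extract_common_components(st, config)$weights[, 1],
              numeric(nrow(stacks[[1]]$runs[[1]])))
  component_matrix(as.matrix(W), names(stacks))
}

#' Pipeline configuration
#'
#' @param out_dir Output directory for stage artifacts.
#' @param sim A [simulation_config()] to generate inputs, or `NULL` to
#'   load them from files.
#' @param manifest,lookup,behaviors,categories Input paths (used when
#'   `sim` is NULL).
#' @param cobe A [cobe_config()].
#' @param mcd An [mcd_config()].
#' @param alpha Familywise level for both comparison batteries.
#' @param rssm_seed Seed of the sex-matched draw.
#' @param rssm_n_draws Number of RSSM draws (>= 2 reports the median p per
#'   measure over draws alongside the first draw's full table).
#' @param stages Stages to run, in order, out of `simulate`, `load`,
#'   `decompose`, `correlate`, `select`, `summarize`, `compare`, `rssm`.
#' @param seed Global seed; stage seeds are derived from it when the
#'   stage-specific config carries no explicit seed.
#' @param write_data Also write the simulated raw runs to disk (slow for
#'   large configs; stage artifacts are always written).
#' @export
pipeline_config <- function(out_dir,
                            sim = simulation_config(),
                            manifest = NULL, lookup = NULL,
                            behaviors = NULL, categories = NULL,
                            cobe = cobe_config(),
                            mcd = mcd_config(),
                            alpha = 0.05,
                            rssm_seed = NULL, rssm_n_draws = 1L,
                            stages = c("simulate", "decompose", "correlate",
                                       "select", "summarize", "compare",
                                       "rssm"),
                            seed = 1L,
                            write_data = FALSE) {
  structure(list(out_dir = out_dir, sim = sim, manifest = manifest,
                 lookup = lookup, behaviors = behaviors,
                 categories = categories, cobe = cobe, mcd = mcd,
                 alpha = alpha, rssm_seed = rssm_seed,
                 rssm_n_draws = as.integer(rssm_n_draws),
                 stages = stages, seed = as.integer(seed),
                 write_data = isTRUE(write_data)),
            class = "pipeline_config")
}

stage_artifact <- function(cfg, name) file.path(cfg$out_dir, name)

#' Run the pipeline
#'
#' Executes the enabled stages in order. Every stage writes a plain
#' tabular artifact so stages are independently re-runnable and diffable;
#' a stage whose inputs are absent (toggled-off upstream stage, no file on
#' disk) fails with an actionable error. A JSON run report with stage
#' status, timings and MD5 digests of the written artifacts is always
#' written.
#'
#' @param cfg A [pipeline_config()].
#' @return The run report (list), invisibly; artifacts under
#'   `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  report <- list(version = as.character(utils::packageVersion("cobemcd")),
                 seed = cfg$seed, stages = list())
  files <- character(0)

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch({
      out <- fun()
      list(status = "ok", outputs = out)
    }, error = function(e) list(status = "failed", error = conditionMessage(e)))
    res$seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    report$stages[[name]] <<- res
    if (res$status == "failed")
      stop(sprintf("stage '%s' failed: %s", name, res$error), call. = FALSE)
    files <<- union(files, res$outputs)
    invisible(res)
  }

  need <- function(what, loader) {
    v <- get0(what, envir = state, inherits = FALSE)
    if (!is.null(v)) return(v)
    v <- loader()
    assign(what, v, envir = state)
    v
  }

  for (stage in cfg$stages) {
    switch(stage,
      simulate = run_stage("simulate", function() {
        sim <- cfg$sim
        if (is.null(sim)) stop("no simulation config supplied")
        ds <- generate_dataset(sim)
        state$stacks <- ds$stacks
        state$lookup <- ds$lookup
        state$behaviors <- ds$behaviors
        state$true_labels <- ds$true_labels
        if (cfg$write_data) write_dataset(ds, file.path(cfg$out_dir, "data"))
        character(0)
      }),
      load = run_stage("load", function() {
        ds <- load_dataset(cfg$manifest, cfg$lookup, cfg$behaviors,
                           cfg$categories)
        state$stacks <- ds$stacks
        state$lookup <- ds$lookup
        state$behaviors <- ds$behaviors
        character(0)
      }),
      decompose = run_stage("decompose", function() {
        if (is.null(state$stacks))
          stop("no input stacks; run the 'simulate' or 'load' stage first")
        state$components <- decompose_cohort(state$stacks, cfg$cobe)
        f <- stage_artifact(cfg, "components.tsv")
        write_components(state$components, f)
        f
      }),
      correlate = run_stage("correlate", function() {
        comp <- need("components", function()
          read_components(stage_artifact(cfg, "components.tsv")))
        state$corr <- common_correlation_matrix(comp)
        f <- stage_artifact(cfg, "correlation.tsv")
        write_correlation(state$corr, f)
        f
      }),
      select = run_stage("select", function() {
        corr <- need("corr", function()
          read_correlation(stage_artifact(cfg, "correlation.tsv")))
        mcd_cfg <- cfg$mcd
        if (is.null(mcd_cfg$seed)) mcd_cfg$seed <- derive_seed(cfg$seed, 41L)
        state$mcd <- select_mcd(corr, mcd_cfg)
        f1 <- stage_artifact(cfg, "groups.csv")
        grp <- data.frame(
          subject_id = corr$subject_ids,
          group = ifelse(corr$subject_ids %in% state$mcd$mcd_ids,
                         "MCD", "CS"))
        utils::write.csv(grp, f1, row.names = FALSE, quote = FALSE)
        f2 <- stage_artifact(cfg, "selection_report.json")
        jsonlite::write_json(list(
          seed = mcd_cfg$seed, threshold = mcd_cfg$threshold,
          n_restarts = mcd_cfg$n_restarts,
          mcd_size = length(state$mcd$mcd_ids),
          cs_size = length(state$mcd$cs_ids),
          max_abs_corr_within = state$mcd$max_abs_corr_within,
          restart_sizes = summary_stats(state$mcd$restart_log$size),
          restart_max_r = summary_stats(state$mcd$restart_log$max_abs_r)),
          f2, auto_unbox = TRUE, digits = NA)
        c(f1, f2)
      }),
      summarize = run_stage("summarize", function() {
        comp <- need("components", function()
          read_components(stage_artifact(cfg, "components.tsv")))
        if (is.null(state$lookup))
          stop("no parcellation lookup available; run 'simulate' or 'load'")
        state$network_table <- summarize_weights_by_network(comp, state$lookup)
        f <- stage_artifact(cfg, "network_weights.csv")
        nw <- data.frame(subject_id = state$network_table$subject_ids,
                         state$network_table$values, check.names = FALSE)
        utils::write.csv(nw, f, row.names = FALSE, quote = FALSE)
        f
      }),
      compare = run_stage("compare", function() {
        groups <- pipeline_groups(cfg, state)
        if (is.null(state$network_table))
          stop("network table missing; run the 'summarize' stage first")
        if (is.null(state$behaviors))
          stop("behavior table missing; run 'simulate' or 'load'")
        net <- compare_network_weights(state$network_table, groups,
                                       alpha = cfg$alpha)
        beh <- compare_behaviors(state$behaviors, groups, alpha = cfg$alpha)
        sexres <- sex_composition_test(groups, state$behaviors)
        state$net_cmp <- net; state$beh_cmp <- beh
        f1 <- stage_artifact(cfg, "network_comparison.csv")
        utils::write.csv(as.data.frame(net), f1, row.names = FALSE,
                         quote = FALSE)
        f2 <- stage_artifact(cfg, "behavior_comparison.csv")
        utils::write.csv(as.data.frame(beh), f2, row.names = FALSE,
                         quote = FALSE)
        f3 <- stage_artifact(cfg, "sex_composition.json")
        jsonlite::write_json(list(counts = sexres$counts,
                                  statistic = sexres$statistic,
                                  df = sexres$df, p = sexres$p),
                             f3, auto_unbox = TRUE, digits = NA)
        c(f1, f2, f3)
      }),
      rssm = run_stage("rssm", function() {
        groups <- pipeline_groups(cfg, state)
        if (is.null(state$beh_cmp))
          stop("full behavioral comparison missing; run 'compare' first")
        flagged <- state$beh_cmp$measure[state$beh_cmp$significant]
        if (length(flagged) == 0L) flagged <- planted_measures()
        sex <- setNames(state$behaviors$sex, state$behaviors$subject_ids)
        target <- table(factor(sex[groups$mcd], c("male", "female")))
        seed0 <- if (is.null(cfg$rssm_seed)) derive_seed(cfg$seed, 97L)
                 else cfg$rssm_seed
        draws <- lapply(seq_len(cfg$rssm_n_draws), function(d) {
          rssm <- draw_rssm(groups$cs, sex,
                            c(male = unname(target[["male"]]),
                              female = unname(target[["female"]])),
                            seed = derive_seed(seed0, d))
          compare_mcd_vs_rssm(state$behaviors, state$network_table,
                              groups$mcd, rssm, alpha = cfg$alpha,
                              measure_subset = flagged)
        })
        first <- draws[[1]]
        med_p <- apply(vapply(draws, function(d) d$behavior$p_raw,
                              numeric(length(flagged))), 1,
                       stats::median)
        f1 <- stage_artifact(cfg, "rssm_behavior_comparison.csv")
        tab <- as.data.frame(first$behavior)
        tab$median_p_over_draws <- med_p
        utils::write.csv(tab, f1, row.names = FALSE, quote = FALSE)
        f2 <- stage_artifact(cfg, "rssm_network_comparison.csv")
        utils::write.csv(as.data.frame(first$network), f2,
                         row.names = FALSE, quote = FALSE)
        c(f1, f2)
      }),
      stop("unknown stage: ", stage)
    )
  }

  report$artifacts <- as.list(tools::md5sum(files[file.exists(files)]))
  jsonlite::write_json(report, stage_artifact(cfg, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

# groups from state or from a groups.csv written by an earlier run
pipeline_groups <- function(cfg, state) {
  if (!is.null(state$mcd))
    return(list(mcd = state$mcd$mcd_ids, cs = state$mcd$cs_ids))
  f <- stage_artifact(cfg, "groups.csv")
  if (!file.exists(f))
    stop("selection stage has not run and no groups.csv found; ",
         "run the 'select' stage first")
  grp <- utils::read.csv(f, stringsAsFactors = FALSE)
  list(mcd = grp$subject_id[grp$group == "MCD"],
       cs = grp$subject_id[grp$group == "CS"])
}

summary_stats <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(list(min = NA, median = NA, max = NA))
  list(min = min(x), median = stats::median(x), max = max(x))
}

#' Sweep the dissimilarity threshold
#'
#' Runs [select_mcd()] at each threshold with a shared base seed and
#' reports the resulting set size and within-set maximum absolute
#' correlation. A threshold under which no pair qualifies is recorded
#' with size 0 rather than raising an error.
#'
#' @param corr A `common_correlation`.
#' @param taus Numeric vector of thresholds in (0, 1).
#' @param n_restarts Restarts per threshold.
#' @param seed Base seed shared across thresholds.
#' @return data.frame with columns `tau`, `mcd_size`, `max_abs_corr_within`.
#' @export
sweep_threshold <- function(corr, taus, n_restarts = 1000L, seed = 1L) {
  if (length(taus) == 0L) stop("empty threshold list")
  if (any(taus <= 0 | taus >= 1)) stop("thresholds must lie in (0, 1)")
  do.call(rbind, lapply(taus, function(tau) {
    res <- tryCatch(
      select_mcd(corr, mcd_config(threshold = tau, n_restarts = n_restarts,
                                  seed = seed)),
      error = function(e) NULL)
    if (is.null(res))
      data.frame(tau = tau, mcd_size = 0L, max_abs_corr_within = NA_real_)
    else
      data.frame(tau = tau, mcd_size = length(res$mcd_ids),
                 max_abs_corr_within = res$max_abs_corr_within)
  }))
}
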