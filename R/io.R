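# ---------------------------------------------------------------------------
# Plain-text interchange formats: run matrices + manifest, components TSV,
# correlation TSV, lookup TSV, behavior CSV, group CSV
# ---------------------------------------------------------------------------

#' Write a numeric matrix as delimited text
#'
#' Tab-delimited, no header, full double precision (`%.17g`) so a
#' write/read round trip is lossless.
#' @param m Numeric matrix.
#' @param path Output file.
#' @export
write_matrix_txt <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = "\t")), con)
  invisible(path)
}

#' Read a delimited numeric matrix (no header)
#' @param path Input file.
#' @export
read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE,
                              colClasses = "numeric"))
}

#' Write a synthetic dataset to disk
#'
#' Produces exactly the input formats the pipeline consumes: a manifest
#' CSV (`subject_id,run_index,path`), one delimited matrix file per run, a
#' behavior CSV (`subject_id,sex,<measures>`), a measure-category TSV, a
#' parcellation lookup TSV and a JSON metadata file echoing the
#' configuration and seed.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (id in names(dataset$stacks)) {
    st <- dataset$stacks[[id]]
    for (k in seq_along(st$runs)) {
      rel <- file.path("runs", sprintf("%s_run%d.tsv", id, st$run_index[k]))
      write_matrix_txt(st$runs[[k]], file.path(dir, rel))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, run_index = st$run_index[k], path = rel)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  beh <- dataset$behaviors
  utils::write.csv(cbind(data.frame(subject_id = beh$subject_ids,
                                    sex = beh$sex), beh$measures),
                   file.path(dir, "behaviors.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(measure = names(beh$categories),
                                category = unname(beh$categories)),
                     file.path(dir, "measure_categories.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_lookup(dataset$lookup, file.path(dir, "lookup.tsv"))
  meta <- dataset$config
  meta$behavior_spec <- NULL
  jsonlite::write_json(
    list(config = unclass(meta),
         true_labels = as.list(dataset$true_labels)),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write / read a parcellation lookup TSV
#' @param lookup A [parcellation_lookup()].
#' @param path File path.
#' @export
write_lookup <- function(lookup, path) {
  utils::write.table(as.data.frame(lookup), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  parcellation_lookup(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read a component matrix TSV
#'
#' P rows by 1 + S columns: `region_index`, then one column per
#' subject component, header `subject_id:component_index`.
#' @param components A [component_matrix()].
#' @param path File path.
#' @export
write_components <- function(components, path) {
  W <- components$weights
  df <- data.frame(region_index = seq_len(nrow(W)))
  df <- cbind(df, as.data.frame(W))
  names(df) <- c("region_index", paste0(components$subject_ids, ":1"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_components
#' @export
read_components <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- sub(":[0-9]+$", "", names(df)[-1])
  component_matrix(as.matrix(df[, -1, drop = FALSE]), ids)
}

#' Write / read a correlation matrix TSV (ids as header row and column)
#' @param corr A `common_correlation`.
#' @param path File path.
#' @export
write_correlation <- function(corr, path) {
  df <- data.frame(subject_id = corr$subject_ids,
                   corr$r, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correlation
#' @export
read_correlation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df$subject_id)
  r <- as.matrix(df[, -1, drop = FALSE])
  # guard against textual round-off breaking exact symmetry
  r <- (r + t(r)) / 2
  diag(r) <- 1
  common_correlation(r, ids)
}

#' Read a behavior CSV (+ optional measure-category TSV)
#' @param path Behavior CSV with header `subject_id,sex,<measures>`.
#' @param categories_path Optional TSV `measure<TAB>category`.
#' @export
read_behaviors <- function(path, categories_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "sex") %in% names(df)))
    stop("behavior CSV needs subject_id and sex columns")
  meas <- df[, setdiff(names(df), c("subject_id", "sex")), drop = FALSE]
  cats <- NULL
  if (!is.null(categories_path)) {
    cd <- utils::read.delim(categories_path, stringsAsFactors = FALSE)
    cats <- setNames(cd$category, cd$measure)[names(meas)]
    names(cats) <- names(meas)
  }
  behavior_table(df$subject_id, df$sex, meas, categories = cats)
}

#' Load a dataset from manifest, lookup and behavior files
#'
#' Cross-validates the three sources and returns their id intersection;
#' subjects missing from any source are excluded with a warning (strict
#' mode: error). A matrix file whose row count disagrees with the lookup
#' is a hard error naming the file.
#'
#' @param manifest_path CSV `subject_id,run_index,path` (paths relative to
#'   the manifest's directory).
#' @param lookup_path Parcellation lookup TSV.
#' @param behavior_path Behavior CSV.
#' @param categories_path Optional measure-category TSV.
#' @param strict Error instead of excluding inconsistent subjects.
#' @return List: `stacks`, `lookup`, `behaviors` (restricted to retained
#'   ids), `excluded` (character vector of dropped ids).
#' @export
load_dataset <- function(manifest_path, lookup_path, behavior_path,
                         categories_path = NULL, strict = FALSE) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "run_index", "path") %in% names(man)))
    stop("manifest needs columns subject_id, run_index, path")
  lookup <- read_lookup(lookup_path)
  behaviors <- read_behaviors(behavior_path, categories_path)
  base <- dirname(manifest_path)
  P <- nrow(lookup)
  man_ids <- unique(man$subject_id)
  beh_ids <- behaviors$subject_ids
  keep <- intersect(man_ids, beh_ids)
  excluded <- union(setdiff(man_ids, keep), setdiff(beh_ids, keep))
  if (length(excluded)) {
    msg <- paste("excluding subjects missing from manifest or behaviors:",
                 paste(sort(excluded), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  stacks <- lapply(keep, function(id) {
    rows <- man[man$subject_id == id, , drop = FALSE]
    rows <- rows[order(rows$run_index), , drop = FALSE]
    runs <- lapply(seq_len(nrow(rows)), function(i) {
      f <- file.path(base, rows$path[i])
      m <- read_matrix_txt(f)
      if (nrow(m) != P)
        stop(sprintf("matrix file %s has %d rows but lookup has %d regions",
                     rows$path[i], nrow(m), P))
      m
    })
    multi_run_stack(id, runs, rows$run_index)
  })
  names(stacks) <- keep
  ib <- match(keep, behaviors$subject_ids)
  behaviors <- behavior_table(keep, behaviors$sex[ib],
                              behaviors$measures[ib, , drop = FALSE],
                              behaviors$categories)
  list(stacks = stacks, lookup = lookup, behaviors = behaviors,
       excluded = sort(excluded))
}
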