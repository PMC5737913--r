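# Plain-text serialization: mention tables and rankings as delimited text,
# sparse datasets as MatrixMarket triplets with sidecars, configs as YAML.

#' Read and write mention tables
#'
#' Mention tables are delimited text with header
#' `patient_id,visit_id,kind,concept_id` and stable column order.
#'
#' @param mentions A mention table data frame.
#' @param path File path.
#' @return `read_mentions()` returns a `mention_table` data frame;
#'   `write_mentions()` returns `path` invisibly.
#' @export
write_mentions <- function(mentions, path) {
  mentions <- as_mention_table(mentions)
  write.csv(mentions[c("patient_id", "visit_id", "kind", "concept_id")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mentions
#' @export
read_mentions <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(patient_id = "integer",
                               visit_id = "integer",
                               kind = "character",
                               concept_id = "character"))
  structure(as_mention_table(m), class = c("mention_table", "data.frame"))
}

#' Serialize a case/control dataset
#'
#' Writes the sparse binary matrix in MatrixMarket coordinate format plus
#' two delimited sidecars: per-patient labels and selected visits
#' (`labels.csv`) and column metadata (`columns.csv`).  `read_case_control()`
#' restores the dataset losslessly.
#'
#' @param ds A `"case_control"` dataset.
#' @param dir Directory to write into (created if needed).
#' @return `dir` invisibly; `read_case_control()` returns the dataset.
#' @export
write_case_control <- function(ds, dir) {
  stopifnot(inherits(ds, "case_control"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ds$x, file.path(dir, "matrix.mtx"))
  write.csv(data.frame(patient_id = ds$patient_id, y = ds$y,
                       selected_visit = ds$selected_visit),
            file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  write.csv(ds$columns, file.path(dir, "columns.csv"),
            row.names = FALSE, quote = FALSE)
  meta <- list(index_condition = ds$index_condition,
               feature_window = ds$feature_window,
               dropped_concepts = as.list(ds$dropped_concepts),
               seed = ds$seed)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_case_control
#' @export
read_case_control <- function(dir) {
  x <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  x <- methods::as(1 * x, "CsparseMatrix")  # pattern matrices to numeric
  labels <- read.csv(file.path(dir, "labels.csv"))
  columns <- read.csv(file.path(dir, "columns.csv"),
                      stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  colnames(x) <- columns$concept_id
  structure(
    list(x = x, y = as.integer(labels$y),
         patient_id = labels$patient_id,
         selected_visit = labels$selected_visit,
         columns = columns,
         index_condition = meta$index_condition,
         feature_window = meta$feature_window,
         dropped_concepts = unlist(meta$dropped_concepts) %||% character(0),
         seed = meta$seed %||% NA_integer_),
    class = "case_control"
  )
}

#' Write ranking tables as delimited text
#'
#' `write_association_table()` writes the machine-readable association
#' ranking (`concept_id,kind,coef,adjusted_or,p_value,p_adjusted,rank,`
#' `separation_flag`); `write_tabulation_table()` writes the baseline
#' ranking (`concept_id,a,b,c,d,unadjusted_or,p_value,rank`);
#' `write_class_table()` writes the comorbidity/class coefficient ranking
#' from [rank_comorbidities()].
#'
#' @param tab Table to write.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_association_table <- function(tab, path) {
  stopifnot(inherits(tab, "association_table"))
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
write_tabulation_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
write_class_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write simulation configs as YAML
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `sim_config_from_yaml()` returns a validated [sim_config()];
#'   `sim_config_to_yaml()` returns `path` invisibly.
#' @export
sim_config_to_yaml <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- unclass(config)
  obj$conditions <- as.list(setNames(config$conditions$prevalence,
                                     config$conditions$condition_id))
  df_to_list <- function(df) {
    if (is.null(df)) return(NULL)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  obj$comorbidity_links <- df_to_list(config$comorbidity_links)
  obj$treatments <- df_to_list(config$treatments)
  obj$noise_meds <- df_to_list(config$noise_meds)
  obj$class_preference_effects <- df_to_list(config$class_preference_effects)
  obj$class_map <- if (is.null(config$class_map)) NULL else
    as.list(config$class_map)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname sim_config_to_yaml
#' @export
sim_config_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  list_to_df <- function(x) {
    if (is.null(x) || !length(x)) return(NULL)
    do.call(rbind, lapply(x, function(r) as.data.frame(r)))
  }
  sim_config(
    n_patients = obj$n_patients,
    conditions = unlist(obj$conditions),
    comorbidity_links = list_to_df(obj$comorbidity_links),
    treatments = list_to_df(obj$treatments),
    noise_meds = list_to_df(obj$noise_meds),
    class_map = if (is.null(obj$class_map)) NULL else
      unlist(obj$class_map),
    class_preference_effects = list_to_df(obj$class_preference_effects),
    visit_count_mean = obj$visit_count_mean %||% 4,
    visit_count_dispersion = obj$visit_count_dispersion %||% 2,
    recording_prob = obj$recording_prob %||% 0.9,
    seed = obj$seed %||% 1L
  )
}
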