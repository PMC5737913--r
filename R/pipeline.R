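#' Run the full detection pipeline on one config
#'
#' Generates (or accepts) a population, fits the regression association
#' model and the tabulation baseline, optionally fits the class-preference
#' model, and evaluates both rankings against an indication reference
#' and/or the simulator truth.  This is the programmatic equivalent of the
#' command-line `run-all`, with structured logging of cohort sizes, the
#' concepts retained at each step, and the chosen penalties.
#'
#' @param config A [sim_config()]; ignored if `mentions` is supplied.
#' @param index_condition Condition id whose treatments are sought.
#' @param mentions Optional pre-existing mention table (with `truth = NULL`
#'   unless supplied).
#' @param truth Optional `"truth_set"` accompanying `mentions`.
#' @param reference Optional `"reference_set"` or path to one.
#' @param class_map Optional named medication-to-class vector; when given,
#'   the class-preference model is fitted.
#' @param fdr_q False discovery rate for the discovery report.
#' @param k Top-list depth for evaluation.
#' @param out_dir Optional directory: artifacts are written as delimited
#'   text (mentions, association table, tabulation table, class table,
#'   evaluation summary).
#' @param seed Integer seed for every stochastic step.
#' @param quiet Suppress progress messages.
#' @param ... Passed to [drug_association()].
#' @return A list with `association` (a `"drug_assoc"`), `tabulation`,
#'   `class_model` (or `NULL`), `report_regression`, `report_tabulation`,
#'   `truth`, `seed`.
#' @export
run_pipeline <- function(config = NULL, index_condition,
                         mentions = NULL, truth = NULL,
                         reference = NULL, class_map = NULL,
                         fdr_q = 0.05, k = 30, out_dir = NULL,
                         seed = 1L, quiet = FALSE, ...) {
  say <- function(...) if (!quiet) message(...)
  if (is.null(mentions)) {
    if (is.null(config)) stop_pr("supply `config` or `mentions`")
    say("simulating population (n = ", config$n_patients,
        ", seed = ", config$seed, ")")
    pop <- generate_population(config)
    mentions <- pop$mentions
    truth <- pop$truth
    if (is.null(class_map)) class_map <- config$class_map
  }
  if (is.character(reference)) reference <- load_reference(reference)
  say("fitting association model (seed = ", seed, ")")
  assoc <- drug_association(mentions, index_condition, seed = seed, ...)
  say("cases: ", assoc$n_cases, ", controls: ", assoc$n_controls)
  say("retained per step: ",
      paste(assoc$retention$step, assoc$retention$n_conditions +
              assoc$retention$n_medications, collapse = ", "))
  say("chosen penalty: ", signif(assoc$selection$lambda_star, 4))
  tab <- tabulate_medications(assoc$dataset)
  rep_reg <- discovery_report(assoc$table, ref = reference,
                              condition = index_condition, q = fdr_q,
                              k = k, truth = truth)
  rep_tab <- discovery_report(tab, ref = reference,
                              condition = index_condition, q = fdr_q,
                              k = k, truth = truth)
  class_model <- NULL
  if (!is.null(class_map) && length(class_map)) {
    say("fitting class-preference model")
    class_model <- tryCatch(
      class_preference(mentions, index_condition, class_map, seed = seed),
      error = function(e) {
        say("class-preference model skipped: ", conditionMessage(e))
        NULL
      }
    )
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mentions(mentions, file.path(out_dir, "mentions.csv"))
    write_association_table(assoc$table,
                            file.path(out_dir, "association_table.csv"))
    write_tabulation_table(tab, file.path(out_dir, "tabulation_table.csv"))
    write.csv(assoc$retention, file.path(out_dir, "retention.csv"),
              row.names = FALSE, quote = FALSE)
    if (!is.null(class_model)) {
      write_class_table(
        rank_comorbidities(class_model,
                           top_n = nrow(class_model$coef)),
        file.path(out_dir, "class_table.csv"))
    }
  }
  list(
    association = assoc,
    tabulation = tab,
    class_model = class_model,
    report_regression = rep_reg,
    report_tabulation = rep_tab,
    truth = truth,
    seed = as.integer(seed)
  )
}
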