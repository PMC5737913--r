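# Evaluation against a medication-indication reference and against
# simulator ground truth.

#' Load a medication-indication reference
#'
#' Reads a two-column delimited text file with header
#' `medication_id,condition_id` (the format of a high-precision
#' indication subset), deduplicates pairs, and records provenance.
#'
#' @param path Path to the file.
#' @param provenance Label stored with the set; defaults to the file name.
#' @return An object of class `"reference_set"` with `pairs` (data frame
#'   `medication_id`, `condition_id`) and `provenance`.
#' @export
load_reference <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop_pr("reference file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("medication_id", "condition_id") %in% names(raw))) {
    stop_pr("reference file needs header medication_id,condition_id")
  }
  bad <- which(is.na(raw$medication_id) | raw$medication_id == "" |
                 is.na(raw$condition_id) | raw$condition_id == "")
  if (length(bad)) {
    stop_pr("malformed reference row at line ", bad[1] + 1L)
  }
  pairs <- unique(raw[c("medication_id", "condition_id")])
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, provenance = provenance),
            class = "reference_set")
}

#' Write a medication-indication reference
#'
#' @param ref A `"reference_set"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  write.csv(ref$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @exportS3Method base::print
print.reference_set <- function(x, ...) {
  cat("Indication reference (", x$provenance, "): ",
      nrow(x$pairs), " pairs\n", sep = "")
  invisible(x)
}

# Extract the ranked medication ids from an association or tabulation
# table (or pass a character vector through).
ranked_meds <- function(ranked) {
  if (is.character(ranked)) return(ranked)
  if (inherits(ranked, "association_table")) {
    return(ranked$concept_id[ranked$kind == "medication"])
  }
  if (is.data.frame(ranked) && "concept_id" %in% names(ranked)) {
    if ("kind" %in% names(ranked)) {
      return(ranked$concept_id[ranked$kind == "medication"])
    }
    return(ranked$concept_id)
  }
  stop_pr("cannot extract a ranked medication list from `ranked`")
}

#' Precision at k against an indication reference
#'
#' Fraction of the top `k` ranked medications having a
#' (medication, condition) pair in the reference.
#'
#' @param ranked Ranked medications: a character vector (best first), an
#'   association table, or a tabulation table.
#' @param ref A `"reference_set"`.
#' @param condition Condition id the pairs must match.
#' @param k Depth, default 30.  If fewer than `k` medications are ranked,
#'   the precision is evaluated at the list length with a warning.
#' @return Proportion in \[0, 1\].
#' @export
precision_at_k <- function(ranked, ref, condition, k = 30) {
  stopifnot(inherits(ref, "reference_set"), k >= 1)
  meds <- ranked_meds(ranked)
  if (!length(meds)) stop_pr("empty ranking")
  if (length(meds) < k) {
    warning("ranking has only ", length(meds),
            " medications; evaluating at that depth", call. = FALSE)
    k <- length(meds)
  }
  in_ref <- ref$pairs$medication_id[ref$pairs$condition_id == condition]
  mean(meds[seq_len(k)] %in% in_ref)
}

#' Discovery report at a fixed false discovery rate
#'
#' Applies the Benjamini-Hochberg step-up procedure at level `q` to the
#' medication p-values of a ranked table (conditions are excluded — the
#' protocol counts drugs), and reports the discovery count, the proportion
#' of discoveries in the reference, and the top-`k` list with in-reference
#' flags.  When no medication is discovered the proportion is reported as
#' `NA`, never as 0.  When simulator truth is supplied, true-treatment
#' recall at `k` and the confounder-only count in the top `k` are added.
#'
#' @param assoc An association table ([fit_final_logistic()]) or
#'   tabulation table ([tabulate_medications()]).
#' @param ref Optional `"reference_set"`.
#' @param condition Condition id.
#' @param q False discovery rate, default 0.05.
#' @param k Depth of the top list, default 30.
#' @param truth Optional `"truth_set"` from the simulator.
#' @return An object of class `"evaluation_report"`.
#' @export
discovery_report <- function(assoc, ref = NULL, condition, q = 0.05,
                             k = 30, truth = NULL) {
  pcol <- if ("p_value" %in% names(assoc)) "p_value" else
    stop_pr("`assoc` has no p_value column")
  meds <- if ("kind" %in% names(assoc)) {
    assoc[assoc$kind == "medication", , drop = FALSE]
  } else {
    assoc
  }
  if (!nrow(meds)) stop_pr("no medication rows in `assoc`")
  fdr <- adjust_fdr(meds[[pcol]], q = q)
  discovered <- meds$concept_id[fdr$reject]
  ref_meds <- if (!is.null(ref)) {
    ref$pairs$medication_id[ref$pairs$condition_id == condition]
  } else {
    character(0)
  }
  n_disc <- length(discovered)
  prop_in_ref <- if (!is.null(ref) && n_disc > 0) {
    mean(discovered %in% ref_meds)
  } else {
    NA_real_
  }
  kk <- min(k, nrow(meds))
  top <- data.frame(
    concept_id = meds$concept_id[seq_len(kk)],
    in_reference = if (is.null(ref)) NA else
      meds$concept_id[seq_len(kk)] %in% ref_meds,
    stringsAsFactors = FALSE
  )
  rec <- if (!is.null(truth)) {
    truth_recovery(meds$concept_id, truth, condition, k = kk)
  }
  structure(
    list(
      condition = condition,
      q = q,
      k = kk,
      top = top,
      precision_at_k = if (is.null(ref)) NA_real_ else
        mean(top$in_reference),
      n_discoveries = n_disc,
      discoveries = discovered,
      prop_discoveries_in_reference = prop_in_ref,
      truth = rec
    ),
    class = "evaluation_report"
  )
}

#' @exportS3Method base::print
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report for condition", x$condition, "\n")
  if (!is.na(x$precision_at_k)) {
    cat(sprintf("  precision@%d: %.3f (%d of %d in reference)\n",
                x$k, x$precision_at_k, sum(x$top$in_reference), x$k))
  }
  cat("  discoveries at FDR", x$q, ":", x$n_discoveries, "\n")
  cat("  proportion of discoveries in reference:",
      if (is.na(x$prop_discoveries_in_reference)) "n/a" else
        sprintf("%.3f", x$prop_discoveries_in_reference), "\n")
  if (!is.null(x$truth)) {
    cat(sprintf("  true-treatment recall@%d: %.3f; confounders in top %d: %d\n",
                x$k, x$truth$recall, x$k, x$truth$n_confounders))
  }
  invisible(x)
}

#' Score a ranking against simulator ground truth
#'
#' @param ranked Ranked medications (vector or table; best first).
#' @param truth A `"truth_set"` from [generate_population()].
#' @param condition Index condition id.
#' @param k Depth, default 10.
#' @return A list with `recall` (fraction of the condition's true
#'   treatments in the top `k`) and `n_confounders` (confounder-only
#'   medications in the top `k`).
#' @export
truth_recovery <- function(ranked, truth, condition, k = 10) {
  if (!inherits(truth, "truth_set")) {
    stop_pr("`truth` must be a truth_set (synthetic runs only)")
  }
  meds <- ranked_meds(ranked)
  topk <- meds[seq_len(min(k, length(meds)))]
  true_meds <- true_treatment_meds(truth, condition)
  conf <- confounder_meds(truth, condition)
  list(
    recall = if (length(true_meds)) mean(true_meds %in% topk) else
      NA_real_,
    n_confounders = sum(conf %in% topk),
    true_in_top = intersect(topk, true_meds),
    confounders_in_top = intersect(topk, conf)
  )
}
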