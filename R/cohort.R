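# Cohort construction: one-visit-per-patient case/control and class-choice
# datasets from a long-format mention table.

# One selected visit per patient: cases (ever mention the index condition)
# get a uniform draw among visits mentioning it; controls a uniform draw
# among all their visits.  Deterministic given seed.
select_visits <- function(mentions, index_condition, seed) {
  is_index <- mentions$kind == "condition" &
    mentions$concept_id == index_condition
  case_ids <- unique(mentions$patient_id[is_index])
  pv <- unique(mentions[, c("patient_id", "visit_id")])
  ipv <- unique(mentions[is_index, c("patient_id", "visit_id")])
  # eligible pool: cases draw among index visits, controls among all visits
  pool <- rbind(pv[!(pv$patient_id %in% case_ids), , drop = FALSE], ipv)
  with_seed(seed, {
    u <- runif(nrow(pool))
    ord <- order(pool$patient_id, u)
    first <- !duplicated(pool$patient_id[ord])
    sel <- pool[ord[first], , drop = FALSE]
    sel <- sel[order(sel$patient_id), , drop = FALSE]
    data.frame(patient_id = sel$patient_id,
               visit_id = sel$visit_id,
               case = sel$patient_id %in% case_ids,
               stringsAsFactors = FALSE,
               row.names = NULL)
  })
}

# Build a patients x concepts binary sparse matrix from mention rows
# restricted to each patient's selected visit.
mentions_to_matrix <- function(rows, patients) {
  concepts <- sort(unique(rows$concept_id))
  kind <- rows$kind[match(concepts, rows$concept_id)]
  i <- match(rows$patient_id, patients)
  j <- match(rows$concept_id, concepts)
  x <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(patients), length(concepts)),
    dimnames = list(NULL, concepts)
  )
  x@x[] <- 1  # collapse duplicate mentions to presence
  list(x = x, columns = data.frame(concept_id = concepts, kind = kind,
                                   stringsAsFactors = FALSE))
}

#' Build the one-visit-per-patient case/control dataset
#'
#' Step 1 of the detection procedure.  Cases are patients with at least one
#' visit mentioning the index condition; everyone else is a control.  For
#' each case one visit is drawn uniformly among visits mentioning the index
#' condition; for each control one visit is drawn uniformly among all their
#' visits.  Features are the binary indicators of every concept (condition
#' or medication) mentioned at the selected visit, excluding the index
#' condition itself, which is captured by the label.
#'
#' @param mentions A mention table (`patient_id`, `visit_id`, `kind`,
#'   `concept_id`).
#' @param index_condition Condition id defining cases.
#' @param seed Integer seed for the visit draws.
#' @param feature_window `"visit"` (default) restricts features to the
#'   selected visit; `"history"` uses each patient's full mention history.
#' @return An object of class `"case_control"`: a list with the sparse 0/1
#'   feature matrix `x` (patients by concepts), integer labels `y`,
#'   `patient_id`, `selected_visit`, column metadata `columns`
#'   (`concept_id`, `kind`), `index_condition`, and the concepts present in
#'   the vocabulary but dropped because no patient mentioned them at a
#'   selected visit (`dropped_concepts`).
#' @export
build_case_control <- function(mentions, index_condition, seed = 1L,
                               feature_window = c("visit", "history")) {
  mentions <- as_mention_table(mentions)
  feature_window <- match.arg(feature_window)
  vocab <- unique(mentions$concept_id)
  if (!(index_condition %in%
        mentions$concept_id[mentions$kind == "condition"])) {
    stop_pr("index condition '", index_condition,
            "' not in the condition vocabulary")
  }
  sel <- select_visits(mentions, index_condition, seed)
  if (!any(sel$case) || all(sel$case)) {
    stop_pr("degenerate design: need at least one case and one control")
  }
  rows <- if (feature_window == "visit") {
    keep <- paste(mentions$patient_id, mentions$visit_id) %in%
      paste(sel$patient_id, sel$visit_id)
    mentions[keep, , drop = FALSE]
  } else {
    mentions
  }
  rows <- rows[!(rows$kind == "condition" &
                   rows$concept_id == index_condition), , drop = FALSE]
  mat <- mentions_to_matrix(rows, sel$patient_id)
  dropped <- setdiff(setdiff(vocab, index_condition),
                     mat$columns$concept_id)
  structure(
    list(
      x = mat$x,
      y = as.integer(sel$case),
      patient_id = sel$patient_id,
      selected_visit = sel$visit_id,
      columns = mat$columns,
      index_condition = index_condition,
      feature_window = feature_window,
      dropped_concepts = dropped,
      seed = as.integer(seed)
    ),
    class = "case_control"
  )
}

#' Construct a case/control dataset directly from a matrix
#'
#' Programmatic constructor used in simulations and tests, bypassing the
#' mention table.
#'
#' @param x Binary matrix or sparse Matrix, patients by concepts, with
#'   column names.
#' @param y 0/1 labels, one per row of `x`.
#' @param kind Character vector of concept kinds (`"condition"` or
#'   `"medication"`), recycled if length 1.
#' @param index_condition Optional index condition id (metadata only).
#' @return A `"case_control"` object.
#' @export
case_control_dataset <- function(x, y, kind = "medication",
                                 index_condition = NA_character_) {
  x <- methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("v", seq_len(ncol(x)))
  }
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% 0:1),
            all(x@x %in% c(0, 1)))
  if (all(y == y[1])) stop_pr("labels are constant")
  kind <- rep_len(kind, ncol(x))
  structure(
    list(
      x = x, y = y,
      patient_id = seq_len(nrow(x)),
      selected_visit = rep(1L, nrow(x)),
      columns = data.frame(concept_id = colnames(x), kind = kind,
                           stringsAsFactors = FALSE),
      index_condition = index_condition,
      feature_window = "visit",
      dropped_concepts = character(0),
      seed = NA_integer_
    ),
    class = "case_control"
  )
}

#' @exportS3Method base::print
print.case_control <- function(x, ...) {
  cat("Case/control dataset\n")
  cat("  index condition:", x$index_condition, "\n")
  cat("  cases:   ", sum(x$y == 1), "\n")
  cat("  controls:", sum(x$y == 0), "\n")
  cat("  features:", ncol(x$x), sprintf("(%d conditions, %d medications)\n",
      sum(x$columns$kind == "condition"),
      sum(x$columns$kind == "medication")))
  if (length(x$dropped_concepts)) {
    cat("  dropped (absent at selected visits):",
        length(x$dropped_concepts), "\n")
  }
  invisible(x)
}

#' Build the drug-class choice dataset
#'
#' Restricts the population to patients with at least one visit where the
#' index condition and at least one class-mapped medication are both
#' mentioned.  One such visit is drawn uniformly per patient; the outcome
#' class is drawn uniformly among the distinct classes whose medications
#' are mentioned at that visit (a visit can mention several classes — the
#' multiplicity survives up to the draw).  Features are the condition
#' mentions at the selected visit, excluding the index condition;
#' medications are excluded by design.
#'
#' @param mentions A mention table.
#' @param index_condition Condition id of interest.
#' @param class_map Named character vector: medication id to class label.
#' @param seed Integer seed.
#' @return An object of class `"class_choice"`: sparse comorbidity matrix
#'   `x`, factor outcome `class` over the configured class labels,
#'   `patient_id`, `selected_visit`, `columns`, `classes`.
#' @export
build_class_choice <- function(mentions, index_condition, class_map,
                               seed = 1L) {
  mentions <- as_mention_table(mentions)
  if (is.null(class_map) || !length(class_map)) {
    stop_pr("`class_map` must be a non-empty named vector")
  }
  classes <- sort(unique(unname(class_map)))
  vk <- paste(mentions$patient_id, mentions$visit_id)
  has_index <- mentions$kind == "condition" &
    mentions$concept_id == index_condition
  mapped_med <- mentions$kind == "medication" &
    mentions$concept_id %in% names(class_map)
  qual_visits <- intersect(unique(vk[has_index]), unique(vk[mapped_med]))
  if (!length(qual_visits)) {
    stop_pr("no patient has a visit mentioning both the index condition ",
            "and a class-mapped medication")
  }
  qual <- mentions[vk %in% qual_visits, , drop = FALSE]
  qvk <- unique(data.frame(patient_id = qual$patient_id,
                           visit_id = qual$visit_id))
  picked <- with_seed(seed, {
    u <- runif(nrow(qvk))
    ord <- order(qvk$patient_id, u)
    first <- !duplicated(qvk$patient_id[ord])
    sel <- qvk[ord[first], , drop = FALSE]
    sel <- sel[order(sel$patient_id), , drop = FALSE]
    skey <- paste(sel$patient_id, sel$visit_id)
    medrows <- qual[qual$kind == "medication" &
                      qual$concept_id %in% names(class_map), , drop = FALSE]
    # distinct (visit, class) pairs at the selected visits; the draw is
    # uniform over the distinct classes mentioned at the visit
    vc <- unique(data.frame(
      key = paste(medrows$patient_id, medrows$visit_id),
      class = unname(class_map[medrows$concept_id]),
      stringsAsFactors = FALSE
    ))
    vc <- vc[vc$key %in% skey, , drop = FALSE]
    vc <- vc[order(vc$key, vc$class), , drop = FALSE]
    u2 <- runif(nrow(vc))
    ord2 <- order(vc$key, u2)
    first2 <- !duplicated(vc$key[ord2])
    win <- vc[ord2[first2], , drop = FALSE]
    list(sel = sel, cls = win$class[match(skey, win$key)])
  })
  sel <- picked$sel
  skey <- paste(sel$patient_id, sel$visit_id)
  feat <- qual[paste(qual$patient_id, qual$visit_id) %in% skey &
                 qual$kind == "condition" &
                 qual$concept_id != index_condition, , drop = FALSE]
  mat <- mentions_to_matrix(feat, sel$patient_id)
  structure(
    list(
      x = mat$x,
      class = factor(picked$cls, levels = classes),
      patient_id = sel$patient_id,
      selected_visit = sel$visit_id,
      columns = mat$columns,
      classes = classes,
      index_condition = index_condition,
      seed = as.integer(seed)
    ),
    class = "class_choice"
  )
}

#' @exportS3Method base::print
print.class_choice <- function(x, ...) {
  cat("Drug-class choice dataset\n")
  cat("  index condition:", x$index_condition, "\n")
  cat("  patients:", length(x$patient_id), "\n")
  cat("  comorbidity features:", ncol(x$x), "\n")
  cat("  class counts:\n")
  print(table(x$class))
  invisible(x)
}
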