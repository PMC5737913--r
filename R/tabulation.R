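# Naive tabulation baseline: per-medication 2x2 tables against case/control
# status, Fisher's exact test, unadjusted odds ratios.

#' Construct a 2x2 contingency table
#'
#' @param a Cases with the medication.
#' @param b Controls with the medication.
#' @param c Cases without the medication.
#' @param d Controls without the medication.
#' @param concept Optional concept id (metadata).
#' @return An object of class `"contingency_2x2"`.
#' @export
contingency_2x2 <- function(a, b, c, d, concept = NA_character_) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_pr("cell counts must be non-negative integers")
  }
  structure(list(a = a, b = b, c = c, d = d, concept = concept),
            class = "contingency_2x2")
}

#' @exportS3Method base::print
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("medication", "no medication"),
                              c("cases", "controls")))
  if (!is.na(x$concept)) cat("Concept:", x$concept, "\n")
  print(m)
  invisible(x)
}

#' Tabulate a concept against case/control status
#'
#' @param ds A `"case_control"` dataset.
#' @param concept A column (concept id) of the dataset.
#' @return A [contingency_2x2()] with `a` = cases with the concept, `b` =
#'   controls with the concept, `c` = cases without, `d` = controls
#'   without.
#' @export
tabulate_concept <- function(ds, concept) {
  stopifnot(inherits(ds, "case_control"))
  j <- match(concept, ds$columns$concept_id)
  if (is.na(j)) stop_pr("unknown concept '", concept, "'")
  x <- as.numeric(ds$x[, j])
  a <- sum(x == 1 & ds$y == 1)
  b <- sum(x == 1 & ds$y == 0)
  contingency_2x2(a, b, sum(ds$y == 1) - a, sum(ds$y == 0) - b,
                  concept = concept)
}

#' Fisher's exact test and unadjusted odds ratio for a 2x2 table
#'
#' The odds ratio is the sample cross-product ratio `a*d / (b*c)`
#' (`Inf` or `0` with a flag when a zero cell makes it degenerate; no
#' continuity correction).  The two-sided p-value sums the hypergeometric
#' probabilities, over all tables with the observed margins, of the tables
#' whose probability does not exceed that of the observed table (with a
#' relative tie tolerance of about 1e-7).
#'
#' @param t A [contingency_2x2()].
#' @param conditional_or If `TRUE`, also report the conditional maximum
#'   likelihood odds ratio from the noncentral hypergeometric model.
#' @return A list with `or`, `p`, `flag` (`"ok"`, `"infinite"`, `"zero"`
#'   or `"undefined"`), and optionally `or_conditional`.
#' @export
fisher_test_2x2 <- function(t, conditional_or = FALSE) {
  stopifnot(inherits(t, "contingency_2x2"))
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  if (a + b + cc + d == 0) stop_pr("empty table")
  num <- a * d
  den <- b * cc
  if (den > 0) {
    or <- num / den
    flag <- if (num == 0) "zero" else "ok"
  } else if (num > 0) {
    or <- Inf
    flag <- "infinite"
  } else {
    or <- NaN
    flag <- "undefined"
  }
  m <- matrix(c(a, cc, b, d), 2, 2)
  p <- fisher.test(m)$p.value
  out <- list(or = or, p = min(p, 1), flag = flag)
  if (conditional_or) {
    out$or_conditional <- unname(fisher.test(m)$estimate)
  }
  out
}

#' Rank tabulation results
#'
#' Sorts by p-value ascending, breaking ties — including the many exact
#' p-values that underflow to zero in large samples — by unadjusted odds
#' ratio descending.
#'
#' @param results Data frame with columns `p_value` and `unadjusted_or`.
#' @return The data frame sorted, with a `rank` column appended.
#' @export
rank_tabulation <- function(results) {
  if (!nrow(results)) stop_pr("no results to rank")
  ord <- order(results$p_value, -results$unadjusted_or, na.last = TRUE)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Tabulation baseline over all medications
#'
#' The naive comparator to [drug_association()]: for every medication
#' column of the case/control dataset, forms the 2x2 table against the
#' labels, applies Fisher's exact test, and ranks by p-value with
#' odds-ratio tie-break.
#'
#' @param ds A `"case_control"` dataset.
#' @param concepts Concept ids to tabulate; defaults to all medication
#'   columns.
#' @return A data frame of class `"tabulation_table"` with columns
#'   `concept_id`, `a`, `b`, `c`, `d`, `unadjusted_or`, `p_value`, `rank`.
#' @export
tabulate_medications <- function(ds, concepts = NULL) {
  stopifnot(inherits(ds, "case_control"))
  if (is.null(concepts)) {
    concepts <- ds$columns$concept_id[ds$columns$kind == "medication"]
  }
  if (!length(concepts)) stop_pr("no medication columns to tabulate")
  rows <- lapply(concepts, function(cid) {
    tb <- tabulate_concept(ds, cid)
    ft <- fisher_test_2x2(tb)
    data.frame(concept_id = cid, a = tb$a, b = tb$b, c = tb$c, d = tb$d,
               unadjusted_or = ft$or, p_value = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- rank_tabulation(do.call(rbind, rows))
  class(out) <- c("tabulation_table", "data.frame")
  out
}
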