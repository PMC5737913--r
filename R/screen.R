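# Feature screening against labels (binary and multiclass).

#' Screen features by correlation with the case/control labels
#'
#' Step 2 of the detection procedure.  Computes the Pearson correlation of
#' each binary concept column with the 0/1 labels, converts it to a
#' two-sided p-value through the t statistic `r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom, and retains columns with `p < alpha`.
#' Zero-variance columns are dropped before testing.  Among retained
#' columns with identical 0/1 patterns (perfectly correlated variables,
#' e.g. two vocabulary labels for one concept) a single representative —
#' the first in column order — is kept and the group is recorded.
#'
#' The screening alpha is deliberately not multiplicity-adjusted; it is a
#' dimension-reduction device, not an inference.
#'
#' @param ds A `"case_control"` dataset.
#' @param alpha Retention threshold in (0, 1), default 0.05.
#' @return An object of class `"screen_result"`: `stats` (per-column
#'   `concept_id`, `kind`, `r`, `p`, `retained`), `retained` (ids surviving
#'   screen and deduplication, in column order), `duplicate_groups` (list
#'   of character vectors, first element the kept representative),
#'   `n_zero_variance`.
#' @export
screen_features <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "case_control"))
  if (alpha <= 0 || alpha >= 1) stop_pr("`alpha` must lie in (0, 1)")
  y <- ds$y
  n <- length(y)
  if (n < 4) stop_pr("need at least 4 patients to screen (t test on n-2 df)")
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop_pr("need at least 2 patients in each label group")
  }
  x <- ds$x
  cs <- Matrix::colSums(x)
  nonconst <- cs > 0 & cs < n
  sy <- sum(y)
  sxy <- as.numeric(Matrix::crossprod(x, y))
  # binary columns: sum(x^2) = sum(x)
  num <- n * sxy - cs * sy
  den <- sqrt((n * cs - cs^2) * (n * sy - sy^2))
  r <- ifelse(nonconst, num / den, NA_real_)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- ifelse(abs(r) >= 1, 0, 2 * pt(-abs(tstat), df = n - 2))
  stats <- data.frame(
    concept_id = ds$columns$concept_id,
    kind = ds$columns$kind,
    r = r,
    p = p,
    retained = !is.na(p) & p < alpha,
    stringsAsFactors = FALSE
  )
  retained_ids <- stats$concept_id[stats$retained]
  # collapse perfectly correlated (identical-pattern) retained columns
  dup_groups <- list()
  if (length(retained_ids) > 1) {
    xs <- x[, retained_ids, drop = FALSE]
    xs <- methods::as(xs, "CsparseMatrix")
    starts <- xs@p[-length(xs@p)] + 1L
    ends <- xs@p[-1L]
    keys <- vapply(seq_along(retained_ids), function(j) {
      if (ends[j] < starts[j]) return("")
      paste(xs@i[starts[j]:ends[j]], collapse = ",")
    }, character(1))
    grp <- split(retained_ids, keys)
    dup_groups <- unname(grp[vapply(grp, length, integer(1)) > 1])
    # keep the first (column-order) member of each duplicate group
    drop <- unlist(lapply(dup_groups, function(g) {
      g[order(match(g, retained_ids))][-1]
    }))
    retained_ids <- setdiff(retained_ids, drop)
  }
  structure(
    list(
      stats = stats,
      retained = retained_ids,
      duplicate_groups = dup_groups,
      n_zero_variance = sum(!nonconst),
      alpha = alpha
    ),
    class = "screen_result"
  )
}

#' @exportS3Method base::print
print.screen_result <- function(x, ...) {
  cat("Correlation screen (alpha =", x$alpha, ")\n")
  cat("  columns tested:   ", nrow(x$stats) - x$n_zero_variance, "\n")
  cat("  zero variance:    ", x$n_zero_variance, "\n")
  cat("  retained:         ", length(x$retained), "\n")
  cat("  duplicate groups: ", length(x$duplicate_groups), "\n")
  invisible(x)
}

#' Screen comorbidities for association with drug-class choice
#'
#' For each comorbidity column, forms the K x 2 contingency table of class
#' against comorbidity presence and applies the chi-square test of
#' independence (no continuity correction); comorbidities with
#' `p < alpha` are retained.  Zero-variance columns are dropped.
#'
#' @param ds A `"class_choice"` dataset.
#' @param alpha Retention threshold in (0, 1).
#' @return A `"screen_result"`-like object with `stats` (`concept_id`,
#'   `statistic`, `p`, `retained`), `retained` ids and `n_zero_variance`.
#' @export
screen_multiclass <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "class_choice"))
  if (alpha <= 0 || alpha >= 1) stop_pr("`alpha` must lie in (0, 1)")
  counts <- table(ds$class)
  if (any(counts == 0)) {
    stop_pr("class(es) with zero patients: ",
            paste(names(counts)[counts == 0], collapse = ", "))
  }
  n <- length(ds$class)
  x <- ds$x
  cs <- Matrix::colSums(x)
  nonconst <- cs > 0 & cs < n
  stat <- p <- rep(NA_real_, ncol(x))
  for (j in which(nonconst)) {
    tab <- table(ds$class, factor(as.numeric(x[, j]), levels = 0:1))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat[j] <- unname(ct$statistic)
    p[j] <- ct$p.value
  }
  stats <- data.frame(
    concept_id = ds$columns$concept_id,
    statistic = stat,
    p = p,
    retained = !is.na(p) & p < alpha,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      stats = stats,
      retained = stats$concept_id[stats$retained],
      duplicate_groups = list(),
      n_zero_variance = sum(!nonconst),
      alpha = alpha
    ),
    class = "screen_result"
  )
}
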