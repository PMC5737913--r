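# Step 4: unpenalized logistic refit on the selected features, adjusted
# odds ratios, Wald p-values and FDR control; plus the drug_association()
# front-end that chains steps 1-4.

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up rule: with order statistics `p_(1) <= ... <= p_(m)`, reject the
#' hypotheses with the `k` smallest p-values, where `k` is the largest
#' index with `p_(k) <= k q / m`.  Adjusted p-values are
#' `min over j >= k of m p_(j) / j`, capped at 1, so that rejection at
#' level `q` is equivalent to an adjusted p-value `<= q`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q Target false discovery rate in (0, 1).
#' @return A list with `reject` (logical, in input order) and `p_adjusted`.
#' @export
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
adjust_fdr <- function(p, q = 0.05) {
  if (q <= 0 || q >= 1) stop_pr("`q` must lie in (0, 1)")
  if (!length(p)) return(list(reject = logical(0), p_adjusted = numeric(0)))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_pr("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  list(reject = reject, p_adjusted = p.adjust(p, method = "BH"))
}

# Flag columns whose 2x2 table against the labels has an empty cell
# (quasi- or complete separation for that column's coefficient).
separation_flags <- function(x, y) {
  cs1 <- as.numeric(Matrix::crossprod(x, y))       # cases with concept
  cs <- Matrix::colSums(x)
  n1 <- sum(y)
  n0 <- length(y) - n1
  a <- cs1; b <- cs - cs1; c <- n1 - cs1; d <- n0 - (cs - cs1)
  a == 0 | b == 0 | c == 0 | d == 0
}

#' Unpenalized logistic refit and association table
#'
#' Step 4 of the detection procedure.  Fits an ordinary maximum-likelihood
#' logistic regression of the labels on the selected features jointly, and
#' reports per feature the coefficient (log adjusted odds ratio), the
#' adjusted odds ratio `exp(beta)`, the two-sided Wald p-value, the
#' Benjamini-Hochberg adjusted p-value, and the rank.  Rows are sorted by
#' p-value ascending with ties broken by odds ratio descending.  P-values
#' below double precision are reported as 0 and ranked by the odds-ratio
#' tie-break.
#'
#' Columns whose 2x2 table against the labels has an empty cell are
#' flagged (`separation_flag`); their Wald statistics are unreliable.  If
#' the fitted model separates the labels perfectly and no individual
#' column is flaggable, an error lists the columns with runaway
#' coefficients.
#'
#' @param ds A `"case_control"` dataset.
#' @param selected A `"selected_set"` from [lasso_select()] or a character
#'   vector of column ids.
#' @return An `"association_table"`: a data frame with columns
#'   `concept_id`, `kind`, `coef`, `adjusted_or`, `p_value`, `p_adjusted`,
#'   `rank`, `separation_flag`.  The fitted `glm` object is attached as
#'   attribute `"fit"`.
#' @export
fit_final_logistic <- function(ds, selected) {
  stopifnot(inherits(ds, "case_control"))
  ids <- if (inherits(selected, "selected_set")) selected$selected
  else as.character(selected)
  if (!length(ids)) stop_pr("`selected` is empty")
  missing <- setdiff(ids, ds$columns$concept_id)
  if (length(missing)) {
    stop_pr("selected ids not in dataset: ",
            paste(head(missing, 5), collapse = ", "))
  }
  x <- ds$x[, ids, drop = FALSE]
  flags <- separation_flags(x, ds$y)
  df <- as.data.frame(as.matrix(x))
  safe <- make.names(ids, unique = TRUE)
  names(df) <- safe
  df$.y <- ds$y
  fit <- suppressWarnings(
    glm(.y ~ ., data = df, family = binomial(),
        control = glm.control(epsilon = 1e-12, maxit = 200))
  )
  co <- summary(fit)$coefficients
  beta <- se <- pv <- setNames(rep(NA_real_, length(ids)), ids)
  rn <- rownames(co)
  for (k in seq_along(ids)) {
    if (safe[k] %in% rn) {
      beta[k] <- co[safe[k], 1]
      se[k] <- co[safe[k], 2]
      pv[k] <- 2 * pnorm(-abs(co[safe[k], 1] / co[safe[k], 2]))
    }
  }
  fitted_p <- fitted(fit)
  fully_separated <- all(abs(fitted_p - ds$y) < 1e-8)
  if (fully_separated && !any(flags)) {
    runaway <- ids[!is.na(beta) & abs(beta) > 10]
    stop_pr("perfect separation of the full model; offending columns: ",
            paste(runaway, collapse = ", "))
  }
  tab <- data.frame(
    concept_id = ids,
    kind = ds$columns$kind[match(ids, ds$columns$concept_id)],
    coef = unname(beta),
    adjusted_or = exp(unname(beta)),
    p_value = unname(pv),
    stringsAsFactors = FALSE
  )
  tab$p_adjusted <- p.adjust(tab$p_value, method = "BH")
  tab$separation_flag <- unname(flags)
  ord <- order(tab$p_value, -tab$adjusted_or, na.last = TRUE)
  tab <- tab[ord, c("concept_id", "kind", "coef", "adjusted_or",
                    "p_value", "p_adjusted", "separation_flag")]
  tab$rank <- seq_len(nrow(tab))
  tab <- tab[, c("concept_id", "kind", "coef", "adjusted_or", "p_value",
                 "p_adjusted", "rank", "separation_flag")]
  rownames(tab) <- NULL
  attr(tab, "fit") <- fit
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' Detect medications associated with an index condition
#'
#' The full four-step procedure over a mention table: (1) one-visit-per-
#' patient case/control dataset via [build_case_control()]; (2) correlation
#' screening via [screen_features()]; (3) LASSO logistic selection under
#' stratified 5-fold cross-validation with the one-standard-error rule via
#' [lasso_select()]; (4) unpenalized logistic refit via
#' [fit_final_logistic()], yielding adjusted odds ratios, Wald p-values and
#' Benjamini-Hochberg adjusted p-values, ranked by p then odds ratio.
#'
#' @param mentions A mention table (`patient_id`, `visit_id`, `kind`,
#'   `concept_id`).
#' @param index_condition Condition id whose treatments are sought.
#' @param alpha_screen Screening threshold, default 0.05.
#' @param n_folds CV folds, default 5.
#' @param penalty_grid_size,penalty_min_ratio Penalty path controls.
#' @param standardize Standardize columns inside the penalized fit?
#' @param feature_window `"visit"` or `"history"`; see
#'   [build_case_control()].
#' @param seed Integer seed governing visit sampling and fold assignment.
#' @return An object of class `"drug_assoc"` with components `table` (the
#'   [association table][fit_final_logistic()]), `screen`, `selection`,
#'   `n_cases`, `n_controls`, `retention` (concepts surviving each step),
#'   `index_condition`, `seed`, `call`.
#' @seealso [tabulate_medications()] for the naive baseline,
#'   [discovery_report()] for evaluation.
#' @export
#' @examples
#' cfg <- sim_config(
#'   n_patients = 400,
#'   conditions = c(htn = 0.4, dm = 0.25),
#'   treatments = data.frame(
#'     medication_id = c("hctz", "metformin"),
#'     condition_id = c("htn", "dm"),
#'     prob = c(0.8, 0.7)
#'   ),
#'   noise_meds = c(vitamin = 0.2),
#'   seed = 11
#' )
#' pop <- generate_population(cfg)
#' fit <- drug_association(pop$mentions, "htn", seed = 11)
#' fit$table
drug_association <- function(mentions, index_condition,
                             alpha_screen = 0.05, n_folds = 5,
                             penalty_grid_size = 100,
                             penalty_min_ratio = 1e-4,
                             standardize = FALSE,
                             feature_window = "visit",
                             seed = 1L) {
  ds <- build_case_control(mentions, index_condition, seed = seed,
                           feature_window = feature_window)
  screen <- screen_features(ds, alpha = alpha_screen)
  if (!length(screen$retained)) {
    stop_pr("no features survive the correlation screen")
  }
  selection <- lasso_select(ds, screen, n_folds = n_folds, seed = seed,
                            grid_size = penalty_grid_size,
                            min_ratio = penalty_min_ratio,
                            standardize = standardize)
  if (!length(selection$selected)) {
    stop_pr("LASSO selected no features at the 1-SE penalty")
  }
  table <- fit_final_logistic(ds, selection)
  retention <- data.frame(
    step = c("dataset", "screen", "lasso", "final"),
    n_conditions = c(sum(ds$columns$kind == "condition"),
                     sum(screen$retained %in%
                           ds$columns$concept_id[
                             ds$columns$kind == "condition"]),
                     sum(selection$selected %in%
                           ds$columns$concept_id[
                             ds$columns$kind == "condition"]),
                     sum(table$kind == "condition")),
    n_medications = c(sum(ds$columns$kind == "medication"),
                      sum(screen$retained %in%
                            ds$columns$concept_id[
                              ds$columns$kind == "medication"]),
                      sum(selection$selected %in%
                            ds$columns$concept_id[
                              ds$columns$kind == "medication"]),
                      sum(table$kind == "medication")),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      table = table,
      screen = screen,
      selection = selection,
      dataset = ds,
      n_cases = sum(ds$y == 1),
      n_controls = sum(ds$y == 0),
      retention = retention,
      index_condition = index_condition,
      seed = as.integer(seed),
      call = match.call()
    ),
    class = "drug_assoc"
  )
}

#' @exportS3Method base::print
print.drug_assoc <- function(x, n = 10, ...) {
  cat("Medication-condition association model\n")
  cat("  index condition:", x$index_condition, "\n")
  cat("  cases:", x$n_cases, " controls:", x$n_controls, "\n")
  cat("  screened:", length(x$screen$retained),
      " selected:", length(x$selection$selected),
      " chosen penalty:", signif(x$selection$lambda_star, 4), "\n")
  cat("Top associations:\n")
  print(head(as.data.frame(x$table), n), digits = 3)
  invisible(x)
}

#' @exportS3Method base::summary
summary.drug_assoc <- function(object, ...) {
  structure(list(model = object), class = "summary.drug_assoc")
}

#' @exportS3Method base::print
print.summary.drug_assoc <- function(x, ...) {
  m <- x$model
  print(m, n = 20)
  cat("\nConcepts retained at each step:\n")
  print(m$retention, row.names = FALSE)
  cat("\nCV deviance at chosen penalty:",
      signif(m$selection$cvm[match(m$selection$lambda_star,
                                   m$selection$lambda)], 4), "\n")
  invisible(x)
}

#' @export
coef.drug_assoc <- function(object, ...) {
  setNames(object$table$coef, object$table$concept_id)
}

#' Predict case probabilities from a fitted association model
#'
#' @param object A `"drug_assoc"` object.
#' @param newdata Optional binary matrix with the selected concepts as
#'   columns; defaults to the training design.
#' @param ... Unused.
#' @return Vector of fitted probabilities of being a case.
#' @export
predict.drug_assoc <- function(object, newdata = NULL, ...) {
  fit <- attr(object$table, "fit")
  if (is.null(newdata)) return(fitted(fit))
  ids <- object$selection$selected
  nd <- as.data.frame(as.matrix(newdata[, ids, drop = FALSE]))
  names(nd) <- make.names(ids, unique = TRUE)
  predict(fit, newdata = nd, type = "response")
}

#' Plot the cross-validation deviance path
#'
#' Mean out-of-fold deviance against `log(lambda)` with one-standard-error
#' bars; vertical lines mark the deviance-minimizing penalty and the 1-SE
#' choice.
#'
#' @param x A `"drug_assoc"` object.
#' @param ... Passed to [plot()].
#' @export
plot.drug_assoc <- function(x, ...) {
  s <- x$selection
  ll <- log(s$lambda)
  graphics::plot(ll, s$cvm, type = "b", pch = 20,
                 xlab = "log(penalty)", ylab = "CV deviance", ...)
  graphics::arrows(ll, s$cvm - s$cvse, ll, s$cvm + s$cvse,
                   angle = 90, code = 3, length = 0.02, col = "grey60")
  graphics::abline(v = log(s$lambda_min), lty = 3)
  graphics::abline(v = log(s$lambda_star), lty = 2)
  invisible(x)
}

#' Residuals of the final logistic fit
#'
#' @param object A `"drug_assoc"` object.
#' @param type Residual type passed to [stats::residuals.glm()].
#' @param ... Unused.
#' @export
residuals.drug_assoc <- function(object, type = "deviance", ...) {
  stats::residuals(attr(object$table, "fit"), type = type)
}
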