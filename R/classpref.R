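# Drug-class preference: L1-penalized multinomial logistic regression of
# class choice on comorbidities, interpreted through pairwise coefficient
# differences and ranked by drop-out penalty.

#' Fit the multinomial LASSO class-preference model
#'
#' Fits `Pr(C = c | X = x) = exp(b_0c + b_c'x) / sum_k exp(b_0k + b_k'x)`
#' with an L1 penalty over a decreasing penalty grid, choosing the penalty
#' by the same stratified cross-validation and one-standard-error rule as
#' the binary pipeline.  No p-values are computed; comorbidities are
#' instead ranked by the drop-out penalty — the largest penalty at which
#' the comorbidity retains a nonzero coefficient for any class.
#'
#' The per-class coefficients of a multinomial logit are identified only up
#' to a common shift per feature; the reported coefficients use the
#' symmetric sum-to-zero parameterization (mean across classes is zero for
#' every feature and for the intercepts), tagged in the model.  Only
#' pairwise differences are interpretable; see [interpret_pair()].
#'
#' @param ds A `"class_choice"` dataset.
#' @param retained A `"screen_result"` from [screen_multiclass()] or a
#'   character vector of comorbidity ids.
#' @param n_folds CV folds, default 5.
#' @param seed Integer seed for fold assignment.
#' @param grid_size,min_ratio Penalty path controls.
#' @param standardize Standardize columns inside the penalized fit?
#' @return An object of class `"class_pref"`: `coef` (comorbidities by
#'   classes matrix, sum-to-zero), `intercepts`, `dropout`, `lambda`,
#'   `cvm`, `cvse`, `lambda_star`, `lambda_min`, `pct_patients`,
#'   `class_counts`, `classes`, `parameterization`.
#' @export
fit_multinomial_lasso <- function(ds, retained, n_folds = 5, seed = 1L,
                                  grid_size = 100, min_ratio = 1e-4,
                                  standardize = FALSE) {
  stopifnot(inherits(ds, "class_choice"))
  ids <- if (inherits(retained, "screen_result")) retained$retained
  else as.character(retained)
  if (!length(ids)) stop_pr("`retained` is empty")
  missing <- setdiff(ids, ds$columns$concept_id)
  if (length(missing)) {
    stop_pr("retained ids not in dataset: ",
            paste(head(missing, 5), collapse = ", "))
  }
  counts <- table(ds$class)
  if (any(counts == 0)) {
    stop_pr("class(es) with zero patients: ",
            paste(names(counts)[counts == 0], collapse = ", "))
  }
  x <- ds$x[, ids, drop = FALSE]
  cv <- cv_lasso_path(x, ds$class, family = "multinomial",
                      n_folds = n_folds, seed = seed,
                      grid_size = grid_size, min_ratio = min_ratio,
                      standardize = standardize)
  K <- length(levels(ds$class))
  beta <- vapply(cv$fit$beta,
                 function(b) as.numeric(b[, cv$index_star]),
                 numeric(length(ids) + as.integer(cv$padded)))
  beta <- matrix(beta, ncol = K,
                 dimnames = list(rownames(cv$fit$beta[[1]]),
                                 levels(ds$class)))
  beta <- beta[rownames(beta) != ".pad", , drop = FALSE]
  a0 <- cv$fit$a0[, cv$index_star]
  # sum-to-zero parameterization: only pairwise differences are identified
  beta <- beta - rowMeans(beta)
  a0 <- a0 - mean(a0)
  structure(
    list(
      coef = beta,
      intercepts = setNames(as.numeric(a0), levels(ds$class)),
      dropout = cv$dropout,
      lambda = cv$lambda,
      cvm = cv$cvm,
      cvse = cv$cvse,
      lambda_star = cv$lambda_star,
      lambda_min = cv$lambda_min,
      pct_patients = setNames(
        100 * as.numeric(Matrix::colSums(x)) / nrow(x), ids),
      class_counts = as.integer(counts),
      classes = levels(ds$class),
      parameterization = "sum-to-zero",
      n_folds = n_folds,
      seed = as.integer(seed)
    ),
    class = "class_pref"
  )
}

#' Model comorbidity-driven preference among drug classes
#'
#' Front-end chaining [build_class_choice()], [screen_multiclass()] and
#' [fit_multinomial_lasso()]: restricts to patients with a visit mentioning
#' both the index condition and a class-mapped medication, draws one such
#' visit and one mentioned class per patient, screens comorbidities by the
#' chi-square test of independence, and fits the penalized multinomial
#' logit.
#'
#' @inheritParams fit_multinomial_lasso
#' @param mentions A mention table.
#' @param index_condition Condition id of interest.
#' @param class_map Named character vector: medication id to class label.
#' @param alpha_screen Chi-square screening threshold, default 0.05.
#' @return A `"class_pref"` object (see [fit_multinomial_lasso()]) with the
#'   screen result and dataset attached.
#' @export
class_preference <- function(mentions, index_condition, class_map,
                             alpha_screen = 0.05, n_folds = 5,
                             grid_size = 100, min_ratio = 1e-4,
                             standardize = FALSE, seed = 1L) {
  ds <- build_class_choice(mentions, index_condition, class_map,
                           seed = seed)
  screen <- screen_multiclass(ds, alpha = alpha_screen)
  if (!length(screen$retained)) {
    stop_pr("no comorbidity survives the chi-square screen")
  }
  model <- fit_multinomial_lasso(ds, screen, n_folds = n_folds,
                                 seed = seed, grid_size = grid_size,
                                 min_ratio = min_ratio,
                                 standardize = standardize)
  model$screen <- screen
  model$dataset <- ds
  model$index_condition <- index_condition
  model$call <- match.call()
  model
}

#' @exportS3Method base::print
print.class_pref <- function(x, n = 13, ...) {
  cat("Drug-class preference model (", x$parameterization,
      " parameterization)\n", sep = "")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  comorbidities:", nrow(x$coef),
      " chosen penalty:", signif(x$lambda_star, 4), "\n")
  cat("Top comorbidities by drop-out penalty:\n")
  print(rank_comorbidities(x, top_n = min(n, nrow(x$coef))), digits = 3)
  invisible(x)
}

#' @export
coef.class_pref <- function(object, ...) object$coef

#' Predicted class probabilities
#'
#' @param object A `"class_pref"` model.
#' @param newdata Binary comorbidity matrix with the model's comorbidities
#'   as columns.
#' @param ... Unused.
#' @return Matrix of class probabilities, one row per patient; rows sum
#'   to 1.
#' @export
predict.class_pref <- function(object, newdata, ...) {
  ids <- rownames(object$coef)
  xm <- as.matrix(newdata)[, ids, drop = FALSE]
  eta <- sweep(xm %*% object$coef, 2, object$intercepts, `+`)
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Odds factor between two drug classes for one comorbidity
#'
#' Returns `exp(beta_a - beta_ref)`: the estimated multiplicative factor by
#' which the comorbidity changes the odds of being prescribed `class_a`
#' rather than `class_ref`.  Because only pairwise differences of
#' multinomial coefficients are identified, this is invariant to the
#' model's parameterization.
#'
#' @param model A `"class_pref"` model, or a numeric coefficient matrix
#'   with comorbidities as rows and classes as columns.
#' @param comorbidity Comorbidity (row) id.
#' @param class_a Class whose odds are in the numerator.
#' @param class_ref Reference class.
#' @return A list of class `"pair_interpretation"` with `difference`
#'   (`beta_a - beta_ref`) and `odds_factor` (`exp(difference)`).
#' @export
#' @examples
#' cf <- matrix(c(0.018, -0.043), nrow = 1,
#'              dimnames = list("asthma", c("A2Blocker", "Beta_Blocker")))
#' interpret_pair(cf, "asthma", "A2Blocker", "Beta_Blocker")
interpret_pair <- function(model, comorbidity, class_a, class_ref) {
  UseMethod("interpret_pair")
}

#' @export
interpret_pair.class_pref <- function(model, comorbidity, class_a,
                                      class_ref) {
  interpret_pair(model$coef, comorbidity, class_a, class_ref)
}

#' @export
interpret_pair.matrix <- function(model, comorbidity, class_a, class_ref) {
  if (!comorbidity %in% rownames(model)) {
    stop_pr("unknown comorbidity '", comorbidity, "'")
  }
  if (!all(c(class_a, class_ref) %in% colnames(model))) {
    stop_pr("unknown class among '", class_a, "', '", class_ref, "'")
  }
  d <- model[comorbidity, class_a] - model[comorbidity, class_ref]
  structure(
    list(comorbidity = comorbidity, class_a = class_a,
         class_ref = class_ref, difference = unname(d),
         odds_factor = unname(exp(d))),
    class = "pair_interpretation"
  )
}

#' @exportS3Method base::print
print.pair_interpretation <- function(x, ...) {
  cat(sprintf(
    "%s multiplies the odds of %s vs %s by %.2f (coef difference %.3f)\n",
    x$comorbidity, x$class_a, x$class_ref, x$odds_factor, x$difference))
  invisible(x)
}

#' Rank comorbidities by LASSO drop-out penalty
#'
#' Orders comorbidities by the largest penalty at which they keep a
#' nonzero coefficient (descending — the model's substitute for a
#' p-value) and returns the coefficient matrix rows with the percent of
#' patients carrying each comorbidity.
#'
#' @param model A `"class_pref"` model.
#' @param top_n Number of comorbidities to return (> 0).
#' @return Data frame: `comorbidity`, one column per class,
#'   `percent_of_patients`, `dropout_penalty`.
#' @export
rank_comorbidities <- function(model, top_n = 13) {
  stopifnot(inherits(model, "class_pref"))
  if (top_n <= 0) stop_pr("`top_n` must be positive")
  ord <- order(-model$dropout, rownames(model$coef), na.last = TRUE)
  ord <- head(ord, top_n)
  out <- data.frame(
    comorbidity = rownames(model$coef)[ord],
    stringsAsFactors = FALSE
  )
  for (cl in model$classes) out[[cl]] <- model$coef[ord, cl]
  out$percent_of_patients <-
    unname(model$pct_patients[rownames(model$coef)[ord]])
  out$dropout_penalty <- unname(model$dropout[ord])
  rownames(out) <- NULL
  out
}
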