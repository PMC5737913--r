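# L1-penalized path fitting with cross-validated one-standard-error penalty
# choice.  One code path serves both the binomial (case/control) and
# multinomial (drug-class) models.

# glmnet needs >= 2 columns; pad single-column designs with an all-zero
# column that can never be selected.
pad_matrix <- function(x) {
  if (ncol(x) >= 2) return(list(x = x, padded = FALSE))
  pad <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(nrow(x), 1),
                              dimnames = list(NULL, ".pad"))
  list(x = cbind(x, pad), padded = TRUE)
}

check_glmnet <- function(fit, lambda) {
  if (!is.null(fit$jerr) && fit$jerr != 0) {
    stop_pr("penalized fit failed to converge near penalty ",
            signif(min(fit$lambda), 4))
  }
  if (length(fit$lambda) < length(lambda)) {
    stop_pr("penalized fit failed to converge at penalty ",
            signif(lambda[length(fit$lambda) + 1L], 4))
  }
  fit
}

# Out-of-fold deviance per penalty for one fitted fold.
fold_deviance <- function(fit, x_te, y_te, family, lambda) {
  eps <- 1e-15
  if (family == "binomial") {
    p <- predict(fit, newx = x_te, s = lambda, type = "response")
    p <- pmin(pmax(p, eps), 1 - eps)
    yv <- as.numeric(y_te)
    -2 * colMeans(yv * log(p) + (1 - yv) * log(1 - p))
  } else {
    arr <- predict(fit, newx = x_te, s = lambda, type = "response")
    ci <- as.integer(y_te)  # factor codes index dim 2
    vapply(seq_along(lambda), function(l) {
      ptrue <- arr[cbind(seq_along(ci), ci, l)]
      -2 * mean(log(pmax(ptrue, eps)))
    }, numeric(1))
  }
}

# Fit the full path, run stratified K-fold CV on a fixed penalty grid, and
# apply the 1-SE rule: the chosen penalty is the largest one whose mean CV
# deviance is within one standard error of the minimum mean CV deviance.
cv_lasso_path <- function(x, y, family = c("binomial", "multinomial"),
                          n_folds = 5, seed = 1L, grid_size = 100,
                          min_ratio = 1e-4, standardize = FALSE) {
  family <- match.arg(family)
  if (n_folds < 2) stop_pr("`n_folds` must be >= 2")
  pm <- pad_matrix(x)
  xw <- pm$x
  full <- check_glmnet(
    glmnet::glmnet(xw, y, family = family, nlambda = grid_size,
                   lambda.min.ratio = min_ratio,
                   standardize = standardize),
    numeric(0)
  )
  lambda <- full$lambda
  strata <- if (family == "binomial") y else as.character(y)
  folds <- with_seed(seed, make_folds(strata, n_folds))
  dev <- matrix(NA_real_, n_folds, length(lambda))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- check_glmnet(
      glmnet::glmnet(xw[tr, , drop = FALSE], y[tr], family = family,
                     lambda = lambda, standardize = standardize),
      lambda
    )
    dev[f, ] <- fold_deviance(fit, xw[!tr, , drop = FALSE], y[!tr],
                              family, lambda)
  }
  cvm <- colMeans(dev)
  cvse <- apply(dev, 2, sd) / sqrt(n_folds)
  i_min <- which.min(cvm)
  threshold <- cvm[i_min] + cvse[i_min]
  i_star <- min(which(cvm <= threshold))  # lambdas are decreasing
  # per-feature drop-out penalty: largest penalty with a nonzero coefficient
  nz <- if (family == "binomial") {
    as.matrix(full$beta != 0)
  } else {
    Reduce(`|`, lapply(full$beta, function(b) as.matrix(b != 0)))
  }
  if (pm$padded) nz <- nz[rownames(nz) != ".pad", , drop = FALSE]
  dropout <- apply(nz, 1, function(rr) {
    if (any(rr)) lambda[min(which(rr))] else NA_real_
  })
  list(
    fit = full,
    lambda = lambda,
    cvm = cvm,
    cvse = cvse,
    lambda_min = lambda[i_min],
    lambda_star = lambda[i_star],
    index_star = i_star,
    dropout = dropout,
    folds = folds,
    padded = pm$padded
  )
}

#' Select predictive features by LASSO logistic regression
#'
#' Step 3 of the detection procedure.  Fits an L1-penalized logistic
#' regression of the case/control labels on the screened features over a
#' decreasing penalty grid (intercept unpenalized), runs stratified
#' `n_folds`-fold cross-validation on the same grid, and selects the
#' penalty by the one-standard-error rule: the largest penalty whose mean
#' out-of-fold deviance is within one standard error of the minimum.  The
#' selected set is the features with nonzero coefficients at that penalty
#' in the full-data fit.
#'
#' By default the binary 0/1 columns are not standardized, so the penalty
#' treats all indicators on the same scale; set `standardize = TRUE` for
#' glmnet-style internal standardization.
#'
#' @param ds A `"case_control"` dataset.
#' @param screened A `"screen_result"` from [screen_features()], or a
#'   character vector of column ids.
#' @param n_folds Number of CV folds (>= 2), default 5.
#' @param seed Integer seed for the fold assignment.
#' @param grid_size Number of penalties on the log-spaced grid.
#' @param min_ratio Smallest penalty as a fraction of the null penalty.
#' @param standardize Standardize columns inside the penalized fit?
#' @return An object of class `"selected_set"`: `selected` (concept ids
#'   with nonzero coefficient at the chosen penalty), `lambda` (the
#'   decreasing penalty path), `cvm`, `cvse`, `lambda_star`, `lambda_min`,
#'   `dropout` (per-feature largest penalty with nonzero coefficient),
#'   `coef_at_star`.
#' @export
lasso_select <- function(ds, screened, n_folds = 5, seed = 1L,
                         grid_size = 100, min_ratio = 1e-4,
                         standardize = FALSE) {
  stopifnot(inherits(ds, "case_control"))
  ids <- if (inherits(screened, "screen_result")) screened$retained
  else as.character(screened)
  if (!length(ids)) stop_pr("no screened features to select from")
  missing <- setdiff(ids, ds$columns$concept_id)
  if (length(missing)) {
    stop_pr("screened ids not in dataset: ",
            paste(head(missing, 5), collapse = ", "))
  }
  x <- ds$x[, ids, drop = FALSE]
  cv <- cv_lasso_path(x, ds$y, family = "binomial", n_folds = n_folds,
                      seed = seed, grid_size = grid_size,
                      min_ratio = min_ratio, standardize = standardize)
  beta <- cv$fit$beta[, cv$index_star]
  names(beta) <- rownames(cv$fit$beta)
  beta <- beta[names(beta) != ".pad"]
  structure(
    list(
      selected = ids[ids %in% names(beta)[beta != 0]],
      lambda = cv$lambda,
      cvm = cv$cvm,
      cvse = cv$cvse,
      lambda_star = cv$lambda_star,
      lambda_min = cv$lambda_min,
      dropout = cv$dropout,
      coef_at_star = beta,
      n_folds = n_folds,
      seed = as.integer(seed)
    ),
    class = "selected_set"
  )
}

#' @exportS3Method base::print
print.selected_set <- function(x, ...) {
  cat("LASSO selection (", x$n_folds, "-fold CV, 1-SE rule)\n", sep = "")
  cat("  penalty grid:   ", length(x$lambda), "values in [",
      signif(min(x$lambda), 3), ",", signif(max(x$lambda), 3), "]\n")
  cat("  chosen penalty: ", signif(x$lambda_star, 4),
      "(deviance-minimizing:", signif(x$lambda_min, 4), ")\n")
  cat("  selected:       ", length(x$selected), "of",
      length(x$dropout), "screened features\n")
  invisible(x)
}
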