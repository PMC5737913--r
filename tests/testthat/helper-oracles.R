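# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (and the library calls that back them).

# Exhaustive Fisher two-sided p: enumerate every table with the observed
# margins, sum the hypergeometric probabilities of tables no more probable
# than the observed one (relative tie tolerance 1e-7).
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b   # row margin: with medication
  n1 <- a + c   # column margin: cases
  n <- a + b + c + d
  lo <- max(0L, m1 + n1 - n)
  hi <- min(m1, n1)
  ks <- lo:hi
  logp <- lchoose(n1, ks) + lchoose(n - n1, m1 - ks) - lchoose(n, m1)
  p_obs <- logp[ks == a]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# Brute-force Benjamini-Hochberg: try every cutoff k explicitly.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  best <- 0L
  for (k in seq_len(m)) {
    if (p[o[k]] <= k * q / m) best <- k
  }
  reject <- logical(m)
  if (best > 0) reject[o[seq_len(best)]] <- TRUE
  reject
}

# Profile-likelihood logistic MLE for a single binary covariate, by direct
# numerical optimization of the log-likelihood over (b0, b1).
oracle_logistic_or <- function(a, b, c, d) {
  nll <- function(th) {
    eta1 <- th[1] + th[2]  # exposed
    eta0 <- th[1]
    -(a * eta1 - (a + b) * log1p(exp(eta1)) +
        c * eta0 - (c + d) * log1p(exp(eta0)))
  }
  fit <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  exp(fit$par[2])
}

# Simulate a case/control dataset from a logistic model with known
# coefficients over independent Bernoulli covariates.
simulate_logistic_cc <- function(n, prev, beta, intercept = -0.5,
                                 seed = 1) {
  set.seed(seed)
  p_feat <- length(prev)
  x <- matrix(rbinom(n * p_feat, 1, rep(prev, each = n)), nrow = n)
  colnames(x) <- paste0("m", seq_len(p_feat))
  eta <- intercept + x %*% beta
  y <- rbinom(n, 1, plogis(eta))
  case_control_dataset(x, y)
}

# Case/control dataset implied by one 2x2 table.
cc_from_table <- function(a, b, c, d, concept = "med") {
  x <- matrix(c(rep(1, a), rep(1, b), rep(0, c), rep(0, d)), ncol = 1,
              dimnames = list(NULL, concept))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  case_control_dataset(x, y)
}
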