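# Internal helpers shared across the package.

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = env)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Stratified fold assignment: within each level of `y`, indices are shuffled
# and dealt cyclically so every fold sees every label.  Consumes the current
# RNG stream; callers wrap in with_seed().
make_folds <- function(y, k) {
  stopifnot(k >= 2)
  fold <- integer(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Uniform draw of one element; avoids sample()'s length-1 surprise.
draw_one <- function(x) {
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), 1L)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pr <- function(...) stop(..., call. = FALSE)
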