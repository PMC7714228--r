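# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child-seed spawning: one master seed fans out to independent
# streams indexed by small integers (k, repeat, stream). Kept below 2^31 - 1.
child_seed <- function(master, a = 0L, b = 0L, stream = 0L) {
  m <- 2147483629
  s <- (abs(as.numeric(master)) %% 1e6) * 1259 +
    as.numeric(a) * 10007 + as.numeric(b) * 101 + as.numeric(stream) * 7919
  as.integer(s %% m) + 1L
}

# z-score with the population (1/N) standard deviation.
zscore_pop <- function(x) {
  m <- mean(x)
  s <- sd_pop(x)
  if (s == 0) {
    stop("cannot z-normalize a constant vector", call. = FALSE)
  }
  (x - m) / s
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

cosine_sim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

check_nonneg_matrix <- function(E, name = "E") {
  if (!is.matrix(E) || !is.numeric(E)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (any(!is.finite(E))) {
    stop(sprintf("`%s` contains non-finite entries", name), call. = FALSE)
  }
  if (any(E < 0)) {
    stop(sprintf("`%s` must be nonnegative", name), call. = FALSE)
  }
  invisible(E)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
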