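# internal helpers: local RNG scoping, truncated normals, assertions

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic entry points route through
# this so that cohorts are reproducible from a single integer.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

# Derive a stream of child seeds from one parent seed, kept below 2^31.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Normal truncated to (lower, Inf), via inverse-CDF so draws stay vectorised
# and reproducible. sd = 0 collapses to the mean.
rtruncnorm_pos <- function(n, mean, sd, lower = 0) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    plo <- pnorm(lower, mean[pos], sd[pos])
    u <- runif(sum(pos), plo, 1)
    out[pos] <- qnorm(u, mean[pos], sd[pos])
  }
  pmax(out, lower + .Machine$double.eps)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_config(...)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
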