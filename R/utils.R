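# internal helpers shared across modules

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-subject seed from a cohort seed; stable under group /
# subject reordering. All arithmetic stays below 2^53 so it is exact in
# doubles, and the result fits a 32-bit integer.
derive_seed <- function(cohort_seed, group_index, subject_index) {
  s <- abs(as.numeric(cohort_seed)) %% 2147483647
  h <- (s * 1000003 + group_index * 10007 + subject_index * 101) %% 2147483629
  as.integer(h + 1)
}

# Trapezoidal integral of y over x restricted to [lo, hi], interpolating the
# endpoint values when lo/hi fall between grid points.
trapz_range <- function(x, y, lo, hi) {
  if (hi <= lo) return(0)
  lo <- max(lo, x[1]); hi <- min(hi, x[length(x)])
  if (hi <= lo) return(0)
  keep <- x > lo & x < hi
  xs <- c(lo, x[keep], hi)
  ys <- c(stats::approx(x, y, lo)$y, y[keep], stats::approx(x, y, hi)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

# Cumulative trapezoid on a grid (same length as x, starting at 0).
cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
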