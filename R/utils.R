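#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist quantile rbinom rnorm runif rpois sd var qt pt
#'   lm glm binomial coef vcov anova pf pchisq cmdscale median fft filter
#'   setNames aggregate as.formula model.matrix qlogis plogis
#' @importFrom utils read.csv write.csv head modifyList
NULL

# upper-triangle vector of a square matrix (row-major invariant order)
upper_tri_vec <- function(m) m[upper.tri(m)]

# z-score a vector; returns NA vector and degenerate flag handled by callers
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x)) / s
}

# all permutations of seq_len(n) as a matrix (n! rows); guarded for small n
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow = nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# deterministic child seed derivation (kept below 2^31)
child_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 1009) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# length-safe uniform sampling (sample() treats a scalar as 1:x)
resample <- function(x, n = 1) x[sample.int(length(x), n)]
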