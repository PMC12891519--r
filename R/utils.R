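# Internal helpers: argument validation, seeded RNG scoping, small stats.

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

assert_scalar_num <- function(x, field, min = -Inf, max = Inf,
                              strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_min && x <= min)
    stop_field(field, sprintf("must be > %g", min))
  if (!strict_min && x < min)
    stop_field(field, sprintf("must be >= %g", min))
  if (x > max)
    stop_field(field, sprintf("must be <= %g", max))
  invisible(x)
}

assert_matrix_like <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("%s must be a numeric matrix (genes x samples)", what),
         call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("%s must have gene rownames and sample colnames", what),
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(sprintf("%s has duplicate gene IDs", what), call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(sprintf("%s has duplicate sample IDs", what), call. = FALSE)
  invisible(x)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched so library code never perturbs user seeds.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed
#'
#' Deterministic fan-out of one pipeline seed into per-stage seeds so any
#' stage can be rerun in isolation. Result is always a valid 32-bit
#' integer seed.
#'
#' @param seed integer global seed.
#' @param k integer stage index (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9973) %% 2147483587L)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions of the same
#' items; 1 for identical partitions, approximately 0 for independent
#' ones. Used to score recovery of planted community structure.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Pearson correlation p-value via the t transform, vectorized.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  t <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df)
  p[df < 1] <- NA_real_
  p
}
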