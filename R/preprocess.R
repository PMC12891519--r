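# Preprocessing: TMM normalization to log2 CPM, expression-fraction and
# IQR informativeness filters, and deterministic location-scale batch
# adjustment.

#' Filter configuration
#'
#' @param min_count a gene must exceed this count (strict `>`) to be
#'   called detected in a sample. Default 1.
#' @param min_fraction minimum fraction of samples (inclusive `>=`) in
#'   which the gene must be detected. Default 0.20.
#' @param iqr_cutoff genes with inter-quartile range strictly below this
#'   value are excluded by [iqr_filter()]. Default 2.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_count = 1L, min_fraction = 0.20,
                          iqr_cutoff = 2) {
  assert_scalar_num(min_count, "min_count", min = 0)
  assert_scalar_num(min_fraction, "min_fraction", min = 0, max = 1)
  assert_scalar_num(iqr_cutoff, "iqr_cutoff", min = 0)
  structure(list(min_count = min_count, min_fraction = min_fraction,
                 iqr_cutoff = iqr_cutoff), class = "filter_config")
}

#' TMM normalization and log2 CPM conversion
#'
#' Trimmed mean of M-values: per-sample scaling factors are the weighted
#' trimmed mean of log2 expression ratios (M-values) against a reference
#' sample, trimming the most extreme `trim_m` of M-values and `trim_a`
#' of average-intensity values, with inverse asymptotic-variance
#' (delta-method) weights. Factors are rescaled to geometric mean 1. The
#' reference is the sample whose 75th count-proportion percentile is
#' closest to the mean across samples.
#'
#' log2CPM = log2((count + 0.5) / (lib_size x factor + 1) x 1e6).
#'
#' @param counts non-negative gene x sample count matrix.
#' @param trim_m fraction trimmed from each tail of the M-values.
#' @param trim_a fraction trimmed from each tail of the A-values.
#' @return list with `log2cpm` matrix (attributes `unit`, `provenance`)
#'   and `factors` (named per-sample scaling factors).
#' @export
tmm_normalize <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  assert_matrix_like(counts, "count matrix")
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop(sprintf("sample(s) with zero total count: %s",
                 paste(colnames(counts)[lib == 0], collapse = ", ")),
         call. = FALSE)
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j] / lib[j], 0.75, names = FALSE), 0)
  ref <- which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(counts)), function(j)
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                    trim_m, trim_a), 0)
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(counts)
  eff_lib <- lib * factors
  log2cpm <- log2(sweep(counts + 0.5, 2, eff_lib + 1, `/`) * 1e6)
  attr(log2cpm, "unit") <- "log2CPM"
  attr(log2cpm, "provenance") <- list(method = "TMM", trim_m = trim_m,
                                      trim_a = trim_a,
                                      reference = colnames(counts)[ref],
                                      factors = factors)
  list(log2cpm = log2cpm, factors = factors)
}

# Weighted trimmed mean of M-values of one sample against the reference.
tmm_pair_factor <- function(y, yr, n, nr, trim_m, trim_a) {
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  if (length(y) == 0) return(1)
  m <- log2((y / n) / (yr / nr))
  a <- 0.5 * log2((y / n) * (yr / nr))
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  lo_m <- stats::quantile(m, trim_m, names = FALSE)
  hi_m <- stats::quantile(m, 1 - trim_m, names = FALSE)
  lo_a <- stats::quantile(a, trim_a, names = FALSE)
  hi_a <- stats::quantile(a, 1 - trim_a, names = FALSE)
  keep2 <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
  if (!any(keep2) || sum(w[keep2]) == 0) return(1)
  f <- 2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
  if (!is.finite(f) || abs(log2(f)) < 1e-10) f <- 1
  f
}

#' Retain genes detected in a minimum fraction of samples
#'
#' A gene is retained iff the fraction of samples with count strictly
#' greater than `min_count` is at least `min_fraction`.
#'
#' @param counts gene x sample count matrix.
#' @param cfg a [filter_config()].
#' @return character vector of retained gene IDs.
#' @export
filter_expressed <- function(counts, cfg = filter_config()) {
  assert_matrix_like(counts, "count matrix")
  frac <- rowMeans(counts > cfg$min_count)
  rownames(counts)[frac >= cfg$min_fraction]
}

#' Retain genes with sufficient inter-quartile range
#'
#' A gene is retained iff its IQR (75th minus 25th percentile, linear
#' interpolation quantiles) is at least `iqr_cutoff`; genes below the
#' cutoff are treated as uninformative and excluded.
#'
#' @param expr gene x sample expression matrix (>= 4 samples).
#' @param cfg a [filter_config()].
#' @return character vector of retained gene IDs.
#' @export
iqr_filter <- function(expr, cfg = filter_config()) {
  assert_matrix_like(expr)
  if (ncol(expr) < 4)
    stop("iqr_filter needs at least 4 samples", call. = FALSE)
  q <- apply(expr, 1, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  iqr <- q[2, ] - q[1, ]
  rownames(expr)[iqr >= cfg$iqr_cutoff]
}

#' Location-scale batch adjustment
#'
#' Per gene and batch, subtracts the batch mean and divides by the batch
#' standard deviation, then restores the gene's pooled mean and pooled
#' standard deviation. A deterministic stand-in for empirical-Bayes batch
#' correction, sufficient for group-level eigengene contrasts.
#'
#' @param expr gene x sample expression matrix.
#' @param batch per-sample batch labels (>= 2 batches, >= 2 samples each).
#' @return adjusted matrix with attribute `unit = "adjusted"`.
#' @export
batch_adjust <- function(expr, batch) {
  assert_matrix_like(expr)
  batch <- as.factor(batch)
  if (length(batch) != ncol(expr))
    stop("batch labels must match sample count", call. = FALSE)
  if (nlevels(batch) < 2) stop("need >= 2 batches", call. = FALSE)
  if (any(table(batch) < 2)) stop("need >= 2 samples per batch", call. = FALSE)
  pooled_mean <- rowMeans(expr)
  # pooled sd = df-weighted within-batch sd, so equal-moment batches map
  # to themselves exactly
  ss <- 0
  for (b in levels(batch)) {
    idx <- which(batch == b)
    sub <- expr[, idx, drop = FALSE]
    ss <- ss + apply(sub, 1, stats::var) * (length(idx) - 1L)
  }
  pooled_sd <- sqrt(ss / (ncol(expr) - nlevels(batch)))
  out <- expr
  skipped <- 0L
  for (b in levels(batch)) {
    idx <- which(batch == b)
    sub <- expr[, idx, drop = FALSE]
    bm <- rowMeans(sub)
    bs <- apply(sub, 1, stats::sd)
    zero <- bs == 0 | pooled_sd == 0
    skipped <- skipped + sum(zero)
    bs[zero] <- 1
    scl <- pooled_sd
    scl[zero] <- 1
    out[, idx] <- (sub - bm) / bs * scl + pooled_mean
  }
  if (skipped > 0)
    warning(sprintf("scale step skipped for %d gene-batch cells with zero variance",
                    skipped), call. = FALSE)
  attr(out, "unit") <- "adjusted"
  attr(out, "provenance") <- list(method = "location-scale",
                                  batches = levels(batch))
  out
}
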