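# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (loops, enumeration, grid search) and never call package code.

# one-factor block matrix: `sizes` modules with given loading, plus
# background genes, Gaussian, unit variance
make_block_expr <- function(sizes, loading = 0.8, n_samples = 100,
                            n_background = 0, seed = 1) {
  withr::with_seed(seed, {
    n_genes <- sum(sizes) + n_background
    labels <- c(rep(seq_along(sizes), sizes), rep(0L, n_background))
    x <- matrix(rnorm(n_genes * n_samples, sd = sqrt(1 - loading^2)),
                n_genes, n_samples)
    x[labels == 0, ] <- rnorm(n_background * n_samples)
    for (m in seq_along(sizes)) {
      if (sizes[m] == 0) next
      e <- rnorm(n_samples)
      x[labels == m, ] <- x[labels == m, , drop = FALSE] +
        loading * matrix(e, sizes[m], n_samples, byrow = TRUE)
    }
    dimnames(x) <- list(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("s%04d", seq_len(n_samples)))
    list(expr = x, labels = stats::setNames(labels, rownames(x)))
  })
}

rand_counts <- function(n_genes = 50, n_samples = 8, seed = 1,
                        mu = 100, size = 5) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
                n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    m
  })
}

# --- oracles ---------------------------------------------------------

# Pearson correlation matrix by explicit loops over the definition
oracle_cor <- function(x) {
  p <- nrow(x)
  out <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    xi <- x[i, ] - mean(x[i, ]); xj <- x[j, ] - mean(x[j, ])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}

# TOM by naive triple loop
oracle_tom <- function(a) {
  p <- nrow(a)
  k <- rowSums(a)
  out <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- sum(a[i, ] * a[, j])
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exact Fisher p by enumeration of the hypergeometric support using
# explicit binomial coefficients on the log scale
oracle_fisher_two_sided <- function(tab) {
  x <- tab[1, 1]; m <- sum(tab[1, ]); k <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, m + k - n); hi <- min(m, k)
  lp <- vapply(lo:hi, function(a)
    lchoose(k, a) + lchoose(n - k, m - a) - lchoose(n, m), 0)
  pr <- exp(lp)
  p_obs <- pr[(lo:hi) == x]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Breslow partial log-likelihood evaluated directly from the definition
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# grid-search maximizer of the partial likelihood
oracle_cox_coef <- function(time, event, x, lim = 5, tol = 1e-6) {
  f <- function(b) oracle_cox_loglik(b, time, event, x)
  lo <- -lim; hi <- lim
  while (hi - lo > tol) {
    g <- seq(lo, hi, length.out = 31)
    v <- vapply(g, f, 0)
    i <- which.max(v)
    lo <- g[max(i - 1, 1)]; hi <- g[min(i + 1, length(g))]
  }
  (lo + hi) / 2
}

# TMM factor for one sample vs reference by explicit sorting/averaging
oracle_tmm_factor <- function(y, yr, trim_m = 0.30, trim_a = 0.05) {
  n <- sum(y); nr <- sum(yr)
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  m <- log2((y / n) / (yr / nr))
  a <- 0.5 * log2((y / n) * (yr / nr))
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  qm <- stats::quantile(m, c(trim_m, 1 - trim_m), names = FALSE)
  qa <- stats::quantile(a, c(trim_a, 1 - trim_a), names = FALSE)
  sel <- m >= qm[1] & m <= qm[2] & a >= qa[1] & a <= qa[2]
  2^(sum(w[sel] * m[sel]) / sum(w[sel]))
}
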