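# network construction: correlation, soft threshold, TOM, communities

test_that("correlation_matrix matches the definitional oracle", {
  withr::with_seed(1, {
    x <- matrix(rnorm(20), 5, 4,
                dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:4)))
    r <- correlation_matrix(x)
    expect_equal(r, oracle_cor(x), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(diag(r), rep(1, 5), ignore_attr = TRUE)
  })
})

test_that("correlation_matrix: duplicates, negation, zero variance", {
  withr::with_seed(2, {
    x <- matrix(rnorm(30), 3, 10,
                dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:10)))
    x["b", ] <- x["a", ]
    x["c", ] <- -x["a", ]
    r <- correlation_matrix(x)
    expect_equal(r["a", "b"], 1)
    expect_equal(r["a", "c"], -1)
    x["c", ] <- 5
    expect_error(correlation_matrix(x), "zero-variance gene.*c")
  })
})

test_that("build_adjacency follows the power law in both modes", {
  r <- matrix(c(1, 0.8, 0.8, 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  a <- build_adjacency(r, network_config(beta = 13))
  expect_equal(a["a", "b"], 0.8^13)
  expect_equal(diag(a), c(a = 0, b = 0))
  s <- build_adjacency(r, network_config("signed", beta = 2))
  expect_equal(s["a", "b"], 0.9^2)
  # unsigned is sign-blind
  rn <- r; rn["a", "b"] <- rn["b", "a"] <- -0.8
  expect_equal(build_adjacency(rn, network_config(beta = 13)), a)
})

test_that("increasing beta never increases off-diagonal adjacency", {
  withr::with_seed(3, {
    for (i in 1:20) {
      x <- matrix(rnorm(80), 8, 10,
                  dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:10)))
      r <- correlation_matrix(x)
      a1 <- build_adjacency(r, network_config(beta = 4))
      a2 <- build_adjacency(r, network_config(beta = 9))
      expect_true(all(a2 <= a1 + 1e-15))
      expect_true(all(a1 >= 0 & a1 <= 1))
    }
  })
})

test_that("topological_overlap matches the triple-loop oracle", {
  withr::with_seed(4, {
    a <- matrix(runif(36, 0, 0.5), 6)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    dimnames(a) <- list(sprintf("g%d", 1:6), sprintf("g%d", 1:6))
    tom <- topological_overlap(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(diag(tom), rep(1, 6), ignore_attr = TRUE)
  })
})

test_that("TOM limits: isolated nodes and the unit triangle", {
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(topological_overlap(z)["a", "b"], 0)
  tri <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(tri) <- 0
  expect_equal(unname(topological_overlap(tri)["a", "b"]), 1)
})

test_that("adjacency/TOM bounds hold on random inputs", {
  withr::with_seed(5, {
    for (i in 1:100) {
      x <- matrix(rnorm(15 * 8), 15, 8,
                  dimnames = list(sprintf("g%02d", 1:15),
                                  sprintf("s%d", 1:8)))
      net <- build_network(x, network_config(beta = sample(1:15, 1)))
      expect_true(all(net$adjacency >= 0 & net$adjacency <= 1))
      expect_true(all(net$tom >= -1e-12 & net$tom <= 1 + 1e-12))
      expect_equal(net$tom, t(net$tom), tolerance = 1e-12)
    }
  })
})

test_that("scale-free fit: exact power law and degenerate input", {
  # multiplicities proportional to k^-2 make the binned log-log exact
  k <- rep(1:10, times = round(2000 * (1:10)^-2))
  fit <- coexnet:::scale_free_fit(k, 10)
  expect_gte(fit$r2, 0.99)
  expect_lt(fit$slope, 0)
  expect_warning(fit0 <- coexnet:::scale_free_fit(rep(3, 50), 10),
                 "degenerate")
  expect_equal(fit0$r2, 0)
})

test_that("scan_soft_threshold matches an independent binned regression", {
  blocks <- make_block_expr(c(20, 15), loading = 0.85, n_samples = 60,
                            n_background = 15, seed = 6)
  r <- correlation_matrix(blocks$expr)
  scan <- scan_soft_threshold(r, powers = c(2, 6, 13),
                              config = network_config())
  for (i in seq_len(nrow(scan))) {
    a <- abs(r)^scan$power[i]; diag(a) <- 0
    k <- rowSums(a)
    brk <- seq(min(k), max(k), length.out = 11)
    bin <- factor(cut(k, brk, include.lowest = TRUE, labels = FALSE),
                  levels = 1:10)
    df <- data.frame(k = as.vector(tapply(k, bin, mean)),
                     f = as.vector(table(bin)))
    df <- df[df$f > 0, ]
    fit <- lm(log10(f / sum(f)) ~ log10(k + 1e-9), data = df)
    r2 <- summary(fit)$r.squared * -sign(coef(fit)[2])
    expect_equal(scan$r_squared[i], unname(r2), tolerance = 1e-10)
  }
  expect_error(scan_soft_threshold(r, powers = integer(0)), "empty")
})

test_that("detect_communities recovers planted blocks exactly", {
  blocks <- make_block_expr(c(50, 50), loading = 0.95, n_samples = 80,
                            seed = 7)
  net <- build_network(blocks$expr, network_config())
  part <- detect_communities(net$tom, network_config())
  expect_identical(length(unique(part$labels[part$labels > 0])), 2L)
  expect_equal(adjusted_rand_index(part$labels, blocks$labels), 1)
})

test_that("pure noise yields an all-background partition", {
  withr::with_seed(8, {
    x <- matrix(rnorm(100 * 60), 100, 60,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("s%02d", 1:60)))
    net <- build_network(x, network_config())
    part <- detect_communities(net$tom, network_config())
    expect_true(all(part$labels == 0))
  })
})

test_that("3-block recovery holds across seeds (ARI >= 0.9)", {
  aris <- vapply(1:10, function(s) {
    blocks <- make_block_expr(c(50, 50, 50), loading = 0.8,
                              n_samples = 100, seed = s)
    net <- build_network(blocks$expr, network_config())
    part <- detect_communities(net$tom, network_config())
    adjusted_rand_index(part$labels, blocks$labels)
  }, 0)
  expect_true(all(aris >= 0.9))
})

test_that("community labels are invariant to gene ordering", {
  blocks <- make_block_expr(c(40, 35), loading = 0.85, n_samples = 60,
                            n_background = 20, seed = 9)
  net1 <- build_network(blocks$expr, network_config())
  p1 <- detect_communities(net1$tom, network_config())
  perm <- withr::with_seed(10, sample(nrow(blocks$expr)))
  net2 <- build_network(blocks$expr[perm, ], network_config())
  p2 <- detect_communities(net2$tom, network_config())
  common <- rownames(blocks$expr)
  expect_equal(adjusted_rand_index(p1$labels[common], p2$labels[common]), 1)
})

test_that("small-instance clustering agrees with naive average linkage", {
  naive_average_linkage_heights <- function(d) {
    # d: full dissimilarity matrix; returns sorted merge heights
    clusters <- as.list(seq_len(nrow(d)))
    heights <- numeric(0)
    while (length(clusters) > 1) {
      best <- c(NA, NA); best_h <- Inf
      for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
      heights <- c(heights, best_h)
      clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
    }
    sort(heights)
  }
  withr::with_seed(11, {
    for (rep in 1:5) {
      x <- matrix(rnorm(8 * 12), 8, 12,
                  dimnames = list(sprintf("g%d", 1:8), sprintf("s%02d", 1:12)))
      tom <- build_network(x, network_config(beta = 2))$tom
      hc <- hclust(as.dist(1 - tom), method = "average")
      expect_equal(sort(hc$height),
                   naive_average_linkage_heights(1 - tom),
                   tolerance = 1e-12)
    }
  })
})

test_that("merge_similar merges by eigengene dissimilarity threshold", {
  # construct two communities sharing one latent factor (eigengene r ~ 0.9)
  # and a third independent one
  withr::with_seed(12, {
    n <- 120
    e1 <- rnorm(n)
    e2 <- 0.95 * e1 + sqrt(1 - 0.95^2) * rnorm(n)  # r ~ 0.95 with e1
    e3 <- rnorm(n)
    mk <- function(e, sz) t(vapply(seq_len(sz), function(i)
      0.95 * e + 0.3 * rnorm(n), numeric(n)))
    x <- rbind(mk(e1, 35), mk(e2, 35), mk(e3, 35))
    dimnames(x) <- list(sprintf("g%03d", 1:105), sprintf("s%03d", 1:n))
    part <- structure(list(labels = stats::setNames(rep(1:3, each = 35),
                                                    rownames(x)),
                           cut_height = 0.5, merge_heights = numeric(0),
                           merge_history = list()),
                      class = "module_partition")
    merged <- merge_similar(part, x, merge_cut_height = 0.25)
    lab <- merged$labels
    expect_identical(length(unique(lab[lab > 0])), 2L)
    # communities 1 and 2 merged; 3 untouched
    expect_identical(unique(unname(lab[1:70])), unique(unname(lab[1:35])))
    expect_false(lab[1] == lab[71])
    expect_gt(length(merged$merge_history), 0)
    # independent eigengenes (dissimilarity ~1) are never merged
    merged2 <- merge_similar(part, x, merge_cut_height = 0.02)
    expect_identical(length(unique(merged2$labels[merged2$labels > 0])), 3L)
  })
})
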