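# eigengenes and trait/group statistics

test_that("rank-1 community: eigengene is the profile, var explained 1", {
  withr::with_seed(1, {
    p <- rnorm(20)
    x <- rbind(p, 2 * p + 3, 0.5 * p - 1)
    dimnames(x) <- list(c("a", "b", "c"), sprintf("s%02d", 1:20))
    res <- compute_eigengene(x)
    expect_equal(res$var_explained, 1, tolerance = 1e-12)
    z <- (p - mean(p)) / sd(p)
    expect_equal(unname(res$eigengene), z / sqrt(sum(z^2)),
                 tolerance = 1e-10)
  })
})

test_that("2-gene variance explained equals (1+|r|)/2", {
  withr::with_seed(2, {
    for (i in 1:20) {
      x <- matrix(rnorm(2 * 30), 2, 30,
                  dimnames = list(c("a", "b"), sprintf("s%02d", 1:30)))
      r <- cor(x[1, ], x[2, ])
      res <- compute_eigengene(x)
      expect_equal(res$var_explained, (1 + abs(r)) / 2, tolerance = 1e-10)
    }
  })
})

test_that("eigengene sign follows mean expression; scaling invariance", {
  withr::with_seed(3, {
    x <- make_block_expr(20, loading = 0.9, n_samples = 40, seed = 3)$expr
    res <- compute_eigengene(x)
    expect_gte(cor(res$eigengene, colMeans((x - rowMeans(x)) /
                                           apply(x, 1, sd))), 0)
    res2 <- compute_eigengene(x * 7.5)
    expect_equal(res2$eigengene, res$eigengene, tolerance = 1e-10)
    # flipping all genes flips nothing after re-alignment to the
    # flipped data's own mean profile
    res3 <- compute_eigengene(-x)
    expect_equal(abs(cor(res3$eigengene, res$eigengene)), 1,
                 tolerance = 1e-10)
  })
})

test_that("constant communities are rejected", {
  x <- matrix(5, 3, 10, dimnames = list(letters[1:3], sprintf("s%02d", 1:10)))
  expect_error(compute_eigengene(x), "constant")
})

test_that("PC1 variance explained dominates any single gene", {
  withr::with_seed(4, {
    for (i in 1:10) {
      x <- matrix(rnorm(6 * 25), 6, 25,
                  dimnames = list(sprintf("g%d", 1:6), sprintf("s%02d", 1:25)))
      res <- compute_eigengene(x)
      z <- (x - rowMeans(x)) / apply(x, 1, sd)
      # variance captured by projecting standardized data on one gene axis
      single <- max(vapply(seq_len(6), function(g) {
        u <- z[g, ] / sqrt(sum(z[g, ]^2))
        sum((z %*% u)^2) / sum(z^2)
      }, 0))
      expect_gte(res$var_explained + 1e-12, single)
    }
  })
})

test_that("trait_correlation matches cor.test and is symmetric", {
  withr::with_seed(5, {
    x <- rnorm(50); y <- 0.4 * x + rnorm(50)
    res <- trait_correlation(x, y)
    ref <- cor.test(x, y)
    expect_equal(res$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    res2 <- trait_correlation(y, x)
    expect_equal(res$r, res2$r)
    expect_equal(res$p, res2$p)
    # perfect linearity
    expect_equal(trait_correlation(1:5 + 0, c(2, 4, 6, 8, 10))$r, 1)
  })
})

test_that("trait_correlation handles missingness and degenerate traits", {
  withr::with_seed(6, {
    x <- rnorm(20); y <- rnorm(20)
    y[c(3, 7)] <- NA
    res <- trait_correlation(x, y)
    expect_identical(res$n_used, 18L)
    expect_identical(res$n_dropped, 2L)
    expect_error(trait_correlation(x, rep(1, 20)), "zero-variance")
    expect_error(trait_correlation(rnorm(3), rnorm(3)), ">= 4")
  })
})

test_that("null trait correlation p-values are uniform", {
  ps <- vapply(1:100, function(s) withr::with_seed(1000 + s, {
    trait_correlation(rnorm(1000), rnorm(1000))$p
  }), 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(max(abs(vapply(1:100, function(s) withr::with_seed(1000 + s, {
    trait_correlation(rnorm(1000), rnorm(1000))$r
  }), 0))), 0.15)
})

test_that("group_difference reproduces the Welch formulas", {
  g1 <- c(1, 2, 3, 4); g2 <- c(2, 3, 4, 5)
  res <- group_difference(c(g1, g2), rep(c("a", "b"), each = 4))
  # stepwise Welch computation
  se2 <- var(g1) / 4 + var(g2) / 4
  t_hand <- (mean(g1) - mean(g2)) / sqrt(se2)
  df_hand <- se2^2 / ((var(g1) / 4)^2 / 3 + (var(g2) / 4)^2 / 3)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  ref <- t.test(g1, g2)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(res$ratio_of_means, mean(g1) / mean(g2))
  # identical groups: t = 0, p = 1
  res0 <- group_difference(rep(c(1, 2, 3), 2), rep(c("a", "b"), 3))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
})

test_that("Welch test has full power at d = 1, n = 50 per group", {
  rej <- vapply(1:200, function(s) withr::with_seed(2000 + s, {
    group_difference(c(rnorm(50), rnorm(50, 1)),
                     rep(c("a", "b"), each = 50))$p < 0.05
  }), TRUE)
  expect_gte(mean(rej), 0.99)
})

test_that("anova_groups matches hand-computed mean squares", {
  x <- c(4, 5, 6, 7, 9, 10, 12, 14, 1, 2, 2, 3)
  g <- rep(c("a", "b", "c"), each = 4)
  res <- anova_groups(x, g)
  gm <- tapply(x, g, mean)
  ssb <- sum(4 * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  f_hand <- (ssb / 2) / (ssw / 9)
  expect_equal(res$f, f_hand, tolerance = 1e-12)
  ref <- anova(lm(x ~ g))
  expect_equal(res$f, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("anova_groups: null uniformity and degenerate input", {
  ps <- vapply(1:200, function(s) withr::with_seed(3000 + s, {
    anova_groups(rnorm(60), rep(1:3, each = 20))$p
  }), 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_warning(res <- anova_groups(rep(2, 9), rep(1:3, each = 3)),
                 "no variance")
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
  expect_error(anova_groups(rnorm(10), rep(1, 10)), ">= 2")
})

test_that("eigengene_set + associate_communities wire up correctly", {
  blocks <- make_block_expr(c(30, 30), loading = 0.9, n_samples = 60,
                            seed = 7)
  part <- structure(list(labels = blocks$labels, cut_height = 0.5,
                         merge_heights = numeric(0), merge_history = list()),
                    class = "module_partition")
  eg <- eigengene_set(blocks$expr, part)
  expect_identical(rownames(eg$eigengenes), c("C1", "C2"))
  expect_equal(unname(rowSums(eg$eigengenes^2)), c(1, 1), tolerance = 1e-10)
  withr::with_seed(8, {
    ann <- data.frame(sample = colnames(blocks$expr),
                      group = rep(c("patient", "control"), 30),
                      trait_x = eg$eigengenes["C1", ] * 2 + rnorm(60, sd = 0.01))
    tbl <- associate_communities(eg, ann, traits = "trait_x")
    r_c1 <- tbl$estimate[tbl$community == "C1" & tbl$statistic == "pearson"]
    expect_gt(abs(r_c1), 0.99)
  })
})
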