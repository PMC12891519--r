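# tercile coding, Cox partial likelihood, prognosis scan

test_that("tercile_split follows the ceiling rank rule", {
  t9 <- tercile_split(9:1)
  expect_equal(unname(table(t9$labels)), c(3L, 3L, 3L), ignore_attr = TRUE)
  t10 <- tercile_split(rnorm(10))
  expect_equal(as.integer(table(t10$labels)), c(4L, 3L, 3L))
  expect_false(t10$tied)
  # labels ordered by value
  v <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  tc <- tercile_split(v)
  expect_true(all(v[tc$labels == 2] > v[tc$labels == 0]))
  expect_error(tercile_split(1:5), "n >= 6")
})

test_that("tied values give a deterministic flagged split", {
  tc1 <- tercile_split(rep(1, 9))
  tc2 <- tercile_split(rep(1, 9))
  expect_identical(tc1$labels, tc2$labels)
  expect_true(tc1$tied)
  expect_equal(as.integer(table(tc1$labels)), c(3L, 3L, 3L))
})

test_that("cox_fit matches the grid-search oracle on tiny instances", {
  withr::with_seed(1, {
    for (i in 1:5) {
      time <- sort(rexp(6)) + (1:6) * 1e-3  # distinct times
      event <- rep(1L, 6)
      x <- rep(c(0, 1), 3)
      fit <- cox_fit(time, event, x)
      expect_equal(fit$coef, oracle_cox_coef(time, event, x),
                   tolerance = 1e-5)
      # optimality: fitted log-likelihood beats the null
      expect_gte(fit$loglik["fit"], fit$loglik["null"])
      expect_equal(unname(fit$loglik["fit"]),
                   oracle_cox_loglik(fit$coef, time, event, x),
                   tolerance = 1e-10)
    }
  })
})

test_that("cox_fit agrees with survival::coxph under Breslow ties", {
  skip_if_not_installed("survival")
  withr::with_seed(2, {
    for (i in 1:10) {
      n <- 80
      x <- rnorm(n)
      time <- round(rexp(n, exp(0.5 * x)), 2) + 0.01  # induce ties
      event <- rbinom(n, 1, 0.7)
      if (sum(event) < 2) next
      fit <- cox_fit(time, event, x)
      ref <- survival::coxph(survival::Surv(time, event) ~ x,
                             ties = "breslow")
      expect_equal(fit$coef, unname(coef(ref)), tolerance = 1e-6)
      expect_equal(fit$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-6)
    }
  })
})

test_that("cox_fit is invariant to time rescaling", {
  withr::with_seed(3, {
    n <- 100
    x <- rnorm(n)
    time <- rexp(n, exp(0.7 * x))
    event <- rbinom(n, 1, 0.8)
    f1 <- cox_fit(time, event, x)
    f2 <- cox_fit(time * 365.25, event, x)
    expect_equal(f1$coef, f2$coef, tolerance = 1e-9)
    expect_equal(f1$se, f2$se, tolerance = 1e-9)
  })
})

test_that("cox_fit rejects bad input and flags separation", {
  expect_error(cox_fit(c(1, 2), c(0, 0), c(1, 2)), ">= 1 event")
  expect_error(cox_fit(c(-1, 2), c(1, 1), c(1, 2)), ">= 0")
  expect_error(cox_fit(c(1, 2), c(1, 1), c(3, 3)), "zero variance")
  # perfect separation: covariate orders events exactly
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 0, 0, 0)
  x <- c(10, 9, 8, 1, 2, 3)
  expect_warning(fit <- cox_fit(time, event, x), "converge")
  expect_false(fit$converged)
})

test_that("ordinal and high-vs-low codings agree in sign", {
  withr::with_seed(4, {
    for (i in 1:5) {
      n <- 200
      e <- rnorm(n)
      sv <- generate_survival(e, list(log_hr = log(2), baseline_rate = 0.3,
                                      censor_horizon = 5), seed = 40 + i)
      lab <- tercile_split(e)$labels
      ford <- cox_fit(sv$time, sv$event, as.numeric(lab))
      keep <- lab != 1
      fhl <- cox_fit(sv$time[keep], sv$event[keep],
                     as.numeric(lab[keep] == 2))
      expect_identical(sign(ford$coef), sign(fhl$coef))
    }
  })
})

test_that("prognosis_scan finds the linked community only", {
  withr::with_seed(5, {
    n <- 300
    blocks <- make_block_expr(c(40, 40), loading = 0.9, n_samples = n,
                              seed = 50)
    part <- structure(list(labels = blocks$labels),
                      class = "module_partition")
    eg <- eigengene_set(blocks$expr, part)
    # survival driven by community 1's eigengene, HR 3 per tercile step
    e1 <- eg$eigengenes["C1", ] / sd(eg$eigengenes["C1", ])
    code <- as.numeric(tercile_split(e1)$labels)
    time <- rexp(n, 0.3 * exp(log(3) * code))
    event <- as.integer(time <= 5)
    time <- pmin(time, 5)
    sv <- data.frame(sample = colnames(eg$eigengenes), time = time,
                     event = event)
    scan <- prognosis_scan(eg, sv)
    ord <- scan[scan$coding == "ordinal", ]
    expect_lt(ord$p[ord$community == "C1"], 0.05)
    expect_gt(ord$hr[ord$community == "C1"], 1)
    expect_gt(ord$p[ord$community == "C2"], 0.05)
  })
})

test_that("permuted survival gives null p-values across communities", {
  withr::with_seed(6, {
    blocks <- make_block_expr(c(30, 30, 30), loading = 0.9,
                              n_samples = 120, seed = 60)
    part <- structure(list(labels = blocks$labels),
                      class = "module_partition")
    eg <- eigengene_set(blocks$expr, part)
    ps <- unlist(lapply(1:20, function(i) {
      time <- rexp(120, 0.3)
      sv <- data.frame(sample = colnames(eg$eigengenes),
                       time = pmin(time, 5),
                       event = as.integer(time <= 5))
      scan <- prognosis_scan(eg, sv)
      scan$p[scan$coding == "ordinal"]
    }))
    expect_gt(mean(ps > 0.05), 0.85)
  })
})

test_that("deathclass_anova delegates per community", {
  withr::with_seed(7, {
    blocks <- make_block_expr(c(30, 30), loading = 0.9, n_samples = 80,
                              seed = 70)
    part <- structure(list(labels = blocks$labels),
                      class = "module_partition")
    eg <- eigengene_set(blocks$expr, part)
    # classes driven by community 1
    cls <- as.integer(cut(eg$eigengenes["C1", ] + rnorm(80, sd = 0.005),
                          breaks = quantile(eg$eigengenes["C1", ],
                                            c(0, .25, .5, .75, 1)),
                          include.lowest = TRUE, labels = FALSE))
    res <- deathclass_anova(eg, cls)
    expect_lt(res$p[res$community == "C1"], 1e-6)
    expect_gt(res$p[res$community == "C2"], 0.01)
    expect_error(deathclass_anova(eg, rep(1L, 80)), ">= 2")
  })
})

test_that("km_curves are valid survival curves", {
  withr::with_seed(8, {
    time <- rexp(60, 0.5)
    event <- rbinom(60, 1, 0.8)
    lab <- tercile_split(rnorm(60))$labels
    km <- km_curves(time, event, lab)
    for (g in unique(km$tercile)) {
      s <- km$survival[km$tercile == g]
      expect_true(all(diff(s) <= 1e-12))
      expect_true(all(s >= 0 & s <= 1))
    }
  })
})
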