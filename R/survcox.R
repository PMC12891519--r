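# Prognosis: tercile coding of eigengenes and Cox proportional-hazards
# fits (Breslow ties, Newton iteration on the partial likelihood), plus
# the ordinal death-class ANOVA used for external validation.

#' Split values into terciles
#'
#' Samples are ranked (ties broken by stable input order) and cut at
#' ranks `ceiling(n/3)` and `ceiling(2n/3)`: labels 0 (low), 1
#' (intermediate), 2 (high).
#'
#' @param values numeric vector (n >= 6).
#' @return a `tercile_coding` list: `labels` (0/1/2, named if input is),
#'   `cut_ranks`, `cut_values`, `tied` (TRUE when ties straddle a cut).
#' @export
tercile_split <- function(values) {
  n <- length(values)
  if (n < 6) stop("need n >= 6 to populate three terciles", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  o <- order(values)           # stable: ties keep input order
  ranks <- integer(n)
  ranks[o] <- seq_len(n)
  c1 <- ceiling(n / 3)
  c2 <- ceiling(2 * n / 3)
  labels <- ifelse(ranks <= c1, 0L, ifelse(ranks <= c2, 1L, 2L))
  names(labels) <- names(values)
  sorted <- values[o]
  tied <- (sorted[c1] == sorted[min(c1 + 1L, n)]) ||
          (sorted[c2] == sorted[min(c2 + 1L, n)])
  structure(list(labels = labels, cut_ranks = c(c1, c2),
                 cut_values = c(sorted[c1], sorted[c2]), tied = tied),
            class = "tercile_coding")
}

#' Cox proportional-hazards fit for a single covariate
#'
#' Maximizes the Breslow partial likelihood by Newton iteration
#' (convergence: relative log-likelihood change < 1e-9 or 50
#' iterations). The standard error comes from the observed information.
#' A monotone likelihood (perfect separation) is flagged as
#' non-convergence with a warning; the last coefficient is still
#' returned.
#'
#' @param time non-negative event/censoring times.
#' @param event 0/1 event indicator (>= 1 event required).
#' @param covariate finite numeric covariate.
#' @return a `survival_fit` list: `coef`, `se`, `hr`, `z`, `p`, `n`,
#'   `events`, `loglik` (at 0 and at the estimate), `converged`,
#'   `iterations`.
#' @export
cox_fit <- function(time, event, covariate) {
  n <- length(time)
  if (length(event) != n || length(covariate) != n)
    stop("time, event and covariate must have equal length", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L)))
    stop("event must be 0/1", call. = FALSE)
  if (sum(event) < 1) stop("need >= 1 event", call. = FALSE)
  if (any(!is.finite(covariate)))
    stop("covariate must be finite", call. = FALSE)
  if (stats::var(covariate) == 0)
    stop("covariate has zero variance", call. = FALSE)

  beta <- 0
  ll0 <- cox_breslow_derivs(0, time, event, covariate)$ll
  ll_old <- ll0
  converged <- FALSE
  iter <- 0L
  warned <- FALSE
  for (iter in seq_len(50L)) {
    d <- cox_breslow_derivs(beta, time, event, covariate)
    if (d$info <= 0 || !is.finite(d$info)) { warned <- TRUE; break }
    step <- d$score / d$info
    if (!is.finite(step)) { warned <- TRUE; break }
    if (abs(step) > 5) step <- sign(step) * 5  # damp wild early steps
    beta <- beta + step
    ll_new <- cox_breslow_derivs(beta, time, event, covariate)$ll
    if (abs(ll_new - ll_old) < 1e-9 * (abs(ll_old) + 0.1)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
    if (abs(beta) > 20) { warned <- TRUE; break }  # monotone likelihood
  }
  if (!converged || warned) {
    converged <- FALSE
    warning("Cox partial likelihood did not converge (possible monotone likelihood); coefficient reported as-is",
            call. = FALSE)
  }
  d <- cox_breslow_derivs(beta, time, event, covariate)
  se <- if (d$info > 0) 1 / sqrt(d$info) else NA_real_
  z <- beta / se
  structure(list(coef = beta, se = se, hr = exp(beta), z = z,
                 p = 2 * stats::pnorm(-abs(z)), n = n,
                 events = sum(event), loglik = c(null = ll0, fit = d$ll),
                 converged = converged, iterations = iter),
            class = "survival_fit")
}

# Breslow partial log-likelihood with first two derivatives for one
# covariate. Risk sets computed on times sorted decreasingly so the
# cumulative sums are O(n log n).
cox_breslow_derivs <- function(beta, time, event, x) {
  o <- order(time, decreasing = TRUE)
  t_s <- time[o]; e_s <- event[o]; x_s <- x[o]
  w <- exp(beta * x_s)
  s0 <- cumsum(w)
  s1 <- cumsum(w * x_s)
  s2 <- cumsum(w * x_s^2)
  # risk set at an event time t: all with time >= t -> last index with
  # t_s >= t in the decreasing ordering; ties share one risk set
  ev_idx <- which(e_s == 1L)
  if (!length(ev_idx)) return(list(ll = 0, score = 0, info = 0))
  # for each event, index of the last sample with time >= its time
  last_ge <- findInterval(-t_s[ev_idx], -t_s)  # both ascending in -t
  S0 <- s0[last_ge]; S1 <- s1[last_ge]; S2 <- s2[last_ge]
  ll <- sum(beta * x_s[ev_idx] - log(S0))
  score <- sum(x_s[ev_idx] - S1 / S0)
  info <- sum(S2 / S0 - (S1 / S0)^2)
  list(ll = ll, score = score, info = info)
}

#' Tercile Cox prognosis scan over all community eigengenes
#'
#' For each community the eigengene is split into terciles and two Cox
#' models are fitted: an ordinal trend model (coding 0/1/2) and a
#' high-vs-low contrast (middle tercile excluded, coding 0/1). Failures
#' in individual communities are caught and reported, not propagated.
#'
#' @param eg_set an [eigengene_set()].
#' @param survival data.frame with `sample`, `time`, `event` columns.
#' @return data.frame: one row per community x coding with `coef`, `se`,
#'   `hr`, `z`, `p`, `n`, `events`, `converged`, `tied`, `error`.
#' @export
prognosis_scan <- function(eg_set, survival) {
  eg <- eg_set$eigengenes
  sv <- survival[match(colnames(eg), survival$sample), , drop = FALSE]
  ok <- !is.na(sv$time) & !is.na(sv$event)
  rows <- list()
  for (cm in rownames(eg)) {
    res <- tryCatch({
      tc <- tercile_split(eg[cm, ok])
      lab <- tc$labels
      ord <- fit_row(sv$time[ok], sv$event[ok], as.numeric(lab),
                     cm, "ordinal", tc$tied)
      hl_keep <- lab != 1L
      hl <- fit_row(sv$time[ok][hl_keep], sv$event[ok][hl_keep],
                    as.numeric(lab[hl_keep] == 2L), cm, "high_vs_low",
                    tc$tied)
      rbind(ord, hl)
    }, error = function(e)
      data.frame(community = cm, coding = c("ordinal", "high_vs_low"),
                 coef = NA_real_, se = NA_real_, hr = NA_real_,
                 z = NA_real_, p = NA_real_, n = NA_integer_,
                 events = NA_integer_, converged = FALSE, tied = NA,
                 error = conditionMessage(e)))
    rows[[length(rows) + 1L]] <- res
  }
  do.call(rbind, rows)
}

fit_row <- function(time, event, covariate, community, coding, tied) {
  fit <- tryCatch(suppressWarnings(cox_fit(time, event, covariate)),
                  error = function(e) e)
  if (inherits(fit, "error"))
    return(data.frame(community = community, coding = coding,
                      coef = NA_real_, se = NA_real_, hr = NA_real_,
                      z = NA_real_, p = NA_real_, n = length(time),
                      events = sum(event), converged = FALSE, tied = tied,
                      error = conditionMessage(fit)))
  data.frame(community = community, coding = coding, coef = fit$coef,
             se = fit$se, hr = fit$hr, z = fit$z, p = fit$p, n = fit$n,
             events = fit$events, converged = fit$converged, tied = tied,
             error = NA_character_)
}

#' One-way ANOVA of eigengenes across ordinal death classes
#'
#' @param eg_set an [eigengene_set()].
#' @param death_class per-sample class in 1..4 (aligned to eigengene
#'   columns; NAs dropped).
#' @return data.frame: `community`, `f`, `df1`, `df2`, `p`.
#' @export
deathclass_anova <- function(eg_set, death_class) {
  eg <- eg_set$eigengenes
  if (length(death_class) != ncol(eg))
    stop("death_class must align with eigengene samples", call. = FALSE)
  ok <- !is.na(death_class)
  if (length(unique(death_class[ok])) < 2)
    stop("need >= 2 death classes present", call. = FALSE)
  rows <- lapply(rownames(eg), function(cm) {
    a <- anova_groups(eg[cm, ok], death_class[ok])
    data.frame(community = cm, f = a$f, df1 = a$df1, df2 = a$df2, p = a$p)
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier coordinates per tercile
#'
#' Product-limit survival curve for each tercile group, for plotting or
#' export.
#'
#' @param time,event survival data.
#' @param labels tercile labels (0/1/2) from [tercile_split()].
#' @return data.frame: `tercile`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_curves <- function(time, event, labels) {
  rows <- list()
  for (g in sort(unique(labels))) {
    idx <- labels == g
    t_g <- time[idx]; e_g <- event[idx]
    ts <- sort(unique(t_g[e_g == 1]))
    s <- 1
    for (tt in ts) {
      n_risk <- sum(t_g >= tt)
      n_event <- sum(t_g == tt & e_g == 1)
      s <- s * (1 - n_event / n_risk)
      rows[[length(rows) + 1L]] <- data.frame(
        tercile = g, time = tt, n_risk = n_risk, n_event = n_event,
        survival = s)
    }
  }
  if (!length(rows))
    return(data.frame(tercile = integer(0), time = numeric(0),
                      n_risk = integer(0), n_event = integer(0),
                      survival = numeric(0)))
  do.call(rbind, rows)
}
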