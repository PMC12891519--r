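# Propensity-score construction of a balanced external control group:
# logistic regression on age, sex, diabetes and BMI, then 1:1
# nearest-neighbor matching without replacement within a caliper.

#' Propensity scores from logistic regression
#'
#' Logistic regression of case status on the covariates, fitted by
#' iteratively reweighted least squares (convergence 1e-8, at most 100
#' iterations). Scores are fitted case probabilities. Perfect separation
#' is flagged with a warning but scores are still returned.
#'
#' @param covariates data.frame of numeric covariates (typically age,
#'   sex 0/1, diabetes 0/1, BMI); must be complete.
#' @param labels logical/0-1 vector: TRUE/1 = case.
#' @return list: `scores` (in (0,1)), `coefficients`, `separation_flag`.
#' @export
propensity_scores <- function(covariates, labels) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(labels))
    stop("covariates and labels must align", call. = FALSE)
  miss <- !stats::complete.cases(covariates)
  if (any(miss))
    stop(sprintf("missing covariates for sample row(s): %s",
                 paste(utils::head(which(miss), 10), collapse = ", ")),
         call. = FALSE)
  y <- as.integer(as.logical(labels))
  dat <- cbind(data.frame(.y = y), covariates)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep)
    warning("possible perfect separation in propensity model", call. = FALSE)
  scores <- as.numeric(stats::fitted(fit))
  names(scores) <- rownames(covariates)
  list(scores = scores, coefficients = stats::coef(fit),
       separation_flag = sep)
}

#' 1:1 nearest-neighbor propensity matching without replacement
#'
#' Cases are processed in descending score order; each is matched to the
#' unused control with the nearest score, provided the distance is
#' within the caliper (default 0.2 standard deviations of the logit
#' scores). Unmatched cases are counted, not imputed.
#'
#' @param scores per-sample propensity scores.
#' @param labels logical/0-1 case indicator aligned with `scores`.
#' @param caliper maximum score distance; `NULL` = 0.2 x sd(logit
#'   scores); `Inf` disables it.
#' @param covariates optional data.frame used to report standardized
#'   mean differences before/after matching.
#' @return a `match_result` list: `pairs` (data.frame case/control
#'   indices and IDs), `caliper`, `n_unmatched`, `smd_before`,
#'   `smd_after`.
#' @export
nn_match <- function(scores, labels, caliper = NULL, covariates = NULL) {
  y <- as.logical(labels)
  if (length(scores) != length(y))
    stop("scores and labels must align", call. = FALSE)
  cases <- which(y)
  controls <- which(!y)
  if (!length(controls)) stop("no controls available", call. = FALSE)
  if (is.null(caliper)) {
    lg <- stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
    caliper <- 0.2 * stats::sd(lg)
  }
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  used <- logical(length(scores))
  ord <- cases[order(-scores[cases], cases)]
  pairs <- list()
  unmatched <- 0L
  for (ca in ord) {
    avail <- controls[!used[controls]]
    if (!length(avail)) { unmatched <- unmatched + 1L; next }
    d <- abs(scores[avail] - scores[ca])
    j <- avail[order(d, avail)[1]]
    if (abs(scores[j] - scores[ca]) > caliper) {
      unmatched <- unmatched + 1L
      next
    }
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      case = ca, control = j, case_id = ids[ca], control_id = ids[j],
      distance = abs(scores[j] - scores[ca]))
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case = integer(0), control = integer(0),
               case_id = character(0), control_id = character(0),
               distance = numeric(0))
  smd_before <- smd_after <- NULL
  if (!is.null(covariates)) {
    smd_before <- covariate_smd(covariates, cases, controls)
    smd_after <- covariate_smd(covariates, pairs$case, pairs$control)
  }
  structure(list(pairs = pairs, caliper = caliper,
                 n_unmatched = unmatched, smd_before = smd_before,
                 smd_after = smd_after),
            class = "match_result")
}

# Absolute standardized mean difference per covariate between two index
# sets.
covariate_smd <- function(covariates, idx_case, idx_control) {
  vapply(covariates, function(v) {
    v <- as.numeric(v)
    if (!length(idx_case) || !length(idx_control)) return(NA_real_)
    m1 <- mean(v[idx_case]); m0 <- mean(v[idx_control])
    s <- sqrt((stats::var(v[idx_case]) + stats::var(v[idx_control])) / 2)
    if (!is.finite(s) || s == 0) return(if (m1 == m0) 0 else Inf)
    abs(m1 - m0) / s
  }, 0)
}
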