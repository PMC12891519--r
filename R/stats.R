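# Community-level statistics: eigengene summaries and their association
# with clinical traits (Pearson), group membership (Welch t) and
# multi-level groupings (one-way ANOVA).

#' First principal component (eigengene) of a community
#'
#' Genes are standardized (mean 0, sd 1 across samples) and the first
#' right-singular direction over samples is extracted. The sign is
#' aligned so the eigengene correlates non-negatively with the
#' community's mean standardized expression, making "higher eigengene =
#' higher community expression".
#'
#' @param expr gene x sample matrix of the community's genes (>= 2 genes,
#'   >= 3 samples, no constant gene).
#' @return list: `eigengene` (unit-norm named vector over samples),
#'   `var_explained` (first squared singular value over total), `sign`
#'   (+1/-1 flip applied).
#' @export
compute_eigengene <- function(expr) {
  assert_matrix_like(expr, "community expression matrix")
  if (nrow(expr) < 2) stop("need >= 2 genes", call. = FALSE)
  if (ncol(expr) < 3) stop("need >= 3 samples", call. = FALSE)
  sds <- apply(expr, 1, stats::sd)
  if (all(sds == 0)) stop("all-constant community", call. = FALSE)
  if (any(sds == 0))
    stop(sprintf("constant gene(s) in community: %s",
                 paste(utils::head(rownames(expr)[sds == 0], 5),
                       collapse = ", ")), call. = FALSE)
  z <- (expr - rowMeans(expr)) / sds
  sv <- svd(z, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  var_explained <- sv$d[1]^2 / sum(sv$d^2)
  s <- sign(stats::cor(eg, colMeans(z)))
  if (is.na(s) || s == 0) s <- 1
  eg <- eg * s
  names(eg) <- colnames(expr)
  list(eigengene = eg, var_explained = var_explained, sign = s)
}

#' Eigengenes for every community of a partition
#'
#' @param expr gene x sample expression matrix.
#' @param partition a `module_partition` (labels 1..K; 0 = background).
#' @return an `eigengene_set`: `eigengenes` (community x sample matrix,
#'   rows `C1..CK`), `var_explained`, `signs`.
#' @export
eigengene_set <- function(expr, partition) {
  labels <- partition$labels
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0)
    return(structure(list(eigengenes = matrix(numeric(0), 0, ncol(expr),
                                              dimnames = list(NULL, colnames(expr))),
                          var_explained = numeric(0), signs = numeric(0)),
                     class = "eigengene_set"))
  res <- lapply(mods, function(m)
    compute_eigengene(expr[names(labels)[labels == m], , drop = FALSE]))
  eg <- do.call(rbind, lapply(res, `[[`, "eigengene"))
  rownames(eg) <- paste0("C", mods)
  structure(list(eigengenes = eg,
                 var_explained = stats::setNames(
                   vapply(res, `[[`, 0, "var_explained"), rownames(eg)),
                 signs = stats::setNames(vapply(res, `[[`, 0, "sign"),
                                         rownames(eg))),
            class = "eigengene_set")
}

#' Pearson correlation between an eigengene and a clinical trait
#'
#' Missing trait values are dropped pairwise (count reported); the
#' two-sided p comes from the t transform with n - 2 degrees of freedom.
#'
#' @param eigengene numeric vector.
#' @param trait numeric vector of the same length (NAs allowed).
#' @return list: `r`, `p`, `n_used`, `n_dropped`.
#' @export
trait_correlation <- function(eigengene, trait) {
  if (length(eigengene) != length(trait))
    stop("eigengene and trait must have equal length", call. = FALSE)
  ok <- is.finite(eigengene) & is.finite(trait)
  n <- sum(ok)
  if (n < 4) stop("need >= 4 paired finite observations", call. = FALSE)
  x <- eigengene[ok]; y <- trait[ok]
  if (stats::sd(y) == 0) stop("zero-variance trait", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero-variance eigengene", call. = FALSE)
  r <- stats::cor(x, y)
  list(r = r, p = cor_pvalue(r, n), n_used = n,
       n_dropped = length(trait) - n)
}

#' Welch two-sample t-test on an eigengene between two groups
#'
#' Reports the Welch statistic with Satterthwaite degrees of freedom,
#' group means, standardized mean difference (difference over the root
#' mean of the two variances) and ratio of means.
#'
#' @param eigengene numeric vector.
#' @param group two-level factor/vector aligned with `eigengene`.
#' @return list: `t`, `df`, `p`, `means` (named), `smd`, `ratio_of_means`.
#' @export
group_difference <- function(eigengene, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2)
    stop("group must have exactly 2 levels", call. = FALSE)
  ok <- is.finite(eigengene) & !is.na(group)
  x <- split(eigengene[ok], group[ok])
  n <- vapply(x, length, 0L)
  if (any(n < 2)) stop("need >= 2 samples per group", call. = FALSE)
  m <- vapply(x, mean, 0)
  v <- vapply(x, stats::var, 0)
  if (any(v == 0)) stop("zero-variance group", call. = FALSE)
  se2 <- v / n
  t_stat <- (m[1] - m[2]) / sqrt(sum(se2))
  df <- sum(se2)^2 / sum(se2^2 / (n - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = unname(t_stat), df = unname(df), p = unname(p), means = m,
       smd = unname((m[1] - m[2]) / sqrt(mean(v))),
       ratio_of_means = unname(m[1] / m[2]))
}

#' One-way ANOVA of an eigengene across k groups
#'
#' @param eigengene numeric vector.
#' @param group factor/vector with k >= 2 non-empty levels.
#' @return list: `f`, `df1`, `df2`, `p`, `group_means`.
#' @export
anova_groups <- function(eigengene, group) {
  group <- factor(group)
  ok <- is.finite(eigengene) & !is.na(group)
  x <- eigengene[ok]; g <- droplevels(group[ok])
  k <- nlevels(g)
  n <- length(x)
  if (k < 2) stop("need >= 2 non-empty groups", call. = FALSE)
  if (n <= k) stop("need total n > number of groups", call. = FALSE)
  gm <- tapply(x, g, mean)
  ng <- tapply(x, g, length)
  ss_between <- sum(ng * (gm - mean(x))^2)
  ss_within <- sum((x - gm[g])^2)
  if (ss_within == 0 && ss_between == 0) {
    warning("no variance within or between groups; F = 0, p = 1",
            call. = FALSE)
    return(list(f = 0, df1 = k - 1, df2 = n - k, p = 1, group_means = gm))
  }
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(f = f, df1 = k - 1, df2 = n - k,
       p = stats::pf(f, k - 1, n - k, lower.tail = FALSE), group_means = gm)
}

#' Associate every community eigengene with traits and group membership
#'
#' Trait correlations are computed within the scope given by
#' `trait_scope` (e.g. patients only), the group contrast across
#' `group`.
#'
#' @param eg_set an [eigengene_set()].
#' @param annotations per-sample data.frame aligned by a `sample` column
#'   to the eigengene columns.
#' @param traits character vector of trait column names.
#' @param group_col column holding the two-level group (default
#'   `"group"`).
#' @param trait_scope logical vector (or NULL for all samples) selecting
#'   the samples used for trait correlations.
#' @return data.frame with one row per community x statistic.
#' @export
associate_communities <- function(eg_set, annotations, traits,
                                  group_col = "group",
                                  trait_scope = NULL) {
  eg <- eg_set$eigengenes
  ann <- annotations[match(colnames(eg), annotations$sample), , drop = FALSE]
  if (any(is.na(ann$sample)))
    stop("annotations missing for some samples", call. = FALSE)
  if (is.null(trait_scope)) trait_scope <- rep(TRUE, ncol(eg))
  rows <- list()
  for (cm in rownames(eg)) {
    for (tr in traits) {
      res <- tryCatch(
        trait_correlation(eg[cm, trait_scope], ann[[tr]][trait_scope]),
        error = function(e) list(r = NA_real_, p = NA_real_,
                                 n_used = NA_integer_, n_dropped = NA_integer_))
      rows[[length(rows) + 1L]] <- data.frame(
        community = cm, statistic = "pearson", variable = tr,
        estimate = res$r, p = res$p, n = res$n_used)
    }
    gd <- tryCatch(group_difference(eg[cm, ], ann[[group_col]]),
                   error = function(e) NULL)
    if (!is.null(gd))
      rows[[length(rows) + 1L]] <- data.frame(
        community = cm, statistic = "welch_t", variable = group_col,
        estimate = gd$smd, p = gd$p, n = ncol(eg))
  }
  do.call(rbind, rows)
}
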