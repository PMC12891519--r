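# Weighted co-expression network construction: Pearson correlation,
# soft-threshold adjacency with scale-free fit diagnostics, topological
# overlap, hierarchical community detection and eigengene-based merging.

#' Network configuration
#'
#' @param signed_mode `"unsigned"` (adjacency `|r|^beta`) or `"signed"`
#'   (`((1+r)/2)^beta`).
#' @param beta soft-threshold power (positive integer, default 13).
#' @param scale_free_r2_target R-squared target used by
#'   [scan_soft_threshold()] to recommend a power. Default 0.80.
#' @param n_degree_bins connectivity bins for the scale-free fit.
#' @param min_module_size smallest community kept by
#'   [detect_communities()]. Default 30.
#' @param tree_cut_height static dendrogram cut height; `NULL` means the
#'   0.99 quantile of merge heights.
#' @param merge_cut_height eigengene-dissimilarity cut below which
#'   communities are merged. Default 0.25.
#' @return a `network_config` list.
#' @export
network_config <- function(signed_mode = c("unsigned", "signed"),
                           beta = 13L, scale_free_r2_target = 0.80,
                           n_degree_bins = 10L, min_module_size = 30L,
                           tree_cut_height = NULL,
                           merge_cut_height = 0.25) {
  signed_mode <- match.arg(signed_mode)
  assert_scalar_num(beta, "beta", min = 1)
  assert_scalar_num(scale_free_r2_target, "scale_free_r2_target",
                    min = 0, max = 1)
  assert_scalar_num(n_degree_bins, "n_degree_bins", min = 2)
  assert_scalar_num(min_module_size, "min_module_size", min = 1)
  if (!is.null(tree_cut_height))
    assert_scalar_num(tree_cut_height, "tree_cut_height", min = 0)
  assert_scalar_num(merge_cut_height, "merge_cut_height", min = 0, max = 1)
  if (merge_cut_height <= 0 || merge_cut_height >= 1)
    stop_field("merge_cut_height", "must be in (0, 1)")
  structure(list(signed_mode = signed_mode, beta = as.integer(beta),
                 scale_free_r2_target = scale_free_r2_target,
                 n_degree_bins = as.integer(n_degree_bins),
                 min_module_size = as.integer(min_module_size),
                 tree_cut_height = tree_cut_height,
                 merge_cut_height = merge_cut_height),
            class = "network_config")
}

#' Gene-gene Pearson correlation matrix
#'
#' @param expr gene x sample expression matrix (>= 3 samples; every gene
#'   must have positive variance).
#' @return symmetric gene x gene correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr) {
  assert_matrix_like(expr)
  if (ncol(expr) < 3) stop("need >= 3 samples", call. = FALSE)
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    stop(sprintf("zero-variance gene(s): %s",
                 paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", ")),
         call. = FALSE)
  r <- stats::cor(t(expr))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Soft-threshold adjacency
#'
#' Unsigned: `a_ij = |r_ij|^beta`; signed: `a_ij = ((1 + r_ij)/2)^beta`.
#' The diagonal is set to 0 so connectivity sums exclude self-edges.
#'
#' @param corr correlation matrix.
#' @param config a [network_config()].
#' @return adjacency matrix with entries in \[0, 1\] and zero diagonal.
#' @export
build_adjacency <- function(corr, config = network_config()) {
  a <- if (config$signed_mode == "unsigned") abs(corr)^config$beta
       else ((1 + corr) / 2)^config$beta
  diag(a) <- 0
  a
}

#' Scan candidate soft-threshold powers for scale-free fit
#'
#' For each candidate power the connectivity `k_i = sum_{j != i} a_ij` is
#' binned into `n_degree_bins` equal-width bins; the scale-free fit is
#' the squared correlation of `log10(mean k per bin)` against
#' `log10(bin frequency)`, reported with the sign of the slope flipped so
#' a positive value indicates the expected decreasing degree
#' distribution. The recommended power is the smallest candidate whose
#' signed R-squared reaches `scale_free_r2_target`, else the maximizer.
#'
#' @param corr correlation matrix (>= 30 genes).
#' @param powers integer vector of candidate powers.
#' @param config a [network_config()] (signedness and binning).
#' @return data.frame (`power`, `r_squared`, `slope`, `mean_k`) with
#'   attribute `recommended`.
#' @export
scan_soft_threshold <- function(corr, powers = c(1:10, 12, 14, 16, 18, 20),
                                config = network_config()) {
  if (length(powers) == 0) stop("empty candidate power list", call. = FALSE)
  if (nrow(corr) < 30)
    stop("need >= 30 genes for a meaningful degree distribution",
         call. = FALSE)
  rows <- lapply(powers, function(p) {
    cfg <- config; cfg$beta <- as.integer(p)
    a <- build_adjacency(corr, cfg)
    k <- rowSums(a)
    fit <- scale_free_fit(k, config$n_degree_bins)
    data.frame(power = p, r_squared = fit$r2, slope = fit$slope,
               mean_k = mean(k))
  })
  scan <- do.call(rbind, rows)
  ok <- which(scan$r_squared >= config$scale_free_r2_target)
  rec <- if (length(ok)) scan$power[ok[1]]
         else scan$power[which.max(scan$r_squared)]
  attr(scan, "recommended") <- rec
  scan
}

# Binned log-log regression of frequency on connectivity; returns signed
# R^2 (positive only for decreasing fits) and slope.
scale_free_fit <- function(k, n_bins) {
  if (max(k) == min(k)) {
    warning("degenerate connectivity distribution; scale-free R^2 set to 0",
            call. = FALSE)
    return(list(r2 = 0, slope = NA_real_))
  }
  brk <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, brk, include.lowest = TRUE, labels = FALSE)
  freq <- tabulate(bin, n_bins)
  keep <- freq > 0
  mean_k <- vapply(seq_len(n_bins), function(b)
    if (freq[b] > 0) mean(k[bin == b]) else NA_real_, 0)
  x <- log10(mean_k[keep] + 1e-9)
  y <- log10(freq[keep] / sum(freq))
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("degenerate connectivity distribution; scale-free R^2 set to 0",
            call. = FALSE)
    return(list(r2 = 0, slope = NA_real_))
  }
  slope <- stats::cov(x, y) / stats::var(x)
  r2 <- stats::cor(x, y)^2
  list(r2 = -sign(slope) * r2, slope = slope)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with unit diagonal. Shared-neighbourhood similarity used as
#' the clustering metric.
#'
#' @param adjacency symmetric adjacency with zero diagonal.
#' @return TOM matrix with entries in \[0, 1\] and unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  if (!isTRUE(all.equal(adjacency, t(adjacency), tolerance = 1e-10)))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adjacency) != 0))
    stop("adjacency diagonal must be zero", call. = FALSE)
  l <- adjacency %*% adjacency
  k <- rowSums(adjacency)
  kmin <- outer(k, k, pmin)
  tom <- (l + adjacency) / (kmin + 1 - adjacency)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect communities by average-linkage clustering of TOM dissimilarity
#'
#' Genes are clustered on `1 - TOM` with average linkage and the tree is
#' cut at a static height. When `tree_cut_height` is `NULL` (default)
#' the height is chosen deterministically as the cut maximizing the
#' TOM-weighted Newman modularity of the resulting partition over a grid
#' of candidate cluster counts; at strong soft-threshold powers merge
#' heights compress into a sliver below 1 and a fixed quantile height is
#' not usable (see the methods vignette). Clusters smaller than
#' `min_module_size` are assigned the background label 0; remaining
#' communities are relabelled 1..K by decreasing size.
#'
#' @param tom TOM matrix.
#' @param config a [network_config()].
#' @return a `module_partition` list: `labels` (named integer vector),
#'   `cut_height`, `merge_heights`, `merge_history`.
#' @export
detect_communities <- function(tom, config = network_config()) {
  genes <- rownames(tom)
  n <- nrow(tom)
  if (n < config$min_module_size) {
    warning("fewer genes than min_module_size; all genes labelled 0",
            call. = FALSE)
    labels <- stats::setNames(integer(n), genes)
    return(structure(list(labels = labels, cut_height = NA_real_,
                          merge_heights = numeric(0),
                          merge_history = list()),
                     class = "module_partition"))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  if (!is.null(config$tree_cut_height)) {
    h <- config$tree_cut_height
    raw <- stats::cutree(hc, h = h)
  } else {
    ks <- unique(round(c(seq(2L, min(n - 1L, 40L)),
                         seq(41, n - 1, length.out = 40))))
    ks <- ks[ks >= 2 & ks <= n - 1]
    cuts <- stats::cutree(hc, k = ks)
    q <- vapply(seq_along(ks), function(i)
      tom_modularity(tom, cuts[, i]), 0)
    best <- which.max(q)
    raw <- cuts[, best]
    # height interval realizing k clusters: between the (n-k)th and
    # (n-k+1)th smallest merge heights
    hs <- sort(hc$height)
    k <- ks[best]
    h <- if (k == 1) hs[n - 1] else (hs[n - k] + hs[n - k + 1]) / 2
  }
  labels <- relabel_by_size(raw, config$min_module_size)
  names(labels) <- genes
  structure(list(labels = labels, cut_height = unname(h),
                 merge_heights = hc$height, merge_history = list()),
            class = "module_partition")
}

# Newman modularity of a partition on the TOM-weighted complete graph
# (diagonal excluded).
tom_modularity <- function(tom, memb) {
  w <- tom
  diag(w) <- 0
  two_w <- sum(w)
  if (two_w == 0) return(0)
  s <- rowSums(w)
  memb <- as.factor(memb)
  within <- sum(diag(rowsum(t(rowsum(w, memb)), memb)))
  strength <- rowsum(s, memb)
  within / two_w - sum((strength / two_w)^2)
}

# Drop clusters below min size (-> 0) and relabel remaining 1..K by
# decreasing size, ties broken by first occurrence.
relabel_by_size <- function(raw, min_size) {
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  out <- integer(length(raw))
  ord <- keep[order(-sizes[keep], match(keep, names(sizes)))]
  for (i in seq_along(ord)) out[raw == ord[i]] <- i
  out
}

#' Merge communities with similar eigengenes
#'
#' Computes each community's eigengene, clusters eigengenes by average
#' linkage on `1 - Pearson correlation`, merges communities falling below
#' `merge_cut_height`, and iterates (recomputing eigengenes from the
#' expression data) until stable.
#'
#' @param partition a `module_partition`.
#' @param expr gene x sample expression matrix covering the partition's
#'   genes.
#' @param merge_cut_height dissimilarity threshold (default 0.25).
#' @return a `module_partition` with `merge_history` recording each pass.
#' @export
merge_similar <- function(partition, expr, merge_cut_height = 0.25) {
  labels <- partition$labels
  history <- partition$merge_history
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    eg <- vapply(mods, function(m)
      compute_eigengene(expr[names(labels)[labels == m], , drop = FALSE])$eigengene,
      numeric(ncol(expr)))
    colnames(eg) <- as.character(mods)
    diss <- 1 - stats::cor(eg)
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    grp <- stats::cutree(hc, h = merge_cut_height)
    if (max(grp) == length(mods)) break
    history <- c(history, list(unname(split(mods, grp))))
    # absorb each merge group into its lowest-numbered member
    newlab <- vapply(seq_along(mods), function(i) min(mods[grp == grp[i]]),
                     numeric(1))
    map <- stats::setNames(as.integer(newlab), as.character(mods))
    pos <- labels > 0
    labels[pos] <- map[as.character(labels[pos])]
  }
  # compact surviving community labels to 1..K by decreasing size
  pos <- labels > 0
  if (any(pos)) {
    sizes <- table(labels[pos])
    ord <- names(sizes)[order(-as.integer(sizes),
                              as.integer(names(sizes)))]
    remap <- stats::setNames(seq_along(ord), ord)
    labels[pos] <- as.integer(remap[as.character(labels[pos])])
  }
  structure(list(labels = labels, cut_height = partition$cut_height,
                 merge_heights = partition$merge_heights,
                 merge_history = history),
            class = "module_partition")
}

#' Build a co-expression network object
#'
#' Convenience constructor bundling correlation, adjacency and TOM under
#' one configuration.
#'
#' @param expr gene x sample expression matrix.
#' @param config a [network_config()].
#' @return a `coexpression_network` list: `genes`, `corr`, `adjacency`,
#'   `tom`, `config`.
#' @export
build_network <- function(expr, config = network_config()) {
  corr <- correlation_matrix(expr)
  adj <- build_adjacency(corr, config)
  tom <- topological_overlap(adj)
  structure(list(genes = rownames(expr), corr = corr, adjacency = adj,
                 tom = tom, config = config),
            class = "coexpression_network")
}
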