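# Cross-cohort validation: per-edge replication of discovery
# correlations in external cohorts, pruning of unconfirmed edges, and
# permutation-based community preservation Z statistics.

#' Recalculate discovery edges in external cohorts and prune
#'
#' Every within-network gene pair ("edge") has its Pearson correlation
#' and two-sided p recomputed in each external cohort. An edge is
#' confirmed if at least one cohort shows a same-sign correlation with
#' p < alpha; unconfirmed edges are removed (adjacency and TOM entries
#' set to 0). Edges whose endpoints are missing from a cohort are
#' evaluated only in the cohorts containing both.
#'
#' @param network a `coexpression_network` from [build_network()].
#' @param cohorts named list of gene x sample expression matrices.
#' @param alpha nominal replication significance level (default 0.05).
#' @return list: `network` (pruned copy), `report` (an
#'   `edge_validation_report`: per-cohort replication correlation
#'   matrices, confirmation matrix, per-cohort gene overlap,
#'   `confirmation_rate`, and `community_rates` when a partition is
#'   supplied later via [edge_confirmation_rates()]).
#' @export
revalidate_edges <- function(network, cohorts, alpha = 0.05) {
  if (!inherits(network, "coexpression_network"))
    stop("network must come from build_network()", call. = FALSE)
  if (!is.list(cohorts) || is.null(names(cohorts)))
    stop("cohorts must be a named list of expression matrices",
         call. = FALSE)
  genes <- network$genes
  p_genes <- length(genes)
  confirmed <- matrix(FALSE, p_genes, p_genes, dimnames = list(genes, genes))
  evaluated <- matrix(FALSE, p_genes, p_genes, dimnames = list(genes, genes))
  rep_cor <- list()
  overlap <- integer(0)
  for (nm in names(cohorts)) {
    expr <- cohorts[[nm]]
    shared <- intersect(genes, rownames(expr))
    overlap[nm] <- length(shared)
    if (length(shared) < 2)
      stop(sprintf("cohort '%s' shares < 2 genes with the network", nm),
           call. = FALSE)
    r <- stats::cor(t(expr[shared, , drop = FALSE]))
    n <- ncol(expr)
    p <- cor_pvalue(r, n)
    same_sign <- sign(r) == sign(network$corr[shared, shared])
    conf <- same_sign & (p < alpha)
    diag(conf) <- FALSE
    confirmed[shared, shared] <- confirmed[shared, shared] | conf
    evaluated[shared, shared] <- TRUE
    full_r <- matrix(NA_real_, p_genes, p_genes,
                     dimnames = list(genes, genes))
    full_r[shared, shared] <- r
    rep_cor[[nm]] <- full_r
  }
  pruned <- network
  drop_mask <- evaluated & !confirmed
  diag(drop_mask) <- FALSE
  pruned$adjacency[drop_mask] <- 0
  pruned$tom[drop_mask] <- 0
  ut <- upper.tri(confirmed)
  report <- structure(list(
    confirmed = confirmed, evaluated = evaluated,
    replication_cor = rep_cor, alpha = alpha, gene_overlap = overlap,
    confirmation_rate = sum(confirmed[ut] & evaluated[ut]) /
      max(sum(evaluated[ut]), 1L)),
    class = "edge_validation_report")
  list(network = pruned, report = report)
}

#' Per-community edge confirmation rates
#'
#' @param report an `edge_validation_report`.
#' @param partition a `module_partition`.
#' @return named numeric vector: fraction of evaluated within-community
#'   edges confirmed, per community.
#' @export
edge_confirmation_rates <- function(report, partition) {
  labels <- partition$labels
  mods <- sort(unique(labels[labels > 0]))
  rates <- stats::setNames(numeric(length(mods)), paste0("C", mods))
  for (i in seq_along(mods)) {
    g <- intersect(names(labels)[labels == mods[i]],
                   rownames(report$confirmed))
    conf <- report$confirmed[g, g]
    ev <- report$evaluated[g, g]
    ut <- upper.tri(conf)
    rates[i] <- sum(conf[ut] & ev[ut]) / max(sum(ev[ut]), 1L)
  }
  rates
}

#' Permutation preservation Z statistics for each community
#'
#' For each community the test-cohort density statistic (mean
#' within-community adjacency at the discovery power) and the
#' connectivity statistic (Pearson correlation of intramodular
#' connectivity between discovery and test) are compared against a null
#' of random same-size gene sets drawn from the shared network gene
#' universe. `Z = (observed - null mean) / null sd`; `Z_summary` is the
#' mean of the density and connectivity Z.
#'
#' @param partition a `module_partition`.
#' @param discovery_expr,test_expr gene x sample expression matrices.
#' @param config a [network_config()] carrying the discovery power.
#' @param n_permutations null draws (>= 50; default 200).
#' @param seed integer seed.
#' @return a `preservation_report` data.frame: one row per community
#'   with observed statistics, null moments, `z_density`,
#'   `z_connectivity`, `z_summary`.
#' @export
preservation_z <- function(partition, discovery_expr, test_expr,
                           config = network_config(),
                           n_permutations = 200L, seed = 1L) {
  if (n_permutations < 50)
    stop("n_permutations must be >= 50", call. = FALSE)
  labels <- partition$labels
  universe <- intersect(intersect(names(labels), rownames(discovery_expr)),
                        rownames(test_expr))
  mods <- sort(unique(labels[labels > 0]))
  rows <- list()
  with_seed(seed, {
    for (m in mods) {
      genes <- intersect(names(labels)[labels == m], universe)
      if (length(genes) < 3) {
        warning(sprintf("community %d has < 3 shared genes; skipped", m),
                call. = FALSE)
        next
      }
      obs <- preservation_stats(genes, discovery_expr, test_expr, config)
      null_d <- numeric(n_permutations)
      null_c <- numeric(n_permutations)
      for (b in seq_len(n_permutations)) {
        rnd <- sample(universe, length(genes))
        st <- preservation_stats(rnd, discovery_expr, test_expr, config)
        null_d[b] <- st$density
        null_c[b] <- st$connectivity
      }
      z_d <- z_or_inf(obs$density, null_d)
      z_c <- z_or_inf(obs$connectivity, null_c)
      rows[[length(rows) + 1L]] <- data.frame(
        community = paste0("C", m), size = length(genes),
        density = obs$density, connectivity = obs$connectivity,
        null_density_mean = mean(null_d), null_density_sd = stats::sd(null_d),
        null_connectivity_mean = mean(null_c),
        null_connectivity_sd = stats::sd(null_c),
        z_density = z_d, z_connectivity = z_c,
        z_summary = mean(c(z_d, z_c)))
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(community = character(0), size = integer(0),
               density = numeric(0), connectivity = numeric(0),
               null_density_mean = numeric(0), null_density_sd = numeric(0),
               null_connectivity_mean = numeric(0),
               null_connectivity_sd = numeric(0), z_density = numeric(0),
               z_connectivity = numeric(0), z_summary = numeric(0))
  attr(out, "n_permutations") <- as.integer(n_permutations)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("preservation_report", class(out))
  out
}

# Density and connectivity preservation statistics for one gene set.
preservation_stats <- function(genes, discovery_expr, test_expr, config) {
  a_test <- build_adjacency(
    stats::cor(t(test_expr[genes, , drop = FALSE])), config)
  a_disc <- build_adjacency(
    stats::cor(t(discovery_expr[genes, , drop = FALSE])), config)
  n <- length(genes)
  density <- sum(a_test) / (n * (n - 1))
  k_disc <- rowSums(a_disc)
  k_test <- rowSums(a_test)
  connectivity <- if (stats::sd(k_disc) == 0 || stats::sd(k_test) == 0) 0
                  else stats::cor(k_disc, k_test)
  list(density = density, connectivity = connectivity)
}

z_or_inf <- function(obs, null) {
  s <- stats::sd(null)
  if (s == 0) {
    warning("null sd is 0; Z reported as +/-Inf", call. = FALSE)
    return(if (obs > mean(null)) Inf else -Inf)
  }
  (obs - mean(null)) / s
}

#' Retain communities preserved in at least one external cohort
#'
#' A community is kept iff its maximum `z_summary` over the supplied
#' reports reaches `z_threshold` (inclusive); genes of removed
#' communities are relabelled 0. If nothing survives, an empty (all
#' background) partition is returned with attribute
#' `status = "no_community_retained"` rather than an error.
#'
#' @param partition a `module_partition`.
#' @param reports list of `preservation_report` objects (one per
#'   external cohort).
#' @param z_threshold preservation threshold (default 3).
#' @return filtered `module_partition` with attribute `retained`
#'   (named logical per community).
#' @export
retain_modules <- function(partition, reports, z_threshold = 3) {
  if (!length(reports)) stop("need >= 1 preservation report", call. = FALSE)
  labels <- partition$labels
  mods <- sort(unique(labels[labels > 0]))
  keep <- stats::setNames(logical(length(mods)), paste0("C", mods))
  for (i in seq_along(mods)) {
    cm <- paste0("C", mods[i])
    zs <- vapply(reports, function(rep) {
      row <- rep[rep$community == cm, , drop = FALSE]
      if (nrow(row) == 0) -Inf else row$z_summary
    }, 0)
    keep[i] <- max(zs) >= z_threshold
  }
  out_labels <- labels
  out_labels[labels %in% mods[!keep]] <- 0L
  out <- structure(list(labels = out_labels,
                        cut_height = partition$cut_height,
                        merge_heights = partition$merge_heights,
                        merge_history = partition$merge_history),
                   class = "module_partition")
  attr(out, "retained") <- keep
  if (!any(keep)) attr(out, "status") <- "no_community_retained"
  out
}
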