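# Gene-set over-representation against a rest-of-network background,
# built on an exact hypergeometric 2x2 test, plus Benjamini-Hochberg FDR.

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test. Two-sided p sums the probabilities of all
#' tables with the same margins whose point probability does not exceed
#' the observed one (relative tolerance 1e-7 on the comparison, the
#' standard convention); one-sided `greater` sums the upper tail of the
#' top-left cell.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param sided `"two"` or `"greater"`.
#' @return the exact p-value.
#' @export
fisher_exact_2x2 <- function(table, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  if (!is.matrix(table) || any(dim(table) != 2))
    stop("table must be a 2x2 matrix", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  x <- table[1, 1]
  m <- sum(table[1, ])   # row-1 margin
  k <- sum(table[, 1])   # col-1 margin
  n_tot <- sum(table)
  if (n_tot == 0) stop("table total must be > 0", call. = FALSE)
  lo <- max(0, m + k - n_tot)
  hi <- min(m, k)
  support <- lo:hi
  probs <- stats::dhyper(support, k, n_tot - k, m)
  p_obs <- probs[support == x]
  if (sided == "greater") {
    p <- sum(probs[support >= x])
  } else {
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  min(p, 1)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q(i) = min_{j >= i} p(j) * m / j` on sorted p-values, clipped to 1
#' and mapped back to input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NAs preserved).
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  out <- rep(NA_real_, length(pvals))
  if (m == 0) return(out)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  res <- numeric(m)
  res[o] <- q
  out[ok] <- res
  out
}

#' Harmonize gene identifiers
#'
#' Exact matching after uppercasing and stripping trailing version
#' suffixes (e.g. `ENSG000001.12` -> `ENSG000001`).
#'
#' @param ids character vector.
#' @return normalized character vector.
#' @export
harmonize_ids <- function(ids) {
  sub("\\.[0-9]+$", "", toupper(ids))
}

#' Over-representation of a gene set in one community
#'
#' One-sided (greater) Fisher exact test of the overlap between the
#' community and the set, with the rest of the network as background:
#' 2x2 = (community & set, community \\ set, rest & set, rest \\ set).
#' The set is intersected with the universe before testing. Fold
#' enrichment = observed overlap / expected overlap under independence.
#'
#' @param community_genes character vector (must be a subset of
#'   `universe`).
#' @param set_genes character vector of gene-set members.
#' @param universe character vector: the network gene universe.
#' @param sided `"greater"` (over-representation, default) or `"two"`.
#' @param harmonize apply [harmonize_ids()] to all inputs first.
#' @return one-row data.frame: `overlap`, `expected`, `odds_ratio`,
#'   `fold_enrichment`, `p`, `community_size`, `set_size_in_universe`,
#'   `universe_size`.
#' @export
ora_community <- function(community_genes, set_genes, universe,
                          sided = c("greater", "two"), harmonize = TRUE) {
  sided <- match.arg(sided)
  if (harmonize) {
    community_genes <- harmonize_ids(community_genes)
    set_genes <- harmonize_ids(set_genes)
    universe <- harmonize_ids(universe)
  }
  universe <- unique(universe)
  community_genes <- unique(community_genes)
  set_genes <- unique(set_genes)
  if (!all(community_genes %in% universe))
    stop("community genes must be a subset of the universe", call. = FALSE)
  set_u <- intersect(set_genes, universe)
  if (length(set_u) == 0) {
    warning("gene set empty after intersection with universe", call. = FALSE)
    return(data.frame(overlap = NA_integer_, expected = NA_real_,
                      odds_ratio = NA_real_, fold_enrichment = NA_real_,
                      p = NA_real_, community_size = length(community_genes),
                      set_size_in_universe = 0L,
                      universe_size = length(universe)))
  }
  a <- length(intersect(community_genes, set_u))
  b <- length(community_genes) - a
  c_ <- length(set_u) - a
  d <- length(universe) - a - b - c_
  expected <- length(community_genes) * length(set_u) / length(universe)
  p <- fisher_exact_2x2(matrix(c(a, c_, b, d), 2),
                        sided = if (sided == "two") "two" else "greater")
  data.frame(overlap = a, expected = expected,
             odds_ratio = (a * d) / (b * c_),  # Inf/NaN on empty margins
             fold_enrichment = a / expected, p = p,
             community_size = length(community_genes),
             set_size_in_universe = length(set_u),
             universe_size = length(universe))
}

#' Enrichment of every community against every gene set
#'
#' @param partition a `module_partition`.
#' @param collection named list of gene-ID vectors (e.g. from
#'   [read_gmt()]).
#' @param universe gene universe; defaults to all partition genes.
#' @param sided passed to [ora_community()].
#' @return data.frame with one row per community x set, with BH q-values
#'   computed across all tests.
#' @export
enrich_communities <- function(partition, collection, universe = NULL,
                               sided = "greater") {
  labels <- partition$labels
  if (is.null(universe)) universe <- names(labels)
  mods <- sort(unique(labels[labels > 0]))
  rows <- list()
  for (m in mods) {
    genes <- names(labels)[labels == m]
    for (s in names(collection)) {
      row <- suppressWarnings(
        ora_community(genes, collection[[s]], universe, sided = sided))
      row <- cbind(data.frame(community = paste0("C", m), set = s), row)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$q <- bh_fdr(out$p)
  out
}
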