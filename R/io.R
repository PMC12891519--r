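# Readers/writers for the pipeline's plain-text formats: gene x sample
# TSV, annotation CSV, GMT gene sets, edge-list TSV, GraphML and YAML
# configuration. Write-then-read is an identity up to 10 significant
# digits of float text.

#' Write a gene x sample expression matrix as TSV
#'
#' First column `gene`, then one column per sample.
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output file.
#' @export
write_expression_tsv <- function(expr, path) {
  assert_matrix_like(expr)
  df <- data.frame(gene = rownames(expr),
                   signif(expr, 10), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression TSV
#'
#' @param path input file written in the [write_expression_tsv()]
#'   dialect.
#' @return numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs gene column plus samples",
                         call. = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene IDs in expression TSV", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1] + 1L
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[bad]]))))[1]
    stop(sprintf("non-numeric cell at row %d, column '%s'",
                 badrow, colnames(df)[bad]), call. = FALSE)
  }
  rownames(m) <- genes
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample IDs in expression TSV", call. = FALSE)
  m
}

#' Write/read sample annotations CSV
#'
#' @param annotations data.frame with a `sample` column.
#' @param path file path.
#' @export
write_annotations_csv <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample" %in% colnames(ann))
    stop("annotations CSV must have a 'sample' column", call. = FALSE)
  if (anyDuplicated(ann$sample))
    stop("duplicate sample IDs in annotations CSV", call. = FALSE)
  ann
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors with attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop(sprintf("malformed GMT line %d: need name, description, >= 1 gene", i),
           call. = FALSE)
    nm <- parts[1]
    if (nm %in% names(sets))
      stop(sprintf("duplicate set name '%s' at GMT line %d", nm, i),
           call. = FALSE)
    sets[[nm]] <- parts[-(1:2)]
    desc[nm] <- parts[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional named descriptions (defaults to set
#'   names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
    if (is.null(descriptions))
      descriptions <- stats::setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as an edge-list TSV
#'
#' Columns: `gene_a`, `gene_b`, `correlation`, `adjacency`, `tom`. Only
#' the upper triangle is written; `tom_floor` bounds file size by
#' dropping weak edges.
#'
#' @param network a `coexpression_network`.
#' @param path output file.
#' @param tom_floor minimum TOM for an edge to be written (default 0,
#'   write all).
#' @export
write_edge_list <- function(network, path, tom_floor = 0) {
  ut <- which(upper.tri(network$tom), arr.ind = TRUE)
  keep <- network$tom[ut] >= tom_floor & network$adjacency[ut] > 0
  ut <- ut[keep, , drop = FALSE]
  df <- data.frame(gene_a = network$genes[ut[, 1]],
                   gene_b = network$genes[ut[, 2]],
                   correlation = signif(network$corr[ut], 10),
                   adjacency = signif(network$adjacency[ut], 10),
                   tom = signif(network$tom[ut], 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV
#'
#' @param path file in the [write_edge_list()] dialect.
#' @return data.frame of edges.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "correlation", "adjacency", "tom")
  if (!all(need %in% colnames(df)))
    stop("edge list missing required columns", call. = FALSE)
  df
}

#' Export a network to GraphML for external viewers
#'
#' @param network a `coexpression_network`.
#' @param partition optional `module_partition` written as a node
#'   attribute.
#' @param path output file.
#' @param tom_floor minimum TOM for an edge to be exported.
#' @export
write_graphml <- function(network, path, partition = NULL,
                          tom_floor = 0.1) {
  ut <- which(upper.tri(network$tom), arr.ind = TRUE)
  keep <- network$tom[ut] >= tom_floor & network$adjacency[ut] > 0
  ut <- ut[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = network$genes[ut[, 1]],
               to = network$genes[ut[, 2]],
               weight = network$tom[ut]),
    directed = FALSE,
    vertices = data.frame(name = network$genes))
  if (!is.null(partition))
    igraph::V(g)$community <- as.integer(
      partition$labels[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write/read a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config_yaml <- function(config, path) {
  obj <- unclass(config)
  obj$cohorts <- lapply(obj$cohorts, unclass)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_sim_config_yaml
#' @export
read_sim_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$cohorts <- lapply(obj$cohorts, function(co)
    cohort_spec(co$name, co$n_samples, co$platform, co$batch_shift_sd,
                co$batch_scale_sd, co$n_patients))
  do.call(sim_config, obj[setdiff(names(obj), "n_modules")])
}
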