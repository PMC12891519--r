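# End-to-end driver: simulate (or ingest) -> preprocess -> network ->
# cross-cohort validation -> eigengene association -> enrichment ->
# prognosis -> propensity matching -> report. Every stage writes its
# outputs under the run directory with a provenance block; identical
# configurations reproduce all outputs bit-exactly.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the synthetic cohorts, or
#'   `NULL` when `paths` supplies user data.
#' @param paths optional named list of input files (`discovery_counts`,
#'   `annotations`, plus `<cohort>_expression` entries and optionally
#'   `gene_sets` in GMT) read instead of simulating.
#' @param filter a [filter_config()].
#' @param network a [network_config()].
#' @param edge_alpha per-edge replication significance level.
#' @param z_threshold community preservation threshold (default 3).
#' @param n_permutations preservation permutations (default 100).
#' @param enrichment_sided `"greater"` or `"two"`.
#' @param caliper matching caliper (`NULL` = 0.2 sd of logit scores).
#' @param seed global seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @param out_dir run directory (created if missing).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            filter = filter_config(),
                            network = network_config(),
                            edge_alpha = 0.05, z_threshold = 3,
                            n_permutations = 100L,
                            enrichment_sided = "greater",
                            caliper = NULL, seed = 1L,
                            out_dir = tempfile("coexnet_run_")) {
  structure(list(sim = sim, paths = paths, filter = filter,
                 network = network, edge_alpha = edge_alpha,
                 z_threshold = z_threshold,
                 n_permutations = as.integer(n_permutations),
                 enrichment_sided = enrichment_sided, caliper = caliper,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full co-expression analysis pipeline
#'
#' Stages: simulate/ingest, preprocess (TMM + filters), network build
#' (soft threshold, TOM, communities, eigengene merge), cross-cohort
#' validation (edge pruning + preservation Z + retention), eigengene
#' association with traits and group, gene-set enrichment, tercile Cox
#' prognosis with death-class ANOVA validation, propensity matching,
#' and a machine-readable summary. A stage failure stops with the stage
#' name; outputs already written are retained.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with all in-memory stage results and
#'   `summary` (also written as `summary.json` in the run directory).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("config must come from pipeline_config()", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat("", file = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # -- simulate / ingest ------------------------------------------------
  data <- stage("simulate", {
    if (!is.null(config$paths)) ingest_inputs(config$paths)
    else {
      sim <- config$sim
      sim$seed <- derive_seed(config$seed, 1L)
      generate_multi_cohort(sim)
    }
  })
  cohort_names <- names(data$expression)
  discovery_name <- cohort_names[1]
  logf("cohorts: %s (discovery = %s)",
       paste(cohort_names, collapse = ", "), discovery_name)

  # -- preprocess -------------------------------------------------------
  prep <- stage("preprocess", {
    out <- list()
    retained <- list()
    for (nm in cohort_names) {
      expr <- data$expression[[nm]]
      platform <- attr(expr, "platform")
      if (identical(platform, "counts")) {
        retained[[nm]] <- filter_expressed(expr, config$filter)
        norm <- tmm_normalize(expr)
        out[[nm]] <- norm$log2cpm
        utils::write.csv(
          data.frame(sample = names(norm$factors),
                     factor = signif(norm$factors, 10)),
          file.path(config$out_dir, paste0("tmm_factors_", nm, ".csv")),
          row.names = FALSE)
        logf("filter_expressed[%s]: >%g counts in >=%.0f%% kept %d/%d genes",
             nm, config$filter$min_count, 100 * config$filter$min_fraction,
             length(retained[[nm]]), nrow(expr))
      } else {
        retained[[nm]] <- iqr_filter(expr, config$filter)
        out[[nm]] <- expr
        logf("iqr_filter[%s]: IQR >= %g kept %d/%d genes", nm,
             config$filter$iqr_cutoff, length(retained[[nm]]), nrow(expr))
      }
    }
    # reproducible transcriptome: detected in discovery AND confirmed in
    # >= 1 external cohort
    external <- setdiff(cohort_names, discovery_name)
    universe <- retained[[discovery_name]]
    if (length(external))
      universe <- intersect(universe,
                            Reduce(union, retained[external]))
    logf("reproducible transcriptome: %d genes", length(universe))
    list(expr = out, retained = retained, universe = universe)
  })

  # -- network ----------------------------------------------------------
  net <- stage("network", {
    disc <- prep$expr[[discovery_name]][prep$universe, , drop = FALSE]
    corr <- correlation_matrix(disc)
    scan <- scan_soft_threshold(corr, config = config$network)
    if (attr(scan, "recommended") != config$network$beta)
      logf("soft-threshold scan recommends beta = %d (configured %d); keeping configured value",
           attr(scan, "recommended"), config$network$beta)
    network <- build_network(disc, config$network)
    partition <- detect_communities(network$tom, config$network)
    partition <- merge_similar(partition, disc,
                               config$network$merge_cut_height)
    logf("communities detected: %d (beta = %d, cut height = %.4f)",
         length(unique(partition$labels[partition$labels > 0])),
         config$network$beta, partition$cut_height)
    utils::write.csv(scan, file.path(config$out_dir, "soft_threshold_scan.csv"),
                     row.names = FALSE)
    list(network = network, partition = partition, scan = scan,
         disc_expr = disc)
  })

  # -- validate ---------------------------------------------------------
  val <- stage("validate", {
    external <- setdiff(cohort_names, discovery_name)
    ext_expr <- lapply(stats::setNames(external, external), function(nm)
      prep$expr[[nm]][intersect(prep$universe, rownames(prep$expr[[nm]])), ,
                      drop = FALSE])
    rv <- revalidate_edges(net$network, ext_expr, config$edge_alpha)
    logf("edge confirmation rate: %.4f (alpha = %g)",
         rv$report$confirmation_rate, config$edge_alpha)
    reports <- list()
    for (i in seq_along(external)) {
      nm <- external[i]
      reports[[nm]] <- preservation_z(
        net$partition, net$disc_expr, ext_expr[[nm]],
        config = config$network, n_permutations = config$n_permutations,
        seed = derive_seed(config$seed, 10L + i))
      utils::write.csv(reports[[nm]],
                       file.path(config$out_dir,
                                 paste0("preservation_", nm, ".csv")),
                       row.names = FALSE)
    }
    retained <- retain_modules(net$partition, reports, config$z_threshold)
    kept <- attr(retained, "retained")
    logf("preservation Z >= %g retained %d/%d communities",
         config$z_threshold, sum(kept), length(kept))
    utils::write.table(
      data.frame(gene = names(retained$labels),
                 community = retained$labels),
      file.path(config$out_dir, "partition.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    write_edge_list(rv$network,
                    file.path(config$out_dir, "network_edges.tsv"),
                    tom_floor = 0.05)
    list(pruned = rv$network, edge_report = rv$report,
         preservation = reports, partition = retained)
  })
  if (identical(attr(val$partition, "status"), "no_community_retained"))
    logf("no community retained; downstream outputs will be empty")

  # -- associate --------------------------------------------------------
  assoc <- stage("associate", {
    eg <- eigengene_set(net$disc_expr, val$partition)
    ann <- data$annotations
    disc_ann <- ann[ann$cohort == discovery_name, , drop = FALSE]
    traits <- intersect(c("ntprobnp", "lvef", "vo2peak", "activity"),
                        colnames(ann))
    tbl <- NULL
    if (nrow(eg$eigengenes) > 0) {
      scope <- disc_ann$group[match(colnames(eg$eigengenes),
                                    disc_ann$sample)] == "patient"
      tbl <- associate_communities(eg, disc_ann, traits,
                                   trait_scope = scope)
      utils::write.csv(tbl, file.path(config$out_dir, "associations.csv"),
                       row.names = FALSE)
      write_expression_tsv(eg$eigengenes,
                           file.path(config$out_dir, "eigengenes.tsv"))
    }
    list(eigengenes = eg, table = tbl)
  })

  # -- enrich -----------------------------------------------------------
  enr <- stage("enrich", {
    collection <- if (!is.null(config$paths$gene_sets))
      read_gmt(config$paths$gene_sets)
    else if (!is.null(data$truth))
      synthetic_gene_sets(data$truth, prep$universe,
                          seed = derive_seed(config$seed, 20L))
    else NULL
    tbl <- NULL
    if (!is.null(collection)) {
      tbl <- enrich_communities(val$partition, collection,
                                universe = intersect(names(val$partition$labels),
                                                     prep$universe),
                                sided = config$enrichment_sided)
      if (!is.null(tbl))
        utils::write.csv(tbl, file.path(config$out_dir, "enrichment.csv"),
                         row.names = FALSE)
    }
    list(collection = collection, table = tbl)
  })

  # -- survival ---------------------------------------------------------
  surv <- stage("survival", {
    ann <- data$annotations
    scan <- NULL; dclass <- NULL
    if (nrow(assoc$eigengenes$eigengenes) > 0) {
      disc_ann <- ann[match(colnames(assoc$eigengenes$eigengenes),
                            ann$sample), , drop = FALSE]
      if (any(!is.na(disc_ann$time))) {
        scan <- prognosis_scan(assoc$eigengenes, disc_ann)
        utils::write.csv(scan, file.path(config$out_dir, "prognosis.csv"),
                         row.names = FALSE)
      }
      # death-class validation in the first external cohort carrying it
      for (nm in setdiff(cohort_names, discovery_name)) {
        co_ann <- ann[ann$cohort == nm, , drop = FALSE]
        if (!all(is.na(co_ann$death_class))) {
          shared <- intersect(names(val$partition$labels),
                              rownames(prep$expr[[nm]]))
          sub <- val$partition
          sub$labels <- sub$labels[shared]
          eg_ext <- eigengene_set(prep$expr[[nm]][shared, , drop = FALSE],
                                  sub)
          if (nrow(eg_ext$eigengenes) > 0) {
            dc <- co_ann$death_class[match(colnames(eg_ext$eigengenes),
                                           co_ann$sample)]
            dclass <- deathclass_anova(eg_ext, dc)
            utils::write.csv(dclass,
                             file.path(config$out_dir,
                                       paste0("deathclass_anova_", nm, ".csv")),
                             row.names = FALSE)
          }
          break
        }
      }
    }
    list(prognosis = scan, deathclass = dclass)
  })

  # -- match ------------------------------------------------------------
  mres <- stage("match", {
    ann <- data$annotations
    disc_ann <- ann[ann$cohort == discovery_name, , drop = FALSE]
    pool_name <- setdiff(cohort_names, discovery_name)[1]
    if (is.na(pool_name)) NULL else {
      pool_ann <- ann[ann$cohort == pool_name, , drop = FALSE]
      cases <- disc_ann[disc_ann$group == "patient", , drop = FALSE]
      both <- rbind(cases, pool_ann)
      cov <- both[, c("age", "sex", "bmi", "diabetes")]
      rownames(cov) <- both$sample
      ps <- propensity_scores(cov, both$cohort == discovery_name)
      mr <- nn_match(ps$scores, both$cohort == discovery_name,
                     caliper = config$caliper, covariates = cov)
      utils::write.csv(mr$pairs, file.path(config$out_dir, "matches.csv"),
                       row.names = FALSE)
      logf("matched %d/%d cases (caliper %.4f, %d unmatched)",
           nrow(mr$pairs), nrow(cases), mr$caliper, mr$n_unmatched)
      mr
    }
  })

  # -- report -----------------------------------------------------------
  summary <- stage("report", {
    kept <- attr(val$partition, "retained")
    s <- list(
      seed = config$seed,
      version = as.character(utils::packageVersion("coexnet")),
      cohorts = cohort_names,
      n_genes_universe = length(prep$universe),
      beta = config$network$beta,
      communities_detected = length(unique(
        net$partition$labels[net$partition$labels > 0])),
      communities_retained = sum(kept),
      edge_confirmation_rate = val$edge_report$confirmation_rate,
      preservation_z = lapply(val$preservation, function(rep)
        stats::setNames(as.list(rep$z_summary), rep$community)),
      associations = if (!is.null(assoc$table))
        nrow(assoc$table) else 0L,
      significant_enrichments = if (!is.null(enr$table))
        sum(enr$table$p < 0.05, na.rm = TRUE) else 0L,
      prognosis = if (!is.null(surv$prognosis))
        lapply(split(surv$prognosis, surv$prognosis$community), function(d)
          list(hr_ordinal = d$hr[d$coding == "ordinal"],
               p_ordinal = d$p[d$coding == "ordinal"]))
      else NULL,
      matched_controls = if (!is.null(mres)) nrow(mres$pairs) else 0L)
    jsonlite::write_json(s, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    s
  })

  invisible(list(data = data, preprocess = prep, network = net,
                 validation = val, association = assoc,
                 enrichment = enr, survival = surv, match = mres,
                 summary = summary, out_dir = config$out_dir))
}

# Condition-style gene-set collection built from the planted truth:
# each set mixes part of one planted module with background genes, so
# enrichment has a known direction. Synthetic stand-ins for the
# exercise / bed-rest / cachexia / senescence collections.
synthetic_gene_sets <- function(truth, universe, seed = 1L) {
  with_seed(seed, {
    labels <- truth$labels[intersect(names(truth$labels), universe)]
    mods <- sort(unique(labels[labels > 0]))
    bg <- names(labels)[labels == 0]
    nm <- c("exercise_synthetic", "bed_rest_synthetic",
            "cachexia_synthetic", "senescence_synthetic")
    sets <- list()
    for (i in seq_along(nm)) {
      m <- mods[((i - 1) %% max(length(mods), 1)) + 1]
      core <- names(labels)[labels == m]
      core <- sample(core, max(3, round(0.6 * length(core))))
      noise <- sample(bg, min(length(bg), 20))
      sets[[nm[i]]] <- c(core, noise)
    }
    attr(sets, "descriptions") <- stats::setNames(
      paste("synthetic condition set planted on module",
            vapply(seq_along(nm), function(i)
              mods[((i - 1) %% max(length(mods), 1)) + 1], 0)), nm)
    sets
  })
}

# Read user-supplied inputs in the documented dialects.
ingest_inputs <- function(paths) {
  if (is.null(paths$discovery_counts) || is.null(paths$annotations))
    stop("paths must include discovery_counts and annotations",
         call. = FALSE)
  expr <- list()
  disc <- read_expression_tsv(paths$discovery_counts)
  attr(disc, "platform") <- "counts"
  expr[["discovery"]] <- disc
  for (nm in names(paths)) {
    if (grepl("_expression$", nm)) {
      co <- sub("_expression$", "", nm)
      m <- read_expression_tsv(paths[[nm]])
      attr(m, "platform") <- if (isTRUE(paths[[paste0(co, "_platform")]] ==
                                        "log-intensity")) "log-intensity"
                             else "counts"
      expr[[co]] <- m
    }
  }
  ann <- read_annotations_csv(paths$annotations)
  list(expression = expr, annotations = ann, truth = NULL)
}
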