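#' Analysis configuration
#'
#' The automated report is driven by a configuration that breaks the
#' workflow into ordered sections, each holding the parameters of one
#' pipeline operation. [default_config()] encodes the pipeline defaults:
#' maximum-missing filter (0.5), median normalization, MinProb
#' imputation, BH FDR, fold change > 2 and FDR < 0.05 regulation flags,
#' 250 permutations when permutation FDR is requested, correlation-edge
#' rule coefficient > 0.5 at FDR < 0.05, Spearman for the
#' clinical-protein block, top-15 knowledge cap, top-25% survival split
#' and side-effect Jaccard cutoff 0.2.
#'
#' @param path YAML file path.
#' @return List of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_analysis_config
#' @export
default_config <- function() {
  read_analysis_config(system.file("config", "default.yml",
                                   package = "proteokg", mustWork = TRUE))
}

config_registry <- list(
  prep = c("filter_mode", "filter_threshold", "normalization",
           "imputation"),
  stats = c("fold_change_min", "fdr_max", "fdr", "permutations",
            "variance"),
  networks = c("method", "min_coefficient", "fdr_max", "absolute"),
  multiomics = c("method", "min_coefficient", "fdr_max", "absolute"),
  knowledge = c("k_per_label", "labels"),
  survival = c("split"),
  prioritization = c("max_jaccard", "mode"))

#' Validate an analysis configuration
#'
#' Fails before any execution when a section or parameter is not known to
#' the operation registry.
#'
#' @param cfg configuration list (e.g. from YAML).
#' @return The validated config, classed `analysis_config`.
#' @export
validate_config <- function(cfg) {
  known <- c(names(config_registry), "order", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown configuration section(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cfg$order)) {
    bad_op <- setdiff(cfg$order, names(config_registry))
    if (length(bad_op)) {
      stop("configuration references unknown operation(s): ",
           paste(bad_op, collapse = ", "), call. = FALSE)
    }
  }
  for (sec in intersect(names(cfg), names(config_registry))) {
    extra <- setdiff(names(cfg[[sec]]), c(config_registry[[sec]], "seed"))
    extra <- setdiff(extra, if (sec == "prep") character(0) else character(0))
    if (length(extra)) {
      stop("unknown parameter(s) in section '", sec, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  structure(cfg, class = c("analysis_config", "list"))
}

#' Run the default analysis pipeline on a project directory
#'
#' Expects `manifest.tsv`, `proteomics.tsv` and optionally `clinical.tsv`,
#' `survival.tsv` and a knowledge graph (`graph_nodes.tsv` /
#' `graph_edges.tsv`, unless one is passed in). Executes preparation,
#' exploration, PCA, design-aware differential testing and the protein
#' correlation network for the proteomics tab; summary statistics (and
#' survival curves when available) for the clinical tab; the
#' clinical-protein Spearman network for the multiomics tab (only when
#' both data types are present); and the betweenness-pruned knowledge
#' summary subgraph of all regulated proteins for the knowledge tab. The
#' run is a pure function of (input files, config, seed).
#'
#' @param project_dir directory with the project files.
#' @param config an `analysis_config` (default [default_config()]).
#' @param graph optional [property_graph()]; read from the project
#'   directory when `NULL`.
#' @param seed integer seed overriding `config$seed` when not `NULL`.
#' @return List of class `ckg_report` with `tabs` (named list of named
#'   lists of data.frames) and `provenance` (config snapshot, seed,
#'   package version).
#' @export
run_default_pipeline <- function(project_dir, config = default_config(),
                                 graph = NULL, seed = NULL) {
  config <- validate_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  man_path <- file.path(project_dir, "manifest.tsv")
  prot_path <- file.path(project_dir, "proteomics.tsv")
  if (!file.exists(man_path) || !file.exists(prot_path)) {
    stop("project directory must contain manifest.tsv and proteomics.tsv",
         call. = FALSE)
  }
  manifest <- utils::read.delim(man_path, stringsAsFactors = FALSE)
  registry <- mint_identifiers(manifest)
  if (is.null(graph) &&
      file.exists(file.path(project_dir, "graph_nodes.tsv"))) {
    graph <- load_graph_tsv(file.path(project_dir, "graph_nodes.tsv"),
                            file.path(project_dir, "graph_edges.tsv"),
                            schema = default_schema(), validate = FALSE)
  }

  mat <- read_experiment_wide(prot_path)
  mat$samples$subject <- registry$manifest$subject_internal[
    match(mat$samples$id, registry$manifest$analytical_sample)]

  pcfg <- config$prep %||% list()
  icfg <- do.call(imputation_config,
                  c(pcfg$imputation %||% list(), list(seed = seed)))
  prep <- prepare_matrix(mat,
                         filter_mode = pcfg$filter_mode %||% "max_missing",
                         filter_threshold = pcfg$filter_threshold %||% 0.5,
                         normalization = pcfg$normalization %||% "median",
                         imputation = icfg)
  proc <- prep$matrix

  scfg <- config$stats %||% list()
  thr <- significance_thresholds(scfg$fold_change_min %||% 2,
                                 scfg$fdr_max %||% 0.05)
  diff <- differential_regulation(proc, thresholds = thr,
                                  fdr = scfg$fdr %||% "bh",
                                  permutations = scfg$permutations %||% 250L,
                                  seed = seed)
  summ <- summarize_matrix(proc)
  pca <- run_pca(proc, n_components = min(2L, min(dim(proc$values))))
  ncfg <- config$networks %||% list()
  net <- correlation_network(proc,
                             method = ncfg$method %||% "pearson",
                             min_coefficient = ncfg$min_coefficient %||% 0.5,
                             fdr_max = ncfg$fdr_max %||% 0.05,
                             absolute = isTRUE(ncfg$absolute), seed = seed)
  proteomics_tab <- list(
    summary_groups = summ$groups,
    dynamic_range = summ$dynamic_range,
    cv = summ$cv,
    pca_scores = data.frame(sample = rownames(pca$scores),
                            as.data.frame(pca$scores),
                            stringsAsFactors = FALSE),
    pca_variance = data.frame(component = seq_along(pca$explained_variance),
                              explained = pca$explained_variance),
    differential_regulation = as.data.frame(diff),
    volcano_payload = volcano_payload(diff),
    network_nodes = net$nodes,
    network_edges = net$edges)

  tabs <- list(proteomics = proteomics_tab)

  clin_path <- file.path(project_dir, "clinical.tsv")
  has_clinical <- file.exists(clin_path)
  if (has_clinical) {
    cmat <- read_experiment_wide(clin_path, log2 = FALSE,
                                 type = "clinical")
    clinical_tab <- list(
      clinical_summary = data.frame(
        variable = cmat$features$id,
        mean = colMeans(cmat$values, na.rm = TRUE),
        sd = apply(cmat$values, 2, stats::sd, na.rm = TRUE),
        stringsAsFactors = FALSE))
    surv_path <- file.path(project_dir, "survival.tsv")
    if (file.exists(surv_path)) {
      surv <- utils::read.delim(surv_path, stringsAsFactors = FALSE)
      marker <- proc$features$id[1]
      keep <- match(proc$samples$id, surv$sample)
      if (!anyNA(keep)) {
        km <- km_logrank(surv$time[keep], surv$event[keep],
                         proc$values[, marker],
                         split = (config$survival %||% list())$split %||%
                           0.25)
        clinical_tab$survival_curves <- km$curves
        clinical_tab$survival_test <- data.frame(
          marker = marker, statistic = km$statistic, pvalue = km$pvalue,
          grouping = km$grouping, stringsAsFactors = FALSE)
      }
    }
    tabs$clinical <- clinical_tab

    # multiomics tab only when several data types are analysed together
    mcfg <- config$multiomics %||% list()
    joint_vals <- cbind(proc$values, cmat$values[
      match(proc$samples$id, cmat$samples$id), , drop = FALSE])
    joint <- expr_matrix(joint_vals, proc$samples,
                         rbind(proc$features,
                               data.frame(id = cmat$features$id,
                                          type = "clinical",
                                          stringsAsFactors = FALSE)))
    mnet <- correlation_network(
      joint, method = mcfg$method %||% "spearman",
      min_coefficient = mcfg$min_coefficient %||% 0.5,
      fdr_max = mcfg$fdr_max %||% 0.05,
      blocks = list(proc$features$id, cmat$features$id),
      absolute = isTRUE(mcfg$absolute), seed = seed)
    tabs$multiomics <- list(network_nodes = mnet$nodes,
                            network_edges = mnet$edges)
  }

  if (!is.null(graph)) {
    kcfg <- config$knowledge %||% list()
    regulated <- unique(diff$feature[diff$regulation != "ns"])
    ks <- suppressWarnings(build_knowledge_subgraph(
      graph, regulated,
      labels = kcfg$labels %||% c("Disease", "Drug", "Pathway",
                                  "Biological_process", "Publication",
                                  "Complex"),
      k_per_label = kcfg$k_per_label %||% 15L))
    tabs$knowledge <- list(
      ranking = if (nrow(as.data.frame(ks$ranking))) ks$ranking else
        data.frame(id = character(), label = character(),
                   betweenness = numeric(), rank = integer()),
      sankey = ks$sankey,
      subgraph_nodes = ks$subgraph$nodes,
      subgraph_edges = ks$subgraph$edges)
  }

  structure(list(tabs = tabs,
                 provenance = list(
                   config = unclass(config), seed = seed,
                   package_version =
                     as.character(utils::packageVersion("proteokg")))),
            class = "ckg_report")
}

#' @export
print.ckg_report <- function(x, ...) {
  cat("<ckg_report> tabs:", paste(names(x$tabs), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a report
#'
#' Writes one folder per tab (every table as TSV; `*_payload` tables also
#' as JSON; network node/edge tables additionally as a GML graph), plus a
#' single hierarchical archive `report.json` containing all tables and
#' the provenance; [load_report()] on the archive reproduces the report.
#'
#' @param report a `ckg_report`.
#' @param out_dir output directory.
#' @param overwrite allow writing over an existing archive.
#' @return Invisibly, the archive path.
#' @export
serialize_report <- function(report, out_dir, overwrite = FALSE) {
  stopifnot(inherits(report, "ckg_report"))
  archive <- file.path(out_dir, "report.json")
  if (file.exists(archive) && !overwrite) {
    stop("archive exists: ", archive, " (use overwrite = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in names(report$tabs)) {
    tdir <- file.path(out_dir, tab)
    dir.create(tdir, showWarnings = FALSE)
    tables <- report$tabs[[tab]]
    for (nm in names(tables)) {
      utils::write.table(tables[[nm]], file.path(tdir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (grepl("_payload$", nm)) {
        jsonlite::write_json(tables[[nm]],
                             file.path(tdir, paste0(nm, ".json")),
                             dataframe = "rows", na = "null",
                             digits = NA)
      }
    }
    if (all(c("network_nodes", "network_edges") %in% names(tables)) &&
        nrow(tables$network_edges)) {
      ng <- property_graph(
        data.frame(id = tables$network_nodes$id, label = "feature",
                   cluster = tables$network_nodes$cluster,
                   stringsAsFactors = FALSE),
        data.frame(from = tables$network_edges$from,
                   to = tables$network_edges$to, type = "correlates",
                   weight = tables$network_edges$coefficient,
                   stringsAsFactors = FALSE))
      export_graph(ng, file.path(tdir, "network.gml"), "gml")
      export_graph(ng, file.path(tdir, "network.json"), "json")
    }
  }
  jsonlite::write_json(list(tabs = report$tabs,
                            provenance = report$provenance),
                       archive, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(archive)
}

#' Load a serialized report archive
#'
#' @param archive path to a `report.json` written by [serialize_report()].
#' @return A `ckg_report`.
#' @export
load_report <- function(archive) {
  x <- jsonlite::fromJSON(archive, simplifyDataFrame = TRUE,
                          simplifyVector = TRUE)
  tabs <- lapply(x$tabs, function(tab) {
    lapply(tab, function(tb) as.data.frame(tb, stringsAsFactors = FALSE))
  })
  structure(list(tabs = tabs, provenance = x$provenance),
            class = "ckg_report")
}
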