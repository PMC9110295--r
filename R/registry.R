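#' Mint internal identifiers for a project manifest
#'
#' Clinical proteomics projects enrol subjects, collect biological samples
#' from them and derive analytical samples (the aliquots actually measured
#' in the mass spectrometer). External identifiers from the manifest are
#' mapped to deterministic, zero-padded internal identifiers with typed
#' prefixes (`P` project, `S` subject, `BS` biological sample, `AS`
#' analytical sample), counters running in manifest order. Re-running on
#' the same manifest yields an identical registry.
#'
#' @param manifest data.frame with columns `subject`, `biological_sample`,
#'   `analytical_sample`, `group`, and optionally `timepoint`, `disease`,
#'   `tissue` (external identifiers / labels).
#' @param project external project identifier (used as the Project node
#'   name); internal id is always `P001` for a single-project registry.
#' @return List of class `project_registry` with `project_id`,
#'   `project_name`, data.frames `subjects`, `biosamples`, `asamples`
#'   (external / internal ids plus hierarchy links and design metadata) and
#'   the augmented `manifest`.
#' @export
mint_identifiers <- function(manifest, project = "PROJECT1") {
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  need <- c("subject", "biological_sample", "analytical_sample", "group")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (cl in need) manifest[[cl]] <- as.character(manifest[[cl]])
  # hierarchy integrity: each AS under one BS, each BS under one subject
  as_bs <- unique(manifest[c("analytical_sample", "biological_sample")])
  if (anyDuplicated(as_bs$analytical_sample)) {
    bad <- as_bs$analytical_sample[duplicated(as_bs$analytical_sample)][1]
    stop("analytical sample '", bad,
         "' is listed under two biological samples", call. = FALSE)
  }
  bs_subj <- unique(manifest[c("biological_sample", "subject")])
  if (anyDuplicated(bs_subj$biological_sample)) {
    bad <- bs_subj$biological_sample[duplicated(bs_subj$biological_sample)][1]
    stop("biological sample '", bad, "' is listed under two subjects",
         call. = FALSE)
  }
  pad <- function(prefix, i) sprintf("%s%03d", prefix, i)
  subj_ext <- unique(manifest$subject)
  subjects <- data.frame(external = subj_ext,
                         internal = pad("S", seq_along(subj_ext)),
                         stringsAsFactors = FALSE)
  bs_ext <- unique(manifest$biological_sample)
  biosamples <- data.frame(external = bs_ext,
                           internal = pad("BS", seq_along(bs_ext)),
                           stringsAsFactors = FALSE)
  biosamples$subject_internal <- subjects$internal[
    match(bs_subj$subject[match(bs_ext, bs_subj$biological_sample)],
          subjects$external)]
  as_ext <- unique(manifest$analytical_sample)
  asamples <- data.frame(external = as_ext,
                         internal = pad("AS", seq_along(as_ext)),
                         stringsAsFactors = FALSE)
  first <- match(as_ext, manifest$analytical_sample)
  asamples$biosample_internal <- biosamples$internal[
    match(manifest$biological_sample[first], biosamples$external)]
  asamples$group <- manifest$group[first]
  for (cl in c("timepoint", "disease", "tissue")) {
    if (cl %in% names(manifest)) {
      biosamples[[cl]] <- manifest[[cl]][
        match(bs_ext, manifest$biological_sample)]
    }
  }
  manifest$subject_internal <- subjects$internal[
    match(manifest$subject, subjects$external)]
  manifest$biosample_internal <- biosamples$internal[
    match(manifest$biological_sample, biosamples$external)]
  manifest$asample_internal <- asamples$internal[
    match(manifest$analytical_sample, asamples$external)]
  structure(list(project_id = "P001", project_name = project,
                 subjects = subjects, biosamples = biosamples,
                 asamples = asamples, manifest = manifest),
            class = "project_registry")
}

#' @export
print.project_registry <- function(x, ...) {
  cat("<project_registry> ", x$project_id, " (", x$project_name, "): ",
      nrow(x$subjects), " subjects, ", nrow(x$biosamples),
      " biological samples, ", nrow(x$asamples), " analytical samples\n",
      sep = "")
  invisible(x)
}

#' Ingest a quantified experiment into the knowledge graph
#'
#' Creates the project chain (Project -HAS_ENROLLED-> Subject
#' -HAS_BIOLOGICAL_SAMPLE-> Biological_sample -SPLITTED_INTO->
#' Analytical_sample, plus BELONGS_TO_PROJECT and disease/tissue links from
#' the registry metadata) and one `HAS_QUANTIFIED_PROTEIN` edge per
#' non-missing (sample, protein) cell, the quantification stored in the
#' edge attribute `value`. Features are mapped to existing Protein nodes
#' through the mapping dictionary; unmapped features are reported, not
#' fatal. Re-ingesting the same matrix is an upsert: edge counts do not
#' change.
#'
#' @param graph a [property_graph()] holding the prior knowledge (Protein
#'   nodes etc.).
#' @param registry a [mint_identifiers()] registry covering every sample in
#'   the matrix.
#' @param matrix an [expr_matrix()]; sample ids must be analytical-sample
#'   external or internal identifiers from the registry.
#' @param mapping optional [build_mapping()] dictionary translating feature
#'   identifiers to Protein node ids; `NULL` uses feature ids verbatim.
#' @return The augmented [property_graph()]; attribute `ingest_report`
#'   lists `unmapped_features` and `n_quantified_edges`.
#' @export
ingest_experiment <- function(graph, registry, matrix, mapping = NULL) {
  stopifnot(inherits(graph, "property_graph"),
            inherits(registry, "project_registry"),
            inherits(matrix, "expr_matrix"))
  sample_ids <- matrix$samples$id
  hit <- match(sample_ids, registry$asamples$external)
  hit2 <- match(sample_ids, registry$asamples$internal)
  internal <- ifelse(is.na(hit), registry$asamples$internal[hit2],
                     registry$asamples$internal[hit])
  if (anyNA(internal)) {
    stop("sample(s) absent from registry: ",
         paste(sample_ids[is.na(internal)], collapse = ", "), call. = FALSE)
  }
  feat <- matrix$features$id
  target <- if (is.null(mapping)) feat else map_identifiers(mapping, feat)
  known <- !is.na(target) & target %in%
    graph$nodes$id[graph$nodes$label == "Protein"]
  unmapped <- feat[!known]

  new_nodes <- rbind(
    data.frame(id = registry$project_id, label = "Project",
               name = registry$project_name, stringsAsFactors = FALSE),
    data.frame(id = registry$subjects$internal, label = "Subject",
               name = registry$subjects$external, stringsAsFactors = FALSE),
    data.frame(id = registry$biosamples$internal, label = "Biological_sample",
               name = registry$biosamples$external, stringsAsFactors = FALSE),
    data.frame(id = registry$asamples$internal, label = "Analytical_sample",
               name = registry$asamples$external, stringsAsFactors = FALSE))
  new_nodes <- new_nodes[!new_nodes$id %in% graph$nodes$id, , drop = FALSE]

  chain <- rbind(
    data.frame(from = registry$project_id,
               to = registry$subjects$internal,
               type = "HAS_ENROLLED", stringsAsFactors = FALSE),
    data.frame(from = registry$biosamples$subject_internal,
               to = registry$biosamples$internal,
               type = "HAS_BIOLOGICAL_SAMPLE", stringsAsFactors = FALSE),
    data.frame(from = registry$asamples$biosample_internal,
               to = registry$asamples$internal,
               type = "SPLITTED_INTO", stringsAsFactors = FALSE),
    data.frame(from = registry$asamples$internal,
               to = registry$project_id,
               type = "BELONGS_TO_PROJECT", stringsAsFactors = FALSE))
  meta_links <- list()
  add_meta <- function(col, type, label) {
    if (col %in% names(registry$biosamples)) {
      v <- registry$biosamples[[col]]
      ok <- !is.na(v) & nzchar(v) & v %in%
        graph$nodes$id[graph$nodes$label == label]
      if (any(ok)) {
        meta_links[[length(meta_links) + 1L]] <<- data.frame(
          from = registry$biosamples$internal[ok], to = v[ok], type = type,
          stringsAsFactors = FALSE)
      }
    }
  }
  add_meta("disease", "HAS_DISEASE", "Disease")
  add_meta("tissue", "FROM_TISSUE", "Tissue")
  if (length(meta_links)) chain <- rbind(chain, do.call(rbind, meta_links))
  if ("disease" %in% names(registry$biosamples)) {
    d <- unique(registry$biosamples$disease)
    d <- d[!is.na(d) & nzchar(d) & d %in%
             graph$nodes$id[graph$nodes$label == "Disease"]]
    if (length(d)) {
      chain <- rbind(chain, data.frame(from = registry$project_id, to = d,
                                       type = "STUDIES_DISEASE",
                                       stringsAsFactors = FALSE))
    }
  }

  vals <- matrix$values[, known, drop = FALSE]
  prot <- target[known]
  obs <- which(!is.na(vals), arr.ind = TRUE)
  quant <- if (nrow(obs)) {
    data.frame(from = internal[obs[, 1]], to = prot[obs[, 2]],
               type = "HAS_QUANTIFIED_PROTEIN",
               value = vals[obs], stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), type = character(),
               value = numeric(), stringsAsFactors = FALSE)
  }

  all_edges <- merge_edge_frames(graph$edges, rbind_fill(chain, quant))
  coll <- collapse_edges(all_edges)
  out <- property_graph(rbind_fill(graph$nodes, new_nodes), coll$edges,
                        schema = graph$schema)
  attr(out, "ingest_report") <- list(unmapped_features = unmapped,
                                     n_quantified_edges = nrow(quant))
  out
}

# row-bind data.frames with differing columns, filling NA
rbind_fill <- function(a, b) {
  if (is.null(a) || !nrow(a)) return(b)
  if (is.null(b) || !nrow(b)) return(a)
  for (nm in setdiff(names(b), names(a))) a[[nm]] <- NA
  for (nm in setdiff(names(a), names(b))) b[[nm]] <- NA
  rbind(a, b[names(a)])
}

merge_edge_frames <- function(a, b) rbind_fill(a, b)
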