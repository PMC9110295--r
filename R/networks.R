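#' Correlation network over features
#'
#' Computes all pairwise correlations (within one feature block, or across
#' the two blocks of a bipartite split such as proteins versus quantitative
#' clinical variables), adjusts p-values with Benjamini-Hochberg across all
#' tested pairs and keeps an edge when the coefficient exceeds
#' `min_coefficient` and the adjusted p is below `fdr_max`. The threshold
#' applies to the signed coefficient by default (the association rule is
#' stated for positive correlation); set `absolute = TRUE` to also keep
#' strong anticorrelations. Isolated nodes are dropped; constant features
#' have undefined coefficients and are excluded with a warning. Communities
#' of the retained graph are found with the Louvain algorithm.
#'
#' @param matrix a complete [expr_matrix()] with at least 3 samples.
#' @param method `"pearson"` (default protein-protein rule) or
#'   `"spearman"` (clinical-protein associations).
#' @param min_coefficient edge-inclusion coefficient threshold
#'   (default 0.5).
#' @param fdr_max maximum BH-adjusted p (default 0.05).
#' @param blocks optional list of two character vectors of feature ids;
#'   only across-block pairs are tested (bipartite mode).
#' @param absolute threshold |coefficient| instead of the signed value.
#' @param cluster run Louvain on the retained edges (default `TRUE`).
#' @param seed seed for the clustering step.
#' @return List of class `correlation_network` with `edges` (data.frame
#'   `from`, `to`, `coefficient`, `pvalue`, `padj`), `nodes` (data.frame
#'   `id`, `cluster`), `method` tag and `modularity` (NA when
#'   `cluster = FALSE` or no edges).
#' @export
correlation_network <- function(matrix, method = c("pearson", "spearman"),
                                min_coefficient = 0.5, fdr_max = 0.05,
                                blocks = NULL, absolute = FALSE,
                                cluster = TRUE, seed = 1L) {
  stopifnot(inherits(matrix, "expr_matrix"))
  method <- match.arg(method)
  v <- matrix$values
  if (anyNA(v)) stop("matrix has missing values; impute first",
                     call. = FALSE)
  n <- nrow(v)
  if (n < 3) stop("need at least 3 samples for correlation", call. = FALSE)
  const <- apply(v, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning(sum(const), " constant feature(s) excluded from the network",
            call. = FALSE)
    v <- v[, !const, drop = FALSE]
  }
  ids <- colnames(v)
  r <- stats::cor(v, method = method)
  # large-sample t approximation on the coefficient (AS 89-style for rho)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pm <- 2 * stats::pt(-abs(tt), df = n - 2)
  pm[r == 1 | r == -1] <- 0
  idx <- which(upper.tri(r), arr.ind = TRUE)
  if (!is.null(blocks)) {
    b1 <- ids %in% blocks[[1]]; b2 <- ids %in% blocks[[2]]
    keep_pair <- (b1[idx[, 1]] & b2[idx[, 2]]) |
      (b2[idx[, 1]] & b1[idx[, 2]])
    idx <- idx[keep_pair, , drop = FALSE]
  }
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      coefficient = r[idx], pvalue = pm[idx],
                      stringsAsFactors = FALSE)
  edges$padj <- bh_fdr(edges$pvalue)
  coefs <- if (absolute) abs(edges$coefficient) else edges$coefficient
  edges <- edges[coefs > min_coefficient & edges$padj < fdr_max, ,
                 drop = FALSE]
  rownames(edges) <- NULL
  ids_kept <- sort(unique(c(edges$from, edges$to)))
  nodes <- data.frame(id = ids_kept,
                      cluster = rep(NA_integer_, length(ids_kept)),
                      stringsAsFactors = FALSE)
  modularity <- NA_real_
  if (cluster && nrow(edges)) {
    cl <- louvain_communities(edges, seed = seed)
    nodes$cluster <- cl$membership[nodes$id]
    modularity <- cl$modularity
  }
  structure(list(edges = edges, nodes = nodes,
                 method = sprintf("%s, coefficient > %s%s, FDR < %s",
                                  method, min_coefficient,
                                  if (absolute) " (absolute)" else "",
                                  fdr_max),
                 modularity = modularity),
            class = "correlation_network")
}

#' Louvain community detection
#'
#' Modularity-maximizing clustering of a weighted undirected graph.
#' Vertices are processed in sorted id order and the random-number stream
#' is seeded, so the partition is deterministic for a given input.
#'
#' @param edges data.frame with columns `from`, `to` and optionally a
#'   numeric weight column (`weight` or `coefficient`).
#' @param nodes optional character vector of node ids (to include
#'   isolated nodes).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed.
#' @return List with `membership` (named integer vector) and `modularity`
#'   `Q` (0 for an edgeless graph, where every node is its own singleton
#'   community).
#' @export
louvain_communities <- function(edges, nodes = NULL, resolution = 1,
                                seed = 1L) {
  all_ids <- sort(unique(c(as.character(edges$from),
                           as.character(edges$to), nodes)))
  if (!length(all_ids)) stop("empty graph", call. = FALSE)
  if (!nrow(edges)) {
    return(list(membership = stats::setNames(seq_along(all_ids), all_ids),
                modularity = 0))
  }
  w <- if ("weight" %in% names(edges)) abs(edges$weight) else
    if ("coefficient" %in% names(edges)) abs(edges$coefficient) else
      rep(1, nrow(edges))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to, weight = w,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = all_ids))
  g <- igraph::simplify(g, edge.attr.comb = "max")
  cl <- withr_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(memb), names(memb)),
       modularity = igraph::modularity(g, memb,
                                       weights = igraph::E(g)$weight))
}

#' Project similarity
#'
#' Compares two projects by the overlap of their identified proteins
#' (Jaccard index and overlap coefficient) and by their protein profiles
#' (Pearson correlation of mean abundances over shared proteins).
#'
#' @param proteins_a,proteins_b character vectors of identified protein
#'   ids.
#' @param profile_a,profile_b optional named numeric vectors of mean
#'   abundances per protein.
#' @return Named list `jaccard`, `overlap`, `pearson`; `pearson` is `NA`
#'   (sentinel) when profiles are absent or fewer than 3 proteins are
#'   shared.
#' @export
project_similarity <- function(proteins_a, proteins_b,
                               profile_a = NULL, profile_b = NULL) {
  proteins_a <- unique(proteins_a); proteins_b <- unique(proteins_b)
  if (!length(proteins_a) && !length(proteins_b)) {
    stop("both protein sets are empty", call. = FALSE)
  }
  inter <- intersect(proteins_a, proteins_b)
  jac <- length(inter) / length(union(proteins_a, proteins_b))
  ovl <- if (min(length(proteins_a), length(proteins_b)) == 0) 0 else
    length(inter) / min(length(proteins_a), length(proteins_b))
  pea <- NA_real_
  if (!is.null(profile_a) && !is.null(profile_b)) {
    shared <- intersect(intersect(names(profile_a), names(profile_b)),
                        inter)
    if (length(shared) >= 3) {
      pea <- stats::cor(profile_a[shared], profile_b[shared])
    }
  }
  list(jaccard = jac, overlap = ovl, pearson = pea)
}

#' Top-k nodes per label by betweenness centrality
#'
#' Exact shortest-path betweenness on the undirected simple view of the
#' graph (unit edge weights, unnormalized pair counts, endpoints
#' excluded); per node label the `k` most central nodes are retained, ties
#' broken by node id ascending.
#'
#' @param graph a [property_graph()].
#' @param k_per_label positive integer cap per label (default 15).
#' @return data.frame with `id`, `label`, `betweenness`, `rank` (within
#'   label), containing at most `k_per_label` rows per label.
#' @export
betweenness_topk <- function(graph, k_per_label = 15L) {
  stopifnot(inherits(graph, "property_graph"))
  if (k_per_label < 1) stop("k_per_label must be >= 1", call. = FALSE)
  bc <- graph_betweenness(graph)
  df <- data.frame(id = graph$nodes$id, label = graph$nodes$label,
                   betweenness = unname(bc[graph$nodes$id]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$label, -df$betweenness, df$id), ]
  out <- do.call(rbind, lapply(split(df, df$label), function(sub) {
    sub <- utils::head(sub, k_per_label)
    sub$rank <- seq_len(nrow(sub))
    sub
  }))
  rownames(out) <- NULL
  out
}

#' Betweenness centrality of every node
#' @param graph a [property_graph()].
#' @return Named numeric vector (unnormalized pair counts, undirected).
#' @export
graph_betweenness <- function(graph) {
  if (!n_edges(graph)) {
    return(stats::setNames(rep(0, n_nodes(graph)), graph$nodes$id))
  }
  ig <- as_igraph(graph, directed = FALSE)
  bc <- igraph::betweenness(ig, directed = FALSE, normalized = FALSE)
  out <- stats::setNames(rep(0, n_nodes(graph)), graph$nodes$id)
  out[names(bc)] <- as.numeric(bc)
  out
}

#' Build the knowledge-summary subgraph
#'
#' Summarizes an analysis as a graph: the regulated proteins are expanded
#' one hop into the knowledge graph towards the target labels (diseases,
#' drugs, pathways, biological processes, publications, complexes, and
#' kinases reached through substrate edges), then betweenness centrality
#' prioritizes the nodes to visualize - per label only the `k_per_label`
#' most central are retained (regulated proteins are always kept). The
#' result carries a Sankey-ready flow table aggregating retained edges by
#' (source label, target label).
#'
#' @param graph a [property_graph()] holding prior knowledge.
#' @param regulated_proteins character vector of regulated protein node
#'   ids; absent ids are logged and skipped. An empty set yields an empty
#'   summary with a warning.
#' @param labels target node labels for the expansion.
#' @param k_per_label retained-node cap per label (default 15).
#' @return List of class `knowledge_summary` with `subgraph`
#'   ([property_graph()]), `ranking` (per-label betweenness ranks of the
#'   retained nodes), `sankey` (data.frame `source_label`, `target_label`,
#'   `weight`) and `skipped` (unknown protein ids).
#' @export
build_knowledge_subgraph <- function(graph, regulated_proteins,
                                     labels = c("Disease", "Drug",
                                                "Pathway",
                                                "Biological_process",
                                                "Publication", "Complex"),
                                     k_per_label = 15L) {
  stopifnot(inherits(graph, "property_graph"))
  skipped <- setdiff(regulated_proteins, graph$nodes$id)
  seeds <- intersect(regulated_proteins, graph$nodes$id)
  if (length(skipped)) {
    message("skipping ", length(skipped),
            " regulated id(s) absent from the graph")
  }
  if (!length(seeds)) {
    warning("no regulated proteins found in the graph; empty summary",
            call. = FALSE)
    empty <- property_graph(data.frame(id = character(),
                                       label = character()),
                            schema = graph$schema)
    return(structure(list(subgraph = empty,
                          ranking = data.frame(),
                          sankey = data.frame(source_label = character(),
                                              target_label = character(),
                                              weight = numeric()),
                          skipped = skipped),
                     class = "knowledge_summary"))
  }
  # 1-hop expansion to the target labels (kinases arrive as Protein
  # neighbours via IS_SUBSTRATE_OF edges)
  expanded <- subgraph_by_pattern(graph, seeds, max_hops = 1L,
                                  target_labels = c(labels, "Protein"))
  keep_lab <- expanded$nodes$label %in% labels |
    expanded$nodes$id %in% seeds |
    (expanded$nodes$label == "Protein" & expanded$nodes$id %in%
       expanded$edges$to[expanded$edges$type == "IS_SUBSTRATE_OF"])
  expanded <- induce_subgraph(expanded, expanded$nodes$id[keep_lab])
  rk <- betweenness_topk(expanded, k_per_label)
  # per-label cap applies to the expansion; seeds are always retained
  keep <- unique(c(seeds, rk$id))
  sub <- induce_subgraph(expanded, keep)
  lab_from <- sub$nodes$label[match(sub$edges$from, sub$nodes$id)]
  lab_to <- sub$nodes$label[match(sub$edges$to, sub$nodes$id)]
  if (nrow(sub$edges)) {
    sk <- stats::aggregate(list(weight = rep(1, nrow(sub$edges))),
                           by = list(source_label = lab_from,
                                     target_label = lab_to), FUN = sum)
    sk <- sk[order(sk$source_label, sk$target_label), ]
    rownames(sk) <- NULL
  } else {
    sk <- data.frame(source_label = character(),
                     target_label = character(), weight = numeric())
  }
  structure(list(subgraph = sub, ranking = rk, sankey = sk,
                 skipped = skipped),
            class = "knowledge_summary")
}
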