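#' Property graphs
#'
#' A `property_graph` is an in-memory typed graph: nodes carry a globally
#' unique string `id`, a `label` (node class, e.g. `Protein`), and arbitrary
#' further attribute columns; directed edges carry `from`, `to`, a `type`
#' (relationship class, e.g. `HAS_QUANTIFIED_PROTEIN`) and attribute
#' columns. An optional [kg_schema()] constrains labels and (type, source
#' label, target label) triples.
#'
#' @param nodes data.frame with columns `id`, `label` plus attributes.
#' @param edges data.frame with columns `from`, `to`, `type` plus
#'   attributes. May have zero rows.
#' @param schema optional [kg_schema()] attached to the graph.
#' @param validate if `TRUE`, fail on any schema violation (see
#'   [validate_schema()]) or dangling edge endpoint.
#'
#' @return An object of class `property_graph`.
#' @export
property_graph <- function(nodes, edges = NULL, schema = NULL,
                           validate = FALSE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(nodes))) {
    stop("nodes need columns 'id' and 'label'", call. = FALSE)
  }
  nodes$id <- as.character(nodes$id)
  nodes$label <- as.character(nodes$label)
  if (anyDuplicated(nodes$id)) {
    stop("node ids must be globally unique; duplicated: ",
         paste(utils::head(unique(nodes$id[duplicated(nodes$id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        type = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "type") %in% names(edges))) {
    stop("edges need columns 'from', 'to' and 'type'", call. = FALSE)
  }
  for (cl in c("from", "to", "type")) edges[[cl]] <- as.character(edges[[cl]])
  dangling <- !(edges$from %in% nodes$id) | !(edges$to %in% nodes$id)
  if (any(dangling)) {
    stop("edges reference absent nodes (rows ",
         paste(utils::head(which(dangling), 10), collapse = ", "), ")",
         call. = FALSE)
  }
  g <- structure(list(nodes = nodes, edges = edges, schema = schema),
                 class = "property_graph")
  if (validate && !is.null(schema)) {
    rep <- validate_schema(g)
    if (nrow(rep$node_violations) || nrow(rep$edge_violations)) {
      stop("schema violations: ",
           nrow(rep$node_violations), " node(s), ",
           nrow(rep$edge_violations), " edge(s); first: ",
           format_first_violation(rep), call. = FALSE)
    }
  }
  g
}

format_first_violation <- function(rep) {
  if (nrow(rep$node_violations)) {
    v <- rep$node_violations[1, ]
    sprintf("node '%s' has unknown label '%s'", v$id, v$label)
  } else {
    v <- rep$edge_violations[1, ]
    sprintf("edge %s-[%s]->%s (%s -> %s) not permitted by schema",
            v$from, v$type, v$to, v$source_label, v$target_label)
  }
}

#' @export
print.property_graph <- function(x, ...) {
  cat("<property_graph> ", nrow(x$nodes), " nodes (",
      length(unique(x$nodes$label)), " labels), ",
      nrow(x$edges), " edges (",
      length(unique(x$edges$type)), " types)",
      if (!is.null(x$schema)) " [schema attached]", "\n", sep = "")
  invisible(x)
}

#' Number of nodes / edges
#' @param graph a [property_graph()].
#' @return integer count.
#' @export
n_nodes <- function(graph) nrow(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Validate a graph against its schema
#'
#' Report-only check: lists every node whose label is unknown to the schema
#' and every edge whose (type, source label, target label) triple is not
#' permitted. An empty report means the graph conforms.
#'
#' @param graph a [property_graph()].
#' @param schema schema to check against; defaults to the one attached to
#'   the graph.
#' @return List of class `schema_report` with data.frames
#'   `node_violations` (`id`, `label`) and `edge_violations`
#'   (`from`, `to`, `type`, `source_label`, `target_label`), and logical
#'   `conformant`.
#' @export
validate_schema <- function(graph, schema = graph$schema) {
  stopifnot(inherits(graph, "property_graph"))
  if (is.null(schema)) stop("no schema attached or supplied", call. = FALSE)
  bad_nodes <- graph$nodes[!(graph$nodes$label %in% schema$node_labels),
                           c("id", "label"), drop = FALSE]
  lab <- graph$nodes$label[match(graph$edges$from, graph$nodes$id)]
  lab2 <- graph$nodes$label[match(graph$edges$to, graph$nodes$id)]
  key <- paste(graph$edges$type, lab, lab2, sep = "\r")
  allowed <- paste(schema$relationships$type, schema$relationships$source,
                   schema$relationships$target, sep = "\r")
  bad <- !(key %in% allowed)
  edge_violations <- data.frame(
    from = graph$edges$from[bad], to = graph$edges$to[bad],
    type = graph$edges$type[bad],
    source_label = lab[bad], target_label = lab2[bad],
    stringsAsFactors = FALSE)
  structure(list(node_violations = bad_nodes,
                 edge_violations = edge_violations,
                 conformant = nrow(bad_nodes) == 0 &&
                   nrow(edge_violations) == 0),
            class = "schema_report")
}

#' @export
print.schema_report <- function(x, ...) {
  if (x$conformant) {
    cat("schema report: conformant, no violations\n")
  } else {
    cat("schema report: ", nrow(x$node_violations), " node and ",
        nrow(x$edge_violations), " edge violation(s)\n", sep = "")
  }
  invisible(x)
}

#' Adjacent nodes
#'
#' @param graph a [property_graph()].
#' @param node_id node identifier (must exist).
#' @param edge_types optional character vector restricting the edge types
#'   followed; `NULL` means no restriction.
#' @param direction `"both"` (default; the graph's associations are used
#'   symmetrically), `"out"` or `"in"`.
#' @return data.frame with columns `neighbor` and `type`, one row per
#'   distinct (neighbor, type) pair.
#' @export
graph_neighbors <- function(graph, node_id, edge_types = NULL,
                            direction = c("both", "out", "in")) {
  direction <- match.arg(direction)
  stopifnot(inherits(graph, "property_graph"))
  if (!node_id %in% graph$nodes$id) {
    stop("unknown node id: ", node_id, call. = FALSE)
  }
  e <- graph$edges
  if (!is.null(edge_types)) e <- e[e$type %in% edge_types, , drop = FALSE]
  out <- e[e$from == node_id, c("to", "type")]
  names(out) <- c("neighbor", "type")
  inc <- e[e$to == node_id, c("from", "type")]
  names(inc) <- c("neighbor", "type")
  res <- switch(direction, out = out, `in` = inc, both = rbind(out, inc))
  res <- unique(res)
  rownames(res) <- NULL
  res[order(res$neighbor, res$type), , drop = FALSE]
}

#' Induced subgraph around seed nodes
#'
#' Breadth-first expansion from `seed_ids` up to `max_hops` hops following
#' permitted edge types in both directions, then induction of all edges
#' among the reached nodes. With `target_labels` set, reached nodes are
#' pruned to the seeds plus nodes carrying one of the target labels.
#'
#' @param graph a [property_graph()].
#' @param seed_ids character vector of existing node ids.
#' @param edge_types optional edge-type filter (`NULL` = all).
#' @param target_labels optional label filter applied to non-seed nodes.
#' @param max_hops positive integer number of hops.
#' @return A [property_graph()] (same schema), nodes restricted as above.
#' @export
subgraph_by_pattern <- function(graph, seed_ids, edge_types = NULL,
                                target_labels = NULL, max_hops = 1L) {
  stopifnot(inherits(graph, "property_graph"), max_hops >= 1)
  missing_seed <- setdiff(seed_ids, graph$nodes$id)
  if (length(missing_seed)) {
    stop("unknown seed id(s): ", paste(missing_seed, collapse = ", "),
         call. = FALSE)
  }
  e <- graph$edges
  if (!is.null(edge_types)) e <- e[e$type %in% edge_types, , drop = FALSE]
  reached <- unique(seed_ids)
  frontier <- reached
  hops <- 0L
  while (hops < max_hops && length(frontier)) {
    nxt <- unique(c(e$to[e$from %in% frontier], e$from[e$to %in% frontier]))
    frontier <- setdiff(nxt, reached)
    reached <- c(reached, frontier)
    hops <- hops + 1L
  }
  if (!is.null(target_labels)) {
    lab <- graph$nodes$label[match(reached, graph$nodes$id)]
    reached <- reached[reached %in% seed_ids | lab %in% target_labels]
  }
  induce_subgraph(graph, reached, edge_types = edge_types)
}

#' Induce the subgraph on an explicit node set
#' @param graph a [property_graph()].
#' @param node_ids node ids to keep (must exist).
#' @param edge_types optional edge-type filter.
#' @return A [property_graph()].
#' @export
induce_subgraph <- function(graph, node_ids, edge_types = NULL) {
  nodes <- graph$nodes[graph$nodes$id %in% node_ids, , drop = FALSE]
  e <- graph$edges
  if (!is.null(edge_types)) e <- e[e$type %in% edge_types, , drop = FALSE]
  e <- e[e$from %in% nodes$id & e$to %in% nodes$id, , drop = FALSE]
  rownames(nodes) <- rownames(e) <- NULL
  property_graph(nodes, e, schema = graph$schema)
}

#' Collapse duplicate edges
#'
#' Edges sharing (from, to, type) are merged to one. When several sources
#' provide the same relationship, a numeric `score` attribute keeps its
#' maximum; every other attribute is last-write-wins in row order.
#'
#' @param edges edge data.frame (`from`, `to`, `type`, attributes).
#' @return list with `edges` (collapsed data.frame) and `n_collapsed`
#'   (number of rows removed).
#' @export
collapse_edges <- function(edges) {
  if (!nrow(edges)) return(list(edges = edges, n_collapsed = 0L))
  key <- paste(edges$from, edges$to, edges$type, sep = "\r")
  if (!anyDuplicated(key)) return(list(edges = edges, n_collapsed = 0L))
  keep <- !duplicated(key, fromLast = TRUE)  # last-write-wins
  out <- edges[keep, , drop = FALSE]
  if ("score" %in% names(edges) && is.numeric(edges$score)) {
    mx <- tapply(edges$score, key, function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
    out$score <- as.numeric(mx[paste(out$from, out$to, out$type, sep = "\r")])
  }
  rownames(out) <- NULL
  list(edges = out, n_collapsed = sum(!keep))
}

#' Convert a property graph to an igraph object
#'
#' Node ids become vertex names, labels a `label` vertex attribute, edge
#' types a `type` edge attribute; remaining columns are carried over as
#' attributes.
#'
#' @param graph a [property_graph()].
#' @param directed keep edge direction (`TRUE`) or collapse to an
#'   undirected simple graph (`FALSE`).
#' @return An `igraph` graph.
#' @export
as_igraph <- function(graph, directed = TRUE) {
  stopifnot(inherits(graph, "property_graph"))
  nodes <- graph$nodes
  names(nodes)[names(nodes) == "id"] <- "name"
  g <- igraph::graph_from_data_frame(graph$edges, directed = directed,
                                     vertices = nodes)
  if (!directed) g <- igraph::simplify(g, edge.attr.comb = "first")
  g
}
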