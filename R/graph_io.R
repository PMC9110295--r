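#' @keywords internal
escape_tsv_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

#' @keywords internal
unescape_tsv_field <- function(x) {
  # protect literal backslashes before expanding \t \n \r
  x <- gsub("\\\\", "\x01", x, fixed = TRUE)
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  gsub("\x01", "\\", x, fixed = TRUE)
}

read_dialect_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- unescape_tsv_field(fields[[1]])
  ncol <- length(header)
  rows <- fields[-1]
  mat <- matrix("", nrow = length(rows), ncol = ncol)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    length(r) <- ncol        # pad dropped trailing empties with NA
    r[is.na(r)] <- ""
    mat[i, ] <- unescape_tsv_field(r)
  }
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  df
}

write_dialect_tsv <- function(df, path) {
  ser <- vapply(seq_len(ncol(df)), function(j) {
    v <- df[[j]]
    s <- if (is.numeric(v)) as.character(v) else as.character(v)
    s[is.na(v)] <- ""
    escape_tsv_field(s)
  }, character(nrow(df)))
  if (nrow(df) == 1) ser <- matrix(ser, nrow = 1)
  if (nrow(df) == 0) ser <- matrix(character(), nrow = 0, ncol = ncol(df))
  lines <- c(paste(escape_tsv_field(names(df)), collapse = "\t"),
             apply(ser, 1, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

convert_attr_types <- function(df, skip) {
  for (nm in setdiff(names(df), skip)) {
    v <- df[[nm]]
    v[!nzchar(v)] <- NA
    df[[nm]] <- utils::type.convert(v, as.is = TRUE)
  }
  df
}

#' Load a property graph from node/edge TSV files
#'
#' Reads the bulk-import dialect: a nodes file with mandatory columns `ID`
#' and `LABEL`, an edges file with `START_ID`, `END_ID` and `TYPE`; any
#' further columns become attributes. Files are UTF-8, tab-separated with a
#' header row; tabs/newlines/backslashes inside fields are
#' backslash-escaped. Duplicated node IDs collapse to a single node with
#' last-write-wins attributes; duplicated (source, target, type) edges are
#' merged keeping the maximum numeric `score`.
#'
#' @param nodes_path,edges_path file paths.
#' @param schema optional [kg_schema()] attached to the result.
#' @param validate if `TRUE`, edges referencing absent nodes and schema
#'   violations are errors; if `FALSE`, dangling edges are dropped with a
#'   warning and schema conformance is not enforced.
#' @return A [property_graph()] whose attribute `import_report` records
#'   `n_nodes_collapsed`, `n_edges_dropped` and `n_edges_collapsed`.
#' @export
load_graph_tsv <- function(nodes_path, edges_path, schema = NULL,
                           validate = FALSE) {
  nodes <- read_dialect_tsv(nodes_path)
  for (cl in c("ID", "LABEL")) {
    if (!cl %in% names(nodes)) {
      stop("nodes file is missing mandatory column '", cl, "'",
           call. = FALSE)
    }
  }
  edges <- read_dialect_tsv(edges_path)
  for (cl in c("START_ID", "END_ID", "TYPE")) {
    if (!cl %in% names(edges)) {
      stop("edges file is missing mandatory column '", cl, "'",
           call. = FALSE)
    }
  }
  nodes <- convert_attr_types(nodes, skip = c("ID", "LABEL"))
  edges <- convert_attr_types(edges, skip = c("START_ID", "END_ID", "TYPE"))
  names(nodes)[match(c("ID", "LABEL"), names(nodes))] <- c("id", "label")
  names(edges)[match(c("START_ID", "END_ID", "TYPE"), names(edges))] <-
    c("from", "to", "type")

  n_nodes_collapsed <- sum(duplicated(nodes$id))
  if (n_nodes_collapsed) {
    nodes <- nodes[!duplicated(nodes$id, fromLast = TRUE), , drop = FALSE]
  }
  dangling <- !(edges$from %in% nodes$id) | !(edges$to %in% nodes$id)
  n_edges_dropped <- 0L
  if (any(dangling)) {
    if (validate) {
      stop("edges reference absent nodes at data row(s) ",
           paste(utils::head(which(dangling), 10), collapse = ", "),
           call. = FALSE)
    }
    warning(sum(dangling), " edge(s) referencing absent nodes dropped",
            call. = FALSE)
    n_edges_dropped <- sum(dangling)
    edges <- edges[!dangling, , drop = FALSE]
  }
  coll <- collapse_edges(edges)
  g <- property_graph(nodes, coll$edges, schema = schema,
                      validate = validate)
  attr(g, "import_report") <- list(n_nodes_collapsed = n_nodes_collapsed,
                                   n_edges_dropped = n_edges_dropped,
                                   n_edges_collapsed = coll$n_collapsed)
  g
}

#' Export a property graph
#'
#' `tsv` writes `<path>_nodes.tsv` and `<path>_edges.tsv` in the import
#' dialect of [load_graph_tsv()] (lossless round trip, numeric attributes
#' to 15 significant digits). `json` writes a single file with `nodes` and
#' `edges` arrays (lossless round trip). `gml` and `graphml` use the igraph
#' writers (Cytoscape-compatible); for `gml`, attribute names are mangled
#' to the alphanumeric characters only, as required by the format.
#'
#' @param graph a [property_graph()].
#' @param path output path; for `tsv`, used as a file-name prefix.
#' @param format one of `"tsv"`, `"json"`, `"gml"`, `"graphml"`.
#' @return Invisibly, the written file path(s).
#' @export
export_graph <- function(graph, path,
                         format = c("tsv", "json", "gml", "graphml")) {
  stopifnot(inherits(graph, "property_graph"))
  format <- match.arg(format)
  if (format == "tsv") {
    nodes <- graph$nodes
    edges <- graph$edges
    names(nodes)[match(c("id", "label"), names(nodes))] <- c("ID", "LABEL")
    names(edges)[match(c("from", "to", "type"), names(edges))] <-
      c("START_ID", "END_ID", "TYPE")
    paths <- paste0(path, c("_nodes.tsv", "_edges.tsv"))
    write_dialect_tsv(nodes, paths[1])
    write_dialect_tsv(edges, paths[2])
    return(invisible(paths))
  }
  if (format == "json") {
    jsonlite::write_json(list(nodes = graph$nodes, edges = graph$edges),
                         path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = FALSE)
    return(invisible(path))
  }
  ig <- as_igraph(graph)
  if (format == "gml") {
    for (what in c("vertex", "edge")) {
      nms <- if (what == "vertex") igraph::vertex_attr_names(ig) else
        igraph::edge_attr_names(ig)
      for (nm in nms) {
        clean <- gsub("[^A-Za-z0-9]", "", nm)
        if (clean != nm && nzchar(clean)) {
          if (what == "vertex") {
            igraph::vertex_attr(ig, clean) <- igraph::vertex_attr(ig, nm)
            ig <- igraph::delete_vertex_attr(ig, nm)
          } else {
            igraph::edge_attr(ig, clean) <- igraph::edge_attr(ig, nm)
            ig <- igraph::delete_edge_attr(ig, nm)
          }
        }
      }
    }
    igraph::write_graph(ig, path, format = "gml")
  } else {
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import an exported graph
#'
#' Counterpart of [export_graph()] for the lossless formats plus GraphML.
#'
#' @param path path (or tsv prefix) given to [export_graph()].
#' @param format `"tsv"`, `"json"` or `"graphml"`.
#' @param schema optional [kg_schema()] to attach.
#' @param validate passed to [load_graph_tsv()] for tsv.
#' @return A [property_graph()].
#' @export
import_graph <- function(path, format = c("tsv", "json", "graphml"),
                         schema = NULL, validate = FALSE) {
  format <- match.arg(format)
  if (format == "tsv") {
    return(load_graph_tsv(paste0(path, "_nodes.tsv"),
                          paste0(path, "_edges.tsv"),
                          schema = schema, validate = validate))
  }
  if (format == "json") {
    x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    nodes <- as.data.frame(x$nodes, stringsAsFactors = FALSE)
    edges <- if (length(x$edges)) {
      as.data.frame(x$edges, stringsAsFactors = FALSE)
    } else NULL
    return(property_graph(nodes, edges, schema = schema,
                          validate = validate))
  }
  ig <- igraph::read_graph(path, format = "graphml")
  nodes <- as.data.frame(igraph::vertex_attr(ig), stringsAsFactors = FALSE)
  names(nodes)[names(nodes) == "name"] <- "id"
  el <- igraph::as_edgelist(ig, names = TRUE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      stringsAsFactors = FALSE)
  for (nm in igraph::edge_attr_names(ig)) {
    edges[[nm]] <- igraph::edge_attr(ig, nm)
  }
  property_graph(nodes, edges, schema = schema, validate = validate)
}
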