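#' Graph schema definitions
#'
#' A `kg_schema` describes the data model of a clinical proteomics knowledge
#' graph: the set of permitted node labels, the permitted relationship types
#' together with their endpoint-label constraints, and optional
#' required-attribute lists per node label or relationship type.
#'
#' @param node_labels character vector of unique, non-empty label names
#'   (case-sensitive).
#' @param relationships data.frame with columns `type`, `source`, `target`;
#'   one row per permitted (type, source label, target label) triple. A type
#'   name may appear with several endpoint pairs.
#' @param required_attributes list with optional elements `nodes` and
#'   `edges`, each a named list mapping a label / type to a character vector
#'   of attribute names that must be present.
#'
#' @return An object of class `kg_schema`.
#' @export
kg_schema <- function(node_labels, relationships,
                      required_attributes = list()) {
  node_labels <- as.character(node_labels)
  if (anyNA(node_labels) || any(!nzchar(node_labels))) {
    stop("node labels must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(node_labels)) {
    stop("duplicated node label: ",
         paste(unique(node_labels[duplicated(node_labels)]), collapse = ", "),
         call. = FALSE)
  }
  relationships <- as.data.frame(relationships, stringsAsFactors = FALSE)
  need <- c("type", "source", "target")
  if (!all(need %in% names(relationships))) {
    stop("relationships must have columns type, source, target", call. = FALSE)
  }
  relationships <- relationships[need]
  if (any(!nzchar(relationships$type))) {
    stop("relationship type names must be non-empty", call. = FALSE)
  }
  bad <- !(relationships$source %in% node_labels) |
    !(relationships$target %in% node_labels)
  if (any(bad)) {
    stop("relationship endpoints not in node_labels: ",
         paste(unique(c(relationships$source[bad], relationships$target[bad])),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(relationships)) {
    stop("duplicated (type, source, target) triple in schema", call. = FALSE)
  }
  structure(
    list(node_labels = node_labels,
         relationships = relationships,
         required_attributes = required_attributes),
    class = "kg_schema"
  )
}

#' Load a schema from its YAML description
#'
#' @param path path to a YAML file with keys `node_labels`, `relationships`
#'   (list of `{type, source, target}` maps) and optionally
#'   `required_attributes`.
#' @return A [kg_schema()] object.
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  rel <- do.call(rbind, lapply(y$relationships, function(r) {
    data.frame(type = r$type, source = r$source, target = r$target,
               stringsAsFactors = FALSE)
  }))
  req <- y$required_attributes
  if (is.null(req)) req <- list()
  kg_schema(unlist(y$node_labels), rel, req)
}

#' The bundled clinical proteomics data model
#'
#' Returns the package's default graph schema: 36 node labels (Protein,
#' Disease, Drug, Metabolite, Project, Subject, Biological_sample,
#' Analytical_sample, ...) connected by 47 relationship types (HAS_PARENT,
#' ASSOCIATED_WITH, HAS_QUANTIFIED_PROTEIN, ACTS_ON, HAS_SIDE_EFFECT, ...).
#'
#' @return A [kg_schema()] object.
#' @export
default_schema <- function() {
  path <- system.file("extdata", "data_model.yml", package = "proteokg",
                      mustWork = TRUE)
  read_schema(path)
}

#' @export
print.kg_schema <- function(x, ...) {
  cat("<kg_schema> ", length(x$node_labels), " node labels, ",
      length(unique(x$relationships$type)), " relationship types (",
      nrow(x$relationships), " endpoint triples)\n", sep = "")
  invisible(x)
}

#' Schema cardinalities
#'
#' @param schema a [kg_schema()].
#' @return Named list with `n_node_labels` (distinct labels) and
#'   `n_relationship_types` (distinct relationship type names).
#' @export
schema_counts <- function(schema) {
  stopifnot(inherits(schema, "kg_schema"))
  list(n_node_labels = length(schema$node_labels),
       n_relationship_types = length(unique(schema$relationships$type)))
}
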