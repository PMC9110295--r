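#' Parse an OBO-like ontology file
#'
#' Minimal reader for flat ontology files made of `[Term]` stanzas with
#' `id:`, `name:`, and optional `synonym:`, `xref:`, `is_a:` and
#' `is_obsolete:` lines. Obsolete terms are excluded (their count is
#' reported), `is_a` edges are extracted, and the `is_a` graph is checked
#' for acyclicity; members of any cycle are reported with a warning.
#'
#' @param path path to the ontology file.
#' @return List of class `ontology_table` with elements `terms` (data.frame
#'   `id`, `name`), `synonyms` / `xrefs` (named lists keyed by term id),
#'   `is_a` (data.frame `child`, `parent`), `n_obsolete`, and `cycles`
#'   (character vector of node ids on cycles, empty when acyclic).
#' @export
parse_ontology <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  starts <- which(trimws(lines) == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path, call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  ids <- names <- character(0)
  synonyms <- xrefs <- list()
  is_a <- list()
  n_obsolete <- 0L
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):ends[k]]
    block <- block[nzchar(trimws(block)) & !startsWith(trimws(block), "[")]
    tag <- sub(":.*$", "", block)
    val <- trimws(sub("^[^:]+:", "", block))
    id <- val[tag == "id"]
    if (!length(id)) {
      stop("[Term] stanza starting at line ", starts[k],
           " has no id", call. = FALSE)
    }
    id <- id[1]
    if (any(tag == "is_obsolete" & tolower(val) == "true")) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    nm <- val[tag == "name"]
    ids <- c(ids, id)
    names <- c(names, if (length(nm)) nm[1] else NA_character_)
    syn <- val[tag == "synonym"]
    # synonym lines quote the text: synonym: "hepatic cirrhosis" EXACT []
    syn <- vapply(syn, function(s) {
      m <- regmatches(s, regexpr('"[^"]*"', s))
      if (length(m)) substr(m, 2, nchar(m) - 1) else s
    }, character(1), USE.NAMES = FALSE)
    synonyms[[id]] <- syn
    xr <- val[tag == "xref"]
    xrefs[[id]] <- sub("\\s.*$", "", xr)  # keep the accession only
    for (p in val[tag == "is_a"]) {
      parent <- trimws(sub("!.*$", "", p))
      is_a[[length(is_a) + 1L]] <- c(id, parent)
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicated term id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  is_a <- if (length(is_a)) {
    df <- do.call(rbind, is_a)
    data.frame(child = df[, 1], parent = df[, 2], stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(), parent = character(),
               stringsAsFactors = FALSE)
  }
  is_a <- is_a[is_a$child %in% ids & is_a$parent %in% ids, , drop = FALSE]
  cycles <- find_cycle_members(ids, is_a)
  if (length(cycles)) {
    warning("is_a graph is cyclic; members: ",
            paste(cycles, collapse = ", "), call. = FALSE)
  }
  structure(list(terms = data.frame(id = ids, name = names,
                                    stringsAsFactors = FALSE),
                 synonyms = synonyms, xrefs = xrefs, is_a = is_a,
                 n_obsolete = n_obsolete, cycles = cycles),
            class = "ontology_table")
}

# nodes that survive iterated leaf-stripping lie on (or feed into) a cycle
find_cycle_members <- function(ids, is_a) {
  if (!nrow(is_a)) return(character(0))
  g <- igraph::graph_from_data_frame(is_a, directed = TRUE,
                                     vertices = data.frame(name = ids))
  if (igraph::is_dag(g)) return(character(0))
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1)
  sort(names(comp$membership)[comp$membership %in% big])
}

#' Build an identifier-mapping dictionary from an ontology
#'
#' Every term name, synonym and external reference (xref) becomes a
#' case-folded key pointing at its term id, so external identifiers in
#' incoming data can be standardized. Primary names take precedence over
#' synonyms, synonyms over xrefs; a tie within the same precedence class is
#' broken by the lexicographically smallest term id and logged as a
#' collision.
#'
#' @param ontology an [parse_ontology()] result.
#' @return List of class `mapping_dictionary` with `entries` (data.frame
#'   `key`, `term_id`, `source` in `name|synonym|xref`) and `collisions`
#'   (data.frame `key`, `winner`, `losers`).
#' @export
build_mapping <- function(ontology) {
  stopifnot(inherits(ontology, "ontology_table"))
  rows <- list()
  add <- function(key, id, source) {
    key <- tolower(key)
    key <- key[nzchar(key) & !is.na(key)]
    if (length(key)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        key = key, term_id = id, source = source, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(ontology$terms))) {
    id <- ontology$terms$id[i]
    add(ontology$terms$name[i], id, "name")
    add(ontology$synonyms[[id]], id, "synonym")
    add(ontology$xrefs[[id]], id, "xref")
  }
  ent <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(), term_id = character(),
               source = character(), stringsAsFactors = FALSE)
  rnk <- c(name = 1L, synonym = 2L, xref = 3L)
  ent$rank <- as.integer(rnk[ent$source])
  ent <- ent[order(ent$key, ent$rank, ent$term_id), , drop = FALSE]
  ent <- ent[!duplicated(ent[c("key", "term_id", "source")]), , drop = FALSE]
  # a tie at the winning precedence class with distinct ids is a collision
  collisions <- list()
  for (k in unique(ent$key[duplicated(ent$key)])) {
    sub <- ent[ent$key == k, , drop = FALSE]
    top <- sub[sub$rank == min(sub$rank), , drop = FALSE]
    ids <- unique(top$term_id)
    if (length(ids) > 1) {
      collisions[[length(collisions) + 1L]] <- data.frame(
        key = k, winner = ids[1],
        losers = paste(ids[-1], collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  win <- ent[!duplicated(ent$key), , drop = FALSE]
  win$rank <- NULL
  collisions <- if (length(collisions)) do.call(rbind, collisions) else
    data.frame(key = character(), winner = character(),
               losers = character(), stringsAsFactors = FALSE)
  if (nrow(collisions)) {
    warning(nrow(collisions), " mapping collision(s); ",
            "smallest term id kept (e.g. key '", collisions$key[1], "')",
            call. = FALSE)
  }
  rownames(win) <- NULL
  structure(list(entries = win, collisions = collisions),
            class = "mapping_dictionary")
}

#' Look up keys in a mapping dictionary
#'
#' Exact, case-folded lookup; no fuzzy matching.
#'
#' @param mapping a [build_mapping()] result.
#' @param keys character vector of external identifiers / names.
#' @return Character vector of term ids, `NA` for unknown keys.
#' @export
map_identifiers <- function(mapping, keys) {
  stopifnot(inherits(mapping, "mapping_dictionary"))
  mapping$entries$term_id[match(tolower(keys), mapping$entries$key)]
}
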