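# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph) so they can certify them.

# exact betweenness by exhaustive shortest-path enumeration (undirected,
# unit weights, endpoints excluded, each unordered pair counted once)
brute_betweenness <- function(node_ids, edges) {
  adj <- lapply(stats::setNames(node_ids, node_ids), function(n) {
    unique(c(edges$to[edges$from == n], edges$from[edges$to == n]))
  })
  bc <- stats::setNames(rep(0, length(node_ids)), node_ids)
  for (s in node_ids) {
    for (t in node_ids) {
      if (s >= t) next
      paths <- list(s)
      shortest <- list()
      repeat {
        nxt <- list()
        for (p in paths) {
          last <- p[length(p)]
          if (last == t) next
          for (nb in adj[[last]]) {
            if (!(nb %in% p)) nxt[[length(nxt) + 1L]] <- c(p, nb)
          }
        }
        if (!length(nxt)) break
        hits <- Filter(function(p) p[length(p)] == t, nxt)
        if (length(hits)) { shortest <- hits; break }
        paths <- nxt
        if (length(nxt[[1]]) > length(node_ids)) break
      }
      if (length(shortest)) {
        inner <- unlist(lapply(shortest, function(p) {
          p[-c(1, length(p))]
        }))
        if (length(inner)) {
          cnt <- table(inner)
          bc[names(cnt)] <- bc[names(cnt)] + as.numeric(cnt) /
            length(shortest)
        }
      }
    }
  }
  bc
}

# all set partitions of a vector (Bell-number enumeration)
all_partitions <- function(items) {
  if (length(items) == 1) return(list(list(items)))
  rest <- all_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(items[1], q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(items[1]), p)
  }
  out
}

# Newman modularity of a partition of an unweighted undirected graph
modularity_q <- function(edges, partition) {
  m <- nrow(edges)
  comm <- stats::setNames(rep(seq_along(partition), lengths(partition)),
                          unlist(partition))
  deg <- table(c(edges$from, edges$to))
  q <- 0
  for (ci in seq_along(partition)) {
    members <- partition[[ci]]
    l_in <- sum(edges$from %in% members & edges$to %in% members)
    d_c <- sum(deg[names(deg) %in% members])
    q <- q + l_in / m - (d_c / (2 * m))^2
  }
  q
}

# canonical form of a partition for set comparison
canon_partition <- function(membership) {
  unname(lapply(split(names(membership), membership), sort))
}

# small hand-built property graph used by several graph tests
toy_graph <- function() {
  nodes <- data.frame(
    id = c("PROT001", "PROT002", "DIS01", "DIS02", "DRUG01"),
    label = c("Protein", "Protein", "Disease", "Disease", "Drug"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c("PROT001", "PROT001", "DRUG01"),
    to = c("DIS01", "DIS02", "PROT001"),
    type = c("ASSOCIATED_WITH", "ASSOCIATED_WITH", "ACTS_ON"),
    action = c(NA, NA, "inhibition"),
    stringsAsFactors = FALSE)
  property_graph(nodes, edges, schema = default_schema())
}
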