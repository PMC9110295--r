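test_that("TSV round trip is the identity and duplicates collapse", {
  tmp <- withr::local_tempdir()
  nodes <- file.path(tmp, "nodes.tsv")
  edges <- file.path(tmp, "edges.tsv")
  writeLines(c("ID\tLABEL\tname", "PROT001\tProtein\talpha",
               "DIS01\tDisease\tcirrhosis"), nodes)
  writeLines(c("START_ID\tEND_ID\tTYPE\tscore",
               "PROT001\tDIS01\tASSOCIATED_WITH\t0.8"), edges)
  g <- load_graph_tsv(nodes, edges, schema = default_schema())
  expect_equal(n_nodes(g), 2)
  expect_equal(n_edges(g), 1)

  # export -> import reproduces nodes, edges and attributes
  pre <- file.path(tmp, "roundtrip")
  export_graph(g, pre, "tsv")
  g2 <- import_graph(pre, "tsv")
  expect_equal(g2$nodes[order(g2$nodes$id), ],
               g$nodes[order(g$nodes$id), ], ignore_attr = TRUE)
  expect_equal(g2$edges, g$edges, ignore_attr = TRUE)

  # duplicated node id collapses, last write wins, collapse counted
  writeLines(c("ID\tLABEL\tname", "PROT001\tProtein\talpha",
               "PROT001\tProtein\tbeta"), nodes)
  writeLines("START_ID\tEND_ID\tTYPE", edges)
  gd <- load_graph_tsv(nodes, edges)
  expect_equal(n_nodes(gd), 1)
  expect_equal(gd$nodes$name, "beta")
  expect_equal(attr(gd, "import_report")$n_nodes_collapsed, 1L)

  # duplicated edges collapse keeping the maximum score
  writeLines(c("ID\tLABEL", "a\tProtein", "b\tDisease"), nodes)
  writeLines(c("START_ID\tEND_ID\tTYPE\tscore",
               "a\tb\tASSOCIATED_WITH\t0.3",
               "a\tb\tASSOCIATED_WITH\t0.9",
               "a\tb\tASSOCIATED_WITH\t0.5"), edges)
  ge <- load_graph_tsv(nodes, edges)
  expect_equal(n_edges(ge), 1)
  expect_equal(ge$edges$score, 0.9)
})

test_that("attribute values containing tabs and newlines survive the dialect", {
  tmp <- withr::local_tempdir()
  g <- property_graph(
    data.frame(id = "n1", label = "Protein",
               note = "has\ttab and\nnewline and \\slash",
               stringsAsFactors = FALSE))
  pre <- file.path(tmp, "esc")
  export_graph(g, pre, "tsv")
  g2 <- import_graph(pre, "tsv")
  expect_equal(g2$nodes$note, "has\ttab and\nnewline and \\slash")
})

test_that("missing mandatory columns and dangling edges are reported", {
  tmp <- withr::local_tempdir()
  nodes <- file.path(tmp, "nodes.tsv")
  edges <- file.path(tmp, "edges.tsv")
  writeLines(c("ID\tname", "a\tx"), nodes)
  writeLines("START_ID\tEND_ID\tTYPE", edges)
  expect_error(load_graph_tsv(nodes, edges), "LABEL")
  writeLines(c("ID\tLABEL", "a\tProtein"), nodes)
  writeLines(c("START_ID\tEND_ID\tTYPE", "a\tmissing\tACTS_ON"), edges)
  expect_error(load_graph_tsv(nodes, edges, validate = TRUE),
               "absent nodes")
  expect_warning(g <- load_graph_tsv(nodes, edges, validate = FALSE),
                 "dropped")
  expect_equal(n_edges(g), 0)
})

test_that("schema validation flags forbidden labels and edge triples", {
  g <- toy_graph()
  expect_true(validate_schema(g)$conformant)

  bad <- property_graph(
    data.frame(id = c("d1", "d2"), label = "Disease",
               stringsAsFactors = FALSE),
    data.frame(from = "d1", to = "d2", type = "HAS_QUANTIFIED_PROTEIN",
               stringsAsFactors = FALSE),
    schema = default_schema())
  rep <- validate_schema(bad)
  expect_false(rep$conformant)
  expect_equal(nrow(rep$edge_violations), 1)
  expect_error(property_graph(bad$nodes, bad$edges,
                              schema = default_schema(), validate = TRUE),
               "schema violation")

  unk <- property_graph(data.frame(id = "x", label = "NotALabel",
                                   stringsAsFactors = FALSE),
                        schema = default_schema())
  expect_equal(nrow(validate_schema(unk)$node_violations), 1)
})

test_that("neighbors respects direction and type filters", {
  nodes <- data.frame(id = c("a", "b", "c", "d"), label = "Protein",
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = c("a", "b", "b"), to = c("b", "c", "d"),
                      type = c("CURATED_INTERACTS_WITH",
                               "CURATED_INTERACTS_WITH",
                               "COMPILED_INTERACTS_WITH"),
                      stringsAsFactors = FALSE)
  g <- property_graph(nodes, edges)
  expect_setequal(graph_neighbors(g, "b")$neighbor, c("a", "c", "d"))
  expect_setequal(graph_neighbors(g, "b", direction = "out")$neighbor,
                  c("c", "d"))
  expect_equal(graph_neighbors(g, "b", direction = "in")$neighbor, "a")
  expect_equal(
    graph_neighbors(g, "b", edge_types = "COMPILED_INTERACTS_WITH")$neighbor,
    "d")
  expect_error(graph_neighbors(g, "nope"), "unknown node")
})

test_that("pattern subgraphs are hop-limited, label-prunable and monotone", {
  # star: protein linked to 2 diseases and 1 drug, disease has a parent
  nodes <- data.frame(
    id = c("p", "d1", "d2", "dr", "d1p"),
    label = c("Protein", "Disease", "Disease", "Drug", "Disease"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c("p", "p", "dr", "d1"),
    to = c("d1", "d2", "p", "d1p"),
    type = c("ASSOCIATED_WITH", "ASSOCIATED_WITH", "ACTS_ON",
             "HAS_PARENT"),
    stringsAsFactors = FALSE)
  g <- property_graph(nodes, edges)
  one <- subgraph_by_pattern(g, "p", max_hops = 1)
  expect_setequal(one$nodes$id, c("p", "d1", "d2", "dr"))
  two <- subgraph_by_pattern(g, "p", max_hops = 2)
  expect_setequal(two$nodes$id, nodes$id)  # whole component
  # monotone in hops
  expect_true(all(one$nodes$id %in% two$nodes$id))
  # label pruning keeps seeds plus the target label only
  dis <- subgraph_by_pattern(g, "p", max_hops = 2,
                             target_labels = "Disease")
  expect_setequal(dis$nodes$id, c("p", "d1", "d2", "d1p"))
  expect_error(subgraph_by_pattern(g, "ghost"), "unknown seed")
})

test_that("json and graphml exports round-trip; gml is Cytoscape-parseable", {
  tmp <- withr::local_tempdir()
  g <- toy_graph()
  jp <- file.path(tmp, "g.json")
  export_graph(g, jp, "json")
  gj <- import_graph(jp, "json")
  expect_equal(gj$nodes[order(gj$nodes$id), ], g$nodes[order(g$nodes$id), ],
               ignore_attr = TRUE)
  expect_equal(gj$edges[order(gj$edges$from, gj$edges$to), ],
               g$edges[order(g$edges$from, g$edges$to), ],
               ignore_attr = TRUE)

  gp <- file.path(tmp, "g.graphml")
  export_graph(g, gp, "graphml")
  gg <- import_graph(gp, "graphml")
  expect_setequal(gg$nodes$id, g$nodes$id)
  expect_equal(nrow(gg$edges), nrow(g$edges))
  expect_setequal(gg$nodes$label, g$nodes$label)

  mp <- file.path(tmp, "g.gml")
  export_graph(g, mp, "gml")
  ig <- igraph::read_graph(mp, format = "gml")
  expect_equal(igraph::vcount(ig), n_nodes(g))
  expect_equal(igraph::ecount(ig), n_edges(g))

  # empty graph export still yields a valid file
  e <- property_graph(data.frame(id = character(), label = character()))
  export_graph(e, file.path(tmp, "empty"), "tsv")
  e2 <- import_graph(file.path(tmp, "empty"), "tsv")
  expect_equal(n_nodes(e2), 0)
  expect_error(export_graph(g, file.path(tmp, "x"), "xlsx"))
})
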