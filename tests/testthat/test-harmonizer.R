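write_obo <- function(lines) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("OBO-like parsing extracts terms, is_a edges and obsoletes", {
  path <- write_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: D001", "name: cirrhosis",
    "synonym: \"hepatic cirrhosis\" EXACT []",
    "xref: ICD10:K74.6", "",
    "[Term]", "id: D002", "name: liver disease", "is_a: D003 ! disease", "",
    "[Term]", "id: D003", "name: disease", "",
    "[Term]", "id: D004", "name: old term", "is_obsolete: true"))
  ont <- parse_ontology(path)
  expect_equal(nrow(ont$terms), 3)  # obsolete excluded
  expect_equal(ont$n_obsolete, 1L)
  expect_equal(ont$is_a,
               data.frame(child = "D002", parent = "D003",
                          stringsAsFactors = FALSE))
  expect_equal(ont$synonyms[["D001"]], "hepatic cirrhosis")
  expect_equal(ont$xrefs[["D001"]], "ICD10:K74.6")
  expect_length(ont$cycles, 0)

  chain <- parse_ontology(write_obo(c(
    "[Term]", "id: A", "name: a", "is_a: B", "",
    "[Term]", "id: B", "name: b", "is_a: C", "",
    "[Term]", "id: C", "name: c")))
  expect_equal(nrow(chain$terms), 3)
  expect_equal(nrow(chain$is_a), 2)

  expect_error(parse_ontology(write_obo(c("[Term]", "name: orphan"))),
               "no id")
  expect_warning(
    cyc <- parse_ontology(write_obo(c(
      "[Term]", "id: X", "name: x", "is_a: Y", "",
      "[Term]", "id: Y", "name: y", "is_a: X"))),
    "cyclic")
  expect_setequal(cyc$cycles, c("X", "Y"))
})

test_that("mapping dictionaries are case-folded with documented precedence", {
  path <- write_obo(c(
    "[Term]", "id: D001", "name: Cirrhosis",
    "synonym: \"hepatic cirrhosis\" EXACT []", "xref: K74.6", "",
    "[Term]", "id: D002", "name: Fibrosis",
    "synonym: \"hepatic cirrhosis\" RELATED []"))
  ont <- parse_ontology(path)
  expect_warning(map <- build_mapping(ont), "collision")
  expect_equal(map_identifiers(map, "cirrhosis"), "D001")
  expect_equal(map_identifiers(map, "CIRRHOSIS"), "D001")
  expect_equal(map_identifiers(map, "k74.6"), "D001")
  # shared synonym resolves to the lexicographically smaller id, logged
  expect_equal(map_identifiers(map, "Hepatic Cirrhosis"), "D001")
  expect_equal(map$collisions$key, "hepatic cirrhosis")
  # unknown key -> NA sentinel
  expect_true(is.na(map_identifiers(map, "unknown thing")))

  # name beats a synonym pointing elsewhere (precedence, not collision)
  ont2 <- parse_ontology(write_obo(c(
    "[Term]", "id: T002", "name: alpha", "",
    "[Term]", "id: T001", "name: beta", "synonym: \"alpha\" EXACT []")))
  map2 <- build_mapping(ont2)
  expect_equal(map_identifiers(map2, "alpha"), "T002")
  expect_equal(nrow(map2$collisions), 0)
})

test_that("mapping construction is a pure function of the ontology file", {
  path <- write_obo(c(
    "[Term]", "id: B2", "name: two", "xref: X:2", "",
    "[Term]", "id: A1", "name: one", "synonym: \"uno\" EXACT []"))
  m1 <- build_mapping(parse_ontology(path))
  m2 <- build_mapping(parse_ontology(path))
  expect_identical(m1, m2)
})

test_that("identifier minting is deterministic, typed and hierarchical", {
  manifest <- data.frame(
    subject = c("pat1", "pat1", "pat2"),
    biological_sample = c("b1", "b2", "b3"),
    analytical_sample = c("a1", "a2", "a3"),
    group = c("case", "case", "control"),
    stringsAsFactors = FALSE)
  reg <- mint_identifiers(manifest, project = "LIVER")
  expect_equal(reg$subjects$internal, c("S001", "S002"))
  expect_equal(reg$biosamples$internal, c("BS001", "BS002", "BS003"))
  expect_equal(reg$asamples$internal, c("AS001", "AS002", "AS003"))
  expect_equal(reg$biosamples$subject_internal,
               c("S001", "S001", "S002"))
  # idempotent
  expect_identical(mint_identifiers(manifest, project = "LIVER"), reg)
  # one analytical sample under two biological samples is an error
  bad <- manifest
  bad$analytical_sample <- c("a1", "a1", "a3")
  expect_error(mint_identifiers(bad), "two biological samples")
})

test_that("experiment ingestion creates one quantification edge per cell", {
  kg <- generate_knowledge_graph(kg_spec(seed = 5))
  manifest <- data.frame(
    subject = c("p1", "p2"), biological_sample = c("b1", "b2"),
    analytical_sample = c("s1", "s2"), group = c("g1", "g2"),
    stringsAsFactors = FALSE)
  reg <- mint_identifiers(manifest)
  vals <- matrix(c(20, 21, NA, 23), nrow = 2,
                 dimnames = list(c("s1", "s2"), c("PROT001", "PROT002")))
  mat <- expr_matrix(vals, data.frame(id = c("s1", "s2"),
                                      group = c("g1", "g2"),
                                      stringsAsFactors = FALSE))
  g2 <- ingest_experiment(kg$graph, reg, mat)
  quant <- g2$edges[g2$edges$type == "HAS_QUANTIFIED_PROTEIN", ]
  expect_equal(nrow(quant), 3)  # one per non-missing cell
  expect_setequal(quant$value[quant$to == "PROT001"], c(20, 21))
  expect_true(validate_schema(g2)$conformant)

  # re-ingestion is an upsert: counts unchanged
  g3 <- ingest_experiment(g2, reg, mat)
  expect_equal(n_edges(g3), n_edges(g2))
  expect_equal(n_nodes(g3), n_nodes(g2))

  # unmapped features are reported, not fatal
  vals2 <- matrix(c(20, 21), nrow = 2,
                  dimnames = list(c("s1", "s2"), "NOT_A_PROTEIN"))
  mat2 <- expr_matrix(vals2, mat$samples)
  g4 <- ingest_experiment(kg$graph, reg, mat2)
  expect_equal(attr(g4, "ingest_report")$n_quantified_edges, 0)
  expect_equal(attr(g4, "ingest_report")$unmapped_features,
               "NOT_A_PROTEIN")

  # sample absent from the registry is an integrity error
  vals3 <- matrix(20, dimnames = list("ghost", "PROT001"))
  expect_error(
    ingest_experiment(kg$graph, reg,
                      expr_matrix(vals3,
                                  data.frame(id = "ghost", group = "g1"))),
    "absent from registry")
})
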