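test_that("correlation networks apply the signed coefficient and FDR rule", {
  set.seed(14)
  n <- 50
  x <- rnorm(n)
  e <- residuals(lm(rnorm(n) ~ x))        # orthogonal noise
  z_half <- 0.49 * as.numeric(scale(x)) +
    sqrt(1 - 0.49^2) * as.numeric(scale(e))  # cor(x, z_half) = 0.49
  v <- cbind(f1 = x, f2 = 2 * x, f3 = z_half, f4 = rnorm(n))
  m <- expr_matrix(v + 20)
  net <- correlation_network(m, "pearson", min_coefficient = 0.5,
                             fdr_max = 0.05)
  key <- paste(net$edges$from, net$edges$to)
  expect_true("f1 f2" %in% key)           # r = 1 survives any threshold
  expect_equal(net$edges$coefficient[key == "f1 f2"], 1)
  # a coefficient below 0.5 fails the "> 0.5" rule despite tiny p
  expect_false("f1 f3" %in% key)
  # isolated nodes are dropped
  expect_false("f4" %in% net$nodes$id)

  # anticorrelation is excluded under the signed rule, kept under absolute
  v2 <- cbind(a = x, b = -x, c = rnorm(n))
  m2 <- expr_matrix(v2 + 20)
  signed <- correlation_network(m2, "pearson")
  expect_equal(nrow(signed$edges), 0)
  absd <- correlation_network(m2, "pearson", absolute = TRUE)
  expect_equal(nrow(absd$edges), 1)
  expect_equal(absd$edges$coefficient, -1)

  # monotone nonlinear pair: rho = 1 under spearman, r < 1 under pearson
  v3 <- cbind(u = 1:20, w = exp(1:20 / 3), q = rnorm(20))
  m3 <- expr_matrix(v3)
  sp <- correlation_network(m3, "spearman")
  pe <- correlation_network(m3, "pearson")
  ksp <- paste(sp$edges$from, sp$edges$to)
  expect_equal(sp$edges$coefficient[ksp == "u w"], 1)
  expect_lt(pe$edges$coefficient[paste(pe$edges$from, pe$edges$to) ==
                                   "u w"], 1)

  # independent noise yields (almost) no edges at the defaults
  set.seed(15)
  noise <- expr_matrix(matrix(rnorm(50 * 20), 50, 20))
  expect_lte(nrow(correlation_network(noise)$edges), 1)

  cst <- expr_matrix(cbind(k = rep(5, 10), l = rnorm(10), o = rnorm(10)))
  expect_warning(correlation_network(cst), "constant")
  expect_error(correlation_network(expr_matrix(v[1:2, ])), "3 samples")
})

test_that("correlation edges are invariant to sample and feature order", {
  set.seed(16)
  v <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  v[, 2] <- v[, 1] + rnorm(30, 0, 0.1)
  v[, 4] <- v[, 3] + rnorm(30, 0, 0.1)
  net <- correlation_network(expr_matrix(v))
  canon <- function(nw) {
    e <- nw$edges
    key <- ifelse(e$from < e$to, paste(e$from, e$to), paste(e$to, e$from))
    sort(key)
  }
  net_perm <- correlation_network(
    expr_matrix(v[sample(30), c(3, 6, 1, 2, 5, 4)]))
  expect_equal(canon(net), canon(net_perm))
})

test_that("Louvain finds the exhaustively optimal two-triangle split", {
  edges <- data.frame(from = c("a", "a", "b", "d", "d", "e", "c"),
                      to = c("b", "c", "c", "e", "f", "f", "d"),
                      stringsAsFactors = FALSE)
  # oracle: maximize modularity over all 203 partitions of 6 nodes
  parts <- all_partitions(c("a", "b", "c", "d", "e", "f"))
  qs <- vapply(parts, function(p) modularity_q(edges, p), numeric(1))
  best <- parts[[which.max(qs)]]
  best <- unname(lapply(best, sort))
  cl <- louvain_communities(edges, seed = 1)
  ours <- canon_partition(cl$membership)
  expect_setequal(lapply(ours, paste, collapse = ","),
                  lapply(best, paste, collapse = ","))
  expect_equal(cl$modularity, max(qs), tolerance = 1e-10)
  expect_length(ours, 2)

  # complete graph: a single community
  k4 <- t(combn(c("w", "x", "y", "z"), 2))
  clk <- louvain_communities(data.frame(from = k4[, 1], to = k4[, 2]))
  expect_equal(length(unique(clk$membership)), 1)

  # edgeless graph: singleton communities with Q = 0
  cle <- louvain_communities(data.frame(from = character(),
                                        to = character()),
                             nodes = c("a", "b", "c"))
  expect_equal(length(unique(cle$membership)), 3)
  expect_equal(cle$modularity, 0)

  # returned partition is at least as modular as singletons
  single <- lapply(sort(unique(c(edges$from, edges$to))), identity)
  expect_gte(cl$modularity, modularity_q(edges, single))
})

test_that("project similarity matches the set-overlap definitions", {
  s <- project_similarity(c("a", "b"), c("b", "c"))
  expect_equal(s$jaccard, 1 / 3)
  expect_equal(s$overlap, 1 / 2)
  ident <- project_similarity(c("a", "b", "c"), c("a", "b", "c"),
                              profile_a = c(a = 1, b = 2, c = 3),
                              profile_b = c(a = 1, b = 2, c = 3))
  expect_equal(unlist(ident), c(jaccard = 1, overlap = 1, pearson = 1))
  dis <- project_similarity(c("a", "b"), c("c", "d"))
  expect_equal(dis$jaccard, 0)
  expect_equal(dis$overlap, 0)
  expect_true(is.na(dis$pearson))
  # symmetry
  s2 <- project_similarity(c("b", "c"), c("a", "b"))
  expect_equal(s, s2[names(s)])
  expect_error(project_similarity(character(0), character(0)), "empty")
})

test_that("betweenness matches brute-force enumeration on small graphs", {
  # path a-b-c: the middle node carries the single pair
  path <- property_graph(
    data.frame(id = c("a", "b", "c"), label = "Protein",
               stringsAsFactors = FALSE),
    data.frame(from = c("a", "b"), to = c("b", "c"),
               type = "CURATED_INTERACTS_WITH", stringsAsFactors = FALSE))
  bc <- graph_betweenness(path)
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))

  # star: the centre is maximal
  star <- property_graph(
    data.frame(id = c("hub", paste0("leaf", 1:4)), label = "Protein",
               stringsAsFactors = FALSE),
    data.frame(from = "hub", to = paste0("leaf", 1:4),
               type = "CURATED_INTERACTS_WITH", stringsAsFactors = FALSE))
  bs <- graph_betweenness(star)
  expect_equal(names(which.max(bs)), "hub")
  expect_equal(unname(bs["hub"]), choose(4, 2))

  # random graphs up to 8 nodes against the exhaustive oracle
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(3:8, 1)
    ids <- letters[1:n]
    pairs <- t(combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.45
    if (!any(keep)) next
    edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                        type = "CURATED_INTERACTS_WITH",
                        stringsAsFactors = FALSE)
    g <- property_graph(data.frame(id = ids, label = "Protein",
                                   stringsAsFactors = FALSE), edges)
    expect_equal(graph_betweenness(g)[ids],
                 brute_betweenness(ids, edges)[ids],
                 tolerance = 1e-10)
  }
})

test_that("top-k retention caps per label with id tie-breaks", {
  # 20 diseases on one protein: cap at 15 keeps exactly 15
  nodes <- rbind(
    data.frame(id = "p1", label = "Protein", stringsAsFactors = FALSE),
    data.frame(id = sprintf("d%02d", 1:20), label = "Disease",
               stringsAsFactors = FALSE))
  edges <- data.frame(from = "p1", to = sprintf("d%02d", 1:20),
                      type = "ASSOCIATED_WITH", stringsAsFactors = FALSE)
  g <- property_graph(nodes, edges)
  tk <- betweenness_topk(g, 15)
  expect_equal(sum(tk$label == "Disease"), 15)
  # all diseases tie at betweenness 0: lowest ids win
  expect_equal(sort(tk$id[tk$label == "Disease"]), sprintf("d%02d", 1:15))
  expect_error(betweenness_topk(g, 0), ">= 1")
})

test_that("knowledge summaries expand, prune and emit Sankey flows", {
  g <- toy_graph()
  ks <- build_knowledge_subgraph(g, "PROT001")
  # single protein with two disease links and one drug: 4-node summary
  expect_setequal(ks$subgraph$nodes$id,
                  c("PROT001", "DIS01", "DIS02", "DRUG01"))
  expect_equal(sum(ks$sankey$weight), 3)
  expect_true(all(c("source_label", "target_label") %in%
                    names(ks$sankey)))

  # k = 1 keeps exactly one node per non-protein label with candidates
  ks1 <- build_knowledge_subgraph(g, "PROT001", k_per_label = 1)
  expect_equal(sum(ks1$subgraph$nodes$label == "Disease"), 1)

  # a hub drug connecting most regulated proteins ranks first among drugs
  nodes <- rbind(
    data.frame(id = sprintf("p%d", 1:4), label = "Protein",
               stringsAsFactors = FALSE),
    data.frame(id = c("hub", "niche"), label = "Drug",
               stringsAsFactors = FALSE))
  edges <- data.frame(from = c("hub", "hub", "hub", "niche"),
                      to = c("p1", "p2", "p3", "p4"),
                      type = "ACTS_ON", stringsAsFactors = FALSE)
  gh <- property_graph(nodes, edges)
  ksh <- build_knowledge_subgraph(gh, sprintf("p%d", 1:4),
                                  labels = "Drug")
  drugs <- ksh$ranking[ksh$ranking$label == "Drug", ]
  expect_equal(drugs$id[drugs$rank == 1], "hub")

  # empty regulated set warns and returns an empty summary
  expect_warning(ks0 <- build_knowledge_subgraph(g, character(0)),
                 "empty")
  expect_equal(n_nodes(ks0$subgraph), 0)
})
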