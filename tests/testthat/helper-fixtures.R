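# hand-built fixture for the treatment-prioritization workflow:
# 5 upregulated proteins, 2 with disease links; an "ideal" drug that
# inhibits both disease-linked proteins with side effects disjoint from
# the regimen and a planted triplet publication; decoys that fail one
# requirement each.
prioritization_fixture <- function() {
  nodes <- rbind(
    data.frame(id = sprintf("up%d", 1:5), label = "Protein",
               stringsAsFactors = FALSE),
    data.frame(id = "other_prot", label = "Protein",
               stringsAsFactors = FALSE),
    data.frame(id = c("disease", "other_disease"), label = "Disease",
               stringsAsFactors = FALSE),
    data.frame(id = c("ideal", "overlap_se", "activator", "quiet",
                      "regA", "regB"),
               label = "Drug", stringsAsFactors = FALSE),
    data.frame(id = sprintf("se%d", 1:6), label = "Side_effect",
               stringsAsFactors = FALSE),
    data.frame(id = c("pub1", "pub2"), label = "Publication",
               stringsAsFactors = FALSE))
  edges <- rbind(
    # disease associations: up1, up2 linked; up3 linked elsewhere only
    data.frame(from = c("up1", "up2", "up3"),
               to = c("disease", "disease", "other_disease"),
               type = "ASSOCIATED_WITH", action = NA,
               stringsAsFactors = FALSE),
    # drug actions
    data.frame(from = c("ideal", "ideal", "overlap_se", "activator",
                        "quiet"),
               to = c("up1", "up2", "up1", "up1", "up2"),
               type = "ACTS_ON",
               action = c("inhibition", "inhibition", "inhibition",
                          "activation", "inhibition"),
               stringsAsFactors = FALSE),
    # side effects: regimen covers se1-se3; ideal/quiet are disjoint,
    # overlap_se shares two of three regimen effects
    data.frame(from = c("regA", "regA", "regB", "overlap_se",
                        "overlap_se", "ideal", "quiet"),
               to = c("se1", "se2", "se3", "se1", "se2", "se4", "se5"),
               type = "HAS_SIDE_EFFECT", action = NA,
               stringsAsFactors = FALSE),
    # publications: pub1 mentions (ideal, up1, disease); pub2 mentions
    # quiet and the disease but no target
    data.frame(from = c("ideal", "up1", "disease", "quiet", "disease"),
               to = c("pub1", "pub1", "pub1", "pub2", "pub2"),
               type = "MENTIONED_IN_PUBLICATION", action = NA,
               stringsAsFactors = FALSE))
  graph <- property_graph(nodes, edges, schema = default_schema(),
                          validate = TRUE)
  diff <- data.frame(feature = c(sprintf("up%d", 1:5), "other_prot"),
                     regulation = c(rep("up", 5), "ns"),
                     stringsAsFactors = FALSE)
  list(graph = graph, diff = diff)
}

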