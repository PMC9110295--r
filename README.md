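# proteokg

Clinical proteomics studies produce a quantified samples-by-proteins
matrix and a pile of questions that the matrix alone cannot answer:
which regulated proteins are already linked to the studied disease,
which drugs inhibit them, what the literature says about the three
together. `proteokg` is an R toolkit for exactly this gap. It combines

* an **embedded property-graph store** — typed nodes and directed,
  typed edges with attributes, validated against a clinical-omics data
  model of 36 node labels and 47 relationship types (proteins, diseases,
  drugs, side effects, pathways, publications, the
  project/subject/sample hierarchy, ...), with lossless TSV/JSON and
  Cytoscape-compatible GML/GraphML import/export; and
* an **automated analysis pipeline** that turns the matrix into a
  statistics report and a prior-knowledge summary subgraph.

The pipeline stages, with their defaults:

1. **Preparation** — log2 transform; drop proteins missing in >50% of
   samples; median centring; imputation by MinProb (left-censored draws
   at each sample's 1% quantile, for values missing not at random), KNN
   (k = 5, for values missing completely at random) or the mixed rule
   (KNN below 50% missingness per feature, MinProb at or above).
2. **Statistics** — design-aware testing (pooled/paired t, ANOVA,
   repeated-measures ANOVA selected from the group/subject structure),
   SAM statistic d = Δmean/(SE + s0), Benjamini–Hochberg FDR (default)
   or permutation-based FDR (250 permutations, with a BH fallback when
   too few distinct label assignments exist); regulation flags at
   fold change > 2 and FDR < 0.05; Fisher-exact enrichment;
   Kaplan–Meier curves with a log-rank test on a top-25% expression
   split.
3. **Networks** — correlation networks (edge iff coefficient > 0.5 and
   FDR < 0.05; Pearson within proteins, Spearman across the
   clinical–protein split) with Louvain communities; project similarity
   (Jaccard, overlap, profile Pearson).
4. **Knowledge summary** — one-hop expansion of the regulated proteins
   into the graph, pruned to the top-15 nodes per label by exact
   betweenness centrality, emitted as a Sankey-ready flow table.
5. **Drug prioritization** — disease-linked upregulated proteins →
   inhibitory drugs → side-effect Jaccard dissimilarity < 0.2 against
   the reference regimen → ranking by (drug, target, disease)
   literature co-mentions.

Seeded generators (`kg_spec()`, `sim_spec()`) produce a miniature
schema-conformant knowledge graph and simulated multi-group LFQ
experiments with planted effects, MNAR+MCAR missingness and survival
times, so the whole pipeline runs and is tested fully offline.

## Worked example

```r
library(proteokg)

dir <- tempfile("demo")
write_project_fixture(dir, seed = 42)   # graph + manifest + matrices
rep <- run_default_pipeline(dir, seed = 42)
rep
#> <ckg_report> tabs: proteomics, clinical, multiomics, knowledge

dr <- rep$tabs$proteomics$differential_regulation
sum(dr$regulation != "ns")
#> [1] 18
head(dr[order(dr$padj), c("feature", "log2fc", "statistic", "padj",
                          "regulation")], 3)
#>     feature    log2fc statistic         padj regulation
#> 155 PROT160 -3.534007 -41.87833 4.102377e-17       down
#> 13  PROT013 -2.980213 -26.47240 6.703576e-14       down
#> 123 PROT127 -2.592351 -25.91906 6.703576e-14       down

head(rep$tabs$knowledge$sankey, 4)
#>   source_label target_label weight
#> 1         Drug      Protein      9
#> 2         Drug  Publication      4
#> 3      Protein      Disease      2
#> 4      Protein      Pathway     10

serialize_report(rep, file.path(dir, "report"))
```

The differential table lists, per feature and contrast, the group
means, log2 fold change, test statistic, raw and BH-adjusted p, and the
`up`/`down`/`ns` flag (here 18 of 191 retained features pass
fold change > 2 at FDR < 0.05; the simulation planted effects on 10% of
200). The Sankey table summarizes how the regulated proteins connect to
prior knowledge — e.g. 10 pathway annotations and 9 inhibiting/activating
drug actions among the retained top-central nodes. `serialize_report()`
writes one folder per tab (TSV tables, JSON plot payloads, GML/JSON
networks) plus a single `report.json` archive that `load_report()`
restores losslessly.

A thin command-line wrapper ships in `inst/cli/proteokg`
(`simulate`, `validate`, `build-graph`, `ingest`, `analyze`,
`prioritize`, `report` subcommands over the same functions).

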