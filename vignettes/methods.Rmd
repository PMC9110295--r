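---
title: "Methods: from quantified proteomes to knowledge summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from quantified proteomes to knowledge summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteokg)
```

`proteokg` couples an embedded property-graph store for clinical
proteomics knowledge with an automated analysis pipeline: a quantified
samples-by-proteins matrix goes in, and a statistics report plus a
prior-knowledge summary subgraph come out. This vignette explains the
models and procedures behind each stage, the parameters that matter, the
numerical choices, and the limits of what the synthetic test data can
certify.

## The graph substrate

Knowledge lives in a typed property graph: nodes carry a globally unique
string identifier, a label (`Protein`, `Disease`, `Drug`, ...) and
arbitrary attributes; directed edges carry a relationship type
(`ASSOCIATED_WITH`, `ACTS_ON`, `HAS_QUANTIFIED_PROTEIN`, ...) and
attributes such as association scores or quantification values. A schema
constrains which labels exist and which (type, source label, target
label) triples are permitted; the bundled data model
(`default_schema()`) has 36 node labels and 47 relationship types
covering molecular entities, ontology-backed annotation classes, the
experimental hierarchy (project, subject, biological sample, analytical
sample) and drugs with their side effects. Schema validation is report-only
on load (permissive exploration) and mandatory inside the pipeline
(strict automation).

Identifiers are namespaced strings taken verbatim from their sources;
project-internal entities get minted, zero-padded identifiers (`S001`,
`BS001`, `AS001`) in manifest order, so re-running ingestion is
idempotent. Redundant edges from overlapping sources collapse to one per
(source, target, type), keeping the maximum numeric `score` — integrating
databases that report the same relationship should strengthen, not
duplicate, it. Graphs round-trip losslessly through a tab-separated
bulk-import dialect (backslash escaping for tabs and newlines; numeric
attributes to 15 significant digits) and JSON; GML and GraphML writers
serve Cytoscape, with GML attribute names reduced to alphanumeric
characters as that format requires.

Ontology files in OBO-like stanzas provide annotation vocabularies.
Mapping dictionaries are built from term names, synonyms and external
references, case-folded, with precedence name > synonym > xref and
lexicographically-smallest-id tie-breaks (collisions are logged). Exact
lookup only: determinism is worth more than recall here.

## Data preparation

Intensities are log2-transformed on load (zeros and non-finite values
become missing). Preparation is a fixed sequence — filter, normalize,
impute — recorded in every report.

**Filtering.** The default removes proteins missing in more than 50% of
samples (`max_missing`, threshold 0.5); minimum-observations-per-group
and minimum-total modes are available. The 0.5 default is deliberate: in
a two-group design it retains "on/off" proteins fully quantified in one
condition and absent in the other — exactly the proteins that
left-censored imputation is designed to rescue. A stricter fraction
(e.g. 0.3) silently discards them.

**Normalization.** Median centring per sample is the default (all sample
medians become 0); quantile normalization (via `limma`) and identity are
alternatives. The choice is recorded in the report provenance.

**Imputation.** Proteomics missingness mixes two mechanisms: cells
missing completely at random (MCAR) and low-abundance cells censored at
the detection limit (missing not at random, MNAR). Three strategies are
implemented:

* `minprob` (default): each missing cell is drawn from a Gaussian
  centred at the q = 0.01 quantile of its sample's observed values with
  s.d. = 0.3 x the sample s.d. This is the standard left-censored
  ("probabilistic minimum") convention; both q and the width multiplier
  are exposed. Draws are seeded and allocated one-per-cell, so a cell's
  imputed value never depends on which other cells are being imputed.
* `knn`: a missing cell takes the unweighted mean of the k = 5 nearest
  samples (Euclidean distance over mutually observed features) that
  observed the feature. Appropriate when missingness is MCAR.
* `mixed`: per feature, KNN when the missing fraction is strictly below
  50%, MinProb at or above it. The comparison is strict at the bound.

Observed values are never altered by imputation, and the complete
("processed") matrix is the basis for everything downstream.

## Statistics

**Exploration.** Feature counts per group, a dynamic-range ranking by
mean linear intensity, and coefficients of variation
(CV% = 100 * sd/mean on the linear scale) as a quality metric.

**Differential regulation.** The test is selected from the design:
pooled-variance t-test for two independent groups (Welch optional;
pooled is the default because it matches the SAM denominator), paired
t-test when every subject appears in both groups, one-way ANOVA with
pairwise post hoc t-tests for more than two groups, and randomized-block
(repeated-measures) ANOVA when subjects recur across all conditions —
unbalanced repeated designs are rejected rather than approximated.
Multiple testing is controlled by Benjamini-Hochberg FDR by default.
Permutation-based FDR is available for two independent groups: labels
are permuted (250 permutations by default), and the FDR at each observed
|statistic| cutoff is the mean number of null exceedances over the
observed exceedances, clipped to [0, 1] and made monotone in the cutoff.
When fewer distinct label assignments exist than permutations requested
the estimate would be unstable, so the function warns and falls back to
BH — the operational reading of "only if the number of permutations is
sufficiently large".

Features are flagged `up` when the linear fold change exceeds 2
(|log2 fold change| > 1, computed on group means of log2 values) and the
adjusted p is below 0.05; `down` symmetrically. Both bounds are strict
and configurable. The SAM moderated statistic
d = (mean difference)/(pooled SE + s0) is provided with an explicit,
user-supplied s0 (no automatic s0 selection is implemented; at s0 = 0 it
is the pooled t).

**Enrichment.** One two-sided Fisher exact test per annotation term on
the 2x2 hit-by-term table within the tested universe, BH across terms.

**Survival.** Samples are split at the 75th percentile of a marker's
expression into high (top 25%) and low groups; Kaplan-Meier curves and a
two-sided log-rank test compare them. Ties at the threshold go to the
low group (the split quantile is exposed). With zero events the test is
undefined and reported as a sentinel rather than an error.

## Networks and knowledge summarization

**Correlation networks.** All pairwise Pearson correlations (within the
protein block) or Spearman correlations (across the clinical-protein
bipartite split) are computed on the complete matrix, p-values from the
large-sample t approximation on the coefficient, BH across all tested
pairs. An edge is kept when the signed coefficient exceeds 0.5 and the
adjusted p is below 0.05. Applying the rule to the signed coefficient is
the literal reading of the association rule; an absolute-value mode is
exposed for anticorrelations. Constant features have no defined
coefficient and are excluded with a warning. Louvain community detection
(resolution 1, seeded, vertices in sorted-id order for determinism)
colours the result; an edgeless graph is defined to have singleton
communities and modularity 0.

**Project similarity.** Jaccard and overlap coefficients on identified
protein sets, Pearson correlation on mean profiles over shared proteins
(sentinel when fewer than 3 are shared).

**Knowledge summary.** Regulated proteins are expanded one hop into the
knowledge graph towards diseases, drugs, pathways, biological processes,
publications, complexes, and kinases reached through substrate edges.
Betweenness centrality — exact shortest-path counts on the undirected
simple view, unit weights, endpoints excluded — prioritizes what to
keep: per label, the top 15 nodes (ties broken by id), with the
regulated proteins always retained. Pruning happens after the full
expansion, so a node's centrality reflects every connection it made, not
only those that survive. The summary carries a Sankey-ready
(source label, target label, weight) flow table.

**Drug prioritization.** Four steps: (1) upregulated proteins with a
known association to the studied disease; (2) drugs connected to them by
inhibition-typed actions (`inhibition`, `antagonist`, `blocker` —
activators never qualify); (3) a side-effect dissimilarity filter — the
Jaccard index between each candidate's side-effect set and the union of
the reference regimen's side effects must be strictly below 0.2
(per-drug maximum comparison is exposed as an option; the union is the
default reading of "side effects associated with the regimens used");
(4) ranking by literature support: per (drug, target, disease) triplet,
the number of publications mentioning all three, a candidate scoring the
maximum over its targets. Final order: co-mention count descending, then
Jaccard ascending, then drug id — a fixed, documented tie-break chain.

## The synthetic study conditions

Every stage is testable offline against seeded generators; their
defaults define the simulated study.

The toy knowledge graph (`kg_spec()`) plants ~110 nodes (44 proteins of
which 4 kinases, 6 diseases, 12 drugs, 15 side effects, 8 pathways, 25
publications) with Bernoulli edges at densities 0.05-0.2 and records
every planted association as ground truth. Generators draw from one
named, seeded stream per stage, so adding a stage never shifts the draws
of another; identical specs produce byte-identical output.

The proteomics simulator (`sim_spec()`) emulates a label-free
quantification (LFQ) cohort: per-feature base log2 intensities
N(25, 3), residual s.d. uniform on [0.2, 0.8], two groups of 10 samples,
200 features, 10% of them shifted by a uniform |log2 effect| in [1, 4]
with random sign. Missingness is MNAR-dominated: a logistic
detection-limit curve in the true log2 intensity, anchored at the 5%
quantile of all cells with slope 3 per log2 unit (a transition width
under one log2 unit, as empirical dropout curves show), plus 0.5% MCAR
cells — about 7% missing overall, >90% of it intensity-dependent. This
is the regime in which a MinProb default is the appropriate imputation;
simulating MCAR-heavy data and then left-censor-imputing it would
mostly measure that mismatch. Survival times are exponential with
hazard scaled by the marker's expression (ratio per s.d.), with
exponential censoring.

What passing tests show — and what they do not: the calibration suite
demonstrates type-I control (null simulations flag well under 5% of
features) and recovery of at least 90% of planted effects with
|log2FC| >= 2 at n = 10/group *among features still quantifiable after
filtering*. Features simulated below the detection limit in most
samples are untestable by any method; end-to-end recovery including
them is also reported (about 90% under the defaults) so the cost of the
detection limit is visible rather than hidden. The simulator does not
model peptide-level structure, batch effects, retention-time artefacts
or correlated biological modules, so the tests certify the statistical
machinery, not performance on any particular real cohort.

## Pipeline, report and formats

`run_default_pipeline()` is a pure function of (input files,
configuration, seed). The YAML configuration names ordered sections
(prep, stats, networks, multiomics, survival, knowledge) with their
parameters; it is validated against the operation registry before
anything runs, and the exact snapshot is embedded in the report
provenance. Tabs: proteomics always; clinical when clinical data are
present; multiomics (the clinical-protein Spearman network) only when
both data types are analysed together; knowledge when a graph is
available. Problem sizes in the shipped fixtures (20 samples x 200
features, ~110-node graph) run the whole pipeline in seconds.

Reports serialize to one folder per tab — every table as TSV, plot
payloads (volcano, Sankey) additionally as JSON, networks as GML and
JSON — plus a single hierarchical archive `report.json` (one object per
tab, one record-set per table, provenance alongside) that
`load_report()` restores losslessly. The archive is deliberately a
single hierarchical text file: it is diff-friendly, and byte-identical
across reruns with the same seed, which the determinism tests assert.

## Known limitations

* The graph store is in-memory and single-writer; there is no
  transactionality or query language, and millions-of-nodes scale is out
  of scope (betweenness is exact, not approximate).
* Co-expression module analysis (WGCNA-style), nonlinear embeddings
  (t-SNE/UMAP), graph representation learning and similarity network
  fusion are intentionally not implemented; PCA is the in-package
  dimensionality reduction.
* Mapping is exact-match after case folding — no fuzzy matching — so
  recall depends entirely on the ontology's synonym coverage.
* The repeated-measures path requires complete, balanced blocks.
* Clinical variables are analysed as a quantitative matrix; ontology
  conformance of clinical codes is accepted verbatim, not verified.
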