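#' Specification for a miniature knowledge graph
#'
#' Counts per node label, association densities per relationship type and
#' score-distribution parameters for [generate_knowledge_graph()]. The
#' defaults give a toy-scale graph (well under the 10,000-node cap) with
#' enough connectivity that every pipeline stage has work to do.
#'
#' @param n_proteins,n_diseases,n_drugs,n_side_effects,n_pathways,n_publications,n_kinases
#'   node counts (kinases are additional Protein nodes flagged
#'   `kinase = TRUE`).
#' @param density_protein_disease,density_drug_protein,density_drug_side_effect,density_protein_pathway,density_mention,density_kinase_substrate
#'   Bernoulli edge probabilities per candidate pair, each in \[0, 1\].
#' @param p_inhibition probability that a drug-protein action is
#'   `inhibition` (otherwise `activation`).
#' @param seed integer seed; the same spec yields byte-identical output.
#' @return List of class `kg_spec`.
#' @export
kg_spec <- function(n_proteins = 40L, n_diseases = 6L, n_drugs = 12L,
                    n_side_effects = 15L, n_pathways = 8L,
                    n_publications = 25L, n_kinases = 4L,
                    density_protein_disease = 0.15,
                    density_drug_protein = 0.15,
                    density_drug_side_effect = 0.2,
                    density_protein_pathway = 0.2,
                    density_mention = 0.05,
                    density_kinase_substrate = 0.1,
                    p_inhibition = 0.7, seed = 1L) {
  counts <- c(n_proteins, n_diseases, n_drugs, n_side_effects, n_pathways,
              n_publications, n_kinases)
  dens <- c(density_protein_disease, density_drug_protein,
            density_drug_side_effect, density_protein_pathway,
            density_mention, density_kinase_substrate, p_inhibition)
  stopifnot(all(counts >= 0), all(dens >= 0), all(dens <= 1))
  if (sum(counts) > 10000) {
    stop("node counts exceed the 10,000-node cap", call. = FALSE)
  }
  structure(as.list(environment()), class = "kg_spec")
}

# deterministic per-stage sub-seed so adding a stage never shifts
# existing draws
stage_seed <- function(seed, stage) {
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 1013904223
  as.integer((as.numeric(seed) * 2654435 + h) %% (2^31 - 1))
}

bernoulli_pairs <- function(from_ids, to_ids, density, seed, stage) {
  if (!length(from_ids) || !length(to_ids) || density == 0) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(from = from_ids, to = to_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$from, grid$to), ]
  keep <- withr_seed(stage_seed(seed, stage),
                     stats::runif(nrow(grid)) < density)
  out <- grid[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a miniature schema-conformant knowledge graph
#'
#' Seeded generator for a toy knowledge graph with Protein, Disease, Drug,
#' Side_effect, Pathway and Publication nodes, scored protein-disease
#' associations, drug actions (inhibition/activation), drug side effects,
#' pathway annotations, publication mention edges and kinase-substrate
#' edges. The output passes [validate_schema()] against
#' [default_schema()] with an empty report, and the planted associations
#' are returned as ground-truth tables.
#'
#' @param spec a [kg_spec()].
#' @return List with `graph` (a [property_graph()]) and `truth` (named
#'   list of the planted edge tables).
#' @export
generate_knowledge_graph <- function(spec = kg_spec()) {
  stopifnot(inherits(spec, "kg_spec"))
  prot <- sprintf("PROT%03d", seq_len(spec$n_proteins + spec$n_kinases))
  kin <- utils::tail(prot, spec$n_kinases)
  dis <- sprintf("DIS%02d", seq_len(spec$n_diseases))
  drug <- sprintf("DRUG%02d", seq_len(spec$n_drugs))
  se <- sprintf("SE%02d", seq_len(spec$n_side_effects))
  path <- sprintf("PATH%02d", seq_len(spec$n_pathways))
  pub <- sprintf("PUB%03d", seq_len(spec$n_publications))
  nodes <- rbind(
    data.frame(id = prot, label = "Protein",
               name = prot, kinase = prot %in% kin,
               stringsAsFactors = FALSE),
    data.frame(id = dis, label = "Disease", name = dis, kinase = NA,
               stringsAsFactors = FALSE),
    data.frame(id = drug, label = "Drug", name = drug, kinase = NA,
               stringsAsFactors = FALSE),
    data.frame(id = se, label = "Side_effect", name = se, kinase = NA,
               stringsAsFactors = FALSE),
    data.frame(id = path, label = "Pathway", name = path, kinase = NA,
               stringsAsFactors = FALSE),
    data.frame(id = pub, label = "Publication", name = pub, kinase = NA,
               stringsAsFactors = FALSE))

  pd <- bernoulli_pairs(prot, dis, spec$density_protein_disease,
                        spec$seed, "protein_disease")
  if (nrow(pd)) {
    pd$score <- withr_seed(stage_seed(spec$seed, "protein_disease_score"),
                           round(stats::runif(nrow(pd)), 3))
  } else pd$score <- numeric(0)
  dp <- bernoulli_pairs(drug, setdiff(prot, character(0)),
                        spec$density_drug_protein, spec$seed,
                        "drug_protein")
  if (nrow(dp)) {
    dp$action <- withr_seed(
      stage_seed(spec$seed, "drug_action"),
      ifelse(stats::runif(nrow(dp)) < spec$p_inhibition,
             "inhibition", "activation"))
  } else dp$action <- character(0)
  ds <- bernoulli_pairs(drug, se, spec$density_drug_side_effect,
                        spec$seed, "drug_side_effect")
  pp <- bernoulli_pairs(prot, path, spec$density_protein_pathway,
                        spec$seed, "protein_pathway")
  ks <- bernoulli_pairs(setdiff(prot, kin), kin,
                        spec$density_kinase_substrate,
                        spec$seed, "kinase_substrate")
  mention_from <- c(prot, drug, dis)
  mn <- bernoulli_pairs(mention_from, pub, spec$density_mention,
                        spec$seed, "mentions")

  typed <- function(df, type) {
    if (!nrow(df)) {
      return(data.frame(from = character(), to = character(),
                        type = character(), stringsAsFactors = FALSE))
    }
    df$type <- type
    df
  }
  edges <- rbind_fill(
    rbind_fill(typed(pd, "ASSOCIATED_WITH"), typed(dp, "ACTS_ON")),
    rbind_fill(
      rbind_fill(typed(ds, "HAS_SIDE_EFFECT"),
                 typed(pp, "ANNOTATED_IN_PATHWAY")),
      rbind_fill(typed(ks, "IS_SUBSTRATE_OF"),
                 typed(mn, "MENTIONED_IN_PUBLICATION"))))
  g <- property_graph(nodes, edges, schema = default_schema(),
                      validate = TRUE)
  list(graph = g,
       truth = list(protein_disease = pd, drug_protein = dp,
                    drug_side_effect = ds, protein_pathway = pp,
                    kinase_substrate = ks, mentions = mn))
}

#' Specification for a simulated proteomics experiment
#'
#' Emulates the statistical structure the analysis pipeline assumes:
#' log-normal base intensities (normal on the log2 scale), planted group
#' shifts on a regulated fraction of features, and a mixture of
#' missing-completely-at-random cells and intensity-dependent
#' missing-not-at-random cells (low-abundance proteins drop out
#' preferentially, with logistic probability in the true log2 intensity).
#'
#' @param n_groups number of groups (default 2).
#' @param n_samples_per_group samples per group (>= 2; default 10).
#' @param n_features number of features (default 200).
#' @param fraction_regulated fraction of features with a planted group
#'   shift (default 0.1).
#' @param effect_range range of the absolute planted log2 effect,
#'   uniform with a random sign (default c(1, 4)).
#' @param feature_mean_mu,feature_mean_sd distribution of per-feature
#'   base log2 intensity (defaults 25 and 3, typical of LFQ).
#' @param feature_sd_range per-feature residual s.d. range (default
#'   c(0.2, 0.8) log2 units).
#' @param mcar_fraction probability that any cell is missing completely
#'   at random (default 0.005; a small share of all missing values, as
#'   reported for label-free data).
#' @param mnar_fraction quantile of the true intensity distribution at
#'   which the detection-limit dropout curve is anchored (default 0.05;
#'   dropout is missing-not-at-random and dominates the missingness).
#' @param mnar_slope logistic slope of the dropout probability per log2
#'   unit below the anchor (default 3, a transition width under one log2
#'   unit).
#' @param baseline_rate,hazard_ratio,censor_rate survival parameters:
#'   exponential event rate at average marker expression, hazard ratio
#'   per standard deviation of marker expression and exponential
#'   censoring rate.
#' @param seed integer seed.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(n_groups = 2L, n_samples_per_group = 10L,
                     n_features = 200L, fraction_regulated = 0.1,
                     effect_range = c(1, 4),
                     feature_mean_mu = 25, feature_mean_sd = 3,
                     feature_sd_range = c(0.2, 0.8),
                     mcar_fraction = 0.005, mnar_fraction = 0.05,
                     mnar_slope = 3,
                     baseline_rate = 0.1, hazard_ratio = 2,
                     censor_rate = 0.05, seed = 1L) {
  stopifnot(n_groups >= 1, n_samples_per_group >= 2, n_features >= 1,
            fraction_regulated >= 0, fraction_regulated <= 1,
            mcar_fraction >= 0, mcar_fraction <= 1,
            mnar_fraction >= 0, mnar_fraction <= 1,
            length(effect_range) == 2, effect_range[1] <= effect_range[2])
  structure(as.list(environment()), class = "sim_spec")
}

#' Simulate a multi-group proteomics experiment
#'
#' @param spec a [sim_spec()].
#' @return List with `matrix` (an [expr_matrix()] of log2 intensities,
#'   missing cells `NA`), `true_values` (the complete matrix before
#'   missingness) and `truth` (data.frame `feature`, `regulated`,
#'   `effect` in log2 units; the shift is applied to every non-reference
#'   group).
#' @export
simulate_proteomics <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n_groups * spec$n_samples_per_group
  p <- spec$n_features
  feats <- sprintf("PROT%03d", seq_len(p))
  groups <- rep(sprintf("group%d", seq_len(spec$n_groups)),
                each = spec$n_samples_per_group)
  samples <- data.frame(id = sprintf("sample%02d", seq_len(n)),
                        group = groups, stringsAsFactors = FALSE)

  base <- withr_seed(stage_seed(spec$seed, "feature_means"),
                     stats::rnorm(p, spec$feature_mean_mu,
                                  spec$feature_mean_sd))
  sds <- withr_seed(stage_seed(spec$seed, "feature_sds"),
                    stats::runif(p, spec$feature_sd_range[1],
                                 spec$feature_sd_range[2]))
  n_reg <- round(spec$fraction_regulated * p)
  reg_idx <- withr_seed(stage_seed(spec$seed, "regulated_set"),
                        sort(sample.int(p, n_reg)))
  effects <- numeric(p)
  if (n_reg > 0) {
    effects[reg_idx] <- withr_seed(
      stage_seed(spec$seed, "effect_sizes"),
      stats::runif(n_reg, spec$effect_range[1], spec$effect_range[2]) *
        sample(c(-1, 1), n_reg, replace = TRUE))
  }
  noise <- withr_seed(stage_seed(spec$seed, "noise"),
                      matrix(stats::rnorm(n * p), n, p))
  true <- sweep(noise, 2, sds, "*")
  true <- sweep(true, 2, base, "+")
  shift <- outer(as.numeric(groups != groups[1]), effects)
  true <- true + shift
  dimnames(true) <- list(samples$id, feats)

  # missingness: MCAR uniform + MNAR logistic in the true intensity
  mcar <- withr_seed(stage_seed(spec$seed, "mcar"),
                     matrix(stats::runif(n * p) < spec$mcar_fraction, n, p))
  # detection-limit dropout: logistic probability in the true log2
  # intensity, anchored at the mnar_fraction quantile of all cells
  loc <- stats::quantile(true, spec$mnar_fraction, names = FALSE)
  pmnar <- stats::plogis(spec$mnar_slope * (loc - true))
  mnar <- withr_seed(stage_seed(spec$seed, "mnar"),
                     matrix(stats::runif(n * p), n, p) < pmnar)
  vals <- true
  vals[mcar | mnar] <- NA
  # keep every sample analysable
  for (s in which(rowSums(!is.na(vals)) == 0)) vals[s, 1] <- true[s, 1]

  list(matrix = expr_matrix(vals, samples,
                            data.frame(id = feats, type = "protein",
                                       stringsAsFactors = FALSE)),
       true_values = true,
       truth = data.frame(feature = feats,
                          regulated = seq_len(p) %in% reg_idx,
                          effect = effects, stringsAsFactors = FALSE))
}

#' Simulate survival times driven by a marker
#'
#' Exponential event times with hazard scaled by the marker's expression
#' (hazard ratio per standard deviation), with exponential censoring.
#'
#' @param spec a [sim_spec()] (uses `baseline_rate`, `hazard_ratio`,
#'   `censor_rate`, `seed`).
#' @param expression an [expr_matrix()].
#' @param marker feature id used as the prognostic marker.
#' @return data.frame with `sample`, `time`, `event` (1 = event,
#'   0 = censored) and `marker_value`.
#' @export
simulate_clinical_survival <- function(spec, expression, marker) {
  stopifnot(inherits(spec, "sim_spec"), inherits(expression, "expr_matrix"))
  if (!marker %in% expression$features$id) {
    stop("unknown marker feature: ", marker, call. = FALSE)
  }
  x <- expression$values[, marker]
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  z <- if (stats::sd(x) == 0) rep(0, length(x)) else
    (x - mean(x)) / stats::sd(x)
  rate <- spec$baseline_rate * spec$hazard_ratio^z
  n <- length(x)
  ev <- withr_seed(stage_seed(spec$seed, "event_times"),
                   stats::rexp(n, rate))
  cs <- if (spec$censor_rate > 0) {
    withr_seed(stage_seed(spec$seed, "censor_times"),
               stats::rexp(n, spec$censor_rate))
  } else rep(Inf, n)
  data.frame(sample = expression$samples$id,
             time = pmin(ev, cs), event = as.integer(ev <= cs),
             marker_value = unname(x), stringsAsFactors = FALSE)
}

#' Write a complete toy project fixture to disk
#'
#' Materializes a seeded knowledge graph (nodes/edges TSV), a manifest, a
#' wide proteomics table (linear intensities, so loaders re-apply the log2
#' transform), a quantitative clinical table and a survival table, ready
#' for [run_default_pipeline()].
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed driving both generators.
#' @param kgspec,simspec optional [kg_spec()] / [sim_spec()]; by default
#'   both use `seed`.
#' @return Invisibly, the list of written paths.
#' @export
write_project_fixture <- function(dir, seed = 1L,
                                  kgspec = kg_spec(seed = seed),
                                  simspec = sim_spec(seed = seed)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kg <- generate_knowledge_graph(kgspec)
  sim <- simulate_proteomics(simspec)
  export_graph(kg$graph, file.path(dir, "graph"), "tsv")

  sm <- sim$matrix$samples
  manifest <- data.frame(subject = sub("sample", "subj", sm$id),
                         biological_sample = sub("sample", "bio", sm$id),
                         analytical_sample = sm$id,
                         group = sm$group, stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  lin <- 2^sim$matrix$values
  wide <- data.frame(sample = sm$id, group = sm$group,
                     check.names = FALSE, stringsAsFactors = FALSE)
  wide <- cbind(wide, as.data.frame(lin, check.names = FALSE))
  utils::write.table(wide, file.path(dir, "proteomics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # quantitative clinical variables: linear combinations of two proteins
  # plus noise, so the clinical-protein correlation network is non-trivial
  compl <- impute_matrix(sim$matrix,
                         imputation_config(seed = simspec$seed))
  v <- compl$values
  noise <- withr_seed(stage_seed(simspec$seed, "clinical_noise"),
                      matrix(stats::rnorm(nrow(v) * 3, 0, 0.5), nrow(v), 3))
  clin <- data.frame(sample = sm$id, group = sm$group,
                     cv_alt = as.numeric(scale(v[, 1])) + noise[, 1],
                     cv_ast = as.numeric(scale(v[, 2])) + noise[, 2],
                     cv_crp = as.numeric(scale(v[, min(3, ncol(v))])) +
                       noise[, 3],
                     stringsAsFactors = FALSE)
  utils::write.table(clin, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  surv <- simulate_clinical_survival(simspec, compl,
                                     compl$features$id[1])
  utils::write.table(surv, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, c("graph_nodes.tsv", "graph_edges.tsv",
                             "manifest.tsv", "proteomics.tsv",
                             "clinical.tsv", "survival.tsv")))
}
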