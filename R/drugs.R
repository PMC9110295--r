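#' Upregulated proteins with a known disease association
#'
#' First step of the treatment-prioritization workflow: among the proteins
#' flagged `up` in a differential analysis, keep those connected to the
#' studied disease by an association edge (`ASSOCIATED_WITH`,
#' `IS_BIOMARKER_OF_DISEASE` or `DETECTED_IN_PATHOLOGY_SAMPLE`).
#'
#' @param graph a [property_graph()].
#' @param diff a [differential_regulation()] result (or any data.frame
#'   with `feature` and `regulation` columns).
#' @param disease disease node id (must exist).
#' @param association_types edge types counted as disease association.
#' @return List with `proteins` (character vector), `n_up` (total
#'   up-flagged) and `n_linked`.
#' @export
disease_linked_upregulated <- function(graph, diff, disease,
                                       association_types =
                                         c("ASSOCIATED_WITH",
                                           "IS_BIOMARKER_OF_DISEASE",
                                           "DETECTED_IN_PATHOLOGY_SAMPLE")) {
  stopifnot(inherits(graph, "property_graph"))
  if (!disease %in% graph$nodes$id) {
    stop("unknown disease id: ", disease, call. = FALSE)
  }
  up <- unique(diff$feature[diff$regulation == "up"])
  e <- graph$edges[graph$edges$type %in% association_types, , drop = FALSE]
  linked <- unique(c(e$from[e$to == disease], e$to[e$from == disease]))
  hits <- sort(intersect(up, linked))
  list(proteins = hits, n_up = length(up), n_linked = length(hits))
}

#' Inhibitory drugs for a protein set
#'
#' Drugs connected to at least one input protein by an action edge whose
#' `action` attribute denotes inhibition (`inhibition`, `antagonist` or
#' `blocker`); activators and unannotated actions are excluded.
#'
#' @param graph a [property_graph()].
#' @param proteins character vector of protein node ids.
#' @param action_types edge types carrying drug-target actions.
#' @param inhibitory_actions accepted values of the `action` attribute.
#' @return Named list mapping drug id to the character vector of input
#'   proteins it inhibits (its targets hit).
#' @export
inhibitors_for <- function(graph, proteins,
                           action_types = "ACTS_ON",
                           inhibitory_actions = c("inhibition",
                                                  "antagonist",
                                                  "blocker")) {
  stopifnot(inherits(graph, "property_graph"))
  if (!length(proteins)) return(stats::setNames(list(), character(0)))
  e <- graph$edges[graph$edges$type %in% action_types, , drop = FALSE]
  if (!"action" %in% names(e)) return(stats::setNames(list(), character(0)))
  e <- e[!is.na(e$action) & e$action %in% inhibitory_actions &
           e$to %in% proteins, , drop = FALSE]
  if (!nrow(e)) return(stats::setNames(list(), character(0)))
  sp <- split(e$to, e$from)
  lapply(sp[sort(names(sp))], function(x) sort(unique(x)))
}

#' Side-effect sets of drugs
#' @param graph a [property_graph()].
#' @param drugs drug node ids.
#' @return Named list mapping drug id to its side-effect node ids.
#' @export
side_effects_of <- function(graph, drugs) {
  e <- graph$edges[graph$edges$type == "HAS_SIDE_EFFECT", , drop = FALSE]
  stats::setNames(lapply(drugs, function(d) sort(unique(e$to[e$from == d]))),
                  drugs)
}

#' Filter candidate drugs by side-effect dissimilarity
#'
#' Computes, per candidate, the Jaccard index between its side-effect set
#' and the reference regimen's side effects (union across the regimen
#' drugs by default; per-drug maximum optional) and retains candidates
#' whose Jaccard is strictly below `max_jaccard` (cutoff of less than the
#' threshold), sorted ascending by Jaccard with ties broken by drug id.
#'
#' @param graph a [property_graph()].
#' @param candidates character vector of candidate drug ids (or the
#'   mapping returned by [inhibitors_for()]).
#' @param reference_regimen character vector of regimen drug ids; each
#'   should carry side-effect edges (drugs without any are flagged).
#' @param max_jaccard strict upper bound (default 0.2).
#' @param mode `"union"` (compare against the union of regimen side
#'   effects) or `"max"` (retain only if the maximum per-regimen-drug
#'   Jaccard is below the bound).
#' @return data.frame with `drug`, `jaccard`, `n_side_effects`,
#'   `retained`; attribute `flagged_regimen` lists regimen drugs without
#'   side-effect edges.
#' @export
side_effect_dissimilarity_filter <- function(graph, candidates,
                                             reference_regimen,
                                             max_jaccard = 0.2,
                                             mode = c("union", "max")) {
  mode <- match.arg(mode)
  if (is.list(candidates)) candidates <- names(candidates)
  regimen_se <- side_effects_of(graph, reference_regimen)
  flagged <- reference_regimen[lengths(regimen_se) == 0]
  if (length(flagged)) {
    warning("regimen drug(s) without side-effect edges: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  ref_union <- sort(unique(unlist(regimen_se)))
  if (!length(ref_union)) {
    stop("reference regimen has no side effects; filter undefined",
         call. = FALSE)
  }
  cand_se <- side_effects_of(graph, candidates)
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 0 else length(intersect(a, b)) / u
  }
  j <- vapply(candidates, function(d) {
    if (mode == "union") {
      jac(cand_se[[d]], ref_union)
    } else {
      max(vapply(regimen_se[lengths(regimen_se) > 0],
                 function(r) jac(cand_se[[d]], r), numeric(1)))
    }
  }, numeric(1))
  out <- data.frame(drug = candidates, jaccard = unname(j),
                    n_side_effects = lengths(cand_se)[candidates],
                    retained = unname(j) < max_jaccard,
                    stringsAsFactors = FALSE)
  out <- out[order(out$jaccard, out$drug), ]
  rownames(out) <- NULL
  attr(out, "flagged_regimen") <- flagged
  out
}

#' Rank candidates by literature triplet co-mentions
#'
#' Counts, per (drug, target, disease) triplet, the publications carrying
#' mention edges to all three entities; a candidate's score is the maximum
#' count over its targets. Final order: co-mention score descending, then
#' side-effect Jaccard ascending, then drug id.
#'
#' @param graph a [property_graph()] with `MENTIONED_IN_PUBLICATION`
#'   edges.
#' @param candidates data.frame from
#'   [side_effect_dissimilarity_filter()] (retained rows are ranked), or a
#'   data.frame with at least `drug` and `jaccard`.
#' @param targets named list mapping drug id to its targets hit (from
#'   [inhibitors_for()]).
#' @param disease disease node id.
#' @return data.frame with `drug`, `jaccard`, `targets`, `comention_count`
#'   and `rank` (1 = best).
#' @export
triplet_comention_rank <- function(graph, candidates, targets, disease) {
  stopifnot(inherits(graph, "property_graph"))
  cand <- candidates[if ("retained" %in% names(candidates))
    candidates$retained else TRUE, , drop = FALSE]
  e <- graph$edges[graph$edges$type == "MENTIONED_IN_PUBLICATION", ,
                   drop = FALSE]
  pubs_of <- function(id) e$to[e$from == id]
  disease_pubs <- pubs_of(disease)
  score <- vapply(cand$drug, function(d) {
    tg <- targets[[d]]
    if (!length(tg)) return(0L)
    dp <- intersect(pubs_of(d), disease_pubs)
    if (!length(dp)) return(0L)
    max(vapply(tg, function(p) length(intersect(dp, pubs_of(p))), 0L))
  }, integer(1))
  out <- data.frame(drug = cand$drug, jaccard = cand$jaccard,
                    targets = vapply(cand$drug, function(d) {
                      paste(targets[[d]], collapse = ";")
                    }, character(1)),
                    comention_count = as.integer(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$comention_count, out$jaccard, out$drug), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' End-to-end drug prioritization
#'
#' Runs the full workflow: disease-linked upregulated proteins, inhibitory
#' drugs for them, side-effect dissimilarity filter against the reference
#' regimen (strict Jaccard cutoff), and literature triplet co-mention
#' ranking.
#'
#' @param graph a [property_graph()].
#' @param diff a [differential_regulation()] result.
#' @param disease disease node id.
#' @param reference_regimen regimen drug ids for the side-effect
#'   comparison.
#' @param max_jaccard strict Jaccard cutoff (default 0.2).
#' @param mode side-effect comparison mode, see
#'   [side_effect_dissimilarity_filter()].
#' @return List of class `drug_prioritization` with `proteins` (the
#'   disease-linked upregulated set and counts), `inhibitors`,
#'   `side_effect_filter` and `ranking`.
#' @export
prioritize_drugs <- function(graph, diff, disease, reference_regimen,
                             max_jaccard = 0.2, mode = "union") {
  step1 <- disease_linked_upregulated(graph, diff, disease)
  inhib <- inhibitors_for(graph, step1$proteins)
  if (!length(inhib)) {
    return(structure(list(proteins = step1, inhibitors = inhib,
                          side_effect_filter = NULL,
                          ranking = data.frame()),
                     class = "drug_prioritization"))
  }
  sef <- side_effect_dissimilarity_filter(graph, inhib, reference_regimen,
                                          max_jaccard = max_jaccard,
                                          mode = mode)
  ranking <- triplet_comention_rank(graph, sef, inhib, disease)
  structure(list(proteins = step1, inhibitors = inhib,
                 side_effect_filter = sef, ranking = ranking),
            class = "drug_prioritization")
}

#' @export
print.drug_prioritization <- function(x, ...) {
  cat("<drug_prioritization> ", x$proteins$n_up, " upregulated, ",
      x$proteins$n_linked, " disease-linked; ",
      length(x$inhibitors), " inhibitory drug(s); ",
      nrow(x$ranking), " candidate(s) after side-effect filter\n",
      sep = "")
  invisible(x)
}
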