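#' Summary statistics of a quantification matrix
#'
#' Exploration-step summaries: per-group sample and feature counts, the
#' dynamic-range ranking of features by average linear-scale intensity, and
#' per-feature coefficients of variation (CV% = 100 * sd / mean, computed
#' on linear intensities) overall and per group.
#'
#' @param matrix an [expr_matrix()] of log2 intensities.
#' @return List with data.frames `groups` (`group`, `n_samples`,
#'   `n_features`), `dynamic_range` (`feature`, `mean_intensity`, `rank`)
#'   and `cv` (`feature`, `group`, `cv_pct`; group `"all"` = overall).
#' @export
summarize_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  lin <- 2^matrix$values
  grp <- matrix$samples$group
  groups <- data.frame(
    group = sort(unique(grp)),
    stringsAsFactors = FALSE)
  groups$n_samples <- vapply(groups$group, function(g) sum(grp == g), 0L)
  groups$n_features <- vapply(groups$group, function(g) {
    sub <- lin[grp == g, , drop = FALSE]
    if (!nrow(sub)) 0L else sum(colSums(!is.na(sub)) > 0)
  }, 0L)
  mean_lin <- colMeans(lin, na.rm = TRUE)
  dr <- data.frame(feature = matrix$features$id,
                   mean_intensity = mean_lin,
                   rank = rank(-mean_lin, ties.method = "min"),
                   stringsAsFactors = FALSE)
  dr <- dr[order(dr$rank, dr$feature), ]
  rownames(dr) <- NULL
  cv_of <- function(sub) {
    m <- colMeans(sub, na.rm = TRUE)
    s <- apply(sub, 2, stats::sd, na.rm = TRUE)
    100 * s / m
  }
  cv <- data.frame(feature = matrix$features$id, group = "all",
                   cv_pct = cv_of(lin), stringsAsFactors = FALSE)
  for (g in groups$group) {
    sub <- lin[grp == g, , drop = FALSE]
    if (nrow(sub) >= 2) {
      cv <- rbind(cv, data.frame(feature = matrix$features$id, group = g,
                                 cv_pct = cv_of(sub),
                                 stringsAsFactors = FALSE))
    }
  }
  rownames(cv) <- NULL
  list(groups = groups, dynamic_range = dr, cv = cv)
}

#' Principal component analysis of samples
#'
#' Linear dimensionality reduction over the processed (complete) matrix;
#' samples are observations, features variables; columns are mean-centred.
#'
#' @param matrix a complete [expr_matrix()].
#' @param n_components number of components to return.
#' @return List with `scores` (samples x components), `loadings`
#'   (features x components) and `explained_variance` (ratios, summing to
#'   at most 1 over the returned components).
#' @export
run_pca <- function(matrix, n_components = 2L) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (anyNA(matrix$values)) {
    stop("matrix has missing values; impute before PCA (see impute_matrix)",
         call. = FALSE)
  }
  n_components <- as.integer(n_components)
  if (n_components > min(dim(matrix$values))) {
    stop("n_components exceeds min(samples, features)", call. = FALSE)
  }
  p <- stats::prcomp(matrix$values, center = TRUE, scale. = FALSE)
  ratio <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(min(n_components, ncol(p$x)))
  list(scores = p$x[, k, drop = FALSE],
       loadings = p$rotation[, k, drop = FALSE],
       explained_variance = ratio[k])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment, monotone in the p-value ranks and capped
#' at 1.
#'
#' @param pvalues numeric vector in \[0, 1\] (NA passed through).
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

pooled_t <- function(va, vb, s0 = 0) {
  na <- nrow(va); nb <- nrow(vb)
  ma <- colMeans(va); mb <- colMeans(vb)
  sa2 <- apply(va, 2, stats::var); sb2 <- apply(vb, 2, stats::var)
  sp2 <- ((na - 1) * sa2 + (nb - 1) * sb2) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  list(diff = ma - mb, se = se, df = na + nb - 2)
}

#' SAM d statistic
#'
#' The significance-analysis-of-microarrays moderated difference
#' `d = (mean_a - mean_b) / (pooled standard error + s0)`; the
#' regularizer `s0` damps features with tiny variance. At `s0 = 0` the
#' statistic is the ordinary pooled-variance t statistic.
#'
#' @param group_a,group_b numeric matrices (samples x features, at least
#'   two rows each) or vectors (a single feature).
#' @param s0 non-negative regularizer.
#' @return Numeric vector of d statistics, one per feature.
#' @export
sam_statistic <- function(group_a, group_b, s0 = 0) {
  if (is.null(dim(group_a))) group_a <- matrix(group_a, ncol = 1)
  if (is.null(dim(group_b))) group_b <- matrix(group_b, ncol = 1)
  if (nrow(group_a) < 2 || nrow(group_b) < 2) {
    stop("both groups need at least 2 values per feature", call. = FALSE)
  }
  pt <- pooled_t(group_a, group_b, s0)
  denom <- pt$se + s0
  if (any(denom == 0)) {
    stop("zero pooled variance with s0 = 0: d statistic undefined",
         call. = FALSE)
  }
  as.numeric(pt$diff / denom)
}

#' Permutation-based FDR for a two-group comparison
#'
#' Estimates, for each feature, the false discovery rate at the cutoff
#' equal to its observed absolute statistic: group labels are permuted,
#' and the FDR is the mean number of null statistics exceeding the cutoff
#' divided by the number of observed statistics exceeding it, clipped to
#' \[0, 1\] and made monotone in the cutoff. Used only if the number of
#' permutations is sufficiently large: when fewer distinct label
#' assignments exist than permutations requested, the estimate would be
#' unstable and the function falls back to Benjamini-Hochberg on t-test
#' p-values with a warning.
#'
#' @param values samples x features numeric matrix (complete).
#' @param groups group label per sample (exactly two levels).
#' @param statistic `"t"` (pooled t) or `"sam"` (d with `s0`).
#' @param s0 SAM regularizer when `statistic = "sam"`.
#' @param permutations number of label permutations (>= 10; default 250).
#' @param seed integer seed, making the estimate reproducible.
#' @return List with `fdr` (per-feature estimate), `statistic` (observed
#'   values), and `method` (`"permutation"` or `"bh_fallback"`).
#' @export
permutation_fdr <- function(values, groups, statistic = c("t", "sam"),
                            s0 = 0, permutations = 250L, seed = 1L) {
  statistic <- match.arg(statistic)
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2) {
    stop("permutation FDR needs exactly two exchangeable groups",
         call. = FALSE)
  }
  if (permutations < 10) {
    stop("permutation count must be at least 10", call. = FALSE)
  }
  ia <- which(groups == lv[1]); ib <- which(groups == lv[2])
  obs <- stat_two_group(values, ia, ib, statistic, s0)
  distinct <- choose(length(groups), length(ia))
  if (distinct < permutations) {
    warning("only ", distinct, " distinct label assignments; ",
            "not sufficiently large for ", permutations,
            " permutations - falling back to BH", call. = FALSE)
    pt <- pooled_t(values[ia, , drop = FALSE], values[ib, , drop = FALSE])
    p <- 2 * stats::pt(-abs(pt$diff / pt$se), df = pt$df)
    return(list(fdr = bh_fdr(p), statistic = obs, method = "bh_fallback"))
  }
  null <- matrix(NA_real_, permutations, ncol(values))
  withr_seed(seed, {
    for (b in seq_len(permutations)) {
      idx <- sample(length(groups), length(ia))
      null[b, ] <- stat_two_group(values, idx,
                                  setdiff(seq_along(groups), idx),
                                  statistic, s0)
    }
  })
  an <- abs(null)
  cut <- abs(obs)
  fdr <- vapply(cut, function(ct) {
    mean_null <- mean(rowSums(an >= ct))
    denom <- sum(cut >= ct)
    min(1, mean_null / denom)
  }, numeric(1))
  # FDR cannot decrease as the cutoff is lowered
  ord <- order(cut, decreasing = TRUE)
  fdr[ord] <- cummax(fdr[ord])
  list(fdr = fdr, statistic = obs, method = "permutation")
}

stat_two_group <- function(values, ia, ib, statistic, s0) {
  pt <- pooled_t(values[ia, , drop = FALSE], values[ib, , drop = FALSE])
  if (statistic == "sam") {
    as.numeric(pt$diff / (pt$se + s0))
  } else {
    as.numeric(pt$diff / pt$se)
  }
}

#' Design-aware differential regulation analysis
#'
#' Identifies the appropriate hypothesis test from the experimental
#' design: two independent groups use a pooled-variance t-test (Welch
#' optional); two groups sharing every subject use a paired t-test; more
#' than two independent groups use one-way ANOVA with pairwise post hoc
#' t-tests; repeated subjects across more than two conditions use
#' repeated-measures ANOVA (subject as blocking factor) with paired post
#' hoc tests. Multiple testing is controlled by Benjamini-Hochberg FDR
#' (default) or permutation-based FDR (two-group designs), and features
#' are flagged `up` when the linear fold change exceeds
#' `fold_change_min` and the adjusted p is below `fdr_max` (`down`
#' symmetric, `ns` otherwise).
#'
#' @param matrix a complete [expr_matrix()] (log2 intensities).
#' @param thresholds list with `fold_change_min` (linear scale, default 2)
#'   and `fdr_max` (default 0.05); see [significance_thresholds()].
#' @param fdr `"bh"` or `"permutation"`.
#' @param permutations,seed permutation-FDR settings.
#' @param variance `"pooled"` (default, matching the SAM denominator) or
#'   `"welch"` for two-group tests.
#' @return data.frame of class `differential_result`: one row per feature
#'   per pairwise contrast with columns `feature`, `contrast`, `group1`,
#'   `group2`, `mean1`, `mean2`, `log2fc`, `statistic`, `pvalue`, `padj`,
#'   `regulation`, `test`, and for ANOVA designs `anova_f`, `anova_p`.
#' @export
differential_regulation <- function(matrix,
                                    thresholds = significance_thresholds(),
                                    fdr = c("bh", "permutation"),
                                    permutations = 250L, seed = 1L,
                                    variance = c("pooled", "welch")) {
  stopifnot(inherits(matrix, "expr_matrix"))
  fdr <- match.arg(fdr)
  variance <- match.arg(variance)
  if (anyNA(matrix$values)) {
    stop("matrix has missing values; run the preparation step first",
         call. = FALSE)
  }
  grp <- as.character(matrix$samples$group)
  lv <- sort(unique(grp))
  if (length(lv) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(grp) < 2)) {
    stop("need at least two samples per group", call. = FALSE)
  }
  subj <- matrix$samples$subject
  paired <- !is.null(subj) && !anyNA(subj) &&
    all(vapply(split(grp, subj), function(g) {
      setequal(unique(g), lv) && length(g) == length(lv)
    }, logical(1)))
  test <- if (length(lv) == 2) {
    if (paired) "paired t-test" else "t-test"
  } else {
    if (paired) "repeated-measures ANOVA" else "ANOVA"
  }

  v <- matrix$values
  feats <- matrix$features$id
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    ia <- which(grp == pr[1]); ib <- which(grp == pr[2])
    if (paired) {
      ord_a <- ia[order(subj[ia])]
      ord_b <- ib[order(subj[ib])]
      dm <- v[ord_a, , drop = FALSE] - v[ord_b, , drop = FALSE]
      m <- colMeans(dm)
      se <- apply(dm, 2, stats::sd) / sqrt(nrow(dm))
      tstat <- ifelse(se == 0 & m == 0, 0, m / se)
      p <- 2 * stats::pt(-abs(tstat), df = nrow(dm) - 1)
      p[se == 0 & m == 0] <- 1
    } else if (variance == "welch") {
      na <- length(ia); nb <- length(ib)
      ma <- colMeans(v[ia, , drop = FALSE])
      mb <- colMeans(v[ib, , drop = FALSE])
      sa2 <- apply(v[ia, , drop = FALSE], 2, stats::var)
      sb2 <- apply(v[ib, , drop = FALSE], 2, stats::var)
      se <- sqrt(sa2 / na + sb2 / nb)
      df <- (sa2 / na + sb2 / nb)^2 /
        ((sa2 / na)^2 / (na - 1) + (sb2 / nb)^2 / (nb - 1))
      tstat <- ifelse(se == 0 & ma == mb, 0, (ma - mb) / se)
      p <- 2 * stats::pt(-abs(tstat), df = df)
      p[se == 0 & ma == mb] <- 1
    } else {
      pt <- pooled_t(v[ia, , drop = FALSE], v[ib, , drop = FALSE])
      tstat <- ifelse(pt$se == 0 & pt$diff == 0, 0, pt$diff / pt$se)
      p <- 2 * stats::pt(-abs(tstat), df = pt$df)
      p[pt$se == 0 & pt$diff == 0] <- 1
    }
    rows[[length(rows) + 1L]] <- data.frame(
      feature = feats,
      contrast = paste(pr[1], "vs", pr[2]),
      group1 = pr[1], group2 = pr[2],
      mean1 = colMeans(v[ia, , drop = FALSE]),
      mean2 = colMeans(v[ib, , drop = FALSE]),
      log2fc = colMeans(v[ia, , drop = FALSE]) -
        colMeans(v[ib, , drop = FALSE]),
      statistic = as.numeric(tstat), pvalue = as.numeric(p),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  if (length(lv) > 2) {
    av <- anova_per_feature(v, grp, if (paired) subj else NULL)
    res$anova_f <- av$f[match(res$feature, feats)]
    res$anova_p <- av$p[match(res$feature, feats)]
  }

  if (fdr == "permutation" && length(lv) == 2 && !paired) {
    pf <- permutation_fdr(v, grp, statistic = "t",
                          permutations = permutations, seed = seed)
    res$padj <- pf$fdr
    attr(res, "fdr_method") <- pf$method
  } else {
    if (fdr == "permutation") {
      warning("permutation FDR requires two independent groups; using BH",
              call. = FALSE)
    }
    res$padj <- bh_fdr(res$pvalue)  # BH across all pairs and features
    attr(res, "fdr_method") <- "bh"
  }
  lfc_min <- log2(thresholds$fold_change_min)
  res$regulation <- ifelse(
    res$padj < thresholds$fdr_max & res$log2fc > lfc_min, "up",
    ifelse(res$padj < thresholds$fdr_max & res$log2fc < -lfc_min, "down",
           "ns"))
  res$test <- test
  class(res) <- c("differential_result", class(res))
  res
}

anova_per_feature <- function(v, grp, subj = NULL) {
  n <- ncol(v)
  f <- p <- numeric(n)
  gf <- factor(grp)
  if (!is.null(subj)) {
    counts <- table(subj, gf)
    if (any(counts != 1)) {
      stop("unbalanced repeated-measures design: every subject must ",
           "appear exactly once per condition", call. = FALSE)
    }
    sf <- factor(subj)
  }
  for (j in seq_len(n)) {
    y <- v[, j]
    fit <- if (is.null(subj)) {
      stats::anova(stats::lm(y ~ gf))
    } else {
      stats::anova(stats::lm(y ~ sf + gf))
    }
    row <- which(rownames(fit) == "gf")
    f[j] <- fit$`F value`[row]
    p[j] <- fit$`Pr(>F)`[row]
    if (is.nan(f[j])) { f[j] <- 0; p[j] <- 1 }
  }
  list(f = f, p = p)
}

#' Significance thresholds for regulation flags
#'
#' @param fold_change_min minimum linear fold change (default 2, i.e.
#'   |log2 fold change| > 1).
#' @param fdr_max maximum adjusted p (default 0.05).
#' @return Named list.
#' @export
significance_thresholds <- function(fold_change_min = 2, fdr_max = 0.05) {
  stopifnot(fold_change_min >= 1, fdr_max > 0, fdr_max < 1)
  list(fold_change_min = fold_change_min, fdr_max = fdr_max)
}

#' Volcano-plot payload
#'
#' @param diff a [differential_regulation()] result.
#' @return data.frame with `feature`, `contrast`, `log2fc`,
#'   `neg_log10_padj` and `regulation` - sufficient to re-render a volcano
#'   figure.
#' @export
volcano_payload <- function(diff) {
  data.frame(feature = diff$feature, contrast = diff$contrast,
             log2fc = diff$log2fc,
             neg_log10_padj = -log10(pmax(diff$padj, 1e-300)),
             regulation = diff$regulation, stringsAsFactors = FALSE)
}

#' Fisher exact enrichment over annotation sets
#'
#' One two-sided Fisher exact test per annotation term on the 2x2 table of
#' hit membership versus term membership within the universe, with
#' Benjamini-Hochberg correction across terms.
#'
#' @param hit_set character vector of significant feature ids (subset of
#'   `universe`).
#' @param annotation_sets named list mapping term id to feature ids.
#' @param universe character vector of all tested feature ids.
#' @return data.frame with `term`, `n_hits`, `n_term`, `odds_ratio`,
#'   `pvalue`, `padj`, sorted by `padj` then `term`.
#' @export
fisher_enrichment <- function(hit_set, annotation_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  hit_set <- intersect(unique(hit_set), universe)
  terms <- names(annotation_sets)
  res <- lapply(terms, function(tm) {
    members <- intersect(annotation_sets[[tm]], universe)
    a <- length(intersect(hit_set, members))
    b <- length(hit_set) - a
    c <- length(members) - a
    d <- length(universe) - length(hit_set) - c
    ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2))
    data.frame(term = tm, n_hits = a, n_term = length(members),
               odds_ratio = unname(ft$estimate), pvalue = ft$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- bh_fdr(res$pvalue)
  res <- res[order(res$padj, res$term), ]
  rownames(res) <- NULL
  res
}

#' Kaplan-Meier curves with marker-expression stratification
#'
#' Splits samples at the (1 - split) quantile of a marker's expression
#' into a high group (top `split` fraction) and a low group, estimates
#' product-limit survival curves per group and tests the difference with a
#' two-sided log-rank test.
#'
#' @param times non-negative event/censoring times.
#' @param events event indicator (1 = event, 0 = censored).
#' @param expression marker expression per sample.
#' @param split top fraction assigned to the high group (default 0.25).
#' @return List of class `survival_result` with `curves` (data.frame
#'   `group`, `time`, `survival`, `n_risk`), `statistic` (log-rank
#'   chi-square), `pvalue`, `groups` (assignment per sample) and
#'   `grouping` tag. With zero events, `statistic`/`pvalue` are `NA` and
#'   the tag notes `no_events`.
#' @export
km_logrank <- function(times, events, expression, split = 0.25) {
  stopifnot(length(times) == length(events),
            length(times) == length(expression),
            all(times >= 0), all(events %in% c(0, 1)),
            split > 0, split < 1)
  thr <- stats::quantile(expression, 1 - split, names = FALSE)
  high <- expression > thr
  if (!any(high) || all(high)) {
    stop("expression split leaves an empty group", call. = FALSE)
  }
  gl <- ifelse(high, "high", "low")
  tag <- sprintf("top %d%% expression", round(100 * split))
  fit <- survival::survfit(survival::Surv(times, events) ~ gl)
  strata_name <- rep(names(fit$strata) %||% "all", fit$strata %||%
                       length(fit$time))
  curves <- data.frame(group = sub("^gl=", "", strata_name),
                       time = fit$time, survival = fit$surv,
                       n_risk = fit$n.risk, stringsAsFactors = FALSE)
  if (sum(events) == 0) {
    return(structure(list(curves = curves, statistic = NA_real_,
                          pvalue = NA_real_, groups = gl,
                          grouping = paste(tag, "(no_events)")),
                     class = "survival_result"))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ gl)
  structure(list(curves = curves, statistic = unname(sd$chisq),
                 pvalue = stats::pchisq(sd$chisq, df = 1,
                                        lower.tail = FALSE),
                 groups = gl, grouping = tag),
            class = "survival_result")
}
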