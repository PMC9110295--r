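test_that("BH adjustment matches the hand step-up computation", {
  # step-up by hand for (0.01, 0.02, 0.03, 0.04), m = 4:
  #   rank 4: 0.04 * 4/4 = 0.04
  #   rank 3: min(0.04, 0.03 * 4/3) = 0.04
  #   rank 2: min(0.04, 0.02 * 4/2) = 0.04
  #   rank 1: min(0.04, 0.01 * 4/1) = 0.04
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.42), 0.42)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # order-invariance up to reordering
  p <- c(0.3, 0.001, 0.04, 0.7, 0.02)
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("SAM d statistic equals its definition and the t at s0 = 0", {
  # mean diff 2, zero pooled variance, s0 = 2 -> d = 1
  a <- matrix(c(5, 5, 5), ncol = 1)
  b <- matrix(c(3, 3, 3), ncol = 1)
  expect_equal(sam_statistic(a, b, s0 = 2), 1)
  expect_error(sam_statistic(a, b, s0 = 0), "undefined")

  set.seed(8)
  ga <- matrix(rnorm(50), 5, 10)
  gb <- matrix(rnorm(60, 1), 6, 10)
  d0 <- sam_statistic(ga, gb, s0 = 0)
  tref <- vapply(1:10, function(j) {
    unname(t.test(ga[, j], gb[, j], var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_equal(d0, tref, tolerance = 1e-12)
  # antisymmetry under group swap
  expect_equal(sam_statistic(gb, ga, s0 = 1),
               -sam_statistic(ga, gb, s0 = 1))
  # s0 shrinks the magnitude
  expect_true(all(abs(sam_statistic(ga, gb, s0 = 2)) < abs(d0)))
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # oracle: enumerate the hypergeometric support for the 2x2 margins and
  # sum the probabilities of tables at most as likely as the observed one
  hyper_two_sided <- function(a, hits, members, universe) {
    support <- max(0, hits + members - universe):min(hits, members)
    pr <- dhyper(support, members, universe - members, hits)
    sum(pr[pr <= dhyper(a, members, universe - members, hits) + 1e-12])
  }
  universe <- paste0("p", 1:4)
  res <- fisher_enrichment(c("p1", "p2"),
                           list(T1 = c("p1", "p2")), universe)
  expect_equal(res$pvalue, hyper_two_sided(2, 2, 2, 4))  # = 1/3
  expect_equal(res$pvalue, 1 / 3)

  # depletion case checked against the same enumeration oracle
  universe2 <- paste0("q", 1:20)
  hits2 <- paste0("q", 1:10)
  term2 <- paste0("q", 11:18)   # disjoint from hits
  res2 <- fisher_enrichment(hits2, list(T2 = term2), universe2)
  expect_equal(res2$pvalue, hyper_two_sided(0, 10, 8, 20))

  # hit set equal to the universe is uninformative
  res3 <- fisher_enrichment(universe, list(T1 = c("p1", "p3")), universe)
  expect_equal(res3$pvalue, 1)
  expect_error(fisher_enrichment("a", list(), character(0)), "universe")
})

test_that("two-group testing flags regulation by FC and FDR thresholds", {
  # identical groups: t = 0, p = 1, ns
  vals <- rbind(matrix(c(1, 2, 3), 3, 5), matrix(c(1, 2, 3), 3, 5))
  m <- expr_matrix(vals, data.frame(id = paste0("s", 1:6),
                                    group = rep(c("a", "b"), each = 3)))
  d <- differential_regulation(m)
  expect_equal(d$statistic, rep(0, 5))
  expect_equal(d$pvalue, rep(1, 5))
  expect_equal(d$regulation, rep("ns", 5))
  expect_equal(unique(d$test), "t-test")

  # a clear shift of 1.5 log2 units is significant and flagged up
  # (fold change 2^1.5 = 2.83 > 2)
  set.seed(2)
  base <- matrix(rnorm(80, 20, 0.1), 8, 10)
  shifted <- base
  shifted[1:4, 1] <- shifted[1:4, 1] + 1.5
  m2 <- expr_matrix(shifted, data.frame(id = paste0("s", 1:8),
                                        group = rep(c("hi", "lo"),
                                                    each = 4)))
  d2 <- differential_regulation(m2)
  expect_equal(d2$regulation[1], "up")
  expect_lt(d2$padj[1], 0.05)
  expect_gt(d2$log2fc[1], 1)
  expect_equal(d2$regulation[-1], rep("ns", 9))

  # composition oracle: equals pooled t + BH done by hand
  pd <- sapply(1:10, function(j) {
    t.test(shifted[1:4, j], shifted[5:8, j], var.equal = TRUE)$p.value
  })
  expect_equal(d2$pvalue, unname(pd), tolerance = 1e-12)
  expect_equal(d2$padj, unname(p.adjust(pd, "BH")), tolerance = 1e-12)
})

test_that("design detection picks paired and ANOVA tests", {
  set.seed(5)
  base <- matrix(rnorm(60, 10, 1), 6, 10)
  samples <- data.frame(id = paste0("s", 1:6),
                        group = rep(c("pre", "post"), each = 3),
                        subject = rep(paste0("p", 1:3), 2))
  m <- expr_matrix(base, samples)
  d <- differential_regulation(m)
  expect_equal(unique(d$test), "paired t-test")
  ref <- t.test(base[4:6, 1], base[1:3, 1], paired = TRUE)
  i <- which(d$feature == m$features$id[1])
  expect_equal(abs(d$statistic[i]), abs(unname(ref$statistic)),
               tolerance = 1e-10)
  expect_equal(d$pvalue[i], ref$p.value, tolerance = 1e-10)

  # three identical groups -> F = 0 everywhere
  v3 <- rbind(matrix(1:4, 2, 4, byrow = TRUE),
              matrix(1:4, 2, 4, byrow = TRUE),
              matrix(1:4, 2, 4, byrow = TRUE))
  m3 <- expr_matrix(v3 + rep(c(0, 0.5), 3),
                    data.frame(id = paste0("s", 1:6),
                               group = rep(c("a", "b", "c"), each = 2)))
  d3 <- differential_regulation(m3)
  expect_equal(unique(d3$test), "ANOVA")
  expect_true(all(abs(d3$anova_f) < 1e-12))
  # one row per feature per pairwise contrast
  expect_equal(nrow(d3), 4 * 3)

  # repeated-measures design with three conditions
  samples_rm <- data.frame(id = paste0("s", 1:9),
                           group = rep(c("a", "b", "c"), each = 3),
                           subject = rep(paste0("p", 1:3), 3))
  set.seed(6)
  mrm <- expr_matrix(matrix(rnorm(45), 9, 5), samples_rm)
  drm <- differential_regulation(mrm)
  expect_equal(unique(drm$test), "repeated-measures ANOVA")
  # blocked ANOVA oracle via aov for the first feature
  y <- mrm$values[, 1]
  fit <- anova(lm(y ~ factor(samples_rm$subject) +
                    factor(samples_rm$group)))
  expect_equal(unique(drm$anova_f[drm$feature == mrm$features$id[1]]),
               fit$`F value`[2], tolerance = 1e-10)

  expect_error(differential_regulation(
    expr_matrix(matrix(1:4, 2), data.frame(id = c("a", "b"),
                                           group = c("x", "y")))),
    "two samples per group")
})

test_that("permutation FDR is seeded, bounded and falls back when small", {
  set.seed(10)
  v <- matrix(rnorm(200), 10, 20)
  grp <- rep(c("a", "b"), each = 5)
  r1 <- permutation_fdr(v, grp, permutations = 250, seed = 42)
  r2 <- permutation_fdr(v, grp, permutations = 250, seed = 42)
  expect_identical(r1$fdr, r2$fdr)
  expect_equal(r1$method, "permutation")
  expect_true(all(r1$fdr >= 0 & r1$fdr <= 1))

  # perfectly separated top feature: no null statistic beats it
  v2 <- v
  v2[1:5, 1] <- v2[1:5, 1] + 50
  r3 <- permutation_fdr(v2, grp, permutations = 100, seed = 1)
  expect_lt(r3$fdr[1], 0.05)

  # 8 samples: choose(8,4) = 70 < 250 achievable assignments -> BH
  expect_warning(
    rf <- permutation_fdr(v[1:8, ], rep(c("a", "b"), each = 4),
                          permutations = 250, seed = 1),
    "falling back to BH")
  expect_equal(rf$method, "bh_fallback")
  expect_error(permutation_fdr(v, grp, permutations = 5), "at least 10")
})

test_that("PCA returns orthonormal components with ordered variance", {
  set.seed(3)
  v <- matrix(rnorm(100, 20), 10, 10)
  m <- expr_matrix(v)
  p <- run_pca(m, 3)
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-12)

  # two samples: a single direction carries all the variance
  p2 <- run_pca(expr_matrix(v[1:2, ]), 1)
  expect_equal(p2$explained_variance[1], 1)

  # full-rank case: scores reproduce pairwise sample distances
  d_orig <- dist(sweep(v, 2, colMeans(v)))
  pf <- run_pca(m, 10)
  expect_equal(as.matrix(dist(pf$scores)), as.matrix(d_orig),
               tolerance = 1e-8, ignore_attr = TRUE)

  na <- v; na[1, 1] <- NA
  expect_error(run_pca(expr_matrix(na), 2), "impute")
})

test_that("matrix summaries rank by linear intensity and report CVs", {
  # two features with linear means 100 and 10 -> ranks 1 and 2
  v <- log2(rbind(c(100, 10), c(100, 10), c(100, 10)))
  colnames(v) <- c("big", "small")
  m <- expr_matrix(v, data.frame(id = paste0("s", 1:3),
                                 group = c("a", "a", "b")))
  s <- summarize_matrix(m)
  expect_equal(s$dynamic_range$feature[s$dynamic_range$rank == 1], "big")
  expect_equal(s$dynamic_range$rank, c(1, 2))
  # constant feature -> CV 0
  expect_equal(s$cv$cv_pct[s$cv$group == "all"], c(0, 0))
  expect_equal(s$groups$n_samples, c(2L, 1L))
})

test_that("survival stratification reproduces the hand log-rank sum", {
  # 6 subjects, 5 events; expression puts s1..s3 in the high group.
  # Oracle: textbook observed-minus-expected arithmetic per event time.
  times <- c(1, 3, 5, 2, 4, 6)
  events <- c(1, 1, 0, 1, 1, 1)
  expr <- c(10, 9, 8, 1, 2, 3)
  logrank_oracle <- function(times, events, high) {
    ev <- sort(unique(times[events == 1]))
    O <- E <- V <- 0
    for (t in ev) {
      at <- times >= t
      n <- sum(at); n1 <- sum(at & high)
      d <- sum(times == t & events == 1)
      d1 <- sum(times == t & events == 1 & high)
      O <- O + d1
      E <- E + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
  }
  km <- km_logrank(times, events, expr, split = 0.5)
  expect_equal(km$statistic,
               logrank_oracle(times, events, expr > median(expr)),
               tolerance = 1e-10)
  expect_equal(km$pvalue,
               pchisq(km$statistic, 1, lower.tail = FALSE))
  # survival curves start at 1 and never increase
  for (g in unique(km$curves$group)) {
    sg <- km$curves$survival[km$curves$group == g]
    expect_true(all(diff(sg) <= 0))
    expect_lte(max(sg), 1)
  }
  # identical event histories in both groups -> statistic 0
  km0 <- km_logrank(c(1, 2, 1, 2), c(1, 1, 1, 1), c(5, 5, 1, 1),
                    split = 0.5)
  expect_equal(km0$statistic, 0, tolerance = 1e-10)
  # no events -> sentinel
  kmn <- km_logrank(c(1, 2, 3, 4), c(0, 0, 0, 0), c(1, 2, 3, 4))
  expect_true(is.na(kmn$pvalue))
  expect_match(kmn$grouping, "no_events")
  expect_true(all(kmn$curves$survival == 1))
})
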