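#' Experiment matrices
#'
#' An `expr_matrix` holds a samples x features quantification matrix of
#' log2 intensities (NA = missing), sample metadata (group label, subject
#' id, optional timepoint) and feature metadata (identifier and type:
#' protein, peptide, phosphosite or clinical).
#'
#' @param values numeric matrix, samples in rows, features in columns;
#'   dimnames are taken as sample / feature ids when metadata is omitted.
#' @param samples data.frame with columns `id`, `group` and optionally
#'   `subject`, `timepoint`.
#' @param features data.frame with columns `id` and optionally `type`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples = NULL, features = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(samples)) {
    samples <- data.frame(id = rownames(values) %||%
                            paste0("sample", seq_len(nrow(values))),
                          group = "all", stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(samples))) {
    stop("sample metadata needs columns 'id' and 'group'", call. = FALSE)
  }
  if (any(is.na(samples$group) | !nzchar(samples$group))) {
    stop("group labels must be non-empty", call. = FALSE)
  }
  if (is.null(features)) {
    features <- data.frame(id = colnames(values) %||%
                             paste0("feature", seq_len(ncol(values))),
                           type = "protein", stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!"type" %in% names(features)) features$type <- "protein"
  if (nrow(samples) != nrow(values) || nrow(features) != ncol(values)) {
    stop("metadata dimensions do not match the value matrix", call. = FALSE)
  }
  if (anyDuplicated(features$id)) {
    stop("feature ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(samples$id)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  dimnames(values) <- list(samples$id, features$id)
  structure(list(values = values, samples = samples, features = features),
            class = "expr_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " features (", sum(is.na(x$values)), " missing cells, ",
      length(unique(x$samples$group)), " groups)\n", sep = "")
  invisible(x)
}

#' Missing-value mask
#' @param matrix an [expr_matrix()].
#' @return Logical samples x features matrix, `TRUE` where missing.
#' @export
missing_mask <- function(matrix) is.na(matrix$values)

#' Read a wide sample x feature quantification table
#'
#' First column `sample`, optional metadata columns `group`, `subject`,
#' `timepoint`; every remaining column is a feature. Intensities are
#' log2-transformed on load unless `log2 = FALSE`; zeros and NaN become
#' missing.
#'
#' @param path TSV file path.
#' @param log2 apply log2 to raw intensities (default `TRUE`).
#' @param type feature type recorded in the metadata.
#' @return An [expr_matrix()].
#' @export
read_experiment_wide <- function(path, log2 = TRUE, type = "protein") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) {
    stop("wide experiment table needs a 'sample' column", call. = FALSE)
  }
  meta_cols <- intersect(c("sample", "group", "subject", "timepoint"),
                         names(df))
  feats <- setdiff(names(df), meta_cols)
  vals <- as.matrix(df[feats])
  storage.mode(vals) <- "double"
  vals[!is.finite(vals) | vals == 0] <- NA
  if (log2) vals <- log2(vals)
  samples <- data.frame(id = as.character(df$sample),
                        group = if ("group" %in% names(df))
                          as.character(df$group) else "all",
                        stringsAsFactors = FALSE)
  if ("subject" %in% names(df)) samples$subject <- as.character(df$subject)
  if ("timepoint" %in% names(df)) samples$timepoint <- df$timepoint
  expr_matrix(vals, samples,
              data.frame(id = feats, type = type, stringsAsFactors = FALSE))
}

#' Read a proteinGroups-style protein table
#'
#' Feature rows with an identifier column plus per-sample intensity
#' columns named `<prefix><sample>` (default prefix `LFQ intensity `).
#' Rows flagged in `Reverse` or `Potential contaminant` columns (value
#' `+`) are dropped. Intensities are log2-transformed, zeros become
#' missing.
#'
#' @param path TSV file path.
#' @param id_column feature identifier column (default
#'   `Majority protein IDs`).
#' @param intensity_prefix sample-column prefix.
#' @param groups optional named vector mapping sample id to group label.
#' @return An [expr_matrix()].
#' @export
read_proteingroups <- function(path, id_column = "Majority protein IDs",
                               intensity_prefix = "LFQ intensity ",
                               groups = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!id_column %in% names(df)) {
    stop("missing identifier column '", id_column, "'", call. = FALSE)
  }
  for (flag in c("Reverse", "Potential contaminant")) {
    if (flag %in% names(df)) df <- df[df[[flag]] != "+", , drop = FALSE]
  }
  icols <- names(df)[startsWith(names(df), intensity_prefix)]
  if (!length(icols)) {
    stop("no columns with prefix '", intensity_prefix, "'", call. = FALSE)
  }
  vals <- t(as.matrix(df[icols]))
  storage.mode(vals) <- "double"
  vals[!is.finite(vals) | vals == 0] <- NA
  vals <- log2(vals)
  ids <- substring(icols, nchar(intensity_prefix) + 1L)
  samples <- data.frame(id = ids,
                        group = if (is.null(groups)) "all" else
                          unname(groups[ids]),
                        stringsAsFactors = FALSE)
  feats <- make.unique(as.character(df[[id_column]]))
  expr_matrix(vals, samples,
              data.frame(id = feats, type = "protein",
                         stringsAsFactors = FALSE))
}

#' Filter features by missingness
#'
#' Removes features identified in too few samples, either as a maximum
#' fraction of missing values (default mode), a minimum number of observed
#' values per group, or a minimum number of observed values in the whole
#' dataset.
#'
#' @param matrix an [expr_matrix()].
#' @param mode `"max_missing"` (threshold = maximum missing fraction),
#'   `"min_per_group"` or `"min_total"` (threshold = minimum observed
#'   count).
#' @param threshold numeric; a fraction in \[0, 1\] for `max_missing`, a
#'   non-negative count otherwise.
#' @return List with `matrix` (filtered [expr_matrix()]) and `dropped`
#'   (character vector of removed feature ids).
#' @export
filter_features <- function(matrix,
                            mode = c("max_missing", "min_per_group",
                                     "min_total"),
                            threshold = 0.5) {
  stopifnot(inherits(matrix, "expr_matrix"))
  mode <- match.arg(mode)
  v <- matrix$values
  if (mode == "max_missing") {
    if (threshold < 0 || threshold > 1) {
      stop("max_missing threshold must be a fraction in [0, 1]",
           call. = FALSE)
    }
    keep <- colMeans(is.na(v)) <= threshold
  } else {
    if (threshold < 0 || threshold != round(threshold)) {
      stop("count threshold must be a non-negative integer", call. = FALSE)
    }
    if (mode == "min_total") {
      keep <- colSums(!is.na(v)) >= threshold
    } else {
      grp <- split(seq_len(nrow(v)), matrix$samples$group)
      per_group <- sapply(grp, function(ix) {
        colSums(!is.na(v[ix, , drop = FALSE]))
      })
      per_group <- matrix(per_group, nrow = ncol(v))
      keep <- apply(per_group, 1, min) >= threshold
    }
  }
  dropped <- matrix$features$id[!keep]
  list(matrix = expr_matrix(v[, keep, drop = FALSE],
                            matrix$samples,
                            matrix$features[keep, , drop = FALSE]),
       dropped = dropped)
}

#' Normalize samples
#'
#' `median` subtracts each sample's median of observed values (all sample
#' medians become 0); `quantile` forces all samples onto the shared
#' empirical distribution (via [limma::normalizeQuantiles()], missing
#' cells stay missing); `none` is the identity.
#'
#' @param matrix an [expr_matrix()].
#' @param method `"median"`, `"quantile"` or `"none"`.
#' @return A normalized [expr_matrix()].
#' @export
normalize_matrix <- function(matrix,
                             method = c("median", "quantile", "none")) {
  stopifnot(inherits(matrix, "expr_matrix"))
  method <- match.arg(method)
  v <- matrix$values
  if (any(rowSums(!is.na(v)) == 0)) {
    stop("sample with all values missing; cannot normalize", call. = FALSE)
  }
  if (method == "none") return(matrix)
  if (method == "median") {
    med <- apply(v, 1, stats::median, na.rm = TRUE)
    v <- sweep(v, 1, med, "-")
  } else {
    v <- t(limma::normalizeQuantiles(t(v)))
    dimnames(v) <- dimnames(matrix$values)
  }
  expr_matrix(v, matrix$samples, matrix$features)
}

#' Imputation configuration
#'
#' @param method `"minprob"` (default; left-censored draws for values
#'   missing not at random), `"knn"` (nearest-neighbour means for values
#'   missing completely at random) or `"mixed"` (per-feature choice by
#'   missingness fraction).
#' @param k neighbour count for KNN (default 5).
#' @param minprob_quantile location of the MinProb distribution: the
#'   q-quantile of each sample's observed values (default 0.01).
#' @param minprob_width MinProb s.d. as a multiple of the sample s.d.
#'   (default 0.3).
#' @param mixed_threshold missingness fraction below which (strictly) a
#'   feature is treated as missing completely at random and imputed by KNN;
#'   at or above it MinProb is used (default 0.5).
#' @param seed integer seed for the MinProb draws.
#' @return List of class `imputation_config`.
#' @export
imputation_config <- function(method = c("minprob", "knn", "mixed"),
                              k = 5L, minprob_quantile = 0.01,
                              minprob_width = 0.3, mixed_threshold = 0.5,
                              seed = 1L) {
  method <- match.arg(method)
  stopifnot(k >= 1, minprob_quantile > 0, minprob_quantile < 0.5,
            minprob_width > 0, mixed_threshold > 0, mixed_threshold < 1)
  structure(list(method = method, k = as.integer(k),
                 minprob_quantile = minprob_quantile,
                 minprob_width = minprob_width,
                 mixed_threshold = mixed_threshold,
                 seed = as.integer(seed)),
            class = "imputation_config")
}

#' Impute missing values
#'
#' Produces the complete "processed" matrix. Observed cells are never
#' altered. `minprob` draws each missing cell from a Gaussian centred at a
#' low quantile of its sample's observed values (probabilistic-minimum
#' imputation for left-censored, missing-not-at-random intensities);
#' `knn` replaces a missing cell by the unweighted mean of the k nearest
#' samples (Euclidean distance over mutually observed features) that
#' observed the feature; `mixed` applies KNN to features with missingness
#' strictly below `mixed_threshold` and MinProb otherwise.
#'
#' @param matrix an [expr_matrix()].
#' @param config an [imputation_config()].
#' @return A complete [expr_matrix()].
#' @export
impute_matrix <- function(matrix, config = imputation_config()) {
  stopifnot(inherits(matrix, "expr_matrix"),
            inherits(config, "imputation_config"))
  v <- matrix$values
  if (!anyNA(v)) return(matrix)
  if (any(rowSums(!is.na(v)) == 0)) {
    stop("sample with no observed values; cannot impute", call. = FALSE)
  }
  cols <- switch(config$method,
                 minprob = list(knn = integer(0), minprob = seq_len(ncol(v))),
                 knn = list(knn = seq_len(ncol(v)), minprob = integer(0)),
                 mixed = {
                   frac <- colMeans(is.na(v))
                   list(knn = which(frac < config$mixed_threshold),
                        minprob = which(frac >= config$mixed_threshold))
                 })
  out <- v
  if (length(cols$knn)) {
    out[, cols$knn] <- impute_knn_cols(v, cols$knn, config$k)
  }
  if (length(cols$minprob)) {
    out[, cols$minprob] <- impute_minprob_cols(v, cols$minprob, config)
  }
  # any cell left without a donor falls back to MinProb
  if (anyNA(out)) {
    left <- which(colSums(is.na(out)) > 0)
    fill <- impute_minprob_cols(out, left, config)
    out[, left] <- fill
  }
  expr_matrix(out, matrix$samples, matrix$features)
}

impute_knn_cols <- function(v, cols, k) {
  n <- nrow(v)
  if (k > n - 1) {
    stop("k = ", k, " larger than the ", n - 1, " available neighbours",
         call. = FALSE)
  }
  # pairwise sample distances over mutually observed features
  d <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(v[i, ]) & !is.na(v[j, ])
      if (any(shared)) {
        d[i, j] <- d[j, i] <- sqrt(mean((v[i, shared] - v[j, shared])^2))
      }
    }
  }
  sub <- v[, cols, drop = FALSE]
  for (s in seq_len(n)) {
    mi <- which(is.na(sub[s, ]))
    if (!length(mi)) next
    ord <- order(d[s, ])
    for (f in mi) {
      donors <- ord[!is.na(sub[ord, f]) & ord != s & is.finite(d[s, ord])]
      if (length(donors)) {
        use <- donors[seq_len(min(k, length(donors)))]
        sub[s, f] <- mean(sub[use, f])
      }
    }
  }
  sub
}

# one seeded standard normal per cell of the full matrix, so a cell's
# draw does not depend on which other cells are being imputed
impute_minprob_cols <- function(v, cols, config) {
  z <- withr_seed(config$seed,
                  matrix(stats::rnorm(length(v)), nrow(v), ncol(v)))
  loc <- apply(v, 1, function(x) {
    stats::quantile(x, config$minprob_quantile, na.rm = TRUE, names = FALSE)
  })
  sdv <- apply(v, 1, stats::sd, na.rm = TRUE)
  sdv[is.na(sdv) | sdv == 0] <- mean(sdv, na.rm = TRUE)
  sub <- v[, cols, drop = FALSE]
  zs <- z[, cols, drop = FALSE]
  mi <- is.na(sub)
  centre <- matrix(loc, nrow(sub), ncol(sub))
  width <- matrix(config$minprob_width * sdv, nrow(sub), ncol(sub))
  sub[mi] <- centre[mi] + width[mi] * zs[mi]
  sub
}

# evaluate expr under a local RNG state, restoring the caller's stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Prepare a matrix with the default pipeline order
#'
#' Fixed order: filter, then normalize, then impute.
#'
#' @param matrix an [expr_matrix()].
#' @param filter_mode,filter_threshold passed to [filter_features()]
#'   (default: drop features missing in more than half the samples).
#' @param normalization passed to [normalize_matrix()].
#' @param imputation an [imputation_config()].
#' @return List with the processed `matrix`, the `dropped` features and the
#'   parameter `config` snapshot.
#' @export
prepare_matrix <- function(matrix, filter_mode = "max_missing",
                           filter_threshold = 0.5,
                           normalization = "median",
                           imputation = imputation_config()) {
  flt <- filter_features(matrix, filter_mode, filter_threshold)
  norm <- normalize_matrix(flt$matrix, normalization)
  imp <- impute_matrix(norm, imputation)
  list(matrix = imp, dropped = flt$dropped,
       config = list(order = c("filter", "normalize", "impute"),
                     filter_mode = filter_mode,
                     filter_threshold = filter_threshold,
                     normalization = normalization,
                     imputation = unclass(imputation)))
}
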