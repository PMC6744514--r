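#' Outlier-trimmed per-cluster mean expression
#'
#' Per gene, cells whose expression is strictly above the gene's
#' `trim_pctile` quantile (type 7) are excluded from every cluster's mean.
#' The strict inequality keeps constant genes (whose quantile equals every
#' value) unchanged by trimming; `trim_pctile = 1` reproduces plain means.
#'
#' @param norm Normalized genes x cells matrix.
#' @param clusters Cluster label per cell.
#' @param trim_pctile Quantile (fraction) above which cells are dropped.
#' @return List: `means` (genes x clusters), `mass` (per gene, total included
#'   expression), `included` (per gene, number of included cells).
#' @export
trimmed_cluster_means <- function(norm, clusters, trim_pctile = 0.99) {
  X <- as.matrix(norm)
  cl <- sort(unique(clusters))
  means <- matrix(0, nrow(X), length(cl),
                  dimnames = list(rownames(X), cl))
  mass <- numeric(nrow(X))
  included <- integer(nrow(X))
  member <- lapply(cl, function(k) clusters == k)
  for (i in seq_len(nrow(X))) {
    v <- X[i, ]
    thr <- stats::quantile(v, trim_pctile, type = 7, names = FALSE)
    keep <- v <= thr
    mass[i] <- sum(v[keep])
    included[i] <- sum(keep)
    for (j in seq_along(cl)) {
      kc <- member[[j]] & keep
      means[i, j] <- if (any(kc)) mean(v[kc]) else 0
    }
  }
  list(means = means, mass = mass, included = included)
}

#' Entropy-based tests of cluster-specific expression
#'
#' Two criteria per gene, both likelihood-ratio (G) statistics against
#' uniformity referred to chi-squared with C - 1 degrees of freedom, where C
#' is the cluster count. Criterion i (non-uniform expression level): the
#' trimmed per-cluster means are converted to shares p_c and the deviance
#' from maximum entropy, 2 N_eff (ln C - H) with H the Shannon entropy of the
#' shares and N_eff the total trimmed expression mass, is tested. Criterion
#' ii (concentration of expressing cells): the per-cluster counts of
#' expressing cells are G-tested against an expectation proportional to
#' cluster sizes. A gene is tested only if expressed in at least `min_cells`
#' cells overall.
#'
#' @param norm Normalized genes x cells matrix.
#' @param clusters Cluster label per cell.
#' @param alpha_i,alpha_ii Significance cutoffs of the two criteria.
#' @param min_cells Minimum expressing cells for a gene to be tested.
#' @param trimmed Optional precomputed [trimmed_cluster_means()] result.
#' @return data.frame per gene: stat_i, p_i, pass_i, stat_ii, p_ii, pass_ii,
#'   tested.
#' @export
entropy_tests <- function(norm, clusters, alpha_i = 1e-5, alpha_ii = 1e-8,
                          min_cells = 10, trimmed = NULL) {
  cl <- sort(unique(clusters))
  C <- length(cl)
  if (C < 2) stop("need at least 2 clusters")
  if (is.null(trimmed)) trimmed <- trimmed_cluster_means(norm, clusters)
  X <- as.matrix(norm)
  sizes <- as.numeric(table(factor(clusters, levels = cl)))

  expressing <- vapply(cl, function(k) {
    rowSums(X[, clusters == k, drop = FALSE] > 0)
  }, numeric(nrow(X)))
  n_expr <- rowSums(expressing)

  res <- data.frame(
    gene = rownames(X), stat_i = NA_real_, p_i = NA_real_, pass_i = FALSE,
    stat_ii = NA_real_, p_ii = NA_real_, pass_ii = FALSE,
    tested = n_expr >= min_cells, stringsAsFactors = FALSE
  )
  for (i in which(res$tested)) {
    m <- trimmed$means[i, ]
    tot <- sum(m)
    if (tot > 0) {
      p <- m / tot
      H <- -sum(ifelse(p > 0, p * log(p), 0))
      g1 <- 2 * trimmed$mass[i] * (log(C) - H)
      res$stat_i[i] <- g1
      res$p_i[i] <- stats::pchisq(g1, df = C - 1, lower.tail = FALSE)
    }
    O <- expressing[i, ]
    E <- n_expr[i] * sizes / sum(sizes)
    g2 <- 2 * sum(ifelse(O > 0, O * log(O / E), 0))
    res$stat_ii[i] <- g2
    res$p_ii[i] <- stats::pchisq(g2, df = C - 1, lower.tail = FALSE)
  }
  res$pass_i <- !is.na(res$p_i) & res$p_i < alpha_i
  res$pass_ii <- !is.na(res$p_ii) & res$p_ii < alpha_ii
  res
}

#' Knee-point enrichment annotation of a cluster mean vector
#'
#' Sorts the per-cluster means increasingly and finds the split minimizing
#' the summed squared error of a separate least-squares line on each side
#' (exhaustive over all split points; ties resolved toward the rightmost
#' split). Clusters whose mean is strictly above the left segment's fitted
#' value at the knee are marked enriched. All-equal means yield no
#' enrichment; an exactly linear (non-constant) profile has no knee and falls
#' back to marking the single top cluster, flagged degenerate.
#'
#' @param means Numeric vector of per-cluster means (length >= 3).
#' @return List: `enriched` (logical, original order), `knee_value`, `split`
#'   (index into the sorted order, NA when degenerate), `degenerate`.
#' @examples
#' knee_annotation(c(1, 1, 1, 1, 10))$enriched   # only the outlier cluster
#' knee_annotation(c(0, 0, 5, 5))$enriched       # the two high clusters
#' @export
knee_annotation <- function(means) {
  C <- length(means)
  if (C < 3) stop("need at least 3 clusters for knee detection")
  if (stats::var(means) == 0) {
    return(list(enriched = rep(FALSE, C), knee_value = means[1],
                split = NA_integer_, degenerate = TRUE))
  }
  o <- order(means)
  y <- means[o]
  x <- seq_len(C)
  seg_fit <- function(idx) {
    if (length(idx) < 2) return(list(sse = 0, at = function(xx) y[idx]))
    f <- stats::lm.fit(cbind(1, x[idx]), y[idx])
    list(sse = sum(f$residuals^2),
         at = function(xx) f$coefficients[1] + f$coefficients[2] * xx)
  }
  one_line <- seg_fit(seq_len(C))$sse
  if (one_line < 1e-12 * sum((y - mean(y))^2)) {
    enr <- rep(FALSE, C)
    enr[which.max(means)] <- TRUE
    return(list(enriched = enr, knee_value = max(means),
                split = NA_integer_, degenerate = TRUE))
  }
  sse <- vapply(seq_len(C - 1), function(s) {
    seg_fit(seq_len(s))$sse + seg_fit((s + 1):C)$sse
  }, numeric(1))
  s <- max(which(sse == min(sse)))
  knee_value <- seg_fit(seq_len(s))$at(s)
  list(enriched = means > knee_value, knee_value = as.numeric(knee_value),
       split = s, degenerate = FALSE)
}

#' Gene x cluster enrichment calls
#'
#' Combines [entropy_tests()] and [knee_annotation()]: genes passing both
#' entropy criteria receive a knee-point annotation of their trimmed cluster
#' means; a passing gene with no cluster above the knee (possible only in
#' degenerate profiles) keeps its top cluster so every passing gene has at
#' least one enriched call.
#'
#' @param norm Normalized genes x cells matrix.
#' @param clusters Cluster label per cell.
#' @param ... Passed to [entropy_tests()].
#' @return List: `calls` (genes x clusters 0/1 integer matrix), `stats` (the
#'   entropy test table), `means` (trimmed cluster means).
#' @export
enrichment_calls <- function(norm, clusters, ...) {
  trimmed <- trimmed_cluster_means(norm, clusters)
  stats_tab <- entropy_tests(norm, clusters, trimmed = trimmed, ...)
  calls <- matrix(0L, nrow(trimmed$means), ncol(trimmed$means),
                  dimnames = dimnames(trimmed$means))
  for (i in which(stats_tab$pass_i & stats_tab$pass_ii)) {
    ka <- knee_annotation(trimmed$means[i, ])
    enr <- ka$enriched
    if (!any(enr)) enr[which.max(trimmed$means[i, ])] <- TRUE
    calls[i, ] <- as.integer(enr)
  }
  list(calls = calls, stats = stats_tab, means = trimmed$means)
}

#' Disease-level summaries of enrichment calls
#'
#' Per disease and cluster, the percentage of the disease's catalog genes
#' (those present in the expression gene universe) enriched in that cluster,
#' plus the percentage with any enriched call; optionally, per-cluster counts
#' of catalog genes passing differential-expression cutoffs.
#'
#' @param calls Genes x clusters 0/1 matrix from [enrichment_calls()].
#' @param catalog data.frame with `gene` and `disease` columns (e.g. from
#'   [read_gwas_catalog()]).
#' @param de_results Optional data.frame with `gene`, `cluster`, `pass`
#'   columns (e.g. from [de_between_timepoints()]`$results`).
#' @return List: `per_cluster` (disease x cluster percentage matrix, NA for
#'   diseases with no gene in the universe), `any_call` (named vector of
#'   percentages per disease), `missing` (catalog genes absent from the
#'   universe), `de_counts` (disease x cluster counts, if `de_results`).
#' @export
disease_summary <- function(calls, catalog, de_results = NULL) {
  diseases <- sort(unique(catalog$disease))
  cl <- colnames(calls)
  per_cluster <- matrix(NA_real_, length(diseases), length(cl),
                        dimnames = list(diseases, cl))
  any_call <- stats::setNames(rep(NA_real_, length(diseases)), diseases)
  missing <- setdiff(unique(catalog$gene), rownames(calls))
  de_counts <- if (!is.null(de_results)) {
    matrix(0L, length(diseases), length(cl), dimnames = list(diseases, cl))
  }
  for (dd in diseases) {
    genes <- intersect(unique(catalog$gene[catalog$disease == dd]),
                       rownames(calls))
    if (!length(genes)) next
    sub <- calls[genes, , drop = FALSE]
    per_cluster[dd, ] <- 100 * colSums(sub) / length(genes)
    any_call[dd] <- 100 * mean(rowSums(sub) > 0)
    if (!is.null(de_results)) {
      hit <- de_results[de_results$gene %in% genes & de_results$pass, ,
                        drop = FALSE]
      if (nrow(hit)) {
        tt <- table(factor(as.character(hit$cluster), levels = cl))
        de_counts[dd, ] <- as.integer(tt)
      }
    }
  }
  out <- list(per_cluster = per_cluster, any_call = any_call,
              missing = missing)
  if (!is.null(de_results)) out$de_counts <- de_counts
  out
}
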