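#' Biweight midcorrelation
#'
#' Robust correlation based on median-centered, biweighted observations
#' (tuning constant 9). Falls back to Pearson when either vector has zero
#' median absolute deviation.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  bw <- function(v) {
    m <- stats::median(v)
    s <- stats::mad(v, constant = 1)
    if (s == 0) return(NULL)
    u <- (v - m) / (9 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    a <- (v - m) * w
    a / sqrt(sum(a^2))
  }
  ax <- bw(x); ay <- bw(y)
  if (is.null(ax) || is.null(ay)) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    return(stats::cor(x, y))
  }
  sum(ax * ay)
}

#' Select variable genes shared between two datasets
#'
#' Per dataset, genes are binned into `n_bins` equal-frequency bins of mean
#' expression; the dispersion (variance / mean) is z-scored within each bin,
#' and genes with z above `z_cutoff` are ranked by z. The intersection of the
#' two datasets' top-`n_top` lists is returned. Bins with fewer than two genes
#' are merged with their left neighbor.
#'
#' @param normA,normB Normalized genes x cells matrices over a shared gene
#'   universe (same rownames); with `normB = NULL` the top list of `normA`
#'   alone is returned.
#' @param n_top Number of top variable genes per dataset before intersecting.
#' @param n_bins Mean-expression bins.
#' @param z_cutoff Within-bin dispersion z-score cutoff.
#' @return Character vector of gene names.
#' @export
select_variable_genes <- function(normA, normB = NULL, n_top = 2000,
                                  n_bins = 20, z_cutoff = 2) {
  if (!is.null(normB)) stopifnot(identical(rownames(normA), rownames(normB)))
  top_genes <- function(m) {
    # mean and dispersion on the de-logged (CPM) scale, as is standard for
    # UMI data; the dispersion is log-transformed before within-bin z-scoring
    e <- expm1(m)
    mu <- Matrix::rowMeans(e)
    v <- row_vars(e)
    disp <- log(ifelse(mu > 0, v / mu, NA))
    disp[!is.finite(disp)] <- min(disp[is.finite(disp)], 0)
    brk <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(mu, breaks = brk, include.lowest = TRUE, labels = FALSE)
    # merge undersized bins leftward so every bin can be z-scored
    repeat {
      sizes <- table(bin)
      small <- as.integer(names(sizes)[sizes < 2])
      if (!length(small)) break
      b <- small[1]
      bin[bin == b] <- if (b > min(bin)) max(bin[bin < b]) else min(bin[bin > b])
    }
    # robust within-bin z (median/MAD) so a handful of extreme-dispersion
    # genes does not mask the rest of the variable set
    z <- stats::ave(disp, bin, FUN = function(d) {
      s <- stats::mad(d)
      if (is.na(s) || s == 0) s <- stats::sd(d)
      if (is.na(s) || s == 0) rep(0, length(d)) else (d - stats::median(d)) / s
    })
    cand <- which(z > z_cutoff)
    cand <- cand[order(z[cand], decreasing = TRUE)]
    rownames(m)[utils::head(cand, n_top)]
  }
  if (is.null(normB)) return(top_genes(normA))
  intersect(top_genes(normA), top_genes(normB))
}

# row variances for sparse or dense matrices
row_vars <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
}

#' Canonical correlation co-embedding of two datasets with quantile alignment
#'
#' Computes canonical vectors from the SVD of the cross-product of the two
#' gene-standardized matrices restricted to `genes`, then aligns each
#' canonical vector across datasets by mapping every cell's within-dataset
#' rank quantile onto the pooled pre-alignment coordinate distribution.
#' Each vector's alignment quality is the biweight midcorrelation between its
#' pre- and post-alignment coordinates (both datasets pooled); vectors with
#' quality at or above `bicor_min` are selected.
#'
#' @param normA,normB Normalized genes x cells matrices, shared gene universe.
#' @param genes Genes to use (e.g. from [select_variable_genes()]).
#' @param n_cc Number of canonical vectors.
#' @param bicor_min Alignment-quality threshold for vector selection.
#' @return List of class `cca_embedding`: `coords` (pooled cells x n_cc,
#'   aligned), `coords_pre` (unaligned), `dataset` (factor "A"/"B" per row),
#'   `barcode`, `scores` (per-vector bicor), `mask` (selected vectors),
#'   `gene_loadings` (genes x n_cc), `genes`.
#' @export
cca_align <- function(normA, normB, genes, n_cc = 20, bicor_min = 0.15) {
  stopifnot(identical(rownames(normA), rownames(normB)))
  genes <- intersect(genes, rownames(normA))
  if (length(genes) < 2) stop("need at least 2 genes for CCA")
  n_cc <- min(n_cc, ncol(normA) - 1L, ncol(normB) - 1L, length(genes))
  Sa <- scale_rows(as.matrix(normA[genes, , drop = FALSE]))
  Sb <- scale_rows(as.matrix(normB[genes, , drop = FALSE]))
  K <- crossprod(Sa, Sb)
  sv <- svd(K, nu = n_cc, nv = n_cc)
  n_ok <- sum(sv$d[seq_len(n_cc)] > max(sv$d) * 1e-10)
  if (n_ok < n_cc) {
    message("rank-deficient cross-product: returning ", n_ok,
            " canonical vectors instead of ", n_cc)
    n_cc <- n_ok
  }
  # deterministic sign: largest-|loading| gene positive per vector
  U <- sv$u[, seq_len(n_cc), drop = FALSE]
  V <- sv$v[, seq_len(n_cc), drop = FALSE]
  load <- (Sa %*% U + Sb %*% V) / 2
  for (j in seq_len(n_cc)) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j]; load[, j] <- -load[, j] }
  }

  pre <- rbind(U, V)
  dataset <- factor(rep(c("A", "B"), c(nrow(U), nrow(V))))
  post <- pre
  for (j in seq_len(n_cc)) {
    pooled <- pre[, j]
    for (d in levels(dataset)) {
      idx <- which(dataset == d)
      r <- rank(pre[idx, j], ties.method = "average")
      p <- (r - 0.5) / length(idx)
      post[idx, j] <- stats::quantile(pooled, p, type = 7, names = FALSE)
    }
  }
  scores <- vapply(seq_len(n_cc), function(j) bicor(pre[, j], post[, j]),
                   numeric(1))
  structure(list(
    coords = post, coords_pre = pre, dataset = dataset,
    barcode = c(colnames(normA), colnames(normB)),
    scores = scores, mask = scores >= bicor_min,
    gene_loadings = load, genes = genes
  ), class = "cca_embedding")
}

# center and unit-scale rows; constant rows become zero
scale_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  s[s == 0] <- 1
  (m - mu) / s
}

#' PCA cell embedding for a single dataset
#'
#' @param norm Normalized genes x cells matrix.
#' @param n_pcs Number of components.
#' @return Cells x n_pcs coordinate matrix.
#' @export
pca_coords <- function(norm, n_pcs = 20) {
  pc <- stats::prcomp(t(as.matrix(norm)), center = TRUE, scale. = FALSE,
                      rank. = n_pcs)
  pc$x
}

#' Shared nearest-neighbor graph and Louvain clustering
#'
#' Builds a k-nearest-neighbor graph (Euclidean, each cell's neighbor set
#' includes itself), weights cell pairs by the Jaccard overlap of their
#' neighbor sets, and partitions the resulting SNN graph with Louvain
#' modularity optimization at the given resolution.
#'
#' @param coords Cells x dims embedding coordinates.
#' @param k Neighbors per cell (must be < number of cells).
#' @param resolution Louvain resolution parameter.
#' @param seed Seed for the community detection.
#' @return List: `snn` (sparse symmetric weight matrix, zero diagonal),
#'   `clusters` (integer labels 1..K), `k`, `resolution`.
#' @export
build_snn_and_cluster <- function(coords, k = 20, resolution = 1, seed = 0L) {
  n <- nrow(coords)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (", n, ")")
  snn <- snn_graph(coords, k)
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(cl))
  list(snn = snn, clusters = relabel_contiguous(labels), k = k,
       resolution = resolution)
}

# SNN from coordinates: Jaccard of kNN sets (self included)
snn_graph <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(nn)),
                            x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(A)
  idx <- Matrix::which(inter > 0, arr.ind = TRUE)
  jac <- inter@x / (2 * k - inter@x)
  snn <- inter
  snn@x <- jac
  Matrix::diag(snn) <- 0
  Matrix::drop0(snn)
}

relabel_contiguous <- function(labels) {
  as.integer(factor(labels, levels = sort(unique(labels))))
}

#' Iterative merge validation of clusters
#'
#' Repeatedly merges cluster pairs that are both highly connected in the SNN
#' graph and not separable by a linear SVM. Per iteration: the mean SNN weight
#' between every cluster pair (sum of cross-weights divided by the product of
#' cluster sizes) is computed; pairs at or above the `conn_pctile` quantile of all
#' current pairwise connectivities are candidates, visited in decreasing
#' connectivity order; the first candidate whose linear-SVM cross-validated
#' accuracy falls below `svm_acc` is merged and the loop restarts. Features
#' for the SVM are the union over the first `n_pcs` principal components of
#' the pair's cells of the top `n_genes` genes by absolute loading.
#'
#' @param norm Normalized genes x cells matrix (feature source).
#' @param clusters Integer labels per cell.
#' @param snn Sparse SNN weight matrix from [build_snn_and_cluster()].
#' @param conn_pctile Connectivity quantile defining merge candidates.
#' @param svm_acc Accuracy below which a pair is considered inseparable.
#' @param n_genes Genes kept per principal component.
#' @param n_pcs Principal components inspected.
#' @param cv_folds Stratified cross-validation folds (leave-one-out when a
#'   cluster has fewer than `2 * cv_folds` cells).
#' @param seed Seed for fold assignment.
#' @return List: `clusters` (relabeled contiguous), `decisions` (data.frame:
#'   iteration, cluster_a, cluster_b, connectivity, threshold, svm_accuracy,
#'   merged).
#' @export
validate_and_merge <- function(norm, clusters, snn, conn_pctile = 0.90,
                               svm_acc = 0.90, n_genes = 100, n_pcs = 5,
                               cv_folds = 5, seed = 0L) {
  labels <- as.integer(clusters)
  decisions <- list()
  set.seed(seed)

  # fold singletons into their most-connected neighbor first
  repeat {
    sizes <- table(labels)
    singles <- as.integer(names(sizes)[sizes == 1])
    if (!length(singles) || length(sizes) < 2) break
    s <- singles[1]
    conn <- cluster_connectivity(snn, labels)
    row <- conn[conn$a == s | conn$b == s, ]
    best <- row[which.max(row$connectivity), ]
    target <- if (best$a == s) best$b else best$a
    labels[labels == s] <- target
    decisions[[length(decisions) + 1L]] <- data.frame(
      iteration = 0L, cluster_a = min(s, target), cluster_b = max(s, target),
      connectivity = best$connectivity, threshold = NA_real_,
      svm_accuracy = NA_real_, merged = TRUE
    )
  }

  it <- 0L
  max_it <- length(unique(labels))
  while (length(unique(labels)) >= 2 && it < max_it) {
    it <- it + 1L
    conn <- cluster_connectivity(snn, labels)
    thr <- stats::quantile(conn$connectivity, conn_pctile, type = 7,
                           names = FALSE)
    # at the boundary the pair counts as a candidate; with two clusters the
    # single pair IS its own 90th percentile and must still be testable
    cand <- conn[conn$connectivity >= thr, , drop = FALSE]
    cand <- cand[order(-cand$connectivity, cand$a, cand$b), , drop = FALSE]
    merged_this_round <- FALSE
    for (i in seq_len(nrow(cand))) {
      a <- cand$a[i]; b <- cand$b[i]
      acc <- svm_pair_accuracy(norm, labels, a, b, n_genes = n_genes,
                               n_pcs = n_pcs, cv_folds = cv_folds)
      decisions[[length(decisions) + 1L]] <- data.frame(
        iteration = it, cluster_a = a, cluster_b = b,
        connectivity = cand$connectivity[i], threshold = thr,
        svm_accuracy = acc, merged = acc < svm_acc
      )
      if (acc < svm_acc) {
        labels[labels == b] <- a
        merged_this_round <- TRUE
        break
      }
    }
    if (!merged_this_round) break
  }
  list(clusters = relabel_contiguous(labels),
       decisions = if (length(decisions)) do.call(rbind, decisions) else
         data.frame(iteration = integer(), cluster_a = integer(),
                    cluster_b = integer(), connectivity = numeric(),
                    threshold = numeric(), svm_accuracy = numeric(),
                    merged = logical()))
}

# mean SNN weight between every cluster pair (zeros included in the mean)
cluster_connectivity <- function(snn, labels) {
  ids <- sort(unique(labels))
  M <- Matrix::sparseMatrix(i = seq_along(labels),
                            j = match(labels, ids), x = 1,
                            dims = c(length(labels), length(ids)))
  S <- as.matrix(Matrix::t(M) %*% snn %*% M)
  sizes <- as.numeric(table(factor(labels, levels = ids)))
  conn <- S / outer(sizes, sizes)
  pairs <- which(upper.tri(conn), arr.ind = TRUE)
  data.frame(a = ids[pairs[, 1]], b = ids[pairs[, 2]],
             connectivity = conn[pairs])
}

# cross-validated linear-SVM accuracy separating clusters a and b
svm_pair_accuracy <- function(norm, labels, a, b, n_genes = 100, n_pcs = 5,
                              cv_folds = 5) {
  cells <- which(labels %in% c(a, b))
  y <- factor(labels[cells])
  X <- as.matrix(norm[, cells, drop = FALSE])
  keep <- which(apply(X, 1, stats::sd) > 0)
  X <- X[keep, , drop = FALSE]
  n_pcs <- min(n_pcs, ncol(X) - 1L, nrow(X))
  pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE, rank. = n_pcs)
  feat_genes <- unique(unlist(lapply(seq_len(n_pcs), function(j) {
    rownames(pc$rotation)[order(abs(pc$rotation[, j]),
                                decreasing = TRUE)[seq_len(min(n_genes, nrow(X)))]]
  })))
  Xi <- t(X[feat_genes, , drop = FALSE])

  # shrink the fold count for small clusters; true leave-one-out only when
  # a cluster is too small even for 2-fold stratification
  n_min <- min(table(y))
  if (n_min < 2 * cv_folds) cv_folds <- max(2L, n_min %/% 2L)
  loo <- n_min < 4
  folds <- if (loo) seq_along(y) else {
    f <- integer(length(y))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      f[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    f
  }
  correct <- 0L
  for (f in unique(folds)) {
    test <- which(folds == f)
    train <- setdiff(seq_along(y), test)
    if (length(unique(y[train])) < 2) next
    fit <- e1071::svm(Xi[train, , drop = FALSE], y[train], kernel = "linear",
                      cost = 1, scale = FALSE)
    pred <- stats::predict(fit, Xi[test, , drop = FALSE])
    correct <- correct + sum(pred == y[test])
  }
  correct / length(y)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 for identical partitions (up to relabeling).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
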