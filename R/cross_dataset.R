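#' Area under the ROC curve of a score ranking
#'
#' @param pos Scores of positive instances.
#' @param neg Scores of negative instances.
#' @return AUROC in \[0, 1\]; ties handled by mid-ranks.
#' @export
auroc <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Neighbor-voting similarity between the clusters of two aligned datasets
#'
#' Builds a k-nearest-neighbor cell graph in the aligned canonical space over
#' the pooled cells, then scores every (A-cluster, B-cluster) pair by one
#' voting pass: membership votes seeded from the A cluster are propagated over
#' the row-normalized graph, and the B cluster is scored by the AUROC of its
#' cells' received votes among all B cells (x 100). Scores are symmetrized by
#' averaging both voting directions. Cluster pairs with a score at or above
#' `block_threshold` are grouped into blocks by single linkage; clusters whose
#' best cross-dataset score is below the threshold are flagged unique.
#'
#' @param embedding A [cca_align()] result over the pooled A + B cells.
#' @param labelsA,labelsB Cluster labels for the cells of datasets A and B, in
#'   the embedding's cell order.
#' @param k Neighbors per cell (reduced and logged if some cluster is
#'   smaller).
#' @param n_cc Number of leading aligned vectors to use.
#' @param block_threshold Similarity required to group two clusters.
#' @return List: `similarity` (A-clusters x B-clusters, \[0, 100\]), `blocks`
#'   (data.frame: dataset, cluster, block), `unique_a`, `unique_b` (logical
#'   vectors named by cluster).
#' @export
neighbor_voting_similarity <- function(embedding, labelsA, labelsB, k = 20,
                                       n_cc = 20, block_threshold = 90) {
  coords <- embedding$coords[, seq_len(min(n_cc, ncol(embedding$coords))),
                             drop = FALSE]
  nA <- length(labelsA); nB <- length(labelsB)
  stopifnot(nA + nB == nrow(coords))
  min_cl <- min(table(labelsA), table(labelsB))
  if (min_cl < k) {
    message("smallest cluster has ", min_cl, " cells; reducing k from ", k)
    k <- max(2L, min_cl)
  }
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  A <- (A + Matrix::t(A)) / 2           # symmetrize
  W <- A / Matrix::rowSums(A)           # row-normalized voting operator

  idxA <- seq_len(nA)
  idxB <- nA + seq_len(nB)
  clA <- sort(unique(labelsA)); clB <- sort(unique(labelsB))

  vote_scores <- function(seed_idx, seed_labels, target_idx, target_labels,
                          seed_cl, target_cl) {
    out <- matrix(NA_real_, length(seed_cl), length(target_cl),
                  dimnames = list(seed_cl, target_cl))
    for (si in seq_along(seed_cl)) {
      v <- numeric(n)
      v[seed_idx[seed_labels == seed_cl[si]]] <- 1
      votes <- as.numeric(W %*% v)[target_idx]
      for (ti in seq_along(target_cl)) {
        is_t <- target_labels == target_cl[ti]
        out[si, ti] <- auroc(votes[is_t], votes[!is_t])
      }
    }
    out
  }
  s_ab <- vote_scores(idxA, labelsA, idxB, labelsB, clA, clB)
  s_ba <- vote_scores(idxB, labelsB, idxA, labelsA, clB, clA)
  sim <- 100 * (s_ab + t(s_ba)) / 2

  ## single-linkage blocks over pairs at/above threshold
  nodes <- c(paste0("A:", clA), paste0("B:", clB))
  hits <- which(sim >= block_threshold, arr.ind = TRUE)
  edges <- if (nrow(hits)) {
    rbind(paste0("A:", clA[hits[, 1]]), paste0("B:", clB[hits[, 2]]))
  } else matrix(character(), 2, 0)
  g <- igraph::graph_from_edgelist(t(edges), directed = FALSE)
  g <- igraph::add_vertices(g, sum(!nodes %in% igraph::V(g)$name),
                            name = nodes[!nodes %in% igraph::V(g)$name])
  comp <- igraph::components(g)$membership
  blocks <- data.frame(
    dataset = substr(names(comp), 1, 1),
    cluster = sub("^[AB]:", "", names(comp)),
    block = as.integer(comp), stringsAsFactors = FALSE
  )
  list(
    similarity = sim,
    blocks = blocks[order(blocks$block, blocks$dataset, blocks$cluster), ],
    unique_a = stats::setNames(apply(sim, 1, max) < block_threshold,
                               rownames(sim)),
    unique_b = stats::setNames(apply(sim, 2, max) < block_threshold,
                               colnames(sim))
  )
}

#' Bootstrapped Spearman-correlation label transfer
#'
#' Selects the union of the top `top_genes_per_cc` genes by absolute loading
#' from each of the first `n_cc` canonical vectors, then runs `n_boot`
#' bootstrap iterations: each draws a bootstrap resample of every reference
#' cluster's cells (from which the cluster centroid, the mean normalized
#' expression, is formed), samples `gene_frac` of the gene set without
#' replacement, computes the Spearman correlation between every query cell
#' and every centroid over the sampled genes, and records the
#' best-correlated cluster (ties broken toward the lowest cluster index; a
#' query cell constant over the sampled genes abstains for that iteration).
#' A cell is assigned the cluster it won in more than `assign_prob` of the
#' iterations, else left unassigned. Cells with genuine cluster identity win
#' the same cluster in nearly every resample; cells without it flip between
#' near-tied clusters and stay unassigned.
#'
#' @param ref_norm Reference normalized genes x cells matrix.
#' @param ref_clusters Reference cluster label per cell.
#' @param embedding A [cca_align()] result supplying `gene_loadings`.
#' @param query_norm Query normalized matrix over a shared gene universe.
#' @param n_boot Bootstrap iterations.
#' @param gene_frac Fraction of genes sampled per iteration.
#' @param top_genes_per_cc,n_cc Gene-set construction parameters.
#' @param assign_prob Winning-probability threshold for assignment.
#' @param centroid_cells Cells drawn (without replacement, capped at the
#'   cluster size) from each reference cluster per bootstrap to form its
#'   centroid. Small draws approximate correlating against individual
#'   reference cells (noisy, so signal-free query cells flip between
#'   near-tied clusters and stay unassigned) while keeping the centroid's
#'   robustness; `Inf` uses every cell and a bootstrap resample instead.
#' @param seed Seed for the bootstrap samples.
#' @return List: `probability` (query cells x reference clusters, win
#'   fractions), `label` (assigned cluster or NA), `assigned` (logical),
#'   `unassigned_frac`, `genes` (the gene set).
#' @export
bootstrap_label_transfer <- function(ref_norm, ref_clusters, embedding,
                                     query_norm, n_boot = 100,
                                     gene_frac = 0.8, top_genes_per_cc = 100,
                                     n_cc = 20, assign_prob = 0.5,
                                     centroid_cells = 10, seed = 1L) {
  L <- embedding$gene_loadings
  n_cc <- min(n_cc, ncol(L))
  gene_set <- unique(unlist(lapply(seq_len(n_cc), function(j) {
    rownames(L)[order(abs(L[, j]), decreasing = TRUE)[
      seq_len(min(top_genes_per_cc, nrow(L)))]]
  })))
  gene_set <- intersect(gene_set, intersect(rownames(ref_norm),
                                            rownames(query_norm)))
  if (length(gene_set) < 5) stop("gene set too small for transfer")

  cl <- sort(unique(ref_clusters))
  R <- as.matrix(ref_norm[gene_set, , drop = FALSE])
  members <- lapply(cl, function(k) which(ref_clusters == k))
  Q <- as.matrix(query_norm[gene_set, , drop = FALSE])
  nq <- ncol(Q)
  wins <- matrix(0L, nq, length(cl),
                 dimnames = list(colnames(query_norm), cl))
  n_votes <- integer(nq)

  set.seed(seed)
  m <- floor(gene_frac * length(gene_set))
  for (b in seq_len(n_boot)) {
    gi <- sample(length(gene_set), m)
    centroids <- vapply(members, function(idx) {
      take <- if (is.finite(centroid_cells) && centroid_cells < length(idx)) {
        sample(idx, centroid_cells)
      } else {
        sample(idx, length(idx), replace = TRUE)
      }
      rowMeans(R[gi, take, drop = FALSE])
    }, numeric(m))
    Qr <- apply(Q[gi, , drop = FALSE], 2, rank)
    Cr <- apply(centroids, 2, rank)
    ok <- apply(Q[gi, , drop = FALSE], 2, function(v) stats::sd(v) > 0)
    if (!any(ok)) next
    rho <- suppressWarnings(stats::cor(Qr[, ok, drop = FALSE], Cr))
    best <- apply(rho, 1, which.max)   # which.max takes the first on ties
    wins[cbind(which(ok), best)] <- wins[cbind(which(ok), best)] + 1L
    n_votes[ok] <- n_votes[ok] + 1L
  }
  prob <- wins / n_boot
  best <- apply(prob, 1, which.max)
  best_p <- prob[cbind(seq_len(nq), best)]
  assigned <- best_p > assign_prob
  list(
    probability = prob,
    label = ifelse(assigned, cl[best], NA),
    assigned = assigned,
    unassigned_frac = mean(!assigned),
    genes = gene_set
  )
}
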