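#' Simulation configuration for the synthetic UMI generator
#'
#' Defaults emulate the structure of droplet scRNA-seq of mouse prefrontal
#' cortex: a small number of discrete cell types with planted marker genes,
#' neuronal cells sequenced roughly 3x deeper than non-neuronal cells,
#' mitochondrial and ribosomal gene blocks with recognizable names, a small
#' fraction of doublets and low-quality cells, and (optionally) two
#' conditions with planted differentially expressed genes. Expression is
#' generated by a two-phase (off/on) process: a gene in a cell is either off
#' (Poisson background with rate well below one count) or on (Poisson with a
#' lognormal rate scaled by cell depth), and the on-probability follows a
#' logistic dropout-mean relation.
#'
#' @param n_clusters Number of planted cell types.
#' @param cells_per_cluster Cells per type.
#' @param n_genes Total genes, including mito/ribo/class-marker blocks.
#' @param markers_per_cluster Genes upregulated in exactly one cluster.
#' @param marker_fold Fold elevation of a marker in its own cluster (> 1).
#' @param neuronal_clusters Indices of clusters treated as neuronal; they
#'   receive `depth_neuronal` and express the pan-neuronal class markers.
#' @param depth_neuronal,depth_non_neuronal Mean UMI per cell by class.
#' @param pct_mito_mean Target mean fraction of UMI from `mt-*` genes.
#' @param n_mito_genes,n_ribo_genes Sizes of the named mito / ribo blocks.
#' @param doublet_rate,lowq_rate Fractions of doublet and low-quality cells.
#' @param n_conditions 1 or 2; with 2, cells split evenly within cluster.
#' @param samples_per_condition Biological replicates per condition (the
#'   `sample` covariate of the NB GLM).
#' @param de_genes_per_cluster,de_fold Planted condition-2 DE genes per
#'   cluster and their fold (half up, half down).
#' @param de_mode How condition DE is expressed: `"coupled"` (fold applied to
#'   expression; on-probability follows through the dropout relation),
#'   `"magnitude"` (on-state rate shifts, on-probability held at baseline) or
#'   `"fraction"` (on-probability shifts, on-state rate unchanged).
#' @param phase2_mu,phase2_sigma Lognormal (meanlog, sdlog) of baseline gene
#'   relative abundance in the on state.
#' @param dropout_logit_intercept,dropout_logit_slope Logistic coefficients of
#'   the on-probability against log expected on-state count.
#' @param bg_rate Phase-I (off) Poisson background rate per gene-cell at the
#'   class mean depth; must be well below 1.
#' @param on_noise_sd Lognormal sd of per-gene-cell rate jitter in the on
#'   state (produces NB-like overdispersion).
#' @param depth_sd_log Lognormal sd of per-cell depth around the class mean.
#' @param seed Integer seed; the whole draw is reproducible from it.
#' @return A classed list (`sim_config`).
#' @export
sim_config <- function(n_clusters = 8,
                       cells_per_cluster = 200,
                       n_genes = 3000,
                       markers_per_cluster = 30,
                       marker_fold = 4,
                       neuronal_clusters = 1:4,
                       depth_neuronal = 13000,
                       depth_non_neuronal = 3800,
                       pct_mito_mean = 0.04,
                       n_mito_genes = 10,
                       n_ribo_genes = 20,
                       doublet_rate = 0.01,
                       lowq_rate = 0.02,
                       n_conditions = 1,
                       samples_per_condition = 2,
                       de_genes_per_cluster = 0,
                       de_fold = 2,
                       de_mode = c("coupled", "magnitude", "fraction"),
                       phase2_mu = 0,
                       phase2_sigma = 1,
                       dropout_logit_intercept = 0.5,
                       dropout_logit_slope = 1.2,
                       bg_rate = 0.02,
                       on_noise_sd = 0.3,
                       depth_sd_log = 0.25,
                       seed = 1L) {
  cfg <- list(
    n_clusters = n_clusters, cells_per_cluster = cells_per_cluster,
    n_genes = n_genes, markers_per_cluster = markers_per_cluster,
    marker_fold = marker_fold, neuronal_clusters = neuronal_clusters,
    depth_neuronal = depth_neuronal, depth_non_neuronal = depth_non_neuronal,
    pct_mito_mean = pct_mito_mean, n_mito_genes = n_mito_genes,
    n_ribo_genes = n_ribo_genes, doublet_rate = doublet_rate,
    lowq_rate = lowq_rate, n_conditions = n_conditions,
    samples_per_condition = samples_per_condition,
    de_genes_per_cluster = de_genes_per_cluster, de_fold = de_fold,
    de_mode = match.arg(de_mode),
    phase2_mu = phase2_mu, phase2_sigma = phase2_sigma,
    dropout_logit_intercept = dropout_logit_intercept,
    dropout_logit_slope = dropout_logit_slope,
    bg_rate = bg_rate, on_noise_sd = on_noise_sd,
    depth_sd_log = depth_sd_log, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_clusters >= 1, cfg$cells_per_cluster >= 1, cfg$n_genes >= 1,
    cfg$marker_fold > 1, cfg$de_fold >= 1,
    cfg$depth_neuronal > 0, cfg$depth_non_neuronal > 0,
    cfg$doublet_rate >= 0, cfg$doublet_rate <= 1,
    cfg$lowq_rate >= 0, cfg$lowq_rate <= 1,
    cfg$pct_mito_mean >= 0, cfg$pct_mito_mean < 1,
    cfg$n_conditions %in% c(1L, 2L)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Pan-neuronal class marker gene names used by the generator
#' @return Character vector.
#' @export
neuronal_class_markers <- function() c("Snap25", "Syt1", "Rbfox3", "Stmn2", "Thy1")

#' Generate a synthetic UMI dataset with known ground truth
#'
#' Draws a genes x cells sparse count matrix under the two-phase model
#' described in [sim_config()], together with per-cell and per-gene ground
#' truth and the latent on/off phase of every gene-cell pair.
#'
#' @param config A [sim_config()].
#' @return List with elements:
#'   * `counts`: `dgCMatrix`, genes x cells, UMI counts;
#'   * `cell_truth`: data.frame (barcode, cluster, class, condition, sample,
#'     is_doublet, is_lowq, depth);
#'   * `gene_truth`: data.frame (gene, marker_of, de_in, de_direction,
#'     family);
#'   * `phase`: `lgCMatrix`, TRUE where the gene is in the on state (doublet
#'     and low-quality columns keep their pre-corruption phase);
#'   * `config`: the config used.
#' @examples
#' sim <- generate_dataset(sim_config(n_clusters = 2, cells_per_cluster = 20,
#'                                    n_genes = 100, neuronal_clusters = 1,
#'                                    seed = 1))
#' dim(sim$counts)
#' table(sim$cell_truth$class)
#' @export
generate_dataset <- function(config = sim_config()) {
  cfg <- config
  n_special <- cfg$n_mito_genes + cfg$n_ribo_genes + length(neuronal_class_markers())
  n_planted <- cfg$markers_per_cluster * cfg$n_clusters +
    cfg$de_genes_per_cluster * cfg$n_clusters * (cfg$n_conditions - 1L)
  if (n_special + n_planted > cfg$n_genes) {
    stop("capacity error: ", n_special + n_planted,
         " special/planted genes exceed n_genes = ", cfg$n_genes)
  }
  set.seed(cfg$seed)

  G <- cfg$n_genes
  K <- cfg$n_clusters
  n_cells <- K * cfg$cells_per_cluster

  ## gene naming: mito, ribo, class markers, cluster markers, DE genes, rest
  mito <- if (cfg$n_mito_genes) paste0("mt-", seq_len(cfg$n_mito_genes)) else character()
  ribo <- if (cfg$n_ribo_genes) {
    half <- ceiling(cfg$n_ribo_genes / 2)
    c(paste0("Rps", seq_len(half)),
      paste0("Rpl", seq_len(cfg$n_ribo_genes - half)))
  } else character()
  class_mk <- neuronal_class_markers()
  gene_truth <- data.frame(
    gene = character(G), marker_of = NA_integer_, de_in = NA_integer_,
    de_direction = NA_character_, family = "none", stringsAsFactors = FALSE
  )
  nm <- c(mito, ribo, class_mk)
  gene_truth$family[seq_along(mito)] <- "mito"
  gene_truth$family[cfg$n_mito_genes + seq_along(ribo)] <- "ribo"
  gene_truth$family[cfg$n_mito_genes + cfg$n_ribo_genes + seq_along(class_mk)] <- "class_marker"
  idx <- length(nm)
  marker_idx <- matrix(0L, cfg$markers_per_cluster, K)
  for (k in seq_len(K)) {
    ii <- idx + seq_len(cfg$markers_per_cluster)
    marker_idx[, k] <- ii
    nm <- c(nm, sprintf("Mk%d-%d", k, seq_len(cfg$markers_per_cluster)))
    gene_truth$marker_of[ii] <- k
    idx <- idx + cfg$markers_per_cluster
  }
  if (cfg$n_conditions == 2L && cfg$de_genes_per_cluster > 0) {
    for (k in seq_len(K)) {
      ii <- idx + seq_len(cfg$de_genes_per_cluster)
      nm <- c(nm, sprintf("De%d-%d", k, seq_len(cfg$de_genes_per_cluster)))
      gene_truth$de_in[ii] <- k
      n_up <- ceiling(cfg$de_genes_per_cluster / 2)
      gene_truth$de_direction[ii] <- rep(c("up", "down"),
                                         c(n_up, cfg$de_genes_per_cluster - n_up))
      idx <- idx + cfg$de_genes_per_cluster
    }
  }
  nm <- c(nm, sprintf("Gene%d", seq_len(G - length(nm))))
  gene_truth$gene <- nm

  ## baseline relative abundance; mito block tuned so its share of expression
  ## is pct_mito_mean on average, ribo given a modestly high constant level
  theta <- stats::rlnorm(G, meanlog = cfg$phase2_mu, sdlog = cfg$phase2_sigma)
  is_mito <- gene_truth$family == "mito"
  is_ribo <- gene_truth$family == "ribo"
  if (any(is_ribo)) theta[is_ribo] <- stats::median(theta) * 4
  if (any(is_mito)) {
    s_rest <- sum(theta[!is_mito])
    theta[is_mito] <- cfg$pct_mito_mean * s_rest /
      ((1 - cfg$pct_mito_mean) * sum(is_mito))
  }

  ## cell-level truth
  cluster <- rep(seq_len(K), each = cfg$cells_per_cluster)
  cls <- ifelse(cluster %in% cfg$neuronal_clusters, "neuronal", "non_neuronal")
  condition <- if (cfg$n_conditions == 2L) {
    unlist(lapply(seq_len(K), function(k) {
      rep_len(c(1L, 2L), cfg$cells_per_cluster)
    }))
  } else rep(1L, n_cells)
  sample_id <- paste0("cond", condition, "_rep",
                      (seq_len(n_cells) %% cfg$samples_per_condition) + 1L)
  depth_mean <- ifelse(cls == "neuronal", cfg$depth_neuronal, cfg$depth_non_neuronal)
  depth <- stats::rlnorm(n_cells, log(depth_mean) - cfg$depth_sd_log^2 / 2,
                         cfg$depth_sd_log)

  ## per-cluster/condition expected profiles and two-phase draw
  counts <- matrix(0L, G, n_cells)
  phase <- matrix(FALSE, G, n_cells)
  for (k in seq_len(K)) {
    fold_base <- rep(1, G)
    fold_base[marker_idx[, k]] <- cfg$marker_fold
    if (cls[match(k, cluster)] == "neuronal") {
      fold_base[gene_truth$family == "class_marker"] <- cfg$marker_fold
    }
    for (tt in seq_len(cfg$n_conditions)) {
      cells <- which(cluster == k & condition == tt)
      if (!length(cells)) next
      fold_expr <- fold_base     # drives the on-state rate
      fold_on <- fold_base       # drives the on-probability
      de_here <- which(gene_truth$de_in %in% k)
      if (tt == 2L && length(de_here)) {
        f <- ifelse(gene_truth$de_direction[de_here] == "up",
                    cfg$de_fold, 1 / cfg$de_fold)
        if (cfg$de_mode %in% c("coupled", "magnitude")) {
          fold_expr[de_here] <- fold_expr[de_here] * f
        }
        if (cfg$de_mode %in% c("coupled", "fraction")) {
          fold_on[de_here] <- fold_on[de_here] * f
        }
      }
      p_expr <- theta * fold_expr
      p_expr <- p_expr / sum(p_expr)
      p_on_ref <- theta * fold_on
      p_on_ref <- p_on_ref / sum(p_on_ref)
      for (c_i in cells) {
        mu_on <- depth[c_i] * p_expr
        mu_ref <- depth[c_i] * p_on_ref
        p_on <- stats::plogis(cfg$dropout_logit_intercept +
                                cfg$dropout_logit_slope * log(mu_ref))
        on <- stats::runif(G) < p_on
        lam <- ifelse(on,
                      mu_on * exp(stats::rnorm(G, -cfg$on_noise_sd^2 / 2,
                                               cfg$on_noise_sd)),
                      cfg$bg_rate * depth[c_i] / mean(depth_mean))
        counts[, c_i] <- stats::rpois(G, lam)
        phase[, c_i] <- on
      }
    }
  }

  ## doublets: add a second random cell's counts
  is_doublet <- rep(FALSE, n_cells)
  n_dbl <- round(cfg$doublet_rate * n_cells)
  if (n_dbl > 0) {
    dbl <- sample(n_cells, n_dbl)
    partner <- sample(setdiff(seq_len(n_cells), dbl), n_dbl, replace = TRUE)
    counts[, dbl] <- counts[, dbl] + counts[, partner]
    is_doublet[dbl] <- TRUE
  }

  ## low-quality cells: half get mito contamination above 10%, half are
  ## thinned so their detected-gene count falls below the class floor
  is_lowq <- rep(FALSE, n_cells)
  n_lowq <- round(cfg$lowq_rate * n_cells)
  if (n_lowq > 0) {
    lq <- sample(which(!is_doublet), n_lowq)
    is_lowq[lq] <- TRUE
    mito_rows <- which(is_mito)
    for (j in seq_along(lq)) {
      c_i <- lq[j]
      if (j %% 2L == 1L && length(mito_rows)) {
        tot <- sum(counts[, c_i])
        target <- stats::runif(1, 0.15, 0.30)
        add <- stats::rpois(1, tot * target / (1 - target))
        counts[mito_rows, c_i] <- counts[mito_rows, c_i] +
          stats::rmultinom(1, add, rep(1, length(mito_rows)))[, 1]
      } else {
        counts[, c_i] <- stats::rbinom(G, counts[, c_i], 0.15)
      }
    }
  }

  barcodes <- sprintf("cell_%04d", seq_len(n_cells))
  dimnames(counts) <- list(nm, barcodes)
  out_counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  phase_m <- methods::as(Matrix::Matrix(phase, sparse = TRUE), "CsparseMatrix")
  dimnames(phase_m) <- dimnames(out_counts)

  list(
    counts = out_counts,
    cell_truth = data.frame(
      barcode = barcodes, cluster = cluster, class = cls,
      condition = condition, sample = sample_id,
      is_doublet = is_doublet, is_lowq = is_lowq,
      depth = depth, stringsAsFactors = FALSE
    ),
    gene_truth = gene_truth,
    phase = phase_m,
    config = cfg
  )
}
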