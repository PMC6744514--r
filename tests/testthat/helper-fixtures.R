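# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small 4-type dataset, clean (no doublets / low-quality cells)
small_clean_sim <- function() {
  fixture("small_clean", function() {
    generate_dataset(sim_config(
      n_clusters = 4, cells_per_cluster = 80, n_genes = 800,
      neuronal_clusters = 1:2, doublet_rate = 0, lowq_rate = 0, seed = 101
    ))
  })
}

# two-condition 4-type dataset with an aligned CCA embedding
small_cca_sim <- function() {
  fixture("small_cca", function() {
    sim <- generate_dataset(sim_config(
      n_clusters = 4, cells_per_cluster = 100, n_genes = 800,
      neuronal_clusters = 1:2, doublet_rate = 0, lowq_rate = 0,
      n_conditions = 2, seed = 102
    ))
    norm <- normalize_log_cpm(sim$counts)
    a <- sim$cell_truth$condition == 1
    genes <- select_variable_genes(norm[, a], norm[, !a])
    emb <- cca_align(norm[, a], norm[, !a], genes, n_cc = 15)
    list(sim = sim, norm = norm, is_a = a, genes = genes, emb = emb)
  })
}

# two well-separated Gaussian blobs in 5 dimensions
two_blob_coords <- function(n_per = 100, sep = 15, seed = 7) {
  set.seed(seed)
  rbind(
    matrix(stats::rnorm(n_per * 5), n_per, 5),
    matrix(stats::rnorm(n_per * 5, mean = sep / sqrt(5)), n_per, 5)
  )
}

# normalized matrix with two populations separated by planted markers
marker_pair_norm <- function(n_per = 100, n_genes = 300, n_markers = 50,
                             fold = 4, seed = 9) {
  set.seed(seed)
  depth <- 4000
  base <- stats::rlnorm(n_genes, 0, 1)
  counts <- matrix(0L, n_genes, 2 * n_per)
  for (i in seq_len(2 * n_per)) {
    f <- rep(1, n_genes)
    if (i > n_per) f[seq_len(n_markers)] <- fold
    p <- base * f
    counts[, i] <- stats::rpois(n_genes, depth * p / sum(p))
  }
  dimnames(counts) <- list(paste0("g", seq_len(n_genes)),
                           paste0("c", seq_len(2 * n_per)))
  normalize_log_cpm(Matrix::Matrix(counts, sparse = TRUE))
}

# compact two-phase dataset with its model fit
two_phase_fixture <- function() {
  fixture("two_phase_fit", function() {
    sim <- generate_dataset(sim_config(
      n_clusters = 2, cells_per_cluster = 150, n_genes = 120,
      markers_per_cluster = 5, neuronal_clusters = 1,
      depth_neuronal = 3000, depth_non_neuronal = 3000,
      n_mito_genes = 3, n_ribo_genes = 4,
      doublet_rate = 0, lowq_rate = 0, seed = 201
    ))
    list(sim = sim, fit = fit_two_phase(sim$counts))
  })
}

# study-scale dataset (8 planted types, 200 cells each, 3000 genes,
# 30 markers per type at 4-fold, two batches) run through the pipeline
full_pipeline_run <- function() {
  fixture("full_run", function() {
    outdir <- file.path(tempdir(), "scortex_full_run")
    cfg <- sim_config(n_conditions = 2, de_genes_per_cluster = 10, seed = 401)
    res <- run_pipeline(cfg, outdir, seed = 4,
                        params = pipeline_params(run_markers = FALSE,
                                                 run_twophase = FALSE,
                                                 run_transfer = FALSE))
    list(cfg = cfg, res = res,
         truth = res$truth$cell_truth[
           match(res$barcodes, res$truth$cell_truth$barcode), ])
  })
}

# tiny deterministic counts for IO round trips
toy_counts <- function() {
  m <- Matrix::Matrix(matrix(c(0, 1, 2, 3, 0, 4), nrow = 3,
                             dimnames = list(c("Gapdh", "Actb", "mt-1"),
                                             c("bc1", "bc2"))), sparse = TRUE)
  methods::as(m, "CsparseMatrix")
}
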