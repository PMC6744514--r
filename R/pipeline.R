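#' Default stage parameters for the end-to-end pipeline
#'
#' Every threshold of the analysis in one place, echoed into the run
#' manifest. Defaults are the study's settings: mito fraction cutoff 0.10,
#' doublet cut at the 99th percentile of detected genes, gene floors 800
#' (non-neuronal) / 1500 (neuronal), top-2000 variable genes, 20 canonical
#' vectors with the first 12 used for broad clustering, bicor >= 0.15 vector
#' selection, k = 20 SNN neighbors, Louvain resolution 2 for the high-res
#' pass, merge validation at the 0.90 connectivity quantile and 0.90 SVM
#' accuracy with the top 100 genes from each of the first 5 PCs, and label
#' transfer with 100 bootstraps over 80% gene resamples and a 0.5 assignment
#' rule.
#'
#' @param ... Overrides of the defaults (unknown names are rejected).
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    mito_max = 0.10, doublet_pctile = 0.99,
    min_genes_non_neuronal = 800, min_genes_neuronal = 1500,
    n_top_var = 2000, n_cc = 20, n_cc_broad = 12, bicor_min = 0.15,
    snn_k = 20, resolution_broad = 1, resolution_highres = 2,
    conn_pctile = 0.90, svm_acc = 0.90, svm_n_genes = 100, svm_n_pcs = 5,
    marker_min_frac = 0.1, de_fc = 1.5, de_q = 0.05,
    transfer_n_boot = 100, transfer_gene_frac = 0.8,
    transfer_top_genes = 100, transfer_assign_prob = 0.5,
    enrich_alpha_i = 1e-5, enrich_alpha_ii = 1e-8,
    phase_bg_cap = 2, phase_fc = 1.5, phase_fdr = 0.05,
    run_markers = TRUE, run_transfer = TRUE, run_twophase = TRUE
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  p
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the pipeline end-to-end and write its artifacts
#'
#' Orchestrates: synthetic-data generation (or a supplied count matrix) ->
#' two-pass class-aware QC -> normalization and mito/ribo gene removal ->
#' embedding (CCA alignment across the two conditions when present, PCA
#' otherwise) -> SNN/Louvain clustering -> iterative merge validation ->
#' cluster markers -> bootstrapped label transfer of the second condition
#' onto the first (when two conditions are present) -> entropy/knee
#' enrichment of an optional gene catalog -> two-phase differential
#' expression across conditions. Every stage writes TSV artifacts under
#' `outdir` and its parameters into `manifest.json`; given the same inputs
#' and seed, artifacts are byte-identical across runs.
#'
#' The QC gene floors are applied in two passes, because the class-specific
#' floors need a class that only exists after clustering: pass 1 filters at
#' the non-neuronal floor, clusters broadly and scores clusters with
#' pan-neuronal markers; pass 2 applies the neuronal floor to cells of
#' neuronal clusters.
#'
#' @param input A [sim_config()] (data are generated) or a list with
#'   `counts` (genes x cells) and `cell_meta` (data.frame with at least a
#'   `condition` column; optional `sample`).
#' @param outdir Output directory, created if needed.
#' @param seed Global seed; all stage seeds derive from it.
#' @param params A [pipeline_params()] list.
#' @param catalog Optional gene-disease catalog data.frame (gene, disease)
#'   for the enrichment stage; skipped when `NULL`.
#' @return Invisibly, a list with the main in-memory results (qc, clusters,
#'   merge decisions, markers, transfer, enrichment, two-phase DE, manifest).
#' @export
run_pipeline <- function(input, outdir, seed = 1L, params = pipeline_params(),
                         catalog = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "scortex",
                   version = as.character(utils::packageVersion("scortex")),
                   seed = seed, params = params, stages = list())
  truth <- NULL

  ## stage: input ----------------------------------------------------------
  if (inherits(input, "sim_config")) {
    sim <- generate_dataset(input)
    counts <- sim$counts
    cell_meta <- sim$cell_truth
    truth <- sim
    write_tsv(sim$cell_truth, file.path(outdir, "ground_truth_cells.tsv"))
    write_tsv(sim$gene_truth, file.path(outdir, "ground_truth_genes.tsv"))
    manifest$stages$simulate <- list(n_genes = nrow(counts),
                                     n_cells = ncol(counts))
  } else {
    counts <- input$counts
    cell_meta <- input$cell_meta
    manifest$stages$input <- list(n_genes = nrow(counts),
                                  n_cells = ncol(counts))
  }
  if (is.null(cell_meta$condition)) cell_meta$condition <- 1L

  ## stage: two-pass QC ----------------------------------------------------
  qc <- compute_qc(counts)
  pass1 <- filter_cells(counts, qc, mito_max = params$mito_max,
                        doublet_pctile = params$doublet_pctile,
                        min_genes_non_neuronal = params$min_genes_non_neuronal,
                        min_genes_neuronal = params$min_genes_non_neuronal)
  kept1 <- colnames(pass1$counts)
  norm1 <- normalize_log_cpm(pass1$counts)
  meta1 <- cell_meta[match(kept1, cell_meta$barcode), , drop = FALSE]

  coords1 <- embed_cells(norm1, meta1$condition, params,
                         n_use = params$n_cc_broad, seed = seed)
  broad <- build_snn_and_cluster(coords1$coords, k = params$snn_k,
                                 resolution = params$resolution_broad,
                                 seed = seed + 1L)
  broad_class <- classify_broad_class(norm1, broad$clusters)
  qc2 <- qc[match(kept1, qc$barcode), , drop = FALSE]
  qc2$broad_class <- broad_class
  pass2 <- filter_cells(pass1$counts, qc2, mito_max = params$mito_max,
                        doublet_pctile = 1,   # doublet cut already applied
                        min_genes_non_neuronal = params$min_genes_non_neuronal,
                        min_genes_neuronal = params$min_genes_neuronal)
  removed <- rbind(pass1$removed, pass2$removed)
  write_tsv(removed, file.path(outdir, "qc_removed_cells.tsv"))
  manifest$stages$qc <- list(
    pass1_thresholds = pass1$thresholds, pass2_thresholds = pass2$thresholds,
    n_removed = nrow(removed), n_kept = ncol(pass2$counts)
  )

  ## stage: normalize ------------------------------------------------------
  clean <- remove_gene_families(pass2$counts)
  norm <- normalize_log_cpm(clean)
  kept <- colnames(norm)
  meta <- cell_meta[match(kept, cell_meta$barcode), , drop = FALSE]

  ## stage: embed + high-res cluster + merge validation --------------------
  emb <- embed_cells(norm, meta$condition, params, n_use = params$n_cc,
                     seed = seed)
  hr <- build_snn_and_cluster(emb$coords, k = params$snn_k,
                              resolution = params$resolution_highres,
                              seed = seed + 2L)
  vm <- validate_and_merge(norm, hr$clusters, hr$snn,
                           conn_pctile = params$conn_pctile,
                           svm_acc = params$svm_acc,
                           n_genes = params$svm_n_genes,
                           n_pcs = params$svm_n_pcs, seed = seed + 3L)
  clusters <- vm$clusters
  write_tsv(data.frame(barcode = kept, level = "high_res",
                       cluster = clusters),
            file.path(outdir, "cluster_assignments.tsv"))
  write_tsv(vm$decisions, file.path(outdir, "merge_decisions.tsv"))
  manifest$stages$cluster <- list(
    n_initial = length(unique(hr$clusters)),
    n_final = length(unique(clusters)),
    n_cc_used = sum(emb$mask %||% TRUE)
  )

  ## stage: markers --------------------------------------------------------
  ## tested on the variable-gene set: the NB GLM is per-gene and the
  ## informative genes for cluster identity are the variable ones
  markers <- NULL
  test_genes <- select_variable_genes(norm, n_top = params$n_top_var)
  if (length(test_genes) < 20) test_genes <- rownames(norm)
  if (isTRUE(params$run_markers)) {
    covs <- data.frame(log_umi = log(Matrix::colSums(clean)))
    if (!is.null(meta$sample)) covs$sample <- meta$sample
    markers <- find_all_markers(clean[test_genes, , drop = FALSE], clusters,
                                covariates = covs,
                                min_frac = params$marker_min_frac)
    write_tsv(markers, file.path(outdir, "cluster_markers.tsv"))
    manifest$stages$markers <- list(n_genes_tested = length(test_genes),
                                    n_tested = sum(markers$tested))
  }

  ## stage: label transfer (condition 2 onto condition 1) ------------------
  transfer <- NULL
  two_cond <- length(unique(meta$condition)) == 2
  if (isTRUE(params$run_transfer) && two_cond && !is.null(emb$embedding)) {
    is_a <- meta$condition == sort(unique(meta$condition))[1]
    transfer <- bootstrap_label_transfer(
      norm[, is_a, drop = FALSE], clusters[is_a], emb$embedding,
      norm[, !is_a, drop = FALSE], n_boot = params$transfer_n_boot,
      gene_frac = params$transfer_gene_frac,
      top_genes_per_cc = params$transfer_top_genes, n_cc = params$n_cc,
      assign_prob = params$transfer_assign_prob, seed = seed + 4L
    )
    write_tsv(data.frame(barcode = kept[!is_a],
                         label = transfer$label,
                         probability = apply(transfer$probability, 1, max),
                         assigned = transfer$assigned),
              file.path(outdir, "label_transfer.tsv"))
    manifest$stages$transfer <- list(
      unassigned_frac = transfer$unassigned_frac,
      n_genes = length(transfer$genes)
    )
  }

  ## stage: enrichment -----------------------------------------------------
  enr <- NULL
  if (!is.null(catalog)) {
    enr <- enrichment_calls(norm, clusters, alpha_i = params$enrich_alpha_i,
                            alpha_ii = params$enrich_alpha_ii)
    ds <- disease_summary(enr$calls, catalog)
    write_tsv(cbind(gene = rownames(enr$calls), as.data.frame(enr$calls)),
              file.path(outdir, "enrichment_calls.tsv"))
    write_tsv(cbind(disease = rownames(ds$per_cluster),
                    as.data.frame(ds$per_cluster)),
              file.path(outdir, "disease_summary.tsv"))
    manifest$stages$enrichment <- list(
      n_pass = sum(rowSums(enr$calls) > 0),
      missing_genes = length(ds$missing)
    )
  } else {
    manifest$stages$enrichment <- "skipped (no catalog)"
  }

  ## stage: two-phase DE across conditions ---------------------------------
  tp <- NULL
  if (isTRUE(params$run_twophase) && two_cond) {
    tp_counts <- clean[test_genes, , drop = FALSE]
    fit <- fit_two_phase(tp_counts, bg_cap = params$phase_bg_cap)
    tp <- phase2_de(tp_counts, fit, meta$condition, clusters,
                    fc = params$phase_fc, fdr = params$phase_fdr)
    write_tsv(tp, file.path(outdir, "two_phase_de.tsv"))
    tp_sum <- do.call(rbind, lapply(split(tp, tp$cluster), function(d)
      data.frame(cluster = d$cluster[1], n_passing = sum(d$pass))))
    write_tsv(tp_sum, file.path(outdir, "two_phase_summary.tsv"))
    manifest$stages$two_phase <- list(n_passing = sum(tp$pass))
  } else {
    manifest$stages$two_phase <- "skipped (single condition)"
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(qc = qc, removed = removed, clusters = clusters,
                 barcodes = kept, merge_decisions = vm$decisions,
                 markers = markers, transfer = transfer, enrichment = enr,
                 two_phase = tp, truth = truth, manifest = manifest,
                 norm = norm, meta = meta, embedding = emb$embedding))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# embed cells: CCA across two conditions when present, else PCA
embed_cells <- function(norm, condition, params, n_use, seed) {
  conds <- sort(unique(condition))
  if (length(conds) == 2) {
    a <- condition == conds[1]
    va <- norm[, a, drop = FALSE]; vb <- norm[, !a, drop = FALSE]
    genes <- select_variable_genes(va, vb, n_top = params$n_top_var)
    if (length(genes) < 10) {
      # too few shared variable genes to anchor an alignment
      return(list(coords = pca_coords(norm, n_use), embedding = NULL,
                  mask = NULL))
    }
    emb <- cca_align(va, vb, genes, n_cc = params$n_cc,
                     bicor_min = params$bicor_min)
    sel <- which(emb$mask)
    if (!length(sel)) sel <- seq_along(emb$mask)
    sel <- sel[seq_len(min(n_use, length(sel)))]
    coords <- matrix(0, ncol(norm), length(sel))
    coords[a, ] <- emb$coords[emb$dataset == "A", sel, drop = FALSE]
    coords[!a, ] <- emb$coords[emb$dataset == "B", sel, drop = FALSE]
    list(coords = coords, embedding = emb, mask = emb$mask)
  } else {
    list(coords = pca_coords(norm, n_use), embedding = NULL, mask = NULL)
  }
}
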