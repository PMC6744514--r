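#' Per-cell quality-control metrics
#'
#' Computes UMI totals, detected-gene counts and the fraction of UMI coming
#' from mitochondrial genes. Broad class is `"unknown"` at this stage; it is
#' filled in after broad clustering (see [classify_broad_class()]).
#'
#' @param counts Genes x cells count matrix (sparse or dense) with rownames.
#' @param mito_genes Character vector of mitochondrial gene names; defaults to
#'   rownames matching `^mt-` (case-insensitive). Names absent from the matrix
#'   trigger a warning, not an error.
#' @return data.frame with barcode, n_umi, n_genes_detected, pct_mito,
#'   broad_class. A cell with zero counts has pct_mito 0 by convention.
#' @export
compute_qc <- function(counts, mito_genes = NULL) {
  if (is.null(mito_genes)) {
    mito_genes <- grep("^mt-", rownames(counts), ignore.case = TRUE, value = TRUE)
  } else {
    miss <- setdiff(mito_genes, rownames(counts))
    if (length(miss)) {
      warning("mito genes not in matrix: ", paste(miss, collapse = ", "))
      mito_genes <- setdiff(mito_genes, miss)
    }
  }
  n_umi <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito_umi <- if (length(mito_genes)) {
    Matrix::colSums(counts[mito_genes, , drop = FALSE])
  } else rep(0, ncol(counts))
  data.frame(
    barcode = colnames(counts),
    n_umi = as.numeric(n_umi),
    n_genes_detected = as.integer(n_genes),
    pct_mito = ifelse(n_umi > 0, mito_umi / n_umi, 0),
    broad_class = rep("unknown", ncol(counts)),
    stringsAsFactors = FALSE
  )
}

#' Assign a broad neuronal / non-neuronal class to clustered cells
#'
#' Scores each cluster by the mean normalized expression of pan-neuronal
#' marker genes and splits the cluster scores at the midpoint of their range.
#' Clusters above the midpoint are called neuronal; if the scores are nearly
#' constant (range below `min_gap`) every cluster is called non_neuronal.
#'
#' @param norm Genes x cells normalized matrix (log CPM).
#' @param clusters Integer cluster label per cell.
#' @param markers Neuronal marker gene names present in `norm`.
#' @param min_gap Minimum score range required to declare any cluster neuronal.
#' @return Character vector per cell: "neuronal" or "non_neuronal".
#' @export
classify_broad_class <- function(norm, clusters,
                                 markers = neuronal_class_markers(),
                                 min_gap = 0.25) {
  markers <- intersect(markers, rownames(norm))
  if (!length(markers)) stop("none of the class marker genes are in the matrix")
  score_cell <- Matrix::colMeans(norm[markers, , drop = FALSE])
  score <- tapply(score_cell, clusters, mean)
  rng <- range(score)
  if (diff(rng) < min_gap) return(rep("non_neuronal", length(clusters)))
  neuronal <- names(score)[score > mean(rng)]
  ifelse(as.character(clusters) %in% neuronal, "neuronal", "non_neuronal")
}

#' Filter cells by mitochondrial load, doublet percentile and gene floors
#'
#' Applies, in order: (1) removal of cells whose mitochondrial fraction is
#' strictly above `mito_max`; (2) removal of presumed doublets, i.e. cells
#' whose detected-gene count is strictly above the `doublet_pctile` percentile
#' (type-7 linear interpolation) computed over the cells surviving step 1;
#' (3) class-specific minimum gene floors (cells with fewer detected genes
#' than the floor for their broad class are removed; `unknown` cells use the
#' non-neuronal floor).
#'
#' @param counts Genes x cells count matrix.
#' @param qc Output of [compute_qc()], with `broad_class` filled in where
#'   known; must be aligned to the columns of `counts`.
#' @param mito_max Maximum tolerated mitochondrial fraction (cells at exactly
#'   the threshold are retained).
#' @param doublet_pctile Percentile (in \[0, 1\]) of detected genes above which
#'   a cell is called a doublet.
#' @param min_genes_non_neuronal,min_genes_neuronal Gene floors by class
#'   (cells with at least the floor are kept).
#' @return List: `counts` (surviving submatrix), `removed` (data.frame of
#'   barcode + rule for each removed cell, first rule that fired),
#'   `thresholds` (mito cutoff, the realized doublet gene-count threshold,
#'   floors). Errors if no cell survives.
#' @export
filter_cells <- function(counts, qc, mito_max = 0.10, doublet_pctile = 0.99,
                         min_genes_non_neuronal = 800,
                         min_genes_neuronal = 1500) {
  stopifnot(nrow(qc) == ncol(counts))
  rule <- rep(NA_character_, nrow(qc))

  rule[qc$pct_mito > mito_max] <- "high_mito"
  surv <- is.na(rule)
  if (!any(surv)) stop("all cells removed by the mitochondrial filter")
  dbl_thresh <- stats::quantile(qc$n_genes_detected[surv], doublet_pctile,
                                type = 7, names = FALSE)
  rule[surv & qc$n_genes_detected > dbl_thresh] <- "doublet_percentile"

  floor_for <- ifelse(qc$broad_class == "neuronal",
                      min_genes_neuronal, min_genes_non_neuronal)
  rule[is.na(rule) & qc$n_genes_detected < floor_for] <- "below_gene_floor"

  keep <- is.na(rule)
  if (!any(keep)) stop("all cells removed by QC filters")
  list(
    counts = counts[, keep, drop = FALSE],
    removed = data.frame(barcode = qc$barcode[!keep], rule = rule[!keep],
                         stringsAsFactors = FALSE),
    thresholds = list(mito_max = mito_max, doublet_pctile = doublet_pctile,
                      doublet_gene_threshold = dbl_thresh,
                      min_genes_non_neuronal = min_genes_non_neuronal,
                      min_genes_neuronal = min_genes_neuronal)
  )
}

#' Remove mitochondrial / ribosomal gene families
#'
#' Drops gene rows by family name patterns. Meant to run after
#' [compute_qc()], so the mitochondrial fraction is frozen before removal.
#'
#' @param counts Genes x cells matrix.
#' @param families Which families to drop.
#' @param mito_pattern,ribo_pattern Regexes defining the families.
#' @return The matrix without the matching rows.
#' @export
remove_gene_families <- function(counts, families = c("mito", "ribo"),
                                 mito_pattern = "^mt-",
                                 ribo_pattern = "^Rp[sl]") {
  drop <- rep(FALSE, nrow(counts))
  if ("mito" %in% families) {
    drop <- drop | grepl(mito_pattern, rownames(counts), ignore.case = TRUE)
  }
  if ("ribo" %in% families) {
    drop <- drop | grepl(ribo_pattern, rownames(counts))
  }
  counts[!drop, , drop = FALSE]
}

#' Log counts-per-million normalization
#'
#' Computes `ln(1 + 1e6 * count / depth)` per entry, where depth is the cell's
#' UMI total. Sparsity is preserved.
#'
#' @param counts Genes x cells count matrix.
#' @return Sparse normalized matrix with the same dimnames.
#' @export
normalize_log_cpm <- function(counts) {
  depth <- Matrix::colSums(counts)
  if (any(depth == 0)) {
    stop("zero-depth cell(s): ",
         paste(colnames(counts)[depth == 0], collapse = ", "))
  }
  x <- methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix")
  per_col <- diff(x@p)
  x@x <- log1p(1e6 * x@x / rep(depth, per_col))
  x
}
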