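#' Read a 10x Genomics MatrixMarket triplet
#'
#' Reads `matrix.mtx`, `genes.tsv`/`features.tsv` and `barcodes.tsv` (plain or
#' gzipped) from a directory and returns a genes x cells sparse count matrix.
#' Duplicate gene symbols are deduplicated by appending `-1`, `-2`, ... to the
#' second and later occurrences. If the on-disk matrix is stored cells x genes
#' (rows match the barcode table instead of the gene table) it is transposed so
#' the result is always genes x cells.
#'
#' @param path Directory containing the triplet.
#' @param cell_meta Optional data.frame of per-cell metadata (one row per
#'   barcode, in barcode order), attached as the `cell_meta` attribute.
#' @return A `dgCMatrix` with gene ids as rownames and barcodes as colnames.
#' @export
read_10x_mtx <- function(path, cell_meta = NULL) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  find_one <- function(cands, what) {
    for (f in cands) {
      p <- file.path(path, f)
      if (file.exists(p)) return(p)
    }
    stop("missing companion file for 10x triplet: expected one of ",
         paste(cands, collapse = ", "), " (", what, ") in ", path)
  }
  gz <- function(x) c(x, paste0(x, ".gz"))
  mtx_path <- find_one(gz("matrix.mtx"), "matrix")
  gene_path <- find_one(c(gz("genes.tsv"), gz("features.tsv")), "gene table")
  bc_path <- find_one(gz("barcodes.tsv"), "barcode table")

  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- utils::read.delim(gene_path, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  # 10x gene tables carry (id, symbol); a one-column table is taken as symbols
  gene_ids <- trimws(if (ncol(genes) >= 2) genes[[2]] else genes[[1]])
  barcodes <- trimws(barcodes)

  if (nrow(m) == length(gene_ids) && ncol(m) == length(barcodes)) {
    # genes x cells as expected
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(gene_ids)) {
    m <- Matrix::t(m)
  } else {
    stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
         " but gene table has ", length(gene_ids), " rows and barcode table ",
         length(barcodes), " rows")
  }
  rownames(m) <- dedup_names(gene_ids)
  colnames(m) <- barcodes
  if (!is.null(cell_meta)) {
    stopifnot(nrow(cell_meta) == ncol(m))
    attr(m, "cell_meta") <- cell_meta
  }
  m
}

#' Write a count matrix as a 10x MatrixMarket triplet
#'
#' @param counts Genes x cells matrix with rownames/colnames.
#' @param path Output directory (created if needed).
#' @export
write_10x_mtx <- function(counts, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"),
                  file.path(path, "matrix.mtx"))
  utils::write.table(data.frame(id = rownames(counts), symbol = rownames(counts)),
                     file.path(path, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  invisible(path)
}

# make duplicated names unique by appending -1, -2, ... to later occurrences
dedup_names <- function(x) {
  dup <- duplicated(x)
  if (!any(dup)) return(x)
  counts <- new.env(parent = emptyenv())
  vapply(x, function(nm) {
    k <- get0(nm, envir = counts, ifnotfound = 0L)
    assign(nm, k + 1L, envir = counts)
    if (k == 0L) nm else paste0(nm, "-", k)
  }, character(1), USE.NAMES = FALSE)
}

# variant functional classes counted as exonic; the standard reading of an
# "exonic mutation" filter on a GWAS-catalog context column
.exonic_classes <- c(
  "missense_variant", "synonymous_variant", "stop_gained", "stop_lost",
  "frameshift_variant", "inframe_insertion", "inframe_deletion",
  "start_lost", "coding_sequence_variant"
)

#' Read a gene-disease association catalog
#'
#' Reads a tab-separated GWAS-catalog-style table and keeps associations whose
#' variant functional class is exonic (missense, synonymous, stop gained/lost,
#' frameshift, inframe indel, start lost, coding sequence) and whose disease is
#' in `diseases`. Gene symbols are whitespace-stripped and matched
#' case-sensitively; (gene, disease) pairs are unique in the result.
#'
#' @param path TSV with columns `gene`, `disease`, `context` (case-insensitive
#'   header match; `MAPPED_GENE` / `DISEASE.TRAIT` / `CONTEXT` also accepted).
#' @param diseases Character vector of disease/trait names to retain.
#' @return data.frame with columns gene, disease, context.
#' @export
read_gwas_catalog <- function(path, diseases) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(cands) {
    hit <- which(tolower(names(tab)) %in% cands)
    if (!length(hit)) {
      stop("catalog schema error: expected columns gene / disease / context ",
           "(or MAPPED_GENE / DISEASE.TRAIT / CONTEXT); got: ",
           paste(names(tab), collapse = ", "))
    }
    hit[1]
  }
  gene <- trimws(tab[[pick(c("gene", "mapped_gene", "reported gene(s)"))]])
  disease <- trimws(tab[[pick(c("disease", "disease.trait", "disease/trait", "trait"))]])
  context <- tolower(trimws(tab[[pick(c("context", "functional_class", "variant_class"))]]))
  keep <- context %in% .exonic_classes & disease %in% diseases
  out <- unique(data.frame(gene = gene[keep], disease = disease[keep],
                           context = context[keep], stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
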