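test_that("per-cell QC metrics follow their definitions", {
  m <- toy_counts()   # mt-1 holds 2 of 3 UMI in bc1, 4 of 7 in bc2
  qc <- compute_qc(m)
  expect_equal(qc$pct_mito, c(2 / 3, 4 / 7))
  expect_equal(qc$n_genes_detected, c(2L, 2L))
  # zero-count cell: 0 genes, pct_mito 0 by convention
  m0 <- cbind(m, empty = c(0, 0, 0))
  qc0 <- compute_qc(m0)
  expect_equal(qc0$n_genes_detected[3], 0L)
  expect_equal(qc0$pct_mito[3], 0)
  # empty matrix is an empty QC table, not an error
  expect_equal(nrow(compute_qc(m[, 0, drop = FALSE])), 0L)
})

test_that("mito filter is strict at the 10% boundary", {
  counts <- Matrix::Matrix(rbind(
    "mt-1" = c(105, 100, 200),
    "g1"   = c(895, 900, 800)
  ), sparse = TRUE)
  colnames(counts) <- c("at_0.105", "at_0.10", "at_0.20")
  qc <- compute_qc(counts)
  f <- filter_cells(counts, qc, min_genes_non_neuronal = 0)
  expect_setequal(f$removed$barcode[f$removed$rule == "high_mito"],
                  c("at_0.105", "at_0.20"))
  expect_true("at_0.10" %in% colnames(f$counts))
})

test_that("the 99th-percentile doublet cut matches the quantile oracle", {
  # 100 cells detecting 1..100 genes: type-7 99th percentile = 99.01,
  # so only the 100-gene cell is strictly above it
  n <- 100
  counts <- Matrix::Matrix(0, 101, n, sparse = TRUE,
                           dimnames = list(c(paste0("g", 1:100), "mt-1"),
                                           paste0("c", 1:n)))
  for (i in 1:n) counts[1:i, i] <- 1
  qc <- compute_qc(counts)
  f <- filter_cells(counts, qc, min_genes_non_neuronal = 0)
  expect_equal(f$thresholds$doublet_gene_threshold,
               stats::quantile(1:100, 0.99, type = 7, names = FALSE))
  expect_equal(f$removed$barcode, "c100")
  expect_equal(f$removed$rule, "doublet_percentile")
})

test_that("class-specific gene floors use each cell's broad class", {
  set.seed(3)
  counts <- Matrix::Matrix(rbind(matrix(1, 1400, 2), 0), sparse = TRUE)
  rownames(counts) <- paste0("g", 1:1401)
  colnames(counts) <- c("neuronal_1400", "non_neuronal_1400")
  qc <- compute_qc(counts)
  qc$broad_class <- c("neuronal", "non_neuronal")
  f <- filter_cells(counts, qc, doublet_pctile = 1)
  expect_equal(f$removed$barcode, "neuronal_1400")
  expect_equal(f$removed$rule, "below_gene_floor")
  expect_true("non_neuronal_1400" %in% colnames(f$counts))
})

test_that("filtering is stable once the percentile threshold is frozen", {
  sim <- generate_dataset(sim_config(n_clusters = 2, cells_per_cluster = 60,
                                     n_genes = 500, neuronal_clusters = 1,
                                     doublet_rate = 0.05, lowq_rate = 0.1,
                                     seed = 9))
  qc <- compute_qc(sim$counts)
  f1 <- filter_cells(sim$counts, qc, min_genes_non_neuronal = 100)
  qc2 <- qc[match(colnames(f1$counts), qc$barcode), ]
  # re-apply with the doublet cut already taken: nothing further to remove
  f2 <- filter_cells(f1$counts, qc2, doublet_pctile = 1,
                     min_genes_non_neuronal = 100)
  expect_equal(ncol(f2$counts), ncol(f1$counts))
  expect_equal(nrow(f2$removed), 0L)
})

test_that("planted low-quality and doublet cells are removed by their rules", {
  sim <- generate_dataset(sim_config(n_clusters = 2, cells_per_cluster = 100,
                                     n_genes = 600, neuronal_clusters = 1,
                                     doublet_rate = 0, lowq_rate = 0.1,
                                     seed = 12))
  qc <- compute_qc(sim$counts)
  truth <- sim$cell_truth
  # mito-corrupted low-quality cells exceed 10% mito
  lowq_mito <- truth$barcode[truth$is_lowq & qc$pct_mito > 0.10]
  f <- filter_cells(sim$counts, qc, min_genes_non_neuronal = 0)
  expect_true(all(lowq_mito %in%
                    f$removed$barcode[f$removed$rule == "high_mito"]))
})

test_that("gene family removal drops mito and ribo rows after QC froze pct_mito", {
  sim <- small_clean_sim()
  fam <- sim$gene_truth$family
  out <- remove_gene_families(sim$counts)
  expect_equal(nrow(out), nrow(sim$counts) - sum(fam %in% c("mito", "ribo")))
  expect_false(any(grepl("^mt-|^Rp[sl]", rownames(out))))
  # no family genes present -> identity
  expect_identical(remove_gene_families(out), out)
})

test_that("log-CPM normalization matches its closed form and identity", {
  counts <- Matrix::Matrix(matrix(c(10, 9990, 5, 95), 2,
                                  dimnames = list(c("a", "b"), c("c1", "c2"))),
                           sparse = TRUE)
  norm <- normalize_log_cpm(counts)
  expect_equal(norm["a", "c1"], log(1 + 1000), tolerance = 1e-12)
  # per-cell sum of exp(x) - 1 recovers one million
  sim <- small_clean_sim()
  n2 <- normalize_log_cpm(sim$counts[, 1:20])
  expect_equal(unname(Matrix::colSums(expm1(as.matrix(n2)))),
               rep(1e6, 20), tolerance = 1e-6)
  # all-equal column stays all-equal
  ce <- Matrix::Matrix(matrix(3, 4, 1, dimnames = list(letters[1:4], "x")),
                       sparse = TRUE)
  expect_equal(length(unique(as.numeric(normalize_log_cpm(ce)))), 1L)
  # zero-depth cell is an error naming the barcode
  z <- Matrix::Matrix(matrix(c(1, 0), 1, 2,
                             dimnames = list("g", c("ok", "dead"))),
                      sparse = TRUE)
  expect_error(normalize_log_cpm(z), "dead")
})

test_that("broad class scoring separates neuronal clusters", {
  sim <- small_clean_sim()
  norm <- normalize_log_cpm(sim$counts)
  cls <- classify_broad_class(norm, sim$cell_truth$cluster)
  expect_identical(cls, sim$cell_truth$class)
})
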