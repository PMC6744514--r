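#!/usr/bin/env Rscript
# Generate the synthetic prefrontal-cortex-like dataset used throughout the
# analysis: 8 cell types (4 neuronal, 4 non-neuronal) x 200 cells, 3000
# genes with 30 four-fold markers per type, two conditions with 10 planted
# DE genes per type, doublets and low-quality cells at realistic rates.
# Writes a 10x MatrixMarket triplet plus ground-truth tables.

library(scortex)

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_conditions = 2, de_genes_per_cluster = 10, seed = 20260901)
sim <- generate_dataset(cfg)

write_10x_mtx(sim$counts, outdir)
write.table(sim$cell_truth, file.path(outdir, "cell_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$gene_truth, file.path(outdir, "gene_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

qc <- compute_qc(sim$counts)
cat(sprintf("cells: %d  genes: %d\n", ncol(sim$counts), nrow(sim$counts)))
cat(sprintf("median UMI neuronal: %.0f  non-neuronal: %.0f\n",
            median(qc$n_umi[sim$cell_truth$class == "neuronal"]),
            median(qc$n_umi[sim$cell_truth$class == "non_neuronal"])))
cat(sprintf("mean mito fraction: %.3f  doublets: %d  low-quality: %d\n",
            mean(qc$pct_mito), sum(sim$cell_truth$is_doublet),
            sum(sim$cell_truth$is_lowq)))
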