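#!/usr/bin/env Rscript
# Cross-condition cluster correspondence (neighbor-voting AUROC similarity)
# and bootstrapped Spearman label transfer of condition-2 cells onto the
# condition-1 reference. Prints the similarity diagonal, unique-cluster
# flags, the assignment rate and transfer accuracy against ground truth.

library(scortex)

counts <- read_10x_mtx("results/data")
cell_truth <- read.delim("results/data/cell_truth.tsv")
assign_tab <- read.delim("results/pipeline/cluster_assignments.tsv")

counts <- counts[, assign_tab$barcode]
truth <- cell_truth[match(assign_tab$barcode, cell_truth$barcode), ]
norm <- normalize_log_cpm(remove_gene_families(counts))

is_a <- truth$condition == 1
genes <- select_variable_genes(norm[, is_a], norm[, !is_a])
emb <- cca_align(norm[, is_a], norm[, !is_a], genes, n_cc = 20)

nv <- neighbor_voting_similarity(emb, truth$cluster[is_a],
                                 truth$cluster[!is_a])
write.table(cbind(cluster_a = rownames(nv$similarity),
                  as.data.frame(round(nv$similarity, 1))),
            "results/pipeline/similarity_map.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(nv$blocks, "results/pipeline/similarity_blocks.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("similarity diagonal (same type across conditions):\n")
print(round(diag(nv$similarity), 1))
cat(sprintf("unique clusters: %d (A), %d (B)\n",
            sum(nv$unique_a), sum(nv$unique_b)))

tr <- bootstrap_label_transfer(norm[, is_a], truth$cluster[is_a], emb,
                               norm[, !is_a], seed = 20260904)
write.table(data.frame(barcode = colnames(norm)[!is_a], label = tr$label,
                       probability = apply(tr$probability, 1, max),
                       assigned = tr$assigned),
            "results/pipeline/label_transfer.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
ok <- tr$assigned
cat(sprintf("transfer gene set: %d genes\n", length(tr$genes)))
cat(sprintf("assigned: %.1f%%  accuracy among assigned: %.1f%%\n",
            100 * mean(ok),
            100 * mean(tr$label[ok] == truth$cluster[!is_a][ok])))
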