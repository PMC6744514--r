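test_that("bicor is a correlation: 1 on identity, robust to one outlier", {
  set.seed(1)
  x <- rnorm(100)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  y <- x + rnorm(100, sd = 0.05)
  expect_gt(bicor(x, y), 0.95)
  y2 <- y; y2[1] <- 100   # a wild outlier barely moves bicor
  expect_gt(bicor(x, y2), 0.9)
  expect_equal(bicor(x, rep(1, 100)), 0)
})

test_that("variable-gene selection excludes constants and finds planted markers", {
  sim <- small_cca_sim()
  va <- sim$norm[, sim$is_a]; vb <- sim$norm[, !sim$is_a]
  genes <- select_variable_genes(va, vb)
  markers <- sim$sim$gene_truth$gene[!is.na(sim$sim$gene_truth$marker_of)]
  expect_gt(mean(markers %in% genes), 0.6)
  # a constant gene can never be selected
  vc <- va; vc[1, ] <- 5
  expect_false(rownames(vc)[1] %in% select_variable_genes(vc, vb))
  # identical datasets: intersection equals each top list
  expect_setequal(select_variable_genes(va, va), select_variable_genes(va))
})

test_that("aligning a dataset with itself is the identity with scores of 1", {
  sim <- small_cca_sim()
  va <- sim$norm[, sim$is_a]
  emb <- cca_align(va, va, sim$genes, n_cc = 8)
  expect_true(all(emb$scores > 0.999))
  expect_true(all(emb$mask))
  pre_a <- emb$coords_pre[emb$dataset == "A", ]
  post_a <- emb$coords[emb$dataset == "A", ]
  expect_equal(post_a, pre_a, tolerance = 1e-8)
})

test_that("alignment improves cross-dataset neighbor mixing under a global shift", {
  sim <- small_cca_sim()
  va <- sim$norm[, sim$is_a]
  vb <- va
  vb@x <- vb@x * 1.3   # per-gene multiplicative batch distortion
  emb <- cca_align(va, vb, sim$genes, n_cc = 10)
  mixing <- function(coords, dataset, k = 10) {
    d <- as.matrix(dist(coords)); diag(d) <- Inf
    nn <- t(apply(d, 1, function(r) order(r)[1:k]))
    mean(vapply(seq_len(nrow(nn)), function(i)
      mean(dataset[nn[i, ]] != dataset[i]), numeric(1)))
  }
  expect_gte(mixing(emb$coords, emb$dataset),
             mixing(emb$coords_pre, emb$dataset))
})

test_that("two well-separated blobs give exactly two clusters over resolutions", {
  coords <- two_blob_coords()
  for (res in c(0.3, 0.5, 1)) {
    cl <- build_snn_and_cluster(coords, k = 30, resolution = res, seed = 4)
    expect_equal(length(unique(cl$clusters)), 2L)
    expect_equal(adjusted_rand_index(cl$clusters, rep(1:2, each = 100)), 1)
  }
  expect_error(build_snn_and_cluster(coords[1:10, ], k = 10), "smaller")
})

test_that("SNN weights are Jaccard overlaps in [0, 1] with no self loops", {
  coords <- two_blob_coords(n_per = 40)
  cl <- build_snn_and_cluster(coords, k = 10, seed = 1)
  w <- cl$snn@x
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(Matrix::diag(cl$snn) == 0))
  expect_equal(as.matrix(cl$snn), t(as.matrix(cl$snn)))
})

test_that("a randomly split population is merged back together", {
  norm <- marker_pair_norm(n_markers = 0)       # one homogeneous population
  coords <- pca_coords(norm, 5)
  set.seed(11)
  split_labels <- sample(rep(1:2, each = 100))
  snn <- build_snn_and_cluster(coords, k = 15, seed = 2)$snn
  vm <- validate_and_merge(norm, split_labels, snn, seed = 3)
  expect_equal(length(unique(vm$clusters)), 1L)
  acc <- vm$decisions$svm_accuracy[vm$decisions$merged & vm$decisions$iteration > 0]
  expect_lt(acc[1], 0.7)   # random split is not separable
})

test_that("two marker-separated populations are not merged", {
  norm <- marker_pair_norm(n_markers = 50, fold = 4)
  coords <- pca_coords(norm, 5)
  labels <- rep(1:2, each = 100)
  snn <- build_snn_and_cluster(coords, k = 15, seed = 2)$snn
  vm <- validate_and_merge(norm, labels, snn, seed = 3)
  expect_equal(length(unique(vm$clusters)), 2L)
  expect_true(all(vm$decisions$svm_accuracy > 0.9, na.rm = TRUE))
})

test_that("merge validation terminates and is invariant to label permutation", {
  sim <- small_clean_sim()
  norm <- normalize_log_cpm(sim$counts)
  coords <- pca_coords(norm, 10)
  set.seed(21)
  over <- build_snn_and_cluster(coords, k = 15, resolution = 3, seed = 5)
  vm1 <- validate_and_merge(norm, over$clusters, over$snn, seed = 6)
  expect_lte(max(vm1$decisions$iteration),
             length(unique(over$clusters)) - 1)
  # permute input labels: same partition up to renaming
  perm <- sample(length(unique(over$clusters)))
  vm2 <- validate_and_merge(norm, perm[over$clusters], over$snn, seed = 6)
  expect_equal(adjusted_rand_index(vm1$clusters, vm2$clusters), 1)
  # single input cluster passes through untouched
  vm3 <- validate_and_merge(norm, rep(1L, ncol(norm)), over$snn, seed = 6)
  expect_equal(unique(vm3$clusters), 1L)
  expect_equal(nrow(vm3$decisions), 0L)
})

test_that("adjusted Rand index matches the mclust reference", {
  set.seed(13)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2)),
               mclust::adjustedRandIndex(1:10, rep(1:5, 2)))
})
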