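test_that("planted markers are recovered with the right sign under Bonferroni", {
  sim <- small_clean_sim()
  truth <- sim$cell_truth
  grp <- factor(ifelse(truth$cluster == 1, "c", "r"), levels = c("r", "c"))
  covs <- data.frame(log_umi = log(Matrix::colSums(sim$counts)),
                     sample = truth$sample)
  mk <- sim$gene_truth$gene[which(sim$gene_truth$marker_of == 1)]
  others <- setdiff(sample(sim$gene_truth$gene, 80), mk)
  r <- nb_glm_test(sim$counts[c(mk, others), ], grp, covs)
  hits <- r$gene[which(r$p_adj < 0.05 & r$direction == "up")]
  expect_gte(mean(mk %in% hits), 0.9)
})

test_that("a gene with identical group distributions has fold change near 1", {
  set.seed(31)
  counts <- Matrix::Matrix(matrix(rpois(400 * 5, 8), 5, 400,
                                  dimnames = list(paste0("g", 1:5), NULL)),
                           sparse = TRUE)
  r <- nb_glm_test(counts, rep(c("a", "b"), each = 200))
  expect_true(all(abs(r$log_fc) < 0.15))
  expect_true(all(r$p_adj >= r$p_raw))
})

test_that("label permutation yields approximately uniform p-values", {
  sim <- small_clean_sim()
  set.seed(17)
  perm <- sample(rep(c("a", "b"), length.out = ncol(sim$counts)))
  genes <- sample(rownames(sim$counts), 250)
  r <- nb_glm_test(sim$counts[genes, ], perm,
                   covariates = data.frame(
                     log_umi = log(Matrix::colSums(sim$counts))))
  p <- r$p_raw[r$tested & !r$fallback]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 2.5 * sqrt(0.05 * 0.95 / length(p)) + 0.01)
})

test_that("with constant covariates the contrast matches a plain two-group NB fit", {
  set.seed(8)
  y <- c(rpois(60, 4), rpois(60, 10))
  counts <- Matrix::Matrix(matrix(y, 1, dimnames = list("g", NULL)),
                           sparse = TRUE)
  grp <- rep(c("a", "b"), each = 60)
  r <- nb_glm_test(counts, grp,
                   covariates = data.frame(cv = rep(1, 120)))
  direct <- suppressWarnings(
    MASS::glm.nb(y ~ g, data = data.frame(y = y, g = grp)))
  expect_equal(r$log_fc, unname(coef(direct)[2]), tolerance = 1e-6)
  expect_equal(r$p_raw, summary(direct)$coefficients[2, 4], tolerance = 1e-6)
})

test_that("timepoint DE honors strict fold-change and q cutoffs by direction", {
  sim <- generate_dataset(sim_config(
    n_clusters = 2, cells_per_cluster = 150, n_genes = 500,
    neuronal_clusters = 1, doublet_rate = 0, lowq_rate = 0,
    n_conditions = 2, de_genes_per_cluster = 10, de_fold = 3,
    de_mode = "coupled", seed = 55
  ))
  gt <- sim$gene_truth
  test_genes <- c(gt$gene[!is.na(gt$de_in)],
                  sample(gt$gene[is.na(gt$de_in) & gt$family == "none"], 60))
  de <- de_between_timepoints(sim$counts[test_genes, ],
                              sim$cell_truth$cluster,
                              sim$cell_truth$condition)
  expect_true(all(de$results$pass ==
                    (de$results$p_adj < 0.05 &
                       abs(de$results$log_fc) > log(1.5)),
                  na.rm = TRUE))
  for (k in 1:2) {
    up <- gt$gene[which(gt$de_in == k & gt$de_direction == "up")]
    got_up <- de$results$gene[de$results$cluster == k & de$results$pass &
                                de$results$direction == "up"]
    expect_gte(mean(up %in% got_up), 0.7)
  }
  expect_equal(de$summary$n_up + de$summary$n_down,
               vapply(split(de$results, de$results$cluster),
                      function(d) sum(d$pass), integer(1)),
               ignore_attr = TRUE)
})

test_that("bimod LRT equals an independent likelihood evaluation", {
  # 10-cell instance; the oracle evaluates the zero-inflated likelihood
  # directly, sharing only the model definition
  a <- c(0, 0, 2.1, 3.5, 0)
  b <- c(1.2, 0, 4.0, 3.3, 2.8)
  oracle_ll <- function(groups) {
    pos <- unlist(lapply(groups, function(g) g[g > 0]))
    mus <- lapply(groups, function(g) mean(g[g > 0]))
    sig <- sqrt(sum(unlist(Map(function(g, m) (g[g > 0] - m)^2,
                               groups, mus))) / length(pos))
    sum(unlist(Map(function(g, m) {
      n0 <- sum(g <= 0); n1 <- sum(g > 0); p0 <- n0 / length(g)
      (if (n0) n0 * log(p0) else 0) +
        (if (n1) n1 * log(1 - p0) + sum(dnorm(g[g > 0], m, sig, log = TRUE))
         else 0)
    }, groups, mus)))
  }
  expected <- 2 * (oracle_ll(list(a, b)) - oracle_ll(list(c(a, b))))
  got <- bimod_lrt(a, b)
  expect_equal(got$statistic, expected, tolerance = 1e-8)
  expect_equal(got$p, pchisq(expected, 2, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("bimod LRT is symmetric, null on identical groups, powered on zero-fraction shifts", {
  set.seed(41)
  a <- c(rep(0, 40), rnorm(160, 3, 1))
  b <- c(rep(0, 160), rnorm(40, 3, 1))
  expect_equal(bimod_lrt(a, b)$statistic, bimod_lrt(b, a)$statistic,
               tolerance = 1e-10)
  expect_lt(bimod_lrt(a, b)$p, 1e-6)
  same <- bimod_lrt(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p, 1)
  allz <- bimod_lrt(rep(0, 5), rep(0, 7))
  expect_equal(allz$p, 1)
})

test_that("depth rescaling equalizes batch mean depths", {
  set.seed(51)
  b1 <- Matrix::Matrix(matrix(rpois(50 * 30, 5), 50), sparse = TRUE)
  b2 <- Matrix::Matrix(matrix(rpois(50 * 40, 10), 50), sparse = TRUE)
  out <- rescale_depth(list(b1, b2))
  m1 <- mean(Matrix::colSums(out[[1]]))
  m2 <- mean(Matrix::colSums(out[[2]]))
  expect_lt(abs(m1 - m2) / m1, 0.01)
  expect_identical(out[[1]], b1)   # shallowest batch untouched
  # scale factor is the depth ratio
  expect_equal(out[[2]][1, 1] / b2[1, 1],
               mean(Matrix::colSums(b1)) / mean(Matrix::colSums(b2)),
               tolerance = 1e-12)
  expect_identical(rescale_depth(list(b1)), list(b1))
})
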