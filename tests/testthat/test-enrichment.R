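test_that("trimmed means drop extreme outliers but keep constant genes intact", {
  clusters <- rep(1:2, each = 50)
  X <- rbind(out = c(rep(1, 99), 500), flat = rep(2, 100))
  colnames(X) <- paste0("c", 1:100)
  tm <- trimmed_cluster_means(X, clusters)
  expect_equal(unname(tm$means["out", "2"]), 1)      # outlier excluded
  expect_equal(unname(tm$means["flat", ]), c(2, 2))  # constants unchanged
  plain <- trimmed_cluster_means(X, clusters, trim_pctile = 1)
  expect_equal(unname(plain$means["out", "2"]), mean(c(rep(1, 49), 500)))
})

test_that("uniform genes carry zero entropy deviance and fail both criteria", {
  clusters <- rep(1:4, each = 25)
  X <- matrix(3, 2, 100, dimnames = list(c("u1", "u2"), paste0("c", 1:100)))
  et <- entropy_tests(X, clusters)
  expect_equal(et$stat_i, c(0, 0), tolerance = 1e-10)
  expect_false(any(et$pass_i))
  expect_false(any(et$pass_ii))
})

test_that("a single-cluster gene passes both criteria decisively", {
  clusters <- rep(1:10, each = 100)
  x <- numeric(1000)
  x[clusters == 7] <- 5          # 100 expressing cells, one cluster
  X <- matrix(rep(x, 3), 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:1000)))
  et <- entropy_tests(X, clusters, min_cells = 10)
  expect_true(all(et$pass_i))
  expect_true(all(et$pass_ii))
  # closed-form G-test oracle for criterion ii: all 100 expressing cells
  # in one of 10 equal clusters
  g_oracle <- 2 * 100 * log(100 / (100 * 100 / 1000))
  expect_equal(et$stat_ii[1], g_oracle, tolerance = 1e-10)
})

test_that("criterion i is calibrated at or below nominal on null genes", {
  set.seed(71)
  clusters <- rep(1:5, each = 60)
  counts <- Matrix::Matrix(matrix(rpois(400 * 300, 4), 400, 300,
                                  dimnames = list(paste0("g", 1:400),
                                                  paste0("c", 1:300))),
                           sparse = TRUE)
  norm <- normalize_log_cpm(counts)
  et <- entropy_tests(norm, clusters, alpha_i = 0.01)
  rate <- mean(et$p_i < 0.01, na.rm = TRUE)
  expect_lte(rate, 0.01 + 2 * sqrt(0.01 * 0.99 / 400))
})

test_that("entropy tests are invariant under cluster relabeling", {
  sim <- small_clean_sim()
  norm <- normalize_log_cpm(sim$counts[1:100, ])
  cl <- sim$cell_truth$cluster
  et1 <- entropy_tests(norm, cl)
  perm <- c(4, 1, 3, 2)
  et2 <- entropy_tests(norm, perm[cl])
  expect_equal(et1$stat_i, et2$stat_i, tolerance = 1e-9)
  expect_equal(et1$stat_ii, et2$stat_ii, tolerance = 1e-9)
})

test_that("knee annotation matches a brute-force two-segment oracle", {
  # independent oracle: exhaustive split of the sorted means, separate OLS
  # per side, rightmost minimal-SSE split, threshold = left fit at the knee
  oracle <- function(means) {
    o <- order(means); y <- means[o]; C <- length(y); x <- seq_len(C)
    fit <- function(idx) {
      if (length(idx) < 2) return(list(sse = 0, pred = function(z) y[idx]))
      co <- coef(lm(y[idx] ~ x[idx]))
      list(sse = sum((y[idx] - (co[1] + co[2] * x[idx]))^2),
           pred = function(z) co[1] + co[2] * z)
    }
    sse <- sapply(1:(C - 1), function(s)
      fit(1:s)$sse + fit((s + 1):C)$sse)
    s <- max(which(abs(sse - min(sse)) < 1e-12))
    means > fit(1:s)$pred(s)
  }
  cases <- list(c(1, 1, 1, 1, 10), c(0, 0, 5, 5), c(0.1, 0.2, 0.15, 3, 4),
                c(2, 2.2, 1.9, 2.1, 8, 9, 2))
  for (m in cases) {
    expect_equal(knee_annotation(m)$enriched, unname(oracle(m)))
  }
  set.seed(81)
  for (i in 1:20) {
    m <- abs(rnorm(sample(4:12, 1), 1, 1.5))
    ka <- knee_annotation(m)
    if (!ka$degenerate) expect_equal(ka$enriched, unname(oracle(m)))
  }
})

test_that("knee handles degenerate profiles as documented", {
  expect_equal(sum(knee_annotation(rep(3, 5))$enriched), 0L)
  lin <- knee_annotation(seq(1, 6))
  expect_true(lin$degenerate)
  expect_equal(which(lin$enriched), 6L)
  # exactly one expressing cluster -> exactly that cluster
  one <- knee_annotation(c(0, 0, 0, 0, 4))
  expect_equal(which(one$enriched), 5L)
})

test_that("knee calls are invariant to positive scaling, values shift-equivariant", {
  m <- c(0.2, 0.5, 0.4, 2.5, 3.1)
  ka <- knee_annotation(m)
  expect_equal(knee_annotation(10 * m)$enriched, ka$enriched)
  expect_equal(knee_annotation(10 * m)$knee_value, 10 * ka$knee_value,
               tolerance = 1e-9)
  shifted <- knee_annotation(m + 5)
  expect_equal(shifted$knee_value, ka$knee_value + 5, tolerance = 1e-9)
})

test_that("passing genes get at least one enriched cluster; summaries are exact", {
  clusters <- rep(1:5, each = 20)
  x <- numeric(100); x[clusters == 3] <- 6
  X <- matrix(rep(x, 4), 4, byrow = TRUE,
              dimnames = list(paste0("G", 1:4), paste0("c", 1:100)))
  X[4, ] <- 3    # uniform gene: must not pass
  ec <- enrichment_calls(X, clusters)
  expect_equal(unname(ec$calls[1:3, "3"]), rep(1L, 3))
  expect_equal(sum(ec$calls[4, ]), 0L)
  expect_true(all(rowSums(ec$calls[ec$stats$pass_i & ec$stats$pass_ii, ,
                                   drop = FALSE]) >= 1))
  catalog <- data.frame(gene = c("G1", "G2", "G3", "G9"),
                        disease = "schizophrenia")
  ds <- disease_summary(ec$calls, catalog)
  # 3 of the 4 catalog genes are in the universe; all enriched in cluster 3
  expect_equal(unname(ds$per_cluster["schizophrenia", "3"]), 100)
  expect_equal(unname(ds$per_cluster["schizophrenia", "1"]), 0)
  expect_equal(ds$missing, "G9")
  # empty enrichment -> all zero
  ds0 <- disease_summary(ec$calls * 0L, catalog)
  expect_true(all(ds0$per_cluster == 0))
  de <- data.frame(gene = c("G1", "G2"), cluster = c(3, 3),
                   pass = c(TRUE, FALSE))
  ds2 <- disease_summary(ec$calls, catalog, de_results = de)
  expect_equal(unname(ds2$de_counts["schizophrenia", "3"]), 1L)
})
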