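#' Negative-binomial GLM differential test with covariates
#'
#' Per gene, regresses raw UMI counts on a binary contrast plus covariates
#' (log UMI, mitochondrial fraction, sample) with a log link and NB error,
#' reporting a Wald p-value on the contrast coefficient and a Bonferroni (or
#' BH) adjustment over the tested genes. Genes expressed in fewer than
#' `min_frac` of the cells of both groups are not tested. Non-converging NB
#' fits fall back to a Poisson GLM with heteroskedasticity-robust (sandwich)
#' standard errors and are flagged.
#'
#' @param counts Genes x cells raw count matrix.
#' @param group Binary contrast per cell (factor or coercible); the reported
#'   log fold change is for the second level relative to the first.
#' @param covariates Optional data.frame of per-cell covariates (e.g.
#'   `log_umi`, `pct_mito`, `sample`); `NULL` for a plain two-group test.
#' @param min_frac Minimum expressing-cell fraction in at least one group.
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return data.frame: gene, log_fc (natural log), fc, statistic, p_raw,
#'   p_adj, direction, tested, fallback.
#' @export
nb_glm_test <- function(counts, group, covariates = NULL, min_frac = 0.1,
                        adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  group <- factor(group)
  stopifnot(nlevels(group) == 2, all(table(group) > 0),
            length(group) == ncol(counts))
  X <- as.matrix(counts)
  frac_a <- rowMeans(X[, group == levels(group)[1], drop = FALSE] > 0)
  frac_b <- rowMeans(X[, group == levels(group)[2], drop = FALSE] > 0)
  tested <- pmax(frac_a, frac_b) >= min_frac

  df0 <- data.frame(group = group)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == ncol(counts))
    covariates <- covariates[, vapply(covariates, function(v)
      length(unique(v)) > 1, logical(1)), drop = FALSE]
    df0 <- cbind(df0, covariates)
  }
  form <- stats::as.formula(paste("y ~", paste(names(df0), collapse = " + ")))

  res <- data.frame(
    gene = rownames(X), log_fc = NA_real_, fc = NA_real_,
    statistic = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
    direction = NA_character_, tested = tested, fallback = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in which(tested)) {
    d <- df0
    d$y <- X[i, ]
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(form, data = d)),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$converged && is.finite(fit$theta)) {
      co <- summary(fit)$coefficients
      row <- grep("^group", rownames(co))[1]
      res$log_fc[i] <- co[row, 1]
      res$statistic[i] <- co[row, 3]
      res$p_raw[i] <- co[row, 4]
    } else {
      fit <- suppressWarnings(stats::glm(form, data = d, family = stats::poisson()))
      vc <- sandwich::vcovHC(fit, type = "HC0")
      row <- grep("^group", names(stats::coef(fit)))[1]
      est <- stats::coef(fit)[row]
      se <- sqrt(vc[row, row])
      res$log_fc[i] <- est
      res$statistic[i] <- est / se
      res$p_raw[i] <- 2 * stats::pnorm(-abs(est / se))
      res$fallback[i] <- TRUE
    }
  }
  res$fc <- exp(res$log_fc)
  res$p_adj[tested] <- stats::p.adjust(res$p_raw[tested], method = adjust)
  res$direction <- ifelse(res$log_fc > 0, "up", "down")
  res
}

#' One-vs-rest cluster markers by NB GLM
#'
#' @param counts Genes x cells raw counts.
#' @param clusters Cluster label per cell.
#' @param covariates Optional per-cell covariates (see [nb_glm_test()]).
#' @param ... Passed to [nb_glm_test()].
#' @return data.frame of per-gene results stacked over clusters, with a
#'   `cluster` column; `direction == "up"` marks genes elevated in the
#'   cluster.
#' @export
find_all_markers <- function(counts, clusters, covariates = NULL, ...) {
  out <- lapply(sort(unique(clusters)), function(k) {
    grp <- factor(ifelse(clusters == k, "cluster", "rest"),
                  levels = c("rest", "cluster"))
    r <- nb_glm_test(counts, grp, covariates = covariates, ...)
    r$cluster <- k
    r
  })
  do.call(rbind, out)
}

#' Per-cluster differential expression between two timepoints / conditions
#'
#' Runs [nb_glm_test()] within each cluster on the timepoint contrast and
#' reports genes passing `fc` (strictly, in either direction on the linear
#' scale: FC > fc or FC < 1/fc) and adjusted p below `q`, split by direction.
#' Clusters missing one of the two timepoints are skipped with a warning.
#'
#' @param counts Genes x cells raw counts.
#' @param clusters Cluster label per cell.
#' @param timepoint Two-level label per cell.
#' @param covariates Optional per-cell covariates.
#' @param fc,q Pass cutoffs (strict inequalities).
#' @param ... Passed to [nb_glm_test()].
#' @return List: `results` (stacked per-cluster data.frame with `cluster` and
#'   `pass` columns), `summary` (cluster, n_up, n_down).
#' @export
de_between_timepoints <- function(counts, clusters, timepoint,
                                  covariates = NULL, fc = 1.5, q = 0.05, ...) {
  timepoint <- factor(timepoint)
  stopifnot(nlevels(timepoint) == 2)
  res <- list()
  for (k in sort(unique(clusters))) {
    cells <- which(clusters == k)
    if (length(unique(timepoint[cells])) < 2) {
      warning("cluster ", k, " absent at one timepoint; skipped")
      next
    }
    cv <- if (is.null(covariates)) NULL else
      covariates[cells, , drop = FALSE]
    r <- nb_glm_test(counts[, cells, drop = FALSE],
                     droplevels(timepoint[cells]), covariates = cv, ...)
    r$cluster <- k
    r$pass <- !is.na(r$p_adj) & r$p_adj < q & abs(r$log_fc) > log(fc)
    res[[length(res) + 1L]] <- r
  }
  results <- do.call(rbind, res)
  summary <- do.call(rbind, lapply(split(results, results$cluster), function(d) {
    data.frame(cluster = d$cluster[1],
               n_up = sum(d$pass & d$direction == "up", na.rm = TRUE),
               n_down = sum(d$pass & d$direction == "down", na.rm = TRUE))
  }))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}

#' Zero-inflated bimodal likelihood-ratio test
#'
#' Models each group of normalized values as a point mass at zero with
#' probability pi plus a Gaussian for the positive values, and compares the
#' pooled model (common pi, mu) to the separate model (per-group pi, mu) by a
#' likelihood ratio; sigma is shared across groups under each hypothesis and
#' profiled by maximum likelihood. The statistic is referred to chi-squared
#' with 2 degrees of freedom. Values <= 0 are counted as the zero component.
#'
#' @param a,b Numeric vectors of normalized expression (log CPM).
#' @return List: `statistic` (2 * delta log-likelihood), `p`.
#' @examples
#' bimod_lrt(c(0, 0, 2.5, 3), c(0, 0, 0, 3.1))$p
#' bimod_lrt(c(0, 1, 2), c(0, 1, 2))$p   # identical groups: 1
#' @export
bimod_lrt <- function(a, b) {
  loglik <- function(groups) {
    pos <- unlist(lapply(groups, function(g) g[g > 0]))
    mus <- lapply(groups, function(g) if (any(g > 0)) mean(g[g > 0]) else NULL)
    if (length(pos)) {
      ss <- sum(unlist(Map(function(g, m) {
        if (is.null(m)) 0 else sum((g[g > 0] - m)^2)
      }, groups, mus)))
      sigma <- max(sqrt(ss / length(pos)), 1e-8)
    } else sigma <- 1
    ll <- 0
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      n0 <- sum(g <= 0); n1 <- sum(g > 0)
      pi0 <- n0 / length(g)
      if (n0 > 0) ll <- ll + n0 * log(pi0)
      if (n1 > 0) {
        ll <- ll + n1 * log(1 - pi0) +
          sum(stats::dnorm(g[g > 0], mus[[i]], sigma, log = TRUE))
      }
    }
    ll
  }
  if (all(c(a, b) <= 0)) return(list(statistic = 0, p = 1))
  stat <- 2 * (loglik(list(a, b)) - loglik(list(c(a, b))))
  stat <- max(stat, 0)
  list(statistic = stat, p = stats::pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Rescale batches to a common sequencing depth
#'
#' Scales every batch's counts so that the batches' mean cell depths all match
#' the shallowest batch's mean depth. Returned matrices hold real-valued
#' scaled expected counts.
#'
#' @param matrices List of genes x cells count matrices over a shared gene
#'   universe; a single batch is returned unchanged.
#' @return List of rescaled matrices in the same order.
#' @export
rescale_depth <- function(matrices) {
  if (length(matrices) == 1) return(matrices)
  if (any(vapply(matrices, ncol, integer(1)) == 0)) stop("empty batch")
  means <- vapply(matrices, function(m) mean(Matrix::colSums(m)), numeric(1))
  target <- min(means)
  Map(function(m, mu) m * (target / mu), matrices, means)
}
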