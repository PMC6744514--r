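#' Gauss-Hermite nodes and weights (Golub-Welsch)
#' @param n Number of nodes.
#' @return List with `nodes`, `weights` for the weight function exp(-x^2).
#' @keywords internal
gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

#' Fit the two-phase (off/on) expression model
#'
#' Each gene in each cell is either off (Phase I: Poisson background at the
#' cell's background rate, estimated from its low-count profile) or on
#' (Phase II: Poisson whose rate carries a gene-specific lognormal prior
#' scaled by the cell's relative depth). Per gene, an EM algorithm estimates
#' the mixing weight and the lognormal (mu, sigma), with the Poisson-
#' lognormal marginal evaluated by Gauss-Hermite quadrature; the M-step for
#' (mu, sigma) is a bounded numerical maximization of the expected complete
#' log-likelihood starting from the current values, so the observed
#' log-likelihood never decreases. Initialization splits cells at the
#' background cap. The defaults (9 quadrature nodes, 20 simplex steps per
#' M-step, 50 EM iterations) keep genome-subset fits fast; posteriors are
#' insensitive to finer settings.
#'
#' @param counts Genes x cells raw count matrix.
#' @param bg_cap Counts at or below this value feed the per-cell background
#'   rate estimate (and the EM initialization split).
#' @param max_iter,tol EM iteration cap and relative log-likelihood change
#'   tolerance.
#' @param n_quad Gauss-Hermite nodes for the Poisson-lognormal marginal.
#' @return List of class `two_phase_fit`: `posterior` (genes x cells matrix
#'   of Phase-II probabilities), `lambda_bg` (per cell), `mu`, `sigma`,
#'   `weight` (per gene, NA for skipped all-zero genes), `depth_factor` (per
#'   cell), `ll_trace` (list of per-gene log-likelihood traces).
#' @export
fit_two_phase <- function(counts, bg_cap = 2, max_iter = 50, tol = 1e-6,
                          n_quad = 9) {
  X <- as.matrix(counts)
  G <- nrow(X); n <- ncol(X)
  depth <- colSums(X)
  s <- depth / mean(depth)
  lambda_bg <- vapply(seq_len(n), function(c_i) {
    low <- X[, c_i][X[, c_i] <= bg_cap]
    max(mean(low), 1e-4)
  }, numeric(1))
  gh <- gauss_hermite(n_quad)

  posterior <- matrix(0, G, n, dimnames = dimnames(X))
  mu <- sigma <- weight <- rep(NA_real_, G)
  ll_trace <- vector("list", G)
  f1_all <- stats::dpois(X, matrix(lambda_bg, G, n, byrow = TRUE))

  for (g in seq_len(G)) {
    x <- X[g, ]
    on0 <- x > bg_cap
    if (!any(on0)) { ll_trace[[g]] <- numeric(0); next }
    y0 <- log(x[on0] / s[on0])
    m <- mean(y0)
    sg <- max(stats::sd(y0), 0.2, na.rm = TRUE)
    if (is.na(sg)) sg <- 0.2
    w <- max(mean(on0), 1 / n)
    f1 <- f1_all[g, ]

    f2_fun <- function(mm, ss) {
      lam <- outer(s, exp(mm + sqrt(2) * ss * gh$nodes))   # n x q
      as.numeric(stats::dpois(x, lam) %*% gh$weights) / sqrt(pi)
    }
    f2 <- f2_fun(m, sg)
    ll <- sum(log(pmax(w * f2 + (1 - w) * f1, 1e-300)))
    trace <- ll
    for (it in seq_len(max_iter)) {
      r <- w * f2 / pmax(w * f2 + (1 - w) * f1, 1e-300)
      w_new <- mean(r)
      obj <- function(par) {
        -sum(r * log(pmax(f2_fun(par[1], exp(par[2])), 1e-300)))
      }
      opt <- stats::optim(c(m, log(sg)), obj, method = "Nelder-Mead",
                          control = list(maxit = 20))
      if (opt$value <= obj(c(m, log(sg)))) {
        m <- opt$par[1]; sg <- exp(opt$par[2])
      }
      w <- w_new
      f2 <- f2_fun(m, sg)
      ll_new <- sum(log(pmax(w * f2 + (1 - w) * f1, 1e-300)))
      trace <- c(trace, ll_new)
      if (abs(ll_new - ll) < tol * (abs(ll) + 1)) { ll <- ll_new; break }
      ll <- ll_new
    }
    posterior[g, ] <- w * f2 / pmax(w * f2 + (1 - w) * f1, 1e-300)
    mu[g] <- m; sigma[g] <- sg; weight[g] <- w
    ll_trace[[g]] <- trace
  }
  structure(list(posterior = posterior, lambda_bg = lambda_bg, mu = mu,
                 sigma = sigma, weight = weight, depth_factor = s,
                 ll_trace = ll_trace), class = "two_phase_fit")
}

# limma-style empirical-Bayes variance shrinkage: moment matching on log s^2
squeeze_var <- function(s2, df) {
  ok <- s2 > 0 & df > 0
  if (sum(ok) < 2) return(list(var_post = s2, df_prior = 0, var_prior = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  ev <- mean(e)
  resid_var <- sum((e - ev)^2) / (sum(ok) - 1) - mean(trigamma(df[ok] / 2))
  if (resid_var <= 0) {
    d0 <- Inf
    s0 <- exp(ev)
  } else {
    d0 <- 2 * trigamma_inv(resid_var)
    s0 <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
  }
  var_post <- if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + df * s2) / (d0 + df)
  list(var_post = var_post, df_prior = d0, var_prior = s0)
}

# Newton inversion of trigamma (as used for the prior df)
trigamma_inv <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Phase-II differential expression with moderated t-statistics
#'
#' Within each cluster, restricts every gene to the cells whose Phase-II
#' posterior exceeds 0.5, takes the log depth-normalized count
#' `log((count + 0.5) / depth_factor)` as response (the half count guards
#' the rare Phase-II cell with a zero count without compressing fold
#' changes), and compares the two groups
#' with a moderated t-statistic: per-gene pooled variances are shrunk toward
#' a common prior with prior degrees of freedom estimated by moment matching.
#' P-values are BH-adjusted within cluster; a gene passes at `fc` (strict,
#' either direction) and `fdr`. Genes with fewer than `min_cells` Phase-II
#' cells in either group are untested.
#'
#' @param counts Genes x cells raw counts.
#' @param fit A [fit_two_phase()] result on the same matrix.
#' @param groups Two-level treatment/control label per cell.
#' @param clusters Cluster label per cell.
#' @param fc,fdr Pass cutoffs.
#' @param posterior_min Phase-II posterior needed to include a cell.
#' @param min_cells Minimum Phase-II cells per group.
#' @return data.frame: gene, cluster, n1, n2, log_fc, fc, t, df, p, fdr,
#'   pass, tested.
#' @export
phase2_de <- function(counts, fit, groups, clusters, fc = 1.5, fdr = 0.05,
                      posterior_min = 0.5, min_cells = 5) {
  X <- as.matrix(counts)
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == ncol(X))
  s <- fit$depth_factor
  Y <- log(sweep(X + 0.5, 2, s, "/"))
  out <- list()
  for (k in sort(unique(clusters))) {
    in_k <- clusters == k
    g1 <- in_k & groups == levels(groups)[1]
    g2 <- in_k & groups == levels(groups)[2]
    n_g <- nrow(X)
    m1 <- m2 <- s2 <- rep(NA_real_, n_g)
    n1 <- n2 <- integer(n_g)
    for (g in seq_len(n_g)) {
      on <- fit$posterior[g, ] > posterior_min
      i1 <- which(on & g1); i2 <- which(on & g2)
      n1[g] <- length(i1); n2[g] <- length(i2)
      if (n1[g] < min_cells || n2[g] < min_cells) next
      y1 <- Y[g, i1]; y2 <- Y[g, i2]
      m1[g] <- mean(y1); m2[g] <- mean(y2)
      s2[g] <- (sum((y1 - m1[g])^2) + sum((y2 - m2[g])^2)) /
        (n1[g] + n2[g] - 2)
    }
    tested <- !is.na(s2)
    res <- data.frame(
      gene = rownames(X), cluster = k, n1 = n1, n2 = n2,
      log_fc = m2 - m1, fc = exp(m2 - m1), t = NA_real_, df = NA_real_,
      p = NA_real_, fdr = NA_real_, pass = FALSE, tested = tested,
      stringsAsFactors = FALSE
    )
    if (any(tested)) {
      df_res <- (n1 + n2 - 2)[tested]
      sq <- squeeze_var(s2[tested], df_res)
      se <- sqrt(sq$var_post * (1 / n1[tested] + 1 / n2[tested]))
      tt <- (m2[tested] - m1[tested]) / se
      df_tot <- df_res + sq$df_prior
      res$t[tested] <- tt
      res$df[tested] <- df_tot
      res$p[tested] <- 2 * stats::pt(-abs(tt), df = df_tot)
      res$fdr[tested] <- stats::p.adjust(res$p[tested], method = "BH")
      res$pass <- res$tested & !is.na(res$fdr) & res$fdr < fdr &
        abs(res$log_fc) > log(fc)
    }
    out[[length(out) + 1L]] <- res
  }
  do.call(rbind, out)
}

#' Percent overlap of passing gene sets between clusters
#'
#' @param de A [phase2_de()] (or compatible) result with `gene`, `cluster`,
#'   `pass` columns.
#' @return Square matrix; entry (i, j) is 100 x |pass_i intersect pass_j| /
#'   |pass_i| (row-conditional overlap).
#' @export
passing_overlap <- function(de) {
  sets <- lapply(split(de, de$cluster), function(d) d$gene[d$pass])
  ids <- names(sets)
  M <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    M[i, j] <- if (length(sets[[i]]))
      100 * length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]]) else NA
  }
  M
}
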