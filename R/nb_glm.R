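#' Median-of-ratios size factors
#'
#' Per-sample scaling constants correcting for sequencing depth. For each
#' gene with all-positive counts the ratio of each sample's count to the
#' gene's geometric mean is formed; a sample's size factor is the median of
#' these ratios, rescaled so that the factors have geometric mean 1.
#'
#' @param counts integer matrix, genes x samples.
#' @return numeric vector of positive size factors, one per sample, named by
#'   column when the matrix has column names.
#' @examples
#' m <- rbind(c(10, 20), c(100, 200), c(4, 8))
#' estimate_size_factors(m)  # c(0.7071, 1.4142)
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) {
    return(setNames(1, colnames(counts)))
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has positive counts in every sample; ",
         "size factors cannot be estimated by median-of-ratios ",
         "(consider a pseudo-reference fallback)")
  }
  x <- counts[pos, , drop = FALSE]
  loggeo <- rowMeans(log(x))
  # median taken on the log scale (the DESeq2 convention; for an even
  # number of genes the two middle ratios are averaged in log space)
  sf <- apply(x, 2, function(col) exp(median(log(col) - loggeo)))
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Per-gene NB dispersion by method of moments with trend shrinkage
#'
#' Estimates the dispersion alpha of the NB parameterization
#' Var = mu + alpha * mu^2. Within each design cell (unique row pattern of
#' the grouping factors) the sample mean and unbiased variance of
#' size-factor-normalized counts are pooled across cells into a per-gene
#' moment estimate
#' alpha_raw = sum_i df_i (v_i - xi * m_i) / sum_i df_i m_i^2,
#' where xi = mean(1/s_j) accounts for the Poisson (shot-noise) part on the
#' normalized scale. A parametric mean--dispersion trend
#' alpha_tr(mu) = a0 + a1 / mu is fitted to genes with positive raw
#' estimates, and the final estimate shrinks log(raw) toward log(trend)
#' with an adaptive weight: the spread of log(raw) around log(trend) is
#' decomposed into sampling noise (approximated by
#' `trigamma(residual_df / 2)`) plus gene-to-gene prior variance, and the
#' weight on the trend is the sampling share of that total — homogeneous
#' data shrink almost fully to the trend while genuinely heterogeneous
#' dispersions keep their gene-wise signal. Genes with zero observed
#' excess variance (v = 0 in every cell) get `alpha_min`; genes with
#' non-positive raw estimates fall back to the trend.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors positive numeric vector, one per sample.
#' @param groups factor (or interaction of factors) of length ncol(counts)
#'   defining the design cells; replicates must exist within cells.
#' @param alpha_min lower bound on the estimate (default 1e-8).
#' @param shrink optional fixed weight in (0, 1] on the trend, overriding
#'   the adaptive weight (default NULL, adaptive).
#' @return numeric vector of dispersions, one per gene.
#' @export
estimate_dispersion <- function(counts, size_factors, groups,
                                alpha_min = 1e-8, shrink = NULL) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) {
    stop("length(groups) must equal ncol(counts)")
  }
  tab <- table(groups)
  if (sum(pmax(tab - 1L, 0L)) < 2) {
    stop("insufficient replication: need >= 2 residual degrees of freedom")
  }
  norm <- sweep(counts, 2, size_factors, "/")
  xi <- mean(1 / size_factors)
  cells <- levels(groups)[tab >= 2]
  num <- den <- vtot <- rep(0, nrow(counts))
  mu_bar <- rowMeans(norm)
  for (cl in cells) {
    j <- which(groups == cl)
    m <- rowMeans(norm[, j, drop = FALSE])
    v <- apply(norm[, j, drop = FALSE], 1, var)
    df <- length(j) - 1
    num <- num + df * (v - xi * m)
    den <- den + df * m^2
    vtot <- vtot + v
  }
  raw <- ifelse(den > 0, num / den, NA_real_)
  # parametric trend a0 + a1/mu fitted on informative genes
  ok <- is.finite(raw) & raw > 0 & mu_bar > 1
  if (sum(ok) >= 10) {
    fit <- lm(raw[ok] ~ I(1 / mu_bar[ok]))
    a0 <- max(coef(fit)[1], alpha_min)
    a1 <- max(coef(fit)[2], 0)
  } else {
    a0 <- max(mean(raw[ok]), alpha_min)
    if (!is.finite(a0)) a0 <- alpha_min
    a1 <- 0
  }
  trend <- pmax(a0 + a1 / pmax(mu_bar, 1e-8), alpha_min)
  if (is.null(shrink)) {
    # adaptive weight: sampling variance of log(raw) over the total
    # spread of log(raw) around log(trend). The sampling variance of the
    # moment estimator is calibrated by Monte Carlo: re-simulate NB
    # counts at the trend dispersion with the observed cell means and
    # measure the spread of the re-estimated raw values.
    s2_samp <- mc_mom_variance(norm, groups, cells, trend, ok)
    lres <- log(raw[ok]) - log(trend[ok])
    s2_tot <- max(stats::mad(lres)^2, s2_samp)
    shrink <- s2_samp / s2_tot
  }
  alpha <- exp((1 - shrink) * log(pmax(raw, alpha_min)) + shrink * log(trend))
  alpha[!is.finite(raw) | raw <= 0] <- trend[!is.finite(raw) | raw <= 0]
  alpha[vtot == 0] <- alpha_min      # zero excess variance: degenerate gene
  pmax(alpha, alpha_min)
}

# Monte-Carlo estimate of the sampling variance of the log moment
# dispersion estimator at the trend, using the observed per-cell means of
# up to 500 informative genes. Runs under a private RNG stream so the
# estimate is deterministic and leaves the caller's RNG state untouched.
mc_mom_variance <- function(norm, groups, cells, trend, ok) {
  idx <- which(ok)
  if (length(idx) > 500L) {
    idx <- idx[round(seq(1L, length(idx), length.out = 500L))]
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(20170913L)
  lraw <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    num <- den <- 0
    for (cl in cells) {
      j <- which(groups == cl)
      m <- mean(norm[i, j])
      y <- rnbinom(length(j), mu = m, size = 1 / max(trend[i], 1e-8))
      num <- num + (length(j) - 1) * (var(y) - m)
      den <- den + (length(j) - 1) * m^2
    }
    if (den > 0 && num > 0) lraw[k] <- log(num / den) - log(trend[i])
  }
  lraw <- lraw[is.finite(lraw)]
  if (length(lraw) < 20) return(trigamma(length(cells)))
  stats::mad(lraw)^2
}

nb_loglik <- function(y, mu, alpha) {
  size <- 1 / max(alpha, 1e-12)
  sum(dnbinom(y, size = size, mu = pmax(mu, 1e-12), log = TRUE))
}

#' Fit a negative-binomial GLM for one gene
#'
#' Maximizes the NB log-likelihood with log link and offset `log(s_j)` by
#' iteratively reweighted least squares at fixed dispersion. Working weights
#' are `mu / (1 + alpha * mu)`. Convergence when `max |delta beta| < tol` or
#' `maxit` iterations.
#'
#' @param y integer counts for one gene (length = number of samples).
#' @param design numeric design matrix (samples x coefficients), full rank.
#' @param size_factors positive per-sample scalars (offset is their log).
#' @param alpha NB dispersion (Var = mu + alpha mu^2).
#' @param tol,maxit IRLS convergence controls.
#' @return an object of class `nb_glm_fit`: list with `beta`, `mu`,
#'   `loglik`, `deviance`, `df` (rank of design), `converged`, `iter`,
#'   `cov` (coefficient covariance), `degenerate` (all-zero gene).
#' @export
fit_nb_glm <- function(y, design, size_factors, alpha,
                       tol = 1e-8, maxit = 100L) {
  design <- as.matrix(design)
  if (length(y) != nrow(design)) stop("length(y) must match nrow(design)")
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) stop("design matrix is not full rank")
  off <- log(size_factors)
  if (all(y == 0)) {
    return(structure(list(beta = rep(NA_real_, ncol(design)),
                          mu = rep(0, length(y)), loglik = 0,
                          deviance = 0, df = ncol(design),
                          converged = TRUE, iter = 0L, cov = NULL,
                          degenerate = TRUE),
                     class = "nb_glm_fit"))
  }
  # initialize from log normalized mean
  beta <- qr.coef(qrd, log(pmax(y / size_factors, 0.5)))
  eta <- drop(design %*% beta) + off
  mu <- exp(eta)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxit)) {
    iter <- it
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    fit <- lm.wfit(design, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(design %*% beta) + off
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    if (delta < tol) { converged <- TRUE; break }
  }
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(design * w, design)
  cov <- tryCatch(solve(xtwx), error = function(e) NULL)
  ll <- nb_loglik(y, mu, alpha)
  # saturated deviance relative to mu = y
  ll_sat <- nb_loglik(y, pmax(y, 1e-8), alpha)
  structure(list(beta = beta, mu = mu, loglik = ll,
                 deviance = 2 * (ll_sat - ll), df = ncol(design),
                 converged = converged, iter = iter, cov = cov,
                 degenerate = FALSE),
            class = "nb_glm_fit")
}

#' Likelihood-ratio test between nested NB-GLM fits
#'
#' @param full,reduced `nb_glm_fit` objects for the same gene/data, the
#'   reduced design nested in the full one.
#' @return list with `stat` (2 * (ll_full - ll_reduced), clipped at 0), `df`
#'   (rank difference) and `p` (upper chi-square tail). Degenerate
#'   (all-zero) genes get `stat = 0`, `p = NA`.
#' @export
nb_lrt <- function(full, reduced) {
  if (!inherits(full, "nb_glm_fit") || !inherits(reduced, "nb_glm_fit")) {
    stop("nb_lrt expects nb_glm_fit objects")
  }
  df <- full$df - reduced$df
  if (df <= 0) stop("reduced model must have fewer coefficients than full")
  if (full$degenerate || reduced$degenerate) {
    return(list(stat = 0, df = df, p = NA_real_))
  }
  stat <- max(2 * (full$loglik - reduced$loglik), 0)
  list(stat = stat, df = df, p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Wald test on one NB-GLM coefficient
#'
#' @param fit `nb_glm_fit` object with coefficient covariance.
#' @param coef index (or name) of the coefficient to test against 0.
#' @return list with `estimate`, `se`, `stat` (z), `p` (two-sided normal).
#' @export
nb_wald <- function(fit, coef = 2L) {
  if (fit$degenerate || is.null(fit$cov)) {
    return(list(estimate = NA_real_, se = NA_real_,
                stat = NA_real_, p = NA_real_))
  }
  est <- fit$beta[coef]
  se <- sqrt(fit$cov[coef, coef])
  z <- est / se
  list(estimate = unname(est), se = unname(se), stat = unname(z),
       p = unname(2 * pnorm(-abs(z))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Implements the BH step-up procedure directly: order the m non-missing
#' p-values increasingly, form p_(i) * m / i, and take running minima from
#' the largest rank down, capped at 1. NA p-values are propagated as NA and
#' excluded from m.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  o <- order(pv)
  scaled <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out[ok[o]] <- adj
  out
}

#' Gene-wise Wald differential test between two conditions
#'
#' DESeq2-style two-group comparison on a count matrix: median-of-ratios
#' size factors, moment/trend dispersions, per-gene NB GLM
#' `~ condition` with a Wald test on the condition coefficient, and BH
#' adjustment. All-zero genes are reported with NA p and padj.
#'
#' @param counts integer matrix, genes x samples.
#' @param condition factor of length ncol(counts) with exactly two levels;
#'   the first level is the reference, the log2 fold change is
#'   second-vs-first.
#' @param size_factors optional; estimated from `counts` when NULL.
#' @param alpha optional per-gene dispersions; estimated when NULL.
#' @return data.frame (gene, baseMean, log2FC, stat, p, padj) with one row
#'   per gene.
#' @export
nb_wald_de <- function(counts, condition, size_factors = NULL, alpha = NULL) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("condition must have exactly two levels")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(alpha)) {
    alpha <- estimate_dispersion(counts, size_factors, condition)
  }
  design <- cbind(intercept = 1,
                  cond = as.integer(condition == levels(condition)[2]))
  norm <- sweep(counts, 2, size_factors, "/")
  n <- nrow(counts)
  res <- data.frame(gene = rownames(counts) %||% paste0("g", seq_len(n)),
                    baseMean = rowMeans(norm), log2FC = NA_real_,
                    stat = NA_real_, p = NA_real_, padj = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fit <- fit_nb_glm(counts[i, ], design, size_factors, alpha[i])
    if (fit$degenerate) next
    w <- nb_wald(fit, 2L)
    res$log2FC[i] <- w$estimate / log(2)
    res$stat[i] <- w$stat
    res$p[i] <- w$p
  }
  res$padj <- bh_adjust(res$p)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
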