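dirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

# move a fraction tau of monosome-group mass to the heavy group
# (tau < 0 moves |tau| of heavy mass to monosomes); light untouched
shift_profile <- function(p, tau, mono_idx, heavy_idx) {
  if (tau == 0) return(p)
  if (tau > 0) {
    from <- mono_idx; to <- heavy_idx; f <- tau
  } else {
    from <- heavy_idx; to <- mono_idx; f <- -tau
  }
  moved <- f * sum(p[from])
  p[from] <- p[from] * (1 - f)
  p[to] <- p[to] + moved * (p[to] / sum(p[to]))
  p
}

#' Simulate polysome-fraction and total-mRNA count matrices
#'
#' Draws NB counts for every gene x condition x replicate x fraction cell:
#' `count ~ NB(mean = s_j * A_g * ribo_fold_gc * profile_gcf * F,
#' dispersion alpha_g)` with `F` the number of fractions (so `A_g` is the
#' per-cell mean under a uniform profile), and total-mRNA counts from the
#' abundance component only (`s_j * A_g * total_fold_gc * F`). Gene
#' classes wire the condition effects: abundance classes fold the totals,
#' translation classes fold all fraction counts and shift profile mass
#' between the monosome and heavy groups; signs of the log folds and of
#' the shift are random per gene. Every effect is recorded in the returned
#' truth table.
#'
#' @param config a [sim_config()] object.
#' @return list with `polysome` and `totals` ([fraction_counts()]
#'   objects) and `truth`, a `sim_truth` list containing the per-gene
#'   class/effect table (`genes`), per-condition profile matrices
#'   (`profiles`, gene x fraction per condition), true per-condition
#'   RiboLoad (`riboload`), and the sampled size factors.
#' @export
simulate_polysome_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  nf <- length(config$fractions)
  nr <- config$n_replicates
  conds <- config$conditions
  genes <- sprintf("gene%05d", seq_len(n))
  design <- fraction_design(fractions = config$fractions,
                            monosome = intersect(4:7, config$fractions),
                            light = intersect(8:10, config$fractions),
                            heavy = intersect(11:16, config$fractions),
                            conditions = conds)
  mono_idx <- match(design$monosome, config$fractions)
  heavy_idx <- match(design$heavy, config$fractions)

  A <- rlnorm(n, config$base_mean_log[1], config$base_mean_log[2])
  alpha <- if (is.list(config$dispersion)) {
    rgamma(n, shape = config$dispersion$shape, rate = config$dispersion$rate)
  } else {
    rep_len(config$dispersion, n)
  }
  cls <- sample(names(config$class_proportions), n, replace = TRUE,
                prob = config$class_proportions)
  sgn_ab <- sample(c(-1, 1), n, replace = TRUE)
  sgn_tr <- sample(c(-1, 1), n, replace = TRUE)
  total_fold <- ifelse(cls %in% c("abundance_only", "both"),
                       config$abundance_effect^sgn_ab, 1)
  ribo_fold <- ifelse(cls %in% c("translation_only", "both"),
                      config$abundance_effect^sgn_tr, 1)
  tau <- ifelse(cls %in% c("translation_only", "both"),
                config$translation_effect * sgn_tr, 0)
  # zero-effect configuration realizes every gene as "neither"
  no_effect <- config$abundance_effect == 1 & config$translation_effect == 0
  if (no_effect) cls[] <- "neither"

  template <- stats::dnorm(seq_len(nf), mean = (nf + 3) / 2, sd = nf / 4)
  template <- template / sum(template)
  p_ref <- dirichlet(n, config$profile_concentration * template)
  p_trt <- t(vapply(seq_len(n), function(i) {
    shift_profile(p_ref[i, ], tau[i], mono_idx, heavy_idx)
  }, numeric(nf)))
  profiles <- setNames(list(p_ref, p_trt), conds)
  for (cc in conds) {
    rownames(profiles[[cc]]) <- genes
    colnames(profiles[[cc]]) <- paste0("f", config$fractions)
  }

  samples <- expand.grid(fraction = config$fractions,
                         replicate = seq_len(nr), condition = conds,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_r%d_f%d", samples$condition,
                            samples$replicate, samples$fraction)
  samples$assay <- "fraction"
  samples <- samples[c("sample", "condition", "replicate", "fraction",
                       "assay")]
  sf <- rlnorm(nrow(samples), 0, config$size_factor_sdlog)

  counts <- matrix(0L, n, nrow(samples), dimnames = list(genes,
                                                         samples$sample))
  for (j in seq_len(nrow(samples))) {
    ci <- if (samples$condition[j] == conds[1]) 1L else 2L
    pf <- profiles[[ci]][, match(samples$fraction[j], config$fractions)]
    rf <- if (ci == 1L) 1 else ribo_fold
    mu <- sf[j] * A * rf * pf * nf
    counts[, j] <- rnbinom(n, mu = mu, size = 1 / alpha)
  }

  tot_samples <- expand.grid(replicate = seq_len(nr), condition = conds,
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
  tot_samples$sample <- sprintf("%s_total_r%d", tot_samples$condition,
                                tot_samples$replicate)
  tot_samples$fraction <- NA_integer_
  tot_samples$assay <- "total"
  tot_samples <- tot_samples[c("sample", "condition", "replicate",
                               "fraction", "assay")]
  sf_tot <- rlnorm(nrow(tot_samples), 0, config$size_factor_sdlog)
  totals <- matrix(0L, n, nrow(tot_samples),
                   dimnames = list(genes, tot_samples$sample))
  for (j in seq_len(nrow(tot_samples))) {
    tf <- if (tot_samples$condition[j] == conds[1]) 1 else total_fold
    mu <- sf_tot[j] * A * tf * nf
    totals[, j] <- rnbinom(n, mu = mu, size = 1 / alpha)
  }

  rl <- vapply(conds, function(cc) {
    rowSums(profiles[[cc]][, heavy_idx, drop = FALSE])
  }, numeric(n))
  truth <- structure(list(
    genes = data.frame(gene = genes, class = cls, base_mean = A,
                       dispersion = alpha, total_fold = total_fold,
                       ribo_fold = ribo_fold, translation_shift = tau,
                       riboload_ref = rl[, 1], riboload_trt = rl[, 2],
                       riboload_fold = rl[, 2] / rl[, 1],
                       stringsAsFactors = FALSE),
    profiles = profiles,
    size_factors = setNames(sf, samples$sample),
    size_factors_total = setNames(sf_tot, tot_samples$sample),
    design = design), class = "sim_truth")

  list(polysome = fraction_counts(counts, samples),
       totals = fraction_counts(totals, tot_samples),
       truth = truth)
}
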