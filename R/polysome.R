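fraction_model_matrices <- function(samples, design,
                                    reduced_with_condition = FALSE) {
  cond <- factor(samples$condition, levels = design$conditions)
  frac <- factor(samples$fraction, levels = design$fractions)
  full <- stats::model.matrix(~ cond * frac)
  reduced <- if (reduced_with_condition) {
    stats::model.matrix(~ cond + frac)
  } else {
    stats::model.matrix(~ frac)
  }
  list(full = full, reduced = reduced)
}

#' Polysome-distribution likelihood-ratio test for one gene
#'
#' Fits the full NB GLM `count ~ condition + fraction +
#' condition:fraction` and the reduced model `count ~ fraction` (as in the
#' original procedure, the reduced model omits the condition main effect,
#' so the test responds to overall ribosome-association changes as well as
#' to pure distribution changes; `reduced_with_condition = TRUE` isolates
#' the interaction) and compares them by likelihood ratio against a
#' chi-square with df equal to the rank difference.
#'
#' @param y integer counts for one gene across all fraction samples.
#' @param samples sample annotation rows matching `y` (columns
#'   `condition`, `fraction`).
#' @param design a [fraction_design()].
#' @param size_factors per-sample size factors.
#' @param alpha NB dispersion for the gene.
#' @param reduced_with_condition keep the condition main effect in the
#'   reduced model (default FALSE, as printed).
#' @return list with `stat`, `df`, `p`.
#' @export
profile_lrt <- function(y, samples, design, size_factors, alpha,
                        reduced_with_condition = FALSE) {
  missing_fr <- setdiff(design$fractions, unique(samples$fraction))
  if (length(missing_fr)) {
    stop("missing fractions: ", paste(missing_fr, collapse = ", "))
  }
  mm <- fraction_model_matrices(samples, design, reduced_with_condition)
  full <- fit_nb_glm(y, mm$full, size_factors, alpha)
  reduced <- fit_nb_glm(y, mm$reduced, size_factors, alpha)
  nb_lrt(full, reduced)
}

#' Per-fraction post-hoc tests for one gene
#'
#' For each fraction, a two-sample Welch t-test on
#' `log2(normalized count + 0.5)` between the two conditions. A fraction
#' is called changed at `p < p_threshold` (raw threshold, no multiplicity
#' correction across the 13 fractions); group flags are the OR over the
#' monosome, light and heavy fraction sets.
#'
#' @param norm numeric vector of size-factor-normalized counts for one
#'   gene across fraction samples.
#' @param samples matching sample annotation (columns `condition`,
#'   `fraction`).
#' @param design a [fraction_design()].
#' @param p_threshold significance threshold (default 0.01).
#' @return list with `p` (named per-fraction p-values) and logical flags
#'   `changed_any`, `changed_mono`, `changed_light`, `changed_heavy`.
#' @export
posthoc_fraction_tests <- function(norm, samples, design,
                                   p_threshold = 0.01) {
  ref <- design$conditions[1]
  pv <- vapply(design$fractions, function(f) {
    sel <- samples$fraction == f
    a <- log2(norm[sel & samples$condition == ref] + 0.5)
    b <- log2(norm[sel & samples$condition != ref] + 0.5)
    welch_p(a, b)
  }, numeric(1))
  names(pv) <- paste0("f", design$fractions)
  sig <- !is.na(pv) & pv < p_threshold
  hit <- function(fr) any(sig[match(fr, design$fractions)])
  list(p = pv, changed_any = any(sig), changed_mono = hit(design$monosome),
       changed_light = hit(design$light), changed_heavy = hit(design$heavy))
}

# Welch two-sample t; zero variance in both groups with equal means -> 1,
# with different means -> 0 (certain difference at machine precision)
welch_p <- function(a, b) {
  va <- var(a); vb <- var(b)
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (va == 0 && vb == 0) return(if (mean(a) == mean(b)) 1 else 0)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                   vb^2 / (length(b)^2 * (length(b) - 1)))
  2 * pt(-abs(t), df)
}

#' Genome-wide polysome-distribution analysis
#'
#' Runs the interaction LRT and the per-fraction post-hoc tests for every
#' gene of a fraction count matrix. Size factors are estimated over all
#' fraction samples by median-of-ratios, dispersions by moments with
#' trend shrinkage over the condition x fraction design cells. LRT
#' p-values are BH-adjusted; all-zero genes carry NA p and padj.
#'
#' @param fc [fraction_counts()] object (fraction samples only).
#' @param design a [fraction_design()].
#' @param padj_threshold LRT significance threshold (default 0.01).
#' @param posthoc_p post-hoc per-fraction threshold (default 0.01).
#' @param reduced_with_condition see [profile_lrt()].
#' @return data.frame with one row per gene: `gene`, `stat`, `df`, `p`,
#'   `padj`, `significant`, per-fraction post-hoc p-value columns
#'   (`p_f4` ...), and flags `changed_any`, `changed_mono`,
#'   `changed_light`, `changed_heavy`.
#' @export
analyze_profiles <- function(fc, design = fraction_design(),
                             padj_threshold = 0.01, posthoc_p = 0.01,
                             reduced_with_condition = FALSE) {
  stopifnot(inherits(fc, "fraction_counts"))
  samples <- fc$samples[fc$samples$assay == "fraction", ]
  counts <- fc$counts[, samples$sample, drop = FALSE]
  sf <- estimate_size_factors(counts)
  cells <- interaction(samples$condition, samples$fraction, drop = TRUE)
  alpha <- estimate_dispersion(counts, sf, cells)
  mm <- fraction_model_matrices(samples, design, reduced_with_condition)
  norm <- sweep(counts, 2, sf, "/")
  n <- nrow(counts)
  stat <- p <- rep(NA_real_, n)
  ph <- matrix(NA_real_, n, length(design$fractions))
  flags <- matrix(FALSE, n, 4)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    full <- fit_nb_glm(y, mm$full, sf, alpha[i])
    reduced <- fit_nb_glm(y, mm$reduced, sf, alpha[i])
    lr <- nb_lrt(full, reduced)
    stat[i] <- lr$stat; p[i] <- lr$p
    pt <- posthoc_fraction_tests(norm[i, ], samples, design, posthoc_p)
    ph[i, ] <- pt$p
    flags[i, ] <- c(pt$changed_any, pt$changed_mono, pt$changed_light,
                    pt$changed_heavy)
  }
  padj <- bh_adjust(p)
  res <- data.frame(gene = rownames(counts), stat = stat,
                    df = ncol(mm$full) - ncol(mm$reduced), p = p,
                    padj = padj,
                    significant = !is.na(padj) & padj < padj_threshold,
                    stringsAsFactors = FALSE)
  colnames(ph) <- paste0("p_f", design$fractions)
  res <- cbind(res, as.data.frame(ph))
  res$changed_any <- flags[, 1]; res$changed_mono <- flags[, 2]
  res$changed_light <- flags[, 3]; res$changed_heavy <- flags[, 4]
  rownames(res) <- NULL
  res
}

#' Ribosome-association differential test
#'
#' Collapses the 13 fraction counts to one ribosome-associated count per
#' condition x replicate (sum over fractions) and runs the two-group Wald
#' NB test on the collapsed matrix (its own size factors and
#' dispersions).
#'
#' @param fc [fraction_counts()] object.
#' @param design a [fraction_design()].
#' @param padj_threshold significance threshold on padj (default 0.01).
#' @return [nb_wald_de()] data.frame plus a `significant` flag.
#' @export
ribosome_association_de <- function(fc, design = fraction_design(),
                                    padj_threshold = 0.01) {
  stopifnot(inherits(fc, "fraction_counts"))
  samples <- fc$samples[fc$samples$assay == "fraction", ]
  counts <- fc$counts[, samples$sample, drop = FALSE]
  grp <- interaction(samples$condition, samples$replicate, drop = TRUE)
  collapsed <- vapply(levels(grp), function(g) {
    rowSums(counts[, grp == g, drop = FALSE])
  }, numeric(nrow(counts)))
  rownames(collapsed) <- rownames(counts)
  cond <- factor(sub("\\..*$", "", levels(grp)), levels = design$conditions)
  res <- nb_wald_de(collapsed, cond)
  res$significant <- !is.na(res$padj) & res$padj < padj_threshold
  res
}

#' RiboLoad: proportion of a gene's reads in heavy polysomes
#'
#' For each condition, size-factor-normalized counts are averaged over
#' replicates per fraction; RiboLoad is the heavy-fraction sum divided by
#' the sum over all fractions (so it is invariant to per-sample depth).
#' The fold is treatment over reference, and a gene is called changed
#' when the fold falls outside the open interval
#' `(window[1], window[2])`, i.e. fold <= 0.75 or >= 1.25 by default.
#'
#' @param fc [fraction_counts()] object.
#' @param design a [fraction_design()].
#' @param window unchanged-fold window, default `c(0.75, 1.25)`.
#' @return data.frame: `gene`, `riboload_<ref>`, `riboload_<trt>`,
#'   `fold`, `changed`. Genes with zero total in a condition get NA and
#'   are counted in attribute `n_zero_total`.
#' @export
riboload <- function(fc, design = fraction_design(),
                     window = c(0.75, 1.25)) {
  stopifnot(inherits(fc, "fraction_counts"))
  samples <- fc$samples[fc$samples$assay == "fraction", ]
  counts <- fc$counts[, samples$sample, drop = FALSE]
  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  heavy <- design$heavy
  rl <- vapply(design$conditions, function(cc) {
    sel <- samples$condition == cc
    m <- vapply(design$fractions, function(f) {
      rowMeans(norm[, sel & samples$fraction == f, drop = FALSE])
    }, numeric(nrow(norm)))
    tot <- rowSums(m)
    hv <- rowSums(m[, match(heavy, design$fractions), drop = FALSE])
    ifelse(tot > 0, hv / tot, NA_real_)
  }, numeric(nrow(counts)))
  fold <- rl[, 2] / rl[, 1]
  out <- data.frame(gene = rownames(counts), rl1 = rl[, 1], rl2 = rl[, 2],
                    fold = fold,
                    changed = !is.na(fold) &
                      (fold <= window[1] | fold >= window[2]),
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("riboload_", design$conditions)
  attr(out, "n_zero_total") <- sum(is.na(fold))
  rownames(out) <- NULL
  out
}

#' Per-gene polysome profile plot data
#'
#' Mean and sd of normalized counts per fraction and condition for
#' selected genes, the numbers behind a per-gene polysome profile plot.
#'
#' @param fc [fraction_counts()] object.
#' @param genes gene ids (default all).
#' @param design a [fraction_design()].
#' @return data.frame (gene, condition, fraction, mean, sd).
#' @export
profile_plot_data <- function(fc, genes = NULL,
                              design = fraction_design()) {
  samples <- fc$samples[fc$samples$assay == "fraction", ]
  counts <- fc$counts[, samples$sample, drop = FALSE]
  if (is.null(genes)) genes <- rownames(counts)
  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  grid <- expand.grid(fraction = design$fractions,
                      condition = design$conditions, gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$mean <- grid$sd <- NA_real_
  for (k in seq_len(nrow(grid))) {
    sel <- samples$condition == grid$condition[k] &
      samples$fraction == grid$fraction[k]
    v <- norm[grid$gene[k], sel]
    grid$mean[k] <- mean(v); grid$sd[k] <- sd(v)
  }
  grid[c("gene", "condition", "fraction", "mean", "sd")]
}
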