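#' Classify genes by abundance and translation changes
#'
#' Combines the two primary calls — differential total mRNA abundance and
#' differential ribosome association (both at padj < 0.01 upstream) — into
#' the four-way class `neither` / `abundance_only` / `translation_only` /
#' `both`, and reports the Venn arithmetic: set sizes, intersection,
#' differences, and the integer percentages in the style "x% of the
#' abundance set shows no translation change".
#'
#' @param abundance_genes gene ids significant in total-mRNA abundance,
#'   or a named logical vector over the universe.
#' @param translation_genes gene ids significant in ribosome association,
#'   or a named logical vector.
#' @param universe gene universe; defaults to the union of all names/ids
#'   supplied. Ids outside the universe are dropped with a warning.
#' @param profile,riboload optional [analyze_profiles()] and [riboload()]
#'   results; their flags are merged into the table as extra columns.
#' @return data.frame (gene, abundance_change, ribo_change, class, plus
#'   any merged flag columns); attribute `venn` is a list with
#'   `n_abundance`, `n_translation`, `n_both`, `n_abundance_only`,
#'   `n_translation_only`, `pct_abundance_only_of_abundance`,
#'   `pct_both_of_translation`.
#' @examples
#' cl <- classify_genes(paste0("g", 1:6340),
#'                      paste0("g", c(1:2985, 7001:7595)),
#'                      universe = paste0("g", 1:20000))
#' attr(cl, "venn")$n_translation_only  # 595
#' @export
classify_genes <- function(abundance_genes, translation_genes,
                           universe = NULL, profile = NULL,
                           riboload = NULL) {
  as_ids <- function(x) {
    if (is.logical(x)) names(x)[x] else as.character(x)
  }
  ab <- unique(as_ids(abundance_genes))
  tr <- unique(as_ids(translation_genes))
  if (is.null(universe)) {
    universe <- sort(unique(c(ab, tr,
                              if (is.logical(abundance_genes))
                                names(abundance_genes),
                              if (is.logical(translation_genes))
                                names(translation_genes))))
  }
  lost <- length(setdiff(ab, universe)) + length(setdiff(tr, universe))
  if (lost) {
    warning(lost, " significant id(s) not in the gene universe; dropped")
    ab <- intersect(ab, universe); tr <- intersect(tr, universe)
  }
  a <- universe %in% ab
  t <- universe %in% tr
  cls <- ifelse(a & t, "both",
                ifelse(a, "abundance_only",
                       ifelse(t, "translation_only", "neither")))
  out <- data.frame(gene = universe, abundance_change = a,
                    ribo_change = t, class = cls, stringsAsFactors = FALSE)
  if (!is.null(profile)) {
    out <- merge(out, profile[c("gene", "changed_any", "changed_mono",
                                "changed_light", "changed_heavy")],
                 by = "gene", all.x = TRUE, sort = FALSE)
  }
  if (!is.null(riboload)) {
    rb <- riboload[c("gene", "fold", "changed")]
    names(rb) <- c("gene", "riboload_fold", "riboload_change")
    out <- merge(out, rb, by = "gene", all.x = TRUE, sort = FALSE)
  }
  out <- out[match(universe, out$gene), ]
  rownames(out) <- NULL
  n_both <- sum(a & t)
  venn <- list(
    n_abundance = sum(a), n_translation = sum(t), n_both = n_both,
    n_abundance_only = sum(a & !t), n_translation_only = sum(t & !a),
    pct_abundance_only_of_abundance =
      round(100 * sum(a & !t) / max(sum(a), 1)),
    pct_both_of_translation = round(100 * n_both / max(sum(t), 1)))
  attr(out, "venn") <- venn
  out
}

#' Cross-tabulate gene classes against target tiers
#'
#' For each cDNA-count tier, the fraction of genes in each class and the
#' fraction carrying each polysome-distribution flag.
#'
#' @param classes [classify_genes()] output (flag columns used when
#'   present).
#' @param tiers [stratify_targets()] output on the same gene universe.
#' @return data.frame with one row per tier: `tier`, `n`, `prop_<class>`
#'   for the four classes (rows sum to 1), and `prop_<flag>` for any flag
#'   columns. Empty tiers get NA proportions.
#' @export
crosstab_targets <- function(classes, tiers) {
  m <- merge(classes, tiers[c("gene", "tier")], by = "gene")
  lvls <- c("0", "1+", "10+", "25+", "50+")
  cls <- c("neither", "abundance_only", "translation_only", "both")
  flags <- intersect(c("changed_any", "changed_mono", "changed_light",
                       "changed_heavy", "riboload_change"), names(m))
  out <- lapply(lvls, function(tl) {
    sub <- m[m$tier == tl, ]
    n <- nrow(sub)
    props <- if (n) {
      vapply(cls, function(cc) mean(sub$class == cc), numeric(1))
    } else {
      setNames(rep(NA_real_, length(cls)), cls)
    }
    fl <- if (n) {
      vapply(flags, function(f) mean(sub[[f]], na.rm = TRUE), numeric(1))
    } else {
      setNames(rep(NA_real_, length(flags)), flags)
    }
    c(list(tier = tl, n = n), as.list(setNames(props, paste0("prop_", cls))),
      if (length(flags)) as.list(setNames(fl, paste0("prop_", flags))))
  })
  do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
}

#' High-expression window around a mean log2 expression
#'
#' Windows of expression are built on the raw count scale by adding and
#' subtracting `delta_counts` reads around the mean: lower =
#' log2(2^mean - delta), upper = log2(2^mean + delta).
#'
#' @param mean_log2 mean expression in log2 counts.
#' @param delta_counts half-width on the raw count scale (default 1000).
#' @param mean_counts optional per-gene mean normalized counts; when
#'   given, the genes falling inside the window are returned too.
#' @return list with `lower`, `upper` (log2 scale) and, when
#'   `mean_counts` was supplied, logical `in_window`.
#' @examples
#' w <- expression_window(11.63)
#' round(c(w$lower, w$upper), 2)
#' @export
expression_window <- function(mean_log2, delta_counts = 1000,
                              mean_counts = NULL) {
  center <- 2^mean_log2
  if (center <= delta_counts) {
    stop("2^mean_log2 must exceed delta_counts")
  }
  out <- list(lower = log2(center - delta_counts),
              upper = log2(center + delta_counts))
  if (!is.null(mean_counts)) {
    out$in_window <- mean_counts >= 2^out$lower &
      mean_counts <= 2^out$upper
  }
  out
}

#' Wilcoxon rank-sum comparison of fold changes
#'
#' Two-sided rank-sum test of the fold-change distribution of a gene
#' subset (e.g. a high-expression window) against all genes.
#'
#' @param all_fc numeric fold changes (typically log2) of all genes.
#' @param subset_fc fold changes of the subset; must be non-empty.
#' @return the two-sided p-value.
#' @export
window_shift_test <- function(all_fc, subset_fc) {
  if (!length(subset_fc)) stop("subset is empty")
  if (!length(all_fc)) stop("all-genes vector is empty")
  wilcox.test(all_fc, subset_fc, alternative = "two.sided")$p.value
}
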