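#' Pipeline configuration
#'
#' Centralizes every analysis threshold: padj < 0.01 for the differential
#' calls, raw p < 0.01 for the per-fraction post-hoc tests, permutation
#' FDR < 0.05 for iCLIP peaks, the (0.75, 1.25) RiboLoad unchanged
#' window, and the strict > 50 unique-cDNA target cut.
#'
#' @param padj differential-expression significance threshold.
#' @param posthoc_p per-fraction post-hoc threshold.
#' @param iclip_fdr peak-enrichment FDR cutoff.
#' @param riboload_window unchanged RiboLoad fold window (pair).
#' @param target_cut strict unique-cDNA target threshold.
#' @param design a [fraction_design()].
#' @param seed integer seed for stochastic stages.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(padj = 0.01, posthoc_p = 0.01,
                            iclip_fdr = 0.05,
                            riboload_window = c(0.75, 1.25),
                            target_cut = 50L,
                            design = fraction_design(), seed = 1L) {
  stopifnot(padj > 0, padj < 1, posthoc_p > 0, posthoc_p < 1,
            iclip_fdr > 0, iclip_fdr < 1,
            length(riboload_window) == 2,
            riboload_window[1] < riboload_window[2],
            target_cut >= 0, inherits(design, "fraction_design"))
  structure(list(padj = padj, posthoc_p = posthoc_p,
                 iclip_fdr = iclip_fdr,
                 riboload_window = riboload_window,
                 target_cut = as.integer(target_cut), design = design,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(logs, stage, n_in, n_out) {
  message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
  rbind(logs, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                         stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' de -> profile -> riboload -> (optional iclip) -> integrate, on count
#' matrices plus optional crosslink data. Writes one TSV per result table
#' and a summary JSON (Venn counts, tier crosstab) under `out_dir`; runs
#' are deterministic under a fixed config seed.
#'
#' @param polysome,totals [fraction_counts()] objects (fraction samples
#'   and total-mRNA samples).
#' @param config a [pipeline_config()].
#' @param crosslinks optional crosslink data.frame for the iCLIP branch.
#' @param gene_models required when `crosslinks` is given.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return list with `total_de`, `ribo_de`, `profile`, `riboload`,
#'   `classes`, `summary`, and when crosslinks were supplied `peaks`,
#'   `tiers`, `crosstab`; `log` holds the per-stage record counts.
#' @export
run_pipeline <- function(polysome, totals, config = pipeline_config(),
                         crosslinks = NULL, gene_models = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(polysome, "fraction_counts"),
            inherits(totals, "fraction_counts"),
            inherits(config, "pipeline_config"))
  if (!is.null(crosslinks) && is.null(gene_models)) {
    stop("iclip stage enabled but no gene annotation supplied")
  }
  design <- config$design
  logs <- data.frame()
  set.seed(config$seed)

  tot_counts <- totals$counts
  cond <- factor(totals$samples$condition, levels = design$conditions)
  total_de <- nb_wald_de(tot_counts, cond)
  total_de$significant <- !is.na(total_de$padj) & total_de$padj < config$padj
  logs <- stage_log(logs, "de_total", nrow(tot_counts),
                    sum(total_de$significant))

  ribo_de <- ribosome_association_de(polysome, design, config$padj)
  logs <- stage_log(logs, "de_ribo", nrow(polysome$counts),
                    sum(ribo_de$significant))

  profile <- analyze_profiles(polysome, design, config$padj,
                              config$posthoc_p)
  logs <- stage_log(logs, "profile", nrow(polysome$counts),
                    sum(profile$significant, na.rm = TRUE))

  rload <- riboload(polysome, design, config$riboload_window)
  logs <- stage_log(logs, "riboload", nrow(polysome$counts),
                    sum(rload$changed, na.rm = TRUE))

  peaks <- tiers <- crosstab <- NULL
  if (!is.null(crosslinks)) {
    ann <- annotate_features(crosslinks, gene_models)
    peaks <- peak_enrichment(ann, gene_models, n_perm = 100L,
                             fdr_cut = config$iclip_fdr,
                             seed = config$seed)
    sig <- peaks[peaks$significant, ]
    tiers <- stratify_targets(sig, genes = rownames(tot_counts),
                              target_cut = config$target_cut)
    logs <- stage_log(logs, "iclip", nrow(crosslinks), nrow(sig))
  }

  # gene universe: genes detected in the total-mRNA matrix
  universe <- total_de$gene[total_de$baseMean > 0]
  classes <- classify_genes(total_de$gene[total_de$significant],
                            ribo_de$gene[ribo_de$significant],
                            universe = universe, profile = profile,
                            riboload = rload)
  logs <- stage_log(logs, "integrate", length(universe), nrow(classes))
  if (!is.null(tiers)) crosstab <- crosstab_targets(classes, tiers)

  summary <- list(venn = attr(classes, "venn"),
                  thresholds = config[c("padj", "posthoc_p", "iclip_fdr",
                                        "riboload_window", "target_cut")],
                  n_genes = length(universe))
  if (!is.null(crosstab)) summary$tier_crosstab <- crosstab

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(total_de, "total_de.tsv"); wt(ribo_de, "ribo_de.tsv")
    wt(profile, "profile.tsv"); wt(rload, "riboload.tsv")
    wt(classes, "classes.tsv"); wt(logs, "stage_log.tsv")
    if (!is.null(peaks)) wt(peaks, "peaks.tsv")
    if (!is.null(tiers)) wt(tiers, "tiers.tsv")
    if (!is.null(crosstab)) wt(crosstab, "tier_crosstab.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(total_de = total_de, ribo_de = ribo_de, profile = profile,
       riboload = rload, classes = classes, peaks = peaks, tiers = tiers,
       crosstab = crosstab, summary = summary, log = logs)
}
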