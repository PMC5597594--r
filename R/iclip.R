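feature_precedence <- c("3UTR", "5UTR", "ORF", "ncRNA", "intron",
                        "intergenic")

#' Annotate crosslink sites with genomic features
#'
#' Strand-aware overlap of crosslink sites with gene-model feature
#' intervals; a site overlapped by several features gets the label
#' highest in the precedence order 3UTR > 5UTR > ORF > ncRNA > intron >
#' intergenic (mature-mRNA features first). Sites outside every model are
#' intergenic. The per-library feature distribution is weighted by unique
#' cDNA counts.
#'
#' @param crosslinks data.frame (contig, position, strand, count) as from
#'   [assign_crosslinks()].
#' @param gene_models [make_gene_models()]-shaped data.frame.
#' @return `crosslinks` with `feature` and `gene_id` columns added;
#'   attribute `distribution` holds the count-weighted feature fractions
#'   (summing to 1).
#' @export
annotate_features <- function(crosslinks, gene_models) {
  sites <- GenomicRanges::GRanges(
    crosslinks$contig,
    IRanges::IRanges(crosslinks$position + 1L, width = 1L),
    strand = crosslinks$strand)
  feats <- GenomicRanges::GRanges(
    gene_models$contig,
    IRanges::IRanges(gene_models$start + 1L, gene_models$end),
    strand = gene_models$strand)
  hits <- GenomicRanges::findOverlaps(sites, feats)
  lab <- rep("intergenic", nrow(crosslinks))
  gid <- rep(NA_character_, nrow(crosslinks))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    rank <- match(gene_models$feature[sh], feature_precedence)
    ord <- order(qh, rank)
    first <- !duplicated(qh[ord])
    lab[qh[ord][first]] <- gene_models$feature[sh[ord][first]]
    gid[qh[ord][first]] <- gene_models$gene_id[sh[ord][first]]
  }
  out <- crosslinks
  out$feature <- lab
  out$gene_id <- gid
  w <- tapply(out$count, factor(out$feature, levels = feature_precedence),
              sum, default = 0)
  attr(out, "distribution") <- w / sum(w)
  out
}

window_scores <- function(pos, counts, half_window) {
  vapply(pos, function(p) {
    sum(counts[abs(pos - p) <= half_window])
  }, numeric(1))
}

#' Permutation peak enrichment of crosslink sites
#'
#' Per gene (or intergenic segment), each site's score is the summed
#' unique-cDNA count in a +/- `half_window` nt window. The null is built
#' by re-placing the gene's crosslink events uniformly at random within
#' the gene span `n_perm` times; the FDR of a score s is the mean
#' permuted number of sites scoring >= s divided by the observed number
#' scoring >= s, clipped to `[0, 1]`. Sites with FDR below `fdr_cut` are
#' significant.
#'
#' @param crosslinks annotated crosslinks (needs `gene_id`; intergenic
#'   sites are grouped into fixed `segment_size` windows per contig).
#' @param gene_models [make_gene_models()]-shaped data.frame.
#' @param half_window half window in nt (default 15, a 31-nt window).
#' @param n_perm number of permutations (default 100; must be >= 1).
#' @param fdr_cut significance cutoff (default 0.05).
#' @param seed integer seed for the permutations.
#' @param segment_size segment length for intergenic sites (default
#'   10000).
#' @return `crosslinks` with `score`, `fdr` and `significant` columns
#'   added.
#' @export
peak_enrichment <- function(crosslinks, gene_models, half_window = 15L,
                            n_perm = 100L, fdr_cut = 0.05, seed = 1L,
                            segment_size = 10000L) {
  if (n_perm < 1) stop("n_perm must be a positive integer")
  set.seed(seed)
  spans <- gene_spans(gene_models)
  cl <- crosslinks
  if (is.null(cl$gene_id)) cl <- annotate_features(cl, gene_models)
  grp <- ifelse(is.na(cl$gene_id),
                paste0("seg:", cl$contig, ":",
                       cl$position %/% segment_size),
                cl$gene_id)
  cl$score <- NA_real_; cl$fdr <- NA_real_
  for (g in unique(grp)) {
    idx <- which(grp == g)
    pos <- cl$position[idx]; cnt <- cl$count[idx]
    if (startsWith(g, "seg:")) {
      lo <- (pos[1] %/% segment_size) * segment_size
      span <- c(lo, lo + segment_size)
    } else {
      sp <- spans[spans$gene_id == g, ]
      span <- c(sp$start, sp$end)
    }
    obs <- window_scores(pos, cnt, half_window)
    n_events <- sum(cnt)
    thr <- sort(unique(obs))
    perm_ge <- matrix(0, n_perm, length(thr))
    for (b in seq_len(n_perm)) {
      rp <- span[1] + sample.int(span[2] - span[1], n_events,
                                 replace = TRUE) - 1L
      tab <- table(rp)
      ppos <- as.integer(names(tab)); pcnt <- as.integer(tab)
      ps <- window_scores(ppos, pcnt, half_window)
      perm_ge[b, ] <- vapply(thr, function(s) sum(ps >= s), numeric(1))
    }
    exp_ge <- colMeans(perm_ge)
    obs_ge <- vapply(thr, function(s) sum(obs >= s), numeric(1))
    fdr_s <- pmin(pmax(exp_ge / obs_ge, 0), 1)
    # enforce monotone non-increasing FDR in the score threshold
    fdr_s <- rev(cummin(rev(fdr_s)))
    cl$score[idx] <- obs
    cl$fdr[idx] <- fdr_s[match(obs, thr)]
    if (length(idx) == 1L && cnt == 1L) cl$fdr[idx] <- 1
  }
  cl$significant <- cl$fdr < fdr_cut
  cl
}

#' Tier genes by unique 3'UTR cDNA counts
#'
#' Sums significant 3'UTR crosslink counts per gene and assigns nested
#' tiers at thresholds 1/10/25/50 (>=). A gene is a target when its total
#' strictly exceeds `target_cut` (default 50).
#'
#' @param annotated annotated (and typically enrichment-filtered)
#'   crosslinks with `gene_id`, `feature`, `count`.
#' @param genes gene universe (ids); genes without 3'UTR sites get tier
#'   "0".
#' @param target_cut strict threshold for `is_target` (default 50).
#' @return data.frame (gene, utr3_count, tier, is_target); tiers are
#'   `"0"`, `"1+"`, `"10+"`, `"25+"`, `"50+"` (highest attained).
#' @export
stratify_targets <- function(annotated, genes = NULL, target_cut = 50L) {
  u3 <- annotated[annotated$feature == "3UTR" & !is.na(annotated$gene_id), ]
  tot <- tapply(u3$count, u3$gene_id, sum)
  if (is.null(genes)) genes <- sort(unique(names(tot)))
  cnt <- ifelse(genes %in% names(tot), tot[genes], 0L)
  cnt[is.na(cnt)] <- 0L
  tier <- cut(cnt, breaks = c(-Inf, 0, 9, 24, 49, Inf),
              labels = c("0", "1+", "10+", "25+", "50+"))
  data.frame(gene = genes, utr3_count = as.integer(cnt),
             tier = as.character(tier), is_target = cnt > target_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}
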