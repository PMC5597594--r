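#' Generate synthetic gene models
#'
#' Tiles `n_genes` non-overlapping gene models along synthetic contigs.
#' Each gene carries, in transcript orientation, a 5'UTR, an ORF
#' (optionally split by one intron) and a 3'UTR; coordinates are 0-based
#' half-open genomic intervals and the 3'UTR lies downstream of the ORF in
#' transcript orientation (left-of on the minus strand). A U-rich window
#' inside each 3'UTR is recorded for the iCLIP simulator.
#'
#' @param n_genes number of genes.
#' @param genes_per_contig genes tiled per contig (default 50).
#' @param utr5_len,orf_len,utr3_len feature lengths in nt.
#' @param intron_prob probability that the ORF is split by one intron.
#' @param intron_len intron length in nt.
#' @param gap intergenic gap between consecutive genes.
#' @param seed integer seed.
#' @return data.frame of class `gene_models` with columns `gene_id`,
#'   `contig`, `strand`, `feature` (`5UTR`/`ORF`/`intron`/`3UTR`),
#'   `start`, `end` (0-based half-open); attribute `utr3_windows` is a
#'   data.frame (gene_id, contig, strand, start, end) of the U-rich
#'   windows, and `contig_lengths` a named vector.
#' @export
make_gene_models <- function(n_genes, genes_per_contig = 50L,
                             utr5_len = 150L, orf_len = 900L,
                             utr3_len = 600L, intron_prob = 0.3,
                             intron_len = 400L, gap = 2000L, seed = 1L) {
  set.seed(seed)
  rows <- list()
  windows <- list()
  for (i in seq_len(n_genes)) {
    gene <- sprintf("gene%05d", i)
    contig <- sprintf("chr%d", (i - 1L) %/% genes_per_contig + 1L)
    slot <- (i - 1L) %% genes_per_contig
    strand <- sample(c("+", "-"), 1L)
    has_intron <- runif(1) < intron_prob
    tx_len <- utr5_len + orf_len + utr3_len + if (has_intron) intron_len else 0L
    g0 <- slot * (tx_len + gap) + gap
    # transcript-ordered feature lengths
    feats <- if (has_intron) {
      half <- orf_len %/% 2L
      data.frame(feature = c("5UTR", "ORF", "intron", "ORF", "3UTR"),
                 len = c(utr5_len, half, intron_len, orf_len - half,
                         utr3_len), stringsAsFactors = FALSE)
    } else {
      data.frame(feature = c("5UTR", "ORF", "3UTR"),
                 len = c(utr5_len, orf_len, utr3_len),
                 stringsAsFactors = FALSE)
    }
    if (strand == "-") feats <- feats[rev(seq_len(nrow(feats))), ]
    starts <- g0 + cumsum(c(0L, head(feats$len, -1L)))
    rows[[i]] <- data.frame(gene_id = gene, contig = contig,
                            strand = strand, feature = feats$feature,
                            start = starts, end = starts + feats$len,
                            stringsAsFactors = FALSE)
    u3 <- rows[[i]][rows[[i]]$feature == "3UTR", ]
    wlen <- min(60L, u3$end - u3$start)
    woff <- sample.int(u3$end - u3$start - wlen + 1L, 1L) - 1L
    windows[[i]] <- data.frame(gene_id = gene, contig = contig,
                               strand = strand, start = u3$start + woff,
                               end = u3$start + woff + wlen,
                               stringsAsFactors = FALSE)
  }
  gm <- do.call(rbind, rows)
  rownames(gm) <- NULL
  cl <- tapply(gm$end + gap, gm$contig, max)
  structure(gm, utr3_windows = do.call(rbind, windows),
            contig_lengths = setNames(as.integer(cl), names(cl)),
            class = c("gene_models", "data.frame"))
}

#' Span of each gene (all features merged)
#'
#' @param gene_models a [make_gene_models()] data.frame.
#' @return data.frame (gene_id, contig, strand, start, end), 0-based
#'   half-open.
#' @export
gene_spans <- function(gene_models) {
  sp <- do.call(rbind, lapply(split(gene_models, gene_models$gene_id),
    function(g) data.frame(gene_id = g$gene_id[1], contig = g$contig[1],
                           strand = g$strand[1], start = min(g$start),
                           end = max(g$end), stringsAsFactors = FALSE)))
  rownames(sp) <- NULL
  sp
}
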