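#' Read a count matrix with its sample sheet
#'
#' Counts are a TSV with the gene id in the first column and one column
#' per sample; the sample sheet is a TSV with columns `sample`,
#' `condition`, `replicate`, `fraction` (empty/NA for total-mRNA
#' samples), `assay`. Duplicate gene ids are summed (transcripts
#' collapsed by gene id). Non-integer or negative cells and sample-sheet
#' mismatches are errors naming the offending row/column.
#'
#' @param counts_path path to the counts TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @return a [fraction_counts()] object.
#' @export
read_counts <- function(counts_path, sample_sheet_path) {
  tab <- read.delim(counts_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  sheet <- read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  if (!"fraction" %in% names(sheet)) sheet$fraction <- NA_integer_
  if (!"assay" %in% names(sheet)) {
    sheet$assay <- ifelse(is.na(sheet$fraction), "total", "fraction")
  }
  gene <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
    stop("non-numeric counts in column '", names(tab)[-1][bad], "'")
  }
  if (any(m < 0) || any(m != floor(m))) {
    idx <- which(m < 0 | m != floor(m), arr.ind = TRUE)[1, ]
    stop("invalid count at gene '", gene[idx[1]], "', sample '",
         colnames(m)[idx[2]], "': counts must be non-negative integers")
  }
  unknown <- setdiff(colnames(m), sheet$sample)
  if (length(unknown)) {
    stop("sample(s) not in sample sheet: ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(gene)) {
    m <- rowsum(m, gene)
    gene <- rownames(m)
  } else {
    rownames(m) <- gene
  }
  sheet <- sheet[match(colnames(m), sheet$sample), ]
  fraction_counts(m, sheet)
}

#' Write a count matrix and its sample sheet
#'
#' @param fc [fraction_counts()] object.
#' @param counts_path,sample_sheet_path output TSV paths.
#' @return invisibly, the paths.
#' @export
write_counts <- function(fc, counts_path, sample_sheet_path) {
  tab <- data.frame(gene = rownames(fc$counts), fc$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fc$samples, sample_sheet_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, sample_sheet_path))
}

#' Write crosslink sites or peaks as BED6
#'
#' The score column carries the unique-cDNA count for crosslinks, or the
#' FDR scaled by 1000 for peak windows.
#'
#' @param x data.frame with `contig`, `position`, `strand` and either
#'   `count` or `fdr`.
#' @param path output path.
#' @param score `"count"` or `"fdr"`.
#' @return invisibly, the path.
#' @export
write_bed <- function(x, path, score = c("count", "fdr")) {
  score <- match.arg(score)
  gr <- GenomicRanges::GRanges(
    x$contig, IRanges::IRanges(x$position + 1L, width = 1L),
    strand = x$strand)
  S4Vectors::mcols(gr)$name <- if (!is.null(x$gene_id)) {
    ifelse(is.na(x$gene_id), ".", x$gene_id)
  } else rep(".", nrow(x))
  S4Vectors::mcols(gr)$score <- if (score == "count") {
    x$count
  } else round(1000 * x$fdr)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read BED6 crosslink sites
#'
#' @param path BED file path (0-based starts, as BED).
#' @return data.frame (contig, position, strand, count) with the BED
#'   score read back as the count.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             position = GenomicRanges::start(gr) - 1L,
             strand = as.character(GenomicRanges::strand(gr)),
             count = as.integer(S4Vectors::mcols(gr)$score),
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with `id`, `sequence`, `qualities`.
#' @param path output path (uncompressed FASTQ).
#' @return invisibly, the path.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$id
  quals <- Biostrings::BStringSet(reads$qualities)
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a read data.frame
#'
#' @param path FASTQ path.
#' @return data.frame (id, sequence, qualities).
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  data.frame(id = names(seqs), sequence = unname(as.character(seqs)),
             qualities = unname(as.character(S4Vectors::mcols(seqs)$qualities)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read gene models as GTF-like TSV
#'
#' Columns gene_id, contig, strand, feature, start, end with 0-based
#' half-open coordinates.
#'
#' @param gene_models [make_gene_models()]-shaped data.frame.
#' @param path TSV path.
#' @return invisibly the path / the data.frame.
#' @export
write_gene_models <- function(gene_models, path) {
  write.table(as.data.frame(gene_models), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  gm <- read.delim(path, stringsAsFactors = FALSE)
  structure(gm, class = c("gene_models", "data.frame"))
}
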