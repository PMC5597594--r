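#' Demultiplex barcoded reads
#'
#' Two barcode schemes are supported. `polyribo`: a separate 10-base
#' barcode read of which the first 5 bases identify the library and the
#' last 5 are the random PCR-deduplication barcode (UMI). `iclip`: the
#' first 7 bases of the read itself, 3 known + 4 random; the 7 barcode
#' bases are removed from the returned sequence. Matching to the known set
#' is exact by default.
#'
#' @param reads data.frame with columns `id`, `sequence` and, for the
#'   polyribo scheme, `barcode` (the 10-base barcode read).
#' @param known_barcodes named character vector, sample id -> known barcode
#'   bases (5 for polyribo, 3 for iclip); must be unique.
#' @param scheme `"polyribo"` or `"iclip"`.
#' @param max_mismatch allowed mismatches to a known barcode (default 0,
#'   exact matching; 1 allows rescue when unambiguous).
#' @return the input data.frame with columns `sample` (or `"unassigned"`)
#'   and `umi` added; iclip sequences have the 7 barcode bases stripped.
#' @export
demultiplex <- function(reads, known_barcodes, scheme = c("polyribo", "iclip"),
                        max_mismatch = 0L) {
  scheme <- match.arg(scheme)
  klen <- if (scheme == "polyribo") 5L else 3L
  ulen <- if (scheme == "polyribo") 5L else 4L
  if (anyDuplicated(known_barcodes)) {
    stop("known barcodes must be unique within a scheme")
  }
  if (any(nchar(known_barcodes) != klen)) {
    stop("known barcodes for scheme '", scheme, "' must have ", klen, " bases")
  }
  if (is.null(names(known_barcodes))) {
    names(known_barcodes) <- known_barcodes
  }
  bc <- if (scheme == "polyribo") {
    if (is.null(reads$barcode)) stop("polyribo scheme needs a 'barcode' column")
    reads$barcode
  } else {
    substr(reads$sequence, 1L, klen + ulen)
  }
  known <- substr(bc, 1L, klen)
  umi <- substr(bc, klen + 1L, klen + ulen)
  if (max_mismatch == 0L) {
    idx <- match(known, known_barcodes)
  } else {
    idx <- vapply(known, function(k) {
      d <- vapply(known_barcodes, function(b) {
        sum(utf8ToInt(k) != utf8ToInt(b))
      }, integer(1))
      hit <- which(d <= max_mismatch)
      if (length(hit) == 1L) hit else NA_integer_
    }, integer(1), USE.NAMES = FALSE)
  }
  reads$sample <- ifelse(is.na(idx), "unassigned", names(known_barcodes)[idx])
  reads$umi <- umi
  if (scheme == "iclip") {
    reads$sequence <- substr(reads$sequence, klen + ulen + 1L,
                             nchar(reads$sequence))
    if (!is.null(reads$qualities)) {
      reads$qualities <- substr(reads$qualities, klen + ulen + 1L,
                                nchar(reads$qualities))
    }
  }
  reads
}

#' Collapse PCR duplicates to unique cDNAs
#'
#' A unique cDNA is one distinct (sample, contig, position, length, UMI)
#' tuple (strand kept alongside): reads sharing mapping position, length and
#' random barcode are PCR duplicates of one molecule. Records with a
#' missing or empty UMI are rejected with a warning.
#'
#' @param assigned data.frame with columns `sample`, `contig`, `position`
#'   (0-based 5' end in transcript orientation is up to the caller; the
#'   tuple is taken as given), `length`, `strand`, `umi`.
#' @return data.frame of unique cDNA records (one row per tuple, original
#'   column set), with attribute `n_rejected` counting dropped records and
#'   `n_input` the input size.
#' @export
deduplicate <- function(assigned) {
  need <- c("sample", "contig", "position", "length", "strand", "umi")
  miss <- setdiff(need, names(assigned))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- is.na(assigned$umi) | assigned$umi == ""
  if (any(bad)) {
    warning(sum(bad), " record(s) without UMI rejected")
    assigned <- assigned[!bad, , drop = FALSE]
  }
  key <- paste(assigned$sample, assigned$contig, assigned$position,
               assigned$length, assigned$umi, sep = "\r")
  out <- assigned[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  attr(out, "n_input") <- length(bad)
  out
}

#' Derive crosslink sites from unique cDNAs
#'
#' The nucleotide immediately 5' of a read's first aligned base (position
#' -1 in transcript orientation) marks the protein--RNA crosslink. On the
#' plus strand the site is `position - 1`; on the minus strand the 5' end
#' in genomic coordinates is `position + length - 1` and the site is one
#' base further right. Sites falling outside the contig are skipped and
#' counted.
#'
#' @param cdnas unique cDNA data.frame from [deduplicate()]; `position` is
#'   the 0-based leftmost genomic coordinate.
#' @param contig_lengths optional named integer vector bounding each
#'   contig; right-boundary checks are skipped when absent.
#' @return data.frame (contig, position, strand, count) sorted by contig
#'   then position, one row per site; attribute `n_skipped` counts
#'   out-of-bounds records.
#' @export
assign_crosslinks <- function(cdnas, contig_lengths = NULL) {
  five_prime <- ifelse(cdnas$strand == "+", cdnas$position,
                       cdnas$position + cdnas$length - 1L)
  site <- ifelse(cdnas$strand == "+", five_prime - 1L, five_prime + 1L)
  keep <- site >= 0L
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[as.character(cdnas$contig)]
    keep <- keep & (is.na(lim) | site < lim)
  }
  skipped <- sum(!keep)
  if (!any(keep)) {
    out <- data.frame(contig = character(), position = integer(),
                      strand = character(), count = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- skipped
    return(out)
  }
  d <- data.frame(contig = as.character(cdnas$contig)[keep],
                  position = site[keep],
                  strand = as.character(cdnas$strand)[keep],
                  stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(d))),
                          by = d[c("contig", "position", "strand")],
                          FUN = sum)
  agg <- agg[order(agg$contig, agg$position, agg$strand), ]
  rownames(agg) <- NULL
  attr(agg, "n_skipped") <- skipped
  agg
}
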