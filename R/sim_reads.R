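random_bases <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# synthetic A-depleted read body (alignment is out of scope: the true
# gene/position travels with the read, so bodies only need to not collide
# with the poly(A) trimming rules)
body_bases <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

inject_duplicates <- function(n_mol, dup_rate) {
  if (dup_rate <= 0) return(seq_len(n_mol))
  extra <- rbinom(1L, n_mol, dup_rate / (1 - dup_rate))
  c(seq_len(n_mol), sample.int(n_mol, extra, replace = TRUE))
}

#' Simulate barcoded 3'-end reads with poly(A) tails
#'
#' Emulates the PolyRibo-3' library layout: each molecule yields a 10-base
#' barcode read (5 known library bases + 5 random deduplication bases) and
#' a body read from near the 3' end of a gene, run into an appended A-tail
#' of configurable length and purity. PCR duplicates are injected at the
#' stated rate (a duplicate shares its molecule's barcode, position and
#' tail).
#'
#' @param gene_models [make_gene_models()] output (3'UTRs required).
#' @param sample_barcodes named character vector, sample -> 5 known bases.
#' @param n_molecules distinct molecules per sample.
#' @param body_len read-body length before the tail (default 40).
#' @param tail_len mean A-tail length (Poisson; default 20).
#' @param tail_purity per-base probability that a tail base is A.
#' @param dup_rate expected fraction of reads that are PCR duplicates.
#' @param seed integer seed.
#' @return list with `reads` (data.frame: id, sequence, qualities,
#'   barcode) and `truth` (data.frame: id, sample, gene, position, length,
#'   umi, molecule) where `position` is the 0-based body start within the
#'   gene span and `molecule` identifies the originating molecule.
#' @export
simulate_reads_3prime <- function(gene_models, sample_barcodes,
                                  n_molecules = 1000L, body_len = 40L,
                                  tail_len = 20L, tail_purity = 0.95,
                                  dup_rate = 0.3, seed = 1L) {
  if (dup_rate < 0 || dup_rate >= 1) stop("dup_rate must lie in [0, 1)")
  if (any(nchar(sample_barcodes) != 5L)) {
    stop("polyribo sample barcodes must have 5 bases")
  }
  set.seed(seed)
  spans <- gene_spans(gene_models)
  out_reads <- list(); out_truth <- list()
  for (s in names(sample_barcodes)) {
    gi <- sample.int(nrow(spans), n_molecules, replace = TRUE)
    span_len <- spans$end[gi] - spans$start[gi]
    # 3'-anchored: body starts within the last 200 nt of the gene span
    offs <- pmax(span_len - body_len - sample.int(200L, n_molecules,
                                                  replace = TRUE), 0L)
    umi <- random_bases(n_molecules, 5L)
    body <- body_bases(n_molecules, body_len)
    tl <- rpois(n_molecules, tail_len)
    tails <- vapply(tl, function(k) {
      if (k == 0L) return("")
      b <- ifelse(runif(k) < tail_purity, "A",
                  sample(c("C", "G", "T"), k, replace = TRUE))
      paste(b, collapse = "")
    }, character(1))
    take <- inject_duplicates(n_molecules, dup_rate)
    ids <- sprintf("%s_read%06d", s, seq_along(take))
    out_reads[[s]] <- data.frame(
      id = ids,
      sequence = paste0(body[take], tails[take]),
      qualities = strrep("I", body_len + tl[take]),
      barcode = paste0(sample_barcodes[[s]], umi[take]),
      stringsAsFactors = FALSE)
    out_truth[[s]] <- data.frame(
      id = ids, sample = s, gene = spans$gene_id[gi][take],
      position = offs[take], length = body_len, umi = umi[take],
      molecule = sprintf("%s_mol%06d", s, take), stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, c(out_reads, make.row.names = FALSE)),
       truth = do.call(rbind, c(out_truth, make.row.names = FALSE)))
}

#' Simulate iCLIP reads around planted crosslink sites
#'
#' Per gene, crosslink events are drawn at a tier-dependent Poisson rate
#' and placed preferentially inside the gene's U-rich 3'UTR window. Each
#' event yields a read starting one nucleotide downstream (transcript
#' orientation) of its crosslink site, carrying a 7-base 5' barcode (3
#' known + 4 random); PCR duplicates are injected at the stated rate.
#'
#' @param gene_models [make_gene_models()] output.
#' @param target_tiers named character vector, gene_id -> tier in
#'   `c("0", "1+", "10+", "25+", "50+")`.
#' @param sample_barcode 3 known bases of the library barcode.
#' @param tier_lambda expected unique-cDNA counts per tier.
#' @param window_frac probability that an event falls in the U-rich
#'   window (rest uniform over the 3'UTR).
#' @param read_lens candidate read lengths (uniformly drawn).
#' @param dup_rate expected fraction of PCR-duplicate reads.
#' @param seed integer seed.
#' @return list with `reads` (id, sequence, qualities; barcode is the
#'   sequence prefix), `truth` (id, sample, gene, contig, strand,
#'   position, length, umi, site: the true crosslink position) and
#'   `sites` (contig, position, strand, gene_id, count of events).
#' @export
simulate_iclip_reads <- function(gene_models, target_tiers,
                                 sample_barcode = "ACG",
                                 tier_lambda = c("0" = 0, "1+" = 3,
                                                 "10+" = 15, "25+" = 35,
                                                 "50+" = 80),
                                 window_frac = 0.8, read_lens = 25:50,
                                 dup_rate = 0.2, seed = 1L) {
  if (nchar(sample_barcode) != 3L) stop("iclip known barcode has 3 bases")
  stopifnot(all(target_tiers %in% names(tier_lambda)))
  set.seed(seed)
  wins <- attr(gene_models, "utr3_windows")
  u3 <- gene_models[gene_models$feature == "3UTR", ]
  rows <- list()
  for (g in names(target_tiers)) {
    lam <- tier_lambda[[target_tiers[[g]]]]
    if (lam == 0) next
    nev <- rpois(1L, lam)
    if (nev == 0L) next
    w <- wins[wins$gene_id == g, ]
    u <- u3[u3$gene_id == g, ]
    inwin <- runif(nev) < window_frac
    pos <- ifelse(inwin,
                  w$start + sample.int(w$end - w$start, nev,
                                       replace = TRUE) - 1L,
                  u$start + sample.int(u$end - u$start, nev,
                                       replace = TRUE) - 1L)
    rows[[g]] <- data.frame(gene = g, contig = u$contig, strand = u$strand,
                            site = pos, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no crosslink events generated; check tiers")
  ev <- do.call(rbind, c(rows, make.row.names = FALSE))
  nev <- nrow(ev)
  ev$umi <- random_bases(nev, 4L)
  ev$length <- sample(read_lens, nev, replace = TRUE)
  # read starts 1 nt downstream of the crosslink in transcript orientation
  ev$position <- ifelse(ev$strand == "+", ev$site + 1L,
                        ev$site - ev$length)
  take <- inject_duplicates(nev, dup_rate)
  ids <- sprintf("iclip_read%06d", seq_along(take))
  body <- body_bases(length(take), max(read_lens))
  reads <- data.frame(
    id = ids,
    sequence = paste0(sample_barcode, ev$umi[take],
                      substr(body, 1L, ev$length[take])),
    qualities = strrep("I", 7L + ev$length[take]),
    stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, sample = "iclip", gene = ev$gene[take],
                      contig = ev$contig[take], strand = ev$strand[take],
                      position = ev$position[take], length = ev$length[take],
                      umi = ev$umi[take], site = ev$site[take],
                      stringsAsFactors = FALSE)
  sites <- stats::aggregate(list(count = rep(1L, nev)),
                            by = ev[c("contig", "site", "strand", "gene")],
                            FUN = sum)
  names(sites)[names(sites) == "site"] <- "position"
  names(sites)[names(sites) == "gene"] <- "gene_id"
  sites <- sites[order(sites$contig, sites$position), ]
  rownames(sites) <- NULL
  list(reads = reads, truth = truth, sites = sites)
}
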