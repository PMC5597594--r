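toy_models <- function() {
  # one plus-strand gene with all features on contig c1
  data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gB"),
    contig = "c1", strand = "+",
    feature = c("5UTR", "ORF", "3UTR", "5UTR", "ORF", "3UTR"),
    start = c(100L, 200L, 1100L, 2000L, 2100L, 3000L),
    end = c(200L, 1100L, 1700L, 2100L, 3000L, 3600L),
    stringsAsFactors = FALSE)
}

test_that("feature annotation uses the stated precedence", {
  gm <- toy_models()
  cl <- data.frame(contig = "c1", position = c(1200L, 5000L, 150L, 250L),
                   strand = "+", count = c(10L, 1L, 2L, 3L),
                   stringsAsFactors = FALSE)
  ann <- annotate_features(cl, gm)
  expect_equal(ann$feature, c("3UTR", "intergenic", "5UTR", "ORF"))
  expect_equal(ann$gene_id[1], "gA")
  expect_true(is.na(ann$gene_id[2]))
  dist <- attr(ann, "distribution")
  expect_equal(sum(dist), 1, tolerance = 1e-9)
  expect_equal(unname(dist[["3UTR"]]), 10 / 16)
  # precedence: a site in gA's ORF that also lies in an overlapping
  # intron wins as ORF
  gm2 <- rbind(gm, data.frame(gene_id = "gC", contig = "c1", strand = "+",
                              feature = "intron", start = 200L, end = 1100L,
                              stringsAsFactors = FALSE))
  ann2 <- annotate_features(cl, gm2)
  expect_equal(ann2$feature[4], "ORF")
  # strand-aware: a minus-strand site does not hit plus-strand features
  clm <- data.frame(contig = "c1", position = 1200L, strand = "-",
                    count = 1L, stringsAsFactors = FALSE)
  expect_equal(annotate_features(clm, gm)$feature, "intergenic")
})

test_that("peak caller keeps concentrated signal, drops uniform noise", {
  gm <- make_gene_models(6, seed = 50)
  spans <- gene_spans(gm)
  g <- spans$gene_id[1]
  # 100 events at one position of gene 1
  conc <- data.frame(contig = spans$contig[1],
                     position = spans$start[1] + 500L,
                     strand = spans$strand[1], count = 100L,
                     gene_id = g, feature = "3UTR",
                     stringsAsFactors = FALSE)
  pk <- peak_enrichment(conc, gm, seed = 51)
  expect_lt(pk$fdr, 0.05)
  expect_true(pk$significant)
  # uniform singletons across gene 2 never pass
  set.seed(52)
  pos <- sort(sample(seq(spans$start[2], spans$end[2] - 1), 40))
  pos <- pos[!duplicated(pos %/% 40)]  # spread out, one per ~40 nt
  unif <- data.frame(contig = spans$contig[2], position = pos,
                     strand = spans$strand[2], count = 1L,
                     gene_id = spans$gene_id[2], feature = "3UTR",
                     stringsAsFactors = FALSE)
  pu <- peak_enrichment(unif, gm, seed = 53)
  expect_true(all(!pu$significant))
  # determinism under a fixed seed
  pk2 <- peak_enrichment(conc, gm, seed = 51)
  expect_identical(pk, pk2)
  expect_error(peak_enrichment(conc, gm, n_perm = 0), "n_perm")
})

test_that("permutation FDR is monotone non-increasing in score", {
  gm <- make_gene_models(2, seed = 54)
  spans <- gene_spans(gm)
  set.seed(55)
  pos <- spans$start[1] + c(rep(100L, 1), 200L, 201L, 202L, 400L, 800L,
                            sample(0:1000, 12))
  cl <- data.frame(contig = spans$contig[1], position = unique(pos),
                   strand = spans$strand[1],
                   count = sample(1:20, length(unique(pos)), TRUE),
                   gene_id = spans$gene_id[1], feature = "3UTR",
                   stringsAsFactors = FALSE)
  pk <- peak_enrichment(cl, gm, seed = 56)
  o <- order(pk$score)
  expect_true(all(diff(pk$fdr[o]) <= 1e-12))
  expect_true(all(pk$fdr >= 0 & pk$fdr <= 1))
  # single singleton event: FDR 1 by construction
  single <- cl[1, ]; single$count <- 1L
  ps <- peak_enrichment(single, gm, seed = 57)
  expect_equal(ps$fdr, 1)
})

test_that("target tiers are nested with the strict >50 target rule", {
  ann <- data.frame(gene_id = c("g1", "g1", "g2", "g3", "g4"),
                    feature = c("3UTR", "3UTR", "3UTR", "3UTR", "ORF"),
                    count = c(40L, 20L, 10L, 50L, 99L),
                    stringsAsFactors = FALSE)
  tt <- stratify_targets(ann, genes = c("g1", "g2", "g3", "g4", "g5"))
  expect_equal(tt$utr3_count, c(60L, 10L, 50L, 0L, 0L))
  expect_equal(tt$tier, c("50+", "10+", "50+", "0", "0"))
  # >50 strict: 60 is a target, exactly 50 is not (but still tier 50+)
  expect_equal(tt$is_target, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("tier 50+ genes recover is_target on the generator", {
  gm <- make_gene_models(30, seed = 58)
  tiers <- setNames(rep(c("0", "50+"), times = c(15, 15)),
                    sprintf("gene%05d", 1:30))
  sim <- simulate_iclip_reads(gm, tiers, dup_rate = 0.2, seed = 59)
  dm <- demultiplex(sim$reads, c(iclip = "ACG"), scheme = "iclip")
  cd <- data.frame(sample = dm$sample, contig = sim$truth$contig,
                   position = sim$truth$position,
                   length = sim$truth$length, strand = sim$truth$strand,
                   umi = dm$umi, stringsAsFactors = FALSE)
  sites <- assign_crosslinks(deduplicate(cd))
  ann <- annotate_features(sites, gm)
  pk <- peak_enrichment(ann, gm, seed = 60)
  tt <- stratify_targets(pk[pk$significant, ], genes = names(tiers))
  hot <- names(tiers)[tiers == "50+"]
  expect_gte(mean(tt$is_target[tt$gene %in% hot]), 0.9)
  expect_true(all(!tt$is_target[!tt$gene %in% hot]))
})
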