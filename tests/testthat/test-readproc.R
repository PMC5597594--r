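test_that("polyribo demultiplexing splits known barcode and UMI", {
  reads <- data.frame(id = c("r1", "r2"),
                      sequence = c("CCCGGG", "TTTAAA"),
                      barcode = c("ACGTGTTTTT", "GGGGGCCCCC"),
                      stringsAsFactors = FALSE)
  out <- demultiplex(reads, c(s1 = "ACGTG"), scheme = "polyribo")
  expect_equal(out$sample, c("s1", "unassigned"))
  expect_equal(out$umi, c("TTTTT", "CCCCC"))
  expect_error(demultiplex(reads, c(s1 = "ACGTG", s2 = "ACGTG"),
                           scheme = "polyribo"), "unique")
  expect_error(demultiplex(reads, c(s1 = "ACG"), scheme = "polyribo"),
               "5 bases")
})

test_that("iclip demultiplexing strips the 7-base barcode", {
  reads <- data.frame(id = "r1", sequence = "ACGTTTTGGGCCC",
                      qualities = "IIIIIIIIIIIII", stringsAsFactors = FALSE)
  out <- demultiplex(reads, c(lib = "ACG"), scheme = "iclip")
  expect_equal(out$sample, "lib")
  expect_equal(out$umi, "TTTT")
  expect_equal(out$sequence, "GGGCCC")
  expect_equal(nchar(out$qualities), 6L)
})

test_that("demultiplexing recovers the generator truth exactly", {
  gm <- make_gene_models(20, seed = 3)
  bcs <- c(a = "AAACC", b = "CCGGT")
  sim <- simulate_reads_3prime(gm, bcs, n_molecules = 500, dup_rate = 0.3,
                               seed = 4)
  out <- demultiplex(sim$reads, bcs, scheme = "polyribo")
  expect_identical(out$sample, sim$truth$sample)
  expect_identical(out$umi, sim$truth$umi)
})

test_that("deduplication counts distinct tuples", {
  base <- data.frame(sample = "s", contig = "g1", position = 10L,
                     length = 40L, strand = "+", umi = "AAAAA",
                     stringsAsFactors = FALSE)
  two_same <- rbind(base, base)
  expect_equal(nrow(deduplicate(two_same)), 1L)
  two_umi <- rbind(base, transform(base, umi = "CCCCC"))
  expect_equal(nrow(deduplicate(two_umi)), 2L)
  with_na <- rbind(base, transform(base, umi = NA))
  expect_warning(d <- deduplicate(with_na), "without UMI")
  expect_equal(attr(d, "n_rejected"), 1L)
})

test_that("dedup equals the brute-force distinct-tuple count and is
           idempotent", {
  set.seed(12)
  n <- 3000
  reads <- data.frame(
    sample = sample(c("a", "b"), n, TRUE),
    contig = sample(sprintf("g%02d", 1:10), n, TRUE),
    position = sample(1:50, n, TRUE),
    length = sample(c(40L, 41L), n, TRUE),
    strand = sample(c("+", "-"), n, TRUE),
    umi = replicate(n, paste(sample(c("A", "C"), 5, TRUE), collapse = "")),
    stringsAsFactors = FALSE)
  d <- deduplicate(reads)
  oracle <- nrow(unique(reads[c("sample", "contig", "position", "length",
                                "umi")]))
  expect_equal(nrow(d), oracle)
  expect_lte(nrow(d), n)
  expect_equal(nrow(deduplicate(d)), nrow(d))
})

test_that("dedup recovers the true molecule count on simulated reads", {
  gm <- make_gene_models(30, seed = 5)
  sim <- simulate_reads_3prime(gm, c(s = "ACGTG"), n_molecules = 800,
                               dup_rate = 0.5, seed = 6)
  dm <- demultiplex(sim$reads, c(s = "ACGTG"), scheme = "polyribo")
  tuples <- data.frame(sample = dm$sample, contig = sim$truth$gene,
                       position = sim$truth$position,
                       length = sim$truth$length, strand = "+",
                       umi = dm$umi, stringsAsFactors = FALSE)
  d <- deduplicate(tuples)
  expect_equal(nrow(d), length(unique(sim$truth$molecule)))
  # zero duplication: reads are already unique molecules
  sim0 <- simulate_reads_3prime(gm, c(s = "ACGTG"), n_molecules = 300,
                                dup_rate = 0, seed = 7)
  expect_equal(nrow(sim0$reads), length(unique(sim0$truth$molecule)))
})

test_that("crosslink sites sit at position -1 with strand mirroring", {
  cd <- data.frame(sample = "s", contig = "c", position = c(100L, 100L),
                   length = c(30L, 30L), strand = c("+", "-"),
                   umi = c("AAAA", "CCCC"), stringsAsFactors = FALSE)
  x <- assign_crosslinks(cd)
  expect_equal(x$position[x$strand == "+"], 99L)
  expect_equal(x$position[x$strand == "-"], 130L)
  # boundary: read at contig start has no upstream base
  cd0 <- data.frame(sample = "s", contig = "c", position = 0L,
                    length = 30L, strand = "+", umi = "AAAA",
                    stringsAsFactors = FALSE)
  x0 <- assign_crosslinks(cd0)
  expect_equal(nrow(x0), 0L)
  expect_equal(attr(x0, "n_skipped"), 1L)
  # shared site accumulates counts
  cd3 <- data.frame(sample = "s", contig = "c", position = 100L,
                    length = c(30L, 31L, 32L), strand = "+",
                    umi = c("AAAA", "CCCC", "GGGG"), stringsAsFactors = FALSE)
  x3 <- assign_crosslinks(deduplicate(cd3))
  expect_equal(x3$count, 3L)
})
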