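test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(100), "sim_config")
  expect_error(sim_config(100, class_proportions = c(
    neither = 0.5, abundance_only = 0.4, translation_only = 0.2,
    both = 0)), "sum to 1")
  expect_error(sim_config(100, fractions = c(4, 4, 5)), "increasing")
  expect_error(sim_config(100, abundance_effect = 0), "> 0")
  expect_error(sim_config(100, translation_effect = 1.2), "\\[0, 1\\)")
})

test_that("fixed seed gives identical output; matrices are valid", {
  cfg <- sim_config(150, seed = 21)
  a <- simulate_polysome_counts(cfg)
  b <- simulate_polysome_counts(cfg)
  expect_identical(a$polysome$counts, b$polysome$counts)
  expect_identical(a$totals$counts, b$totals$counts)
  expect_identical(a$truth$genes, b$truth$genes)
  expect_true(all(a$polysome$counts >= 0))
  expect_identical(storage.mode(a$polysome$counts), "integer")
  expect_equal(ncol(a$polysome$counts), 2 * 4 * 13)
  expect_equal(ncol(a$totals$counts), 2 * 4)
})

test_that("profiles are simplices and the shift moves mono mass to heavy", {
  cfg <- sim_config(300, translation_effect = 0.3, seed = 22)
  sim <- simulate_polysome_counts(cfg)
  for (p in sim$truth$profiles) {
    expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  }
  tr <- sim$truth$genes
  up <- tr$translation_shift > 0
  mono <- 1:4; heavy <- 8:13
  d_mono <- rowSums(sim$truth$profiles[[2]][, mono]) -
    rowSums(sim$truth$profiles[[1]][, mono])
  d_heavy <- rowSums(sim$truth$profiles[[2]][, heavy]) -
    rowSums(sim$truth$profiles[[1]][, heavy])
  expect_true(all(d_mono[up] < 0))
  expect_true(all(d_heavy[up] > 0))
  expect_equal(d_mono[up], -d_heavy[up], tolerance = 1e-9)
})

test_that("zero effects realize every gene as neither", {
  cfg <- sim_config(200, abundance_effect = 1, translation_effect = 0,
                    seed = 23)
  sim <- simulate_polysome_counts(cfg)
  expect_true(all(sim$truth$genes$class == "neither"))
  expect_true(all(sim$truth$genes$total_fold == 1))
  expect_identical(sim$truth$profiles[[1]], sim$truth$profiles[[2]])
})

test_that("class frequencies match proportions at n = 2000", {
  cfg <- sim_config(2000, seed = 24)
  sim <- simulate_polysome_counts(cfg)
  freq <- table(sim$truth$genes$class) / 2000
  expected <- cfg$class_proportions
  for (cl in names(expected)) {
    tol <- 3 * sqrt(expected[[cl]] * (1 - expected[[cl]]) / 2000)
    expect_lt(abs(freq[[cl]] - expected[[cl]]), tol + 1e-12)
  }
})

test_that("empirical NB moments match the specification", {
  # high-mean cells: empirical mean within 5% of the specified NB mean
  cfg <- sim_config(2000, base_mean_log = c(log(500), 0), dispersion = 0.05,
                    abundance_effect = 1, translation_effect = 0, seed = 25)
  sim <- simulate_polysome_counts(cfg)
  truth <- sim$truth
  samples <- sim$polysome$samples
  sf <- truth$size_factors
  mu_mat <- vapply(seq_len(nrow(samples)), function(j) {
    pf <- truth$profiles[[samples$condition[j]]][, paste0("f",
                                                          samples$fraction[j])]
    sf[j] * truth$genes$base_mean * pf * 13
  }, numeric(2000))
  hi <- mu_mat >= 100
  expect_gt(sum(hi), 1e5)
  rel <- abs(rowMeans((sim$polysome$counts / mu_mat - 1) * hi) /
               rowMeans(hi))
  expect_lt(mean(rel), 0.05)
  # variance identity Var = mu + alpha mu^2 at fixed mu
  set.seed(26)
  y <- matrix(rnbinom(3000 * 50, mu = 300, size = 1 / 0.05), 3000)
  v <- apply(y, 1, var)
  expect_equal(mean(v), 300 + 0.05 * 300^2, tolerance = 0.03)
})

test_that("iCLIP generator honours tiers and the -1 site contract", {
  gm <- make_gene_models(25, seed = 31)
  tiers <- setNames(rep(c("0", "1+", "10+", "25+", "50+"), each = 5),
                    sprintf("gene%05d", 1:25))
  sim <- simulate_iclip_reads(gm, tiers, seed = 32)
  expect_false(any(sim$truth$gene %in% names(tiers)[tiers == "0"]))
  # read start is 1 nt downstream of the crosslink in transcript
  # orientation on both strands
  plus <- sim$truth$strand == "+"
  expect_true(all(sim$truth$position[plus] == sim$truth$site[plus] + 1L))
  expect_true(all(sim$truth$position[!plus] + sim$truth$length[!plus] ==
                    sim$truth$site[!plus]))
  # crosslinks fall inside the gene's 3'UTR
  u3 <- gm[gm$feature == "3UTR", ]
  m <- match(sim$truth$gene, u3$gene_id)
  expect_true(all(sim$truth$site >= u3$start[m] &
                    sim$truth$site < u3$end[m]))
  # tier "50+" genes deliver >= 50 unique events with high probability
  n50 <- table(factor(sim$sites$gene_id[sim$sites$gene_id %in%
                                          names(tiers)[tiers == "50+"]]))
  tot <- tapply(sim$sites$count, sim$sites$gene_id, sum)
  expect_true(all(tot[names(tiers)[tiers == "50+"]] >= 50))
})

test_that("gene models are well-formed", {
  gm <- make_gene_models(40, seed = 33)
  expect_true(all(gm$end > gm$start))
  for (g in split(gm, gm$gene_id)) {
    o <- g[order(g$start), ]
    expect_true(all(o$start[-1] >= o$end[-nrow(o)]))  # non-overlapping
    u3 <- o[o$feature == "3UTR", ]
    orf <- o[o$feature == "ORF", ]
    if (g$strand[1] == "+") {
      expect_true(u3$start >= max(orf$end))
    } else {
      expect_true(u3$end <= min(orf$start))
    }
  }
  spans <- gene_spans(gm)
  expect_equal(nrow(spans), 40L)
})
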