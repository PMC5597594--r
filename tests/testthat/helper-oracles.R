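# Independent brute-force implementations used as oracles. These stay
# deliberately naive (full enumeration) and share no code with the package.

# leftmost start of a substring that starts and ends on 'A', holds >= a
# A's and <= m non-A bases; NA if none exists. Exhaustive enumeration of
# every (i, j) pair, vectorized with a cumulative A count.
oracle_run_start <- function(chars, a, m) {
  n <- length(chars)
  is_a <- chars == "A"
  cs <- cumsum(is_a)
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  n_a <- cs[j] - cs[i] + is_a[i]
  ok <- is_a[i] & is_a[j] & n_a >= a & (j - i + 1 - n_a) <= m
  if (!any(ok)) NA_integer_ else min(i[ok])
}

# reference trimmer: same three-stage contract, brute-force scanning
oracle_trim <- function(seq, rules = polytrans::default_trim_rules()) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  len <- length(chars)
  fired <- FALSE
  for (r in seq_len(nrow(rules$terminal))) {
    w <- rules$terminal[r, 1]; a <- rules$terminal[r, 2]
    m <- rules$terminal[r, 3]
    wlen <- min(w, len)
    if (wlen < a) next
    from <- len - wlen + 1
    s <- oracle_run_start(chars[from:len], a, m)
    if (!is.na(s)) {
      len <- from + s - 2
      chars <- chars[seq_len(len)]
      fired <- TRUE
      break
    }
  }
  if (len > 0) {
    s <- oracle_run_start(chars, rules$internal[1], rules$internal[2])
    if (!is.na(s)) {
      len <- s - 1
      chars <- chars[seq_len(len)]
      fired <- TRUE
    }
  }
  if (!fired) {
    while (len > 0 && chars[len] == "A") len <- len - 1
  }
  substr(seq, 1, len)
}

# random reads enriched in A-runs so the rules actually fire
random_reads <- function(n, min_len = 5, max_len = 70, a_bias = 0.45) {
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    p <- c(a_bias, rep((1 - a_bias) / 3, 3))
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
}

# tiny deterministic fraction_counts fixture: two conditions, nrep
# replicates, all 13 fractions
toy_fraction_counts <- function(n_genes = 20, nrep = 4, seed = 42,
                                mu = 100, alpha = 0.05) {
  set.seed(seed)
  samples <- expand.grid(fraction = 4:16, replicate = seq_len(nrep),
                         condition = c("L", "LE"), stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_r%d_f%d", samples$condition,
                            samples$replicate, samples$fraction)
  samples$assay <- "fraction"
  samples <- samples[c("sample", "condition", "replicate", "fraction",
                       "assay")]
  counts <- matrix(rnbinom(n_genes * nrow(samples), mu = mu,
                           size = 1 / alpha),
                   n_genes, nrow(samples),
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   samples$sample))
  polytrans::fraction_counts(counts, samples)
}
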