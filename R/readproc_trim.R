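#' Default poly(A) trimming rule table
#'
#' Terminal rules are ordered (window length, minimum A-tract length,
#' allowed non-A mismatches inside the tract) triples, scanned in order with
#' first match winning; the internal rule is a (minimum tract, mismatches)
#' pair applied to the whole read after terminal trimming.
#'
#' @return list with `terminal` (17 x 3 integer matrix, columns
#'   `window`, `tract`, `mismatch`) and `internal` (length-2 integer
#'   vector).
#' @export
default_trim_rules <- function() {
  terminal <- matrix(c(
    20L, 17L, 2L,  19L, 16L, 2L,  18L, 15L, 2L,  17L, 14L, 2L,
    16L, 13L, 1L,  15L, 12L, 1L,  14L, 11L, 1L,  13L, 10L, 1L,
    12L, 10L, 1L,  11L,  9L, 1L,  10L,  8L, 1L,   9L,  8L, 1L,
     8L,  7L, 0L,   7L,  6L, 0L,   6L,  5L, 0L,   5L,  3L, 0L,
     4L,  3L, 0L), ncol = 3, byrow = TRUE,
    dimnames = list(NULL, c("window", "tract", "mismatch")))
  list(terminal = terminal, internal = c(tract = 17L, mismatch = 2L))
}

validate_trim_rules <- function(rules) {
  t <- rules$terminal
  if (!is.matrix(t) || ncol(t) != 3) stop("terminal rules must be an n x 3 matrix")
  if (any(t[, 1] < t[, 2]) || any(t[, 2] < 1) || any(t[, 3] < 0)) {
    stop("each terminal rule needs window >= tract >= 1 and mismatch >= 0")
  }
  if (length(rules$internal) != 2 || rules$internal[1] < 1 ||
      rules$internal[2] < 0) {
    stop("internal rule must be (min tract >= 1, mismatches >= 0)")
  }
  invisible(rules)
}

# Leftmost start (1-based index into `is_a`) of a run containing >= a A's
# with <= m interleaved non-A bases, starting and ending on an A; NA when
# no such run exists. The minimal run from a given A-start ends at the a-th
# A after it, so a start qualifies iff the gap to that A holds <= m non-A.
run_start <- function(is_a, a, m) {
  apos <- which(is_a)
  k <- length(apos) - a + 1L
  if (k < 1L) return(NA_integer_)
  starts <- apos[seq_len(k)]
  ends <- apos[seq_len(k) + a - 1L]
  ok <- (ends - starts + 1L - a) <= m
  if (!any(ok)) return(NA_integer_)
  starts[which.max(ok)]
}

#' Trim poly(A) tracts from a 3'-end read
#'
#' Three-stage rule-based trimming of the poly(A) tail that 3'-end reads
#' run into. Stage 1 scans the terminal rule table in order: rule
#' `(w, a, m)` fires when the last `min(w, len)` bases contain a run of at
#' least `a` A's with at most `m` interleaved non-A bases (the run starts
#' and ends on an A); the first firing rule trims from the start of the
#' leftmost such run to the read end. Stage 2 applies the internal rule the
#' same way to the whole remaining read. Stage 3 strips any trailing A's,
#' but only from reads no rule fired on (reads whose terminal tract is
#' shorter than the smallest rule); the worked behaviour of the original
#' procedure keeps a genomic A immediately upstream of a removed tract.
#'
#' @param seq character vector of read sequences (A/C/G/T/N).
#' @param rules rule table from [default_trim_rules()] (the default) or a
#'   list of the same shape.
#' @return character vector of trimmed sequences (always a prefix of the
#'   input; possibly empty).
#' @examples
#' trim_polya(paste0("GATTACA", strrep("A", 20)))  # "GATTACA"
#' trim_polya("TTTTTTAA")                          # "TTTTTT"
#' @export
trim_polya <- function(seq, rules = default_trim_rules()) {
  validate_trim_rules(rules)
  vapply(seq, trim_polya_one, character(1), rules = rules, USE.NAMES = FALSE)
}

trim_polya_one <- function(seq, rules) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  is_a <- chars == "A"
  len <- length(is_a)
  fired <- FALSE
  # stage 1: terminal rules, printed order, first match wins
  for (r in seq_len(nrow(rules$terminal))) {
    w <- rules$terminal[r, 1]; a <- rules$terminal[r, 2]
    m <- rules$terminal[r, 3]
    wlen <- min(w, len)
    if (wlen < a) next
    win_from <- len - wlen + 1L
    s <- run_start(is_a[win_from:len], a, m)
    if (!is.na(s)) {
      len <- win_from + s - 2L  # keep bases before the run
      is_a <- is_a[seq_len(len)]
      fired <- TRUE
      break
    }
  }
  # stage 2: internal tract rule on the remaining read
  if (len > 0L) {
    s <- run_start(is_a, rules$internal[1], rules$internal[2])
    if (!is.na(s)) {
      len <- s - 1L
      is_a <- is_a[seq_len(len)]
      fired <- TRUE
    }
  }
  # stage 3: residual terminal A's on untouched reads
  if (!fired) {
    while (len > 0L && is_a[len]) len <- len - 1L
  }
  substr(seq, 1L, len)
}
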