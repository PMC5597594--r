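#' Fraction count matrix container
#'
#' Lightweight DGEList-style container: an integer count matrix (genes x
#' samples) plus a sample annotation table. Fraction samples carry the
#' gradient fraction label (4--16); total-mRNA samples carry
#' `fraction = NA` and `assay = "total"`.
#'
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param samples data.frame with one row per column of `counts` and
#'   columns `sample`, `condition`, `replicate`, `fraction` (integer or
#'   NA), `assay` (`"fraction"` or `"total"`).
#' @return object of class `fraction_counts`.
#' @export
fraction_counts <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("counts must be a non-negative integer matrix")
  }
  storage.mode(counts) <- "integer"
  samples <- as.data.frame(samples)
  if (nrow(samples) != ncol(counts)) {
    stop("samples must have one row per count column")
  }
  need <- c("sample", "condition", "replicate", "fraction", "assay")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet misses columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids")
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = samples),
            class = "fraction_counts")
}

#' @export
print.fraction_counts <- function(x, ...) {
  cat("fraction_counts:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "),
      "\n")
  fr <- sort(unique(x$samples$fraction[!is.na(x$samples$fraction)]))
  if (length(fr)) cat("  fractions:", paste(fr, collapse = ", "), "\n")
  if (any(x$samples$assay == "total")) {
    cat("  total-mRNA samples:", sum(x$samples$assay == "total"), "\n")
  }
  invisible(x)
}

#' @export
dim.fraction_counts <- function(x) dim(x$counts)

#' Sucrose-gradient fraction design
#'
#' Fraction labels and their grouping into monosomes, light polysomes and
#' heavy polysomes. The defaults are fractions 4--16 with monosomes 4--7,
#' light 8--10, heavy 11--16; the groups must partition the fractions.
#'
#' @param fractions ordered integer fraction labels.
#' @param monosome,light,heavy integer label subsets.
#' @param conditions pair of condition labels, reference first.
#' @return object of class `fraction_design`.
#' @export
fraction_design <- function(fractions = 4:16, monosome = 4:7, light = 8:10,
                            heavy = 11:16, conditions = c("L", "LE")) {
  if (any(diff(fractions) <= 0)) stop("fractions must be strictly increasing")
  grp <- sort(c(monosome, light, heavy))
  if (!identical(as.integer(grp), as.integer(sort(fractions)))) {
    stop("monosome/light/heavy groups must partition the fractions")
  }
  if (length(conditions) != 2L) stop("exactly two conditions are required")
  structure(list(fractions = as.integer(fractions),
                 monosome = as.integer(monosome),
                 light = as.integer(light), heavy = as.integer(heavy),
                 conditions = conditions),
            class = "fraction_design")
}

#' @export
print.fraction_design <- function(x, ...) {
  cat("fraction_design: fractions", paste(range(x$fractions), collapse = "-"),
      "| monosome", paste(range(x$monosome), collapse = "-"),
      "| light", paste(range(x$light), collapse = "-"),
      "| heavy", paste(range(x$heavy), collapse = "-"), "\n")
  invisible(x)
}
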