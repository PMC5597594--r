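#' Simulation configuration
#'
#' The stated world of the synthetic-data generator: a two-condition
#' polysome-profiling experiment (reference `L`, treatment `LE`) with four
#' biological replicates and 13 gradient fractions labelled 4--16. Genes
#' fall into four classes: `neither`, `abundance_only` (total mRNA changes,
#' ribosome association does not), `translation_only` (ribosome
#' association and polysome distribution change, total mRNA does not) and
#' `both`.
#'
#' @param n_genes number of genes.
#' @param n_replicates biological replicates per condition (default 4).
#' @param fractions ordered integer fraction labels (default 4:16).
#' @param conditions pair of condition labels, reference first.
#' @param base_mean_log `c(meanlog, sdlog)` of the lognormal distribution
#'   of per-gene expected counts per fraction sample.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2): a
#'   scalar, a per-gene vector, or `list(shape=, rate=)` for gamma-drawn
#'   per-gene values.
#' @param class_proportions named proportions over the four gene classes,
#'   summing to 1.
#' @param abundance_effect multiplicative fold (> 0) applied, with random
#'   sign of the log, to total mRNA (abundance classes) and to all
#'   fraction counts (translation classes).
#' @param translation_effect fraction (0--1) of monosome-group profile
#'   mass moved to the heavy group (or the reverse, with random sign) in
#'   translation classes.
#' @param size_factor_sdlog sdlog of the lognormal per-sample depth
#'   factors (default 0.15).
#' @param profile_concentration Dirichlet concentration of per-gene
#'   profiles around the unimodal template (default 50).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_replicates = 4L, fractions = 4:16,
                       conditions = c("L", "LE"),
                       base_mean_log = c(meanlog = log(100), sdlog = 1.2),
                       dispersion = 0.05,
                       class_proportions = c(neither = 0.7,
                                             abundance_only = 0.1,
                                             translation_only = 0.1,
                                             both = 0.1),
                       abundance_effect = 2, translation_effect = 0.3,
                       size_factor_sdlog = 0.15,
                       profile_concentration = 50, seed = 1L) {
  if (n_genes < 1 || n_replicates < 1) {
    stop("n_genes and n_replicates must be positive")
  }
  if (any(diff(fractions) <= 0)) stop("fractions must be strictly increasing")
  if (length(conditions) != 2L) stop("conditions must be a pair of labels")
  cls <- c("neither", "abundance_only", "translation_only", "both")
  if (!setequal(names(class_proportions), cls)) {
    stop("class_proportions needs exactly the names: ",
         paste(cls, collapse = ", "))
  }
  class_proportions <- class_proportions[cls]
  if (abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0)) {
    stop("class_proportions must be non-negative and sum to 1")
  }
  if (abundance_effect <= 0) stop("abundance_effect must be > 0")
  if (translation_effect < 0 || translation_effect >= 1) {
    stop("translation_effect must lie in [0, 1)")
  }
  if (is.list(dispersion)) {
    if (!all(c("shape", "rate") %in% names(dispersion))) {
      stop("gamma dispersion needs 'shape' and 'rate'")
    }
  } else if (any(dispersion <= 0)) {
    stop("dispersion must be positive")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 fractions = as.integer(fractions), conditions = conditions,
                 base_mean_log = base_mean_log, dispersion = dispersion,
                 class_proportions = class_proportions,
                 abundance_effect = abundance_effect,
                 translation_effect = translation_effect,
                 size_factor_sdlog = size_factor_sdlog,
                 profile_concentration = profile_concentration,
                 seed = as.integer(seed)),
            class = "sim_config")
}
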