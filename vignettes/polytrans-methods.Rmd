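---
title: "Models and methods behind polytrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polytrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytrans)
```

# The experimental design being modelled

polytrans analyses a two-condition polysome-profiling experiment in which
cytoplasmic extracts are separated on a sucrose gradient into 13 fractions,
labelled 4–16: fractions 4–7 carry monosome-bound mRNA, 8–10 light
polysomes, 11–16 heavy polysomes. Each fraction is sequenced from the mRNA
3′ end (counts per gene per fraction per replicate), and total cellular
mRNA abundance is measured in parallel by conventional mRNA-seq. The
default design has four biological replicates per condition, a reference
condition `L` and a treatment `LE`. The companion iCLIP branch maps the
binding sites of an RNA-binding protein on those mRNAs at nucleotide
resolution.

Three distinct questions are asked of these data, and they are kept as
separate statistical calls throughout:

* **Abundance change** — does total mRNA for a gene change between
  conditions? (Wald test on the total-mRNA matrix.)
* **Ribosome-association change** — does the amount of mRNA bound to
  ribosomes change? (Wald test on fraction counts summed over all 13
  fractions per replicate.)
* **Polysome-distribution change** — does the *shape* of the profile over
  fractions change? (Likelihood-ratio test with an interaction model, plus
  per-fraction post-hoc tests and the RiboLoad statistic.)

# The count model

All differential calls use a negative-binomial GLM with log link,

$$y_{gj} \sim \mathrm{NB}(\mu_{gj},\ \alpha_g), \qquad
\mathrm{Var}(y_{gj}) = \mu_{gj} + \alpha_g \mu_{gj}^2, \qquad
\log \mu_{gj} = x_j^\top \beta_g + \log s_j,$$

with per-sample size factors $s_j$ as offsets. The machinery is written
from scratch and kept deliberately small:

* **Size factors** (`estimate_size_factors`) use the median-of-ratios
  estimator: for genes positive in all samples, the per-sample median of
  $y_{gj} / (\prod_k y_{gk})^{1/n}$, taken on the log scale and rescaled to
  geometric mean 1. A matrix with no all-positive gene is an error rather
  than a silent fallback.
* **Dispersion** (`estimate_dispersion`) is a per-gene method-of-moments
  estimate pooled over the design cells, shrunk in log space toward a
  parametric mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$. The
  shrinkage weight is adaptive: the sampling variance of the log moment
  estimator is calibrated by Monte Carlo (re-simulating counts at the trend
  dispersion under a private, fixed RNG stream so results stay
  deterministic), and the weight on the trend is the sampling share of the
  total spread of gene estimates around the trend. Homogeneous data
  therefore shrink almost fully to the trend, which is what keeps the
  likelihood-ratio test close to its nominal size; genuinely heterogeneous
  dispersions retain per-gene signal. This is intentionally *not* a clone
  of DESeq2's empirical-Bayes machinery — it preserves the same NB-GLM/LRT
  contract while staying independently testable, and divergences from
  exact DESeq2 output are expected.
* **Fitting** (`fit_nb_glm`) is IRLS at fixed dispersion with working
  weights $\mu/(1+\alpha\mu)$, convergence at $\max|\Delta\beta| < 10^{-8}$
  or 100 iterations, linear predictors clamped to $\pm 30$. All-zero genes
  are flagged degenerate and reported downstream with NA p-values rather
  than dropped.
* **Testing**: `nb_wald` on a single coefficient (normal reference);
  `nb_lrt` between nested fits, $2(\ell_1-\ell_0)$ clipped at zero against
  $\chi^2$ with the rank difference as df. `bh_adjust` implements the
  Benjamini–Hochberg step-up directly (NAs excluded from $m$ and
  propagated).

## The polysome-distribution LRT

The full model is `count ~ condition + fraction + condition:fraction`, the
reduced model `count ~ fraction` — *as printed in the original procedure*,
i.e. without the condition main effect. The test therefore responds both to
an overall ribosome-association change and to a pure redistribution across
fractions. Because that conflation can be undesirable,
`reduced_with_condition = TRUE` switches the reduced model to
`~ condition + fraction`, isolating the interaction. With 13 fractions the
default test has 13 degrees of freedom (condition main effect plus 12
interaction terms).

Per-fraction post-hoc tests are Welch two-sample t-tests on
$\log_2(\text{normalized count} + 0.5)$ — the original procedure says only
"pairwise t-test"; the log transform stabilizes NB variance and the Welch
flavour is the safer default under unequal variances. Calls use the raw
threshold p < 0.01 with *no* correction across the 13 fractions, matching
the published procedure; group flags (monosome/light/heavy) are ORs over
their fractions. The alternative of testing within-gene fraction
*proportions* rather than normalized counts is not implemented as a mode;
counts were chosen because the LRT already operates on counts and the two
tests then share a scale.

## RiboLoad

RiboLoad is the proportion of a gene's reads in heavy polysomes: per
condition, normalized counts are averaged over replicates per fraction and
the heavy-fraction sum is divided by the sum over all 13 fractions. It is
invariant to per-sample scaling by construction. The fold is treatment over
reference, and a gene is "changed" when the fold leaves the open interval
(0.75, 1.25) — bounds treated as changed when attained, i.e. fold ≤ 0.75 or
≥ 1.25. Both the LE/L ratio direction and the bound convention follow the
published window; they are parameters of `riboload()` and
`pipeline_config()`.

# Read preprocessing

**Demultiplexing** supports the two published barcode layouts: a separate
10-base barcode read with 5 known library bases + 5 random deduplication
bases (3′-end libraries), and a 7-base in-read prefix with 3 known + 4
random (iCLIP). Matching is exact by default — the original protocol states
no mismatch tolerance — with an optional Hamming-1 rescue.

**Deduplication** collapses reads to unique cDNAs keyed by (sample,
contig, position, length, UMI): two reads agreeing in mapping position,
length and random barcode are PCR copies of one molecule.

**Poly(A) trimming** applies the published 17-rule table `(window, tract,
mismatches)` from (20, 17, 2) down to (4, 3, 0), in printed order with
first match winning; a rule fires when the terminal window contains a run
of ≥ *tract* A's with ≤ *mismatches* interleaved non-A bases (the run must
start and end on an A; mismatch minimality makes the leftmost qualifying
start well defined). The read is cut from the start of that run. The
internal rule (17, 2) then cuts at the first internal tract, and finally
trailing A's are stripped — *only* from reads no rule fired on. That
conditionality is deliberate: the worked behaviour of the reference
procedure keeps a genomic A immediately upstream of a removed tract
(`GATTACA` + 20 A's trims to `GATTACA`, not `GATTAC`), while an untouched
read with a sub-threshold tail (`TTTTTTAA`) still loses its terminal A's.
A consequence worth knowing: the map is *not* strictly idempotent — a
second pass sees re-aligned windows and can trim further. The test suite
pins both the worked examples and an explicit counterexample, and checks
the engine against an exhaustive brute-force scanner on 10^4 random reads.
Whether the firing tract must terminate the read (anchored) was left open
by the source; the run may sit anywhere in the window here, which is the
more aggressive and simpler reading.

**Crosslink extraction**: position −1 of each unique cDNA (the base
immediately 5′ of the first aligned base, in transcript orientation) is the
crosslink site; on the minus strand this mirrors to genomic
`5′end + 1`. Sites falling off the contig are skipped and counted.

# iCLIP peak enrichment

Each site's score is the summed unique-cDNA count within ±15 nt (a 31-nt
window). The null re-places the host gene's crosslink events uniformly
within the gene span (intergenic sites within fixed 10-kb segments) 100
times; the FDR at score s is the mean permuted count of sites scoring ≥ s
over the observed count scoring ≥ s, clipped to [0, 1] and made monotone
non-increasing in s. Sites with FDR < 0.05 are kept. The original analysis
used iCount, whose exact randomization region and FDR formula are not
printed; this estimator is a documented stand-in with the same inputs and
thresholds. Feature annotation resolves overlaps by the precedence
3′UTR > 5′UTR > ORF > ncRNA > intron > intergenic — the precedence is not
stated in the source; mature-mRNA features are put first because the input
is nucleus-depleted cytoplasm and the published feature distribution is
dominated by 3′UTRs. Target tiers stack at ≥ 1 / ≥ 10 / ≥ 25 / ≥ 50 unique
3′UTR cDNAs; the *target* call itself is strict (> 50), and both
conventions are reported because the source uses ">50" and "50+" side by
side.

# The synthetic-data generator

The generator is first-class, tested code and the only data source the
package needs. Its defaults state the world the analysis is built for:
2 conditions × 4 replicates × 13 fractions; per-gene expected counts
lognormal (meanlog `log(100)`, sdlog 1.2 — a typical bulk RNA-seq dynamic
range; the source does not state per-fraction depth, so it is exposed as a
parameter); NB dispersion 0.05 (a routine value for bulk replicates);
per-sample depth factors lognormal(0, 0.15); per-gene fraction profiles
Dirichlet-distributed (concentration 50) around a unimodal template peaked
in the light/heavy boundary.

Gene classes wire the condition effects. `abundance_only` genes fold their
*total-mRNA* mean (2-fold by default, random sign) while fraction counts
stay put; `translation_only` genes fold their *fraction* counts and shift a
fraction (default 30%) of monosome-group profile mass into the heavy group
(or the reverse, with the sign of the fold), with the profile renormalized;
`both` genes get both. This wiring is a deliberate interpretation: the
source's class vocabulary requires abundance-only genes to change in total
mRNA but not in ribosome association, so the "fold on all fractions" is
attached to the translation classes where ribosome association genuinely
changes. Every effect, profile and depth factor is recorded in the truth
object for parameter-recovery tests.

Read-level simulators emit the two published library layouts with
synthetic (A-depleted) bodies — genome alignment is out of scope, so the
true (gene, position) travels with each read. PCR duplicates are injected
at a stated rate; iCLIP crosslinks concentrate (80%) in a designated U-rich
3′UTR window per gene, with tier-dependent Poisson event counts (0 / 3 /
15 / 35 / 80 for tiers 0 / 1+ / 10+ / 25+ / 50+).

What a green test does **not** establish: the generator has no sequence
content worth mapping, no positional biases, no quality-score error model
beyond constant Q, no batch structure, and its profiles are smoother than
real gradient data. Recovery results calibrate the statistics, not the
full experimental pipeline.

# Numerical and design choices

* Thresholds live in `pipeline_config()`: padj < 0.01 for both
  differential calls, raw p < 0.01 for post-hoc tests, permutation
  FDR < 0.05, RiboLoad window (0.75, 1.25), target cut > 50.
* LRT statistics are clipped at zero (solver noise can make the nested
  log-likelihood fractionally higher); nested-deviance monotonicity is
  asserted to 10^-6 in the tests.
* Zero-count genes propagate NA p-values; zero-variance post-hoc cells
  give p = 1 when means agree and p = 0 when they differ.
* The gene universe for classification is the set of genes detected in the
  total-mRNA matrix.
* Reported percentages round to the nearest integer, matching the
  published "53%" / "83%" style.
* All stochastic stages take explicit seeds; a fixed seed gives
  byte-identical outputs end to end.

# Known limitations

* The dispersion estimator is moment-based; at very low counts it leans
  almost entirely on the trend, and the LRT retains a mild liberal bias
  (null rejection ≈ 1.5% at a 1% threshold in the calibration suite) that
  is inherent to plug-in dispersions with 4 replicates per cell.
* No outlier handling (Cook's distance), no independent filtering, no
  fold-change shrinkage.
* The permutation FDR is an expected/observed ratio per score level, not
  iCount's exact estimator.
* Trimming is single-pass by contract; see the idempotence caveat above.
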