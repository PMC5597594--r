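# polytrans

Differential-translation analysis for polysome-profiled 3′-end RNA-seq,
with an iCLIP branch and a ground-truthed synthetic-data generator.

## What problem this solves

Polysome profiling separates a cell's mRNA on a sucrose gradient by how
many ribosomes each transcript carries — here into 13 fractions (4–16):
monosomes (4–7), light polysomes (8–10), heavy polysomes (11–16). Each
fraction is sequenced from the mRNA 3′ end, and total mRNA abundance is
measured in parallel by mRNA-seq. Comparing two conditions (reference `L`
vs. treatment `LE`, e.g. mitogen-activated B cells with and without a
DNA-damaging agent), a gene can change in

* **abundance** — its total mRNA level,
* **ribosome association** — the amount of its mRNA bound to ribosomes,
* **polysome distribution** — the shape of its profile across fractions,

and these are decoupled in practice: translational control moves mRNA
between monosomes and heavy polysomes without touching abundance.
polytrans makes all three calls, classifies genes, and ties them to the
binding targets of an RNA-binding protein mapped by iCLIP.

## The statistics at the core

Counts are modelled as negative binomial, `Var = μ + αμ²`, with a log-link
GLM and size-factor offsets (`log μ_gj = x_jᵀβ_g + log s_j`; median-of-
ratios `s_j`, moment/trend dispersion `α_g`, IRLS fitting — all
implemented in this package):

* **Abundance / ribosome-association changes**: Wald test on the
  condition coefficient, BH-adjusted, padj < 0.01. Ribosome association
  uses fraction counts summed over the 13 fractions per replicate.
* **Polysome distribution**: likelihood-ratio test of
  `count ~ condition + fraction + condition:fraction` against
  `count ~ fraction` (χ², df 13), then per-fraction Welch t-tests on
  log2(normalized count + 0.5) at raw p < 0.01 to localize the change to
  monosome / light / heavy groups.
* **RiboLoad**: heavy-fraction reads over all reads per gene; a gene is
  changed when the LE/L fold leaves (0.75, 1.25).
* **iCLIP**: crosslink sites at read position −1, 31-nt-window permutation
  peak enrichment (100 permutations, FDR < 0.05), gene tiers at
  1+/10+/25+/50+ unique 3′UTR cDNAs, targets at > 50.

Read preprocessing implements the published barcode schemes (5+5 and 3+4
known+random bases), UMI deduplication by (position, length, UMI), and the
17-rule poly(A)-tract trimmer with the internal (17, 2) rule.

## Worked example

```r
library(polytrans)

cfg <- sim_config(n_genes = 500, seed = 42)    # 2 cond x 4 reps x 13 fractions
sim <- simulate_polysome_counts(cfg)           # counts + ground truth
res <- run_pipeline(sim$polysome, sim$totals, pipeline_config(seed = 42))
#> [de_total] in=500 out=92
#> [de_ribo] in=500 out=99
#> [profile] in=500 out=99
#> [riboload] in=500 out=61
#> [integrate] in=500 out=500

str(res$summary$venn)
#> $ n_abundance                    : int 92
#> $ n_translation                  : int 99
#> $ n_both                         : int 46
#> $ n_abundance_only               : int 46
#> $ n_translation_only             : int 53
#> $ pct_abundance_only_of_abundance: num 50
#> $ pct_both_of_translation        : num 46

head(res$riboload[res$riboload$changed, ], 3)
#>        gene riboload_L riboload_LE      fold changed
#> 1 gene00001  0.3648486   0.2237182 0.6131811    TRUE
#> 3 gene00003  0.4531896   0.2586864 0.5708128    TRUE
#> 8 gene00008  0.4333432   0.2576031 0.5944553    TRUE

mean(res$classes$class == sim$truth$genes$class)   # recovery vs. truth
#> [1] 0.986
```

Reading the output: 92 of 500 genes changed in total mRNA abundance, 99 in
ribosome association, 46 in both; `gene00001` moved mRNA out of heavy
polysomes (RiboLoad fold 0.61 < 0.75 ⇒ translationally down) and its
profile change localizes to the heavy fractions. Against the generator's
truth table the four-way classification is 98.6% accurate at these effect
sizes.

A command-line front end with `simulate`, `prep` (demultiplex + trim) and
`run` subcommands is installed at `inst/cli/polytrans`.

## Layout

* `R/` — simulator (`sim_*`), read processing (`readproc_*`), NB-GLM
  machinery (`nb_glm.R`), polysome statistics (`polysome.R`), iCLIP
  (`iclip.R`), integration (`integrate.R`), IO and pipeline.
* `tests/testthat/` — unit + property suites per module, brute-force
  oracles in `helper-oracles.R`, acceptance criteria in
  `test-acceptance.R`.
* `vignettes/polytrans-methods.Rmd` — models, assumptions, parameter
  choices and known limitations.
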