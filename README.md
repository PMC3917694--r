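# passerclock

Bayesian relaxed-clock divergence dating for multi-gene nucleotide
alignments, built around the analysis design used to date the passerine
(songbird) radiation from seven nuclear genes, five passerine fossils
and the New Zealand–Antarctica vicariance event.

For molecular systematists who want a self-contained, testable R
implementation of the full dating workflow:

* **Partitioned likelihoods** — GTR+Γ₄+I with per-partition rate
  multipliers (coding genes split into codon positions 1+2 vs 3), via
  Felsenstein pruning in C++ with exact site-pattern compression.
* **Three clock models** — strict, autocorrelated lognormal (TK02) and
  independent gamma rates (IGR, "white noise"): each branch carries a
  relative rate `r_b`; under IGR `r_b ~ Gamma(mean 1, var ν/t_b)`, so
  longer branches have less rate noise.
* **Calibrated uniform tree prior** — root age on a uniform window,
  fossil calibrations as offset-exponential densities
  (`λ = 1/(mean − offset)`), remaining node ages uniform over the
  order-constrained region, normalised *exactly* by recursive
  piecewise-polynomial integration over the tree.
* **Metropolis-coupled MCMC** with prior-only (data-free) runs that
  expose the realized calibration priors, plus convergence diagnostics
  (ASDSF, log-likelihood ESS).
* **Stepping-stone marginal likelihoods** on a Beta(0.4, 1) power ladder
  and `2 ln BF` clock-model comparison.
* **Gene-wise evaluation** — Kendall's τ between single-gene and
  combined node ages, CI-width precision tables with Kruskal–Wallis
  tests, CI overlap, saturation (p-distance vs MRCA age) tables, and
  rate-based root-age back-calculation.
* **A synthetic-data generator** emulating the seven-gene passerine
  supermatrix (622/504/419/800/749/2947/1152 bp; root Uniform(52, 85)
  Mya; fossil minima 10.4/16.3/16.3/16.3/18.0 Mya with mean 58), so the
  entire pipeline is exercisable offline.

## Worked example

```r
library(passerclock)

## a small synthetic seven-gene data set with known truth
fx <- makePasserineFixture(scale = 0.1, seed = 1, nTaxa = 14)
fx$alignment
#> MultiGeneAlignment: 14 taxa, 7 genes, 719 sites
#>   genes: MOS (62 bp), MYC (50 bp), GAPDH (42 bp), MB (80 bp),
#>          ODC1 (75 bp), RAG1 (295 bp), RAG2 (115 bp)

## date it under the wide root window (52-85 Mya), IGR clock
cfg <- scenarioConfig(fx$alignment,
                      geneLengths = sapply(fx$alignment@genes, ncol),
                      codingFlags = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                      TRUE, TRUE),
                      calibrations = fx$calibrations,
                      rootScenario = "wide", clock = "IGR",
                      nGenerations = 8000, nRuns = 2, seed = 1)
rep <- runScenario(cfg, tree = fx$tree)

rep$rootSummary[, c("median", "lower", "upper")]
#>     median    lower    upper
#> 1 68.60487 53.14553 84.36682
rootAge(fx$tree)   # the generating truth
#> [1] 65.4254
```

The root-age posterior median (here ≈ 68.6 Mya) and its central 95%
credibility interval are printed in My before present; the true
generating root age lies inside the interval. `rep$nodeAges` tabulates
every consensus clade's posterior probability, median age and CI —
the per-node table the chronogram annotations are built from — and
`rep$realizedPriorRoot` gives the data-free (realized prior) root
quantiles for comparison.

To compare clock models on the same data:

```r
ss <- steppingStoneConfig(nSteps = 12, seed = 1)
mlStrict <- steppingStoneLogml(fx$alignment, fx$scheme, fx$calibrations,
                               clockModel("strict"), ss)
mlIGR <- steppingStoneLogml(fx$alignment, fx$scheme, fx$calibrations,
                            clockModel("IGR"), ss)
bayesFactor2ln(mlIGR, mlStrict)   # > 0 favours the relaxed clock
```

A thin command-line wrapper over these functions (subcommands
`simulate | date | prior-only | select-clock | gene-eval`) is installed
at `inst/scripts/passerclock.R`.

## The methods vignette

`vignettes/passerclock-methods.Rmd` documents the models, priors,
proposal kernels, the exact tree-prior normalisation, the stepping-stone
estimator, every tunable default and the known limitations of the
synthetic generator.
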