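---
title: "Models and methods behind passerclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind passerclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(passerclock)
```

# What the package estimates

`passerclock` performs Bayesian divergence-time estimation for multi-gene
nucleotide alignments: given a partitioned supermatrix, a set of fossil
and geological calibrations, and a relaxed-clock model, it samples rooted
chronograms (trees with node ages in My) from the posterior by Markov
chain Monte Carlo, compares clock models by stepping-stone marginal
likelihoods, and evaluates how well individual genes reproduce the
combined time-scale.  The package is organised around the analysis design
used for dating the passerine radiation with seven nuclear genes, five
passerine fossils, and the New Zealand–Antarctica vicariance event as a
root constraint, and ships a synthetic-data generator that emulates that
design so the entire pipeline is testable without any downloads.

# Substitution model and likelihood

Each partition evolves under GTR+Γ₄+I: a general time-reversible rate
matrix normalised to one expected substitution per site, discrete-gamma
rate variation with four equal-probability categories (mean-of-bin rule,
`discretizeGamma()`; the mean rule rather than the median rule, matching
the dominant convention), and a proportion of invariant sites.  The
likelihood is computed by Felsenstein's pruning algorithm over compressed
site patterns (identical columns share computation exactly), with
per-node rescaling and log-scaler accumulation so alignments of a few
thousand sites by up to a couple of hundred taxa do not underflow.  Gaps
and `?` are treated as fully missing; IUPAC ambiguity codes contribute
partial likelihood over their compatible states.  The invariant-sites
term is combined with the gamma mixture on the log scale.

Coding genes are split into a combined first+second codon-position
partition and a third-position partition; introns form one partition
each (the reference seven-gene configuration yields eleven partitions).
Substitution models are unlinked across partitions by default
(`mcmcConfig(linkModels = )` shares one model when the generating process
is known to be shared, as for the synthetic fixture).  Per-partition rate
multipliers are constrained to a length-weighted mean of one and carry a
flat Dirichlet prior on the weighted simplex.

# Clock models

All clocks act through *relative* branch rates `r_b` multiplied by a base
clock rate `c` (substitutions/site/My):

* **strict** — `r_b = 1` everywhere;
* **IGR** (independent gamma rates, white noise) — `r_b` is an
  independent Gamma draw with mean 1 and variance `nu / t_b` for a branch
  of duration `t_b`, so longer branches average away rate noise;
* **TK02** — `r_b` is lognormal with *expectation* equal to the parent
  branch's rate and log-variance `nu * t_b`; the two root-adjacent
  branches descend from the base rate (relative rate 1), a convention the
  original model description leaves open.

The relative-rate parameterisation keeps the variance parameter `nu`
dimensionless, which is what makes the Exp(10) prior on `nu` (mean 0.1)
meaningful for both relaxed clocks.  An absolute-rate reading of the IGR
variance contract would put rate standard deviations orders of magnitude
above the rate itself under the same prior, so the package documents and
tests the relative contract.

Priors: `c` carries the empirical-Bayes lognormal prior — its median is
a strict-clock tree height in substitutions divided by the mean root age
under the root calibration (`empiricalBayesClockPrior()`), with log-SD 1;
`nu ~ Exp(10)`; `alpha ~ Exp(1)`; `pInv ~ U(0,1)`; exchangeabilities and
base frequencies carry flat Dirichlets.

# The calibrated uniform tree prior

Node ages are given the uniform tree prior extended to calibrated
settings: the root age follows its uniform calibration window, each
calibrated node's age follows its offset-exponential density
(`lambda = 1/(mean - offset)`, hard minimum at the fossil's youngest
stratigraphic bound), and the remaining internal ages are uniform over
the order-constrained feasible region given the root and calibrated
ages.  The feasible-region volume is computed *exactly* by recursive
piecewise-polynomial integration over the tree (each subtree carries a
piecewise polynomial `V(t)` = volume of valid age assignments below age
`t`; products are integrated upward in shifted local bases, with ages
rescaled by the root age for conditioning).  The density is therefore
properly normalised conditional on the calibrated ages, which the test
suite verifies by quadrature on five-taxon trees and by Monte-Carlo
volume estimation.

Two consequences worth knowing:

* with only a root calibration, the marginal prior on the root age is
  exactly the configured window (recovered by data-free MCMC);
* with internal calibrations, the *realized* marginal priors on
  calibrated nodes can differ from the specified densities because of the
  joint order constraints — the prior-only run exists precisely to expose
  those realized priors, and the package reports them rather than
  pretending the marginals are the specified ones.

The reference calibration configuration is: root Uniform(52, 85) Mya
(the wide reading of the New Zealand–Antarctica separation), five
offset-exponential fossil calibrations with minima 10.4 (Meliphagidae),
16.3 (Orthonychidae, Cracticidae, Oriolidae) and 18.0 (Certhioidea) Mya,
all with mean 58 Mya (the Tyrannidae–Laniidae divergence used as a common
prior mean), a rooting constraint making Acanthisitta sister to all
other passerines, and monophyly constraints on every calibrated clade.
Whether the "58 Mya mean" should be the mean of the full offset
distribution or of the exponential part alone is ambiguous; the package
uses the full-distribution mean and exposes both `offset` and `meanAge`
so users can configure the alternative.  The de-facto-uncalibrated root
scenario is Uniform(20, 4000) Mya, exactly as wide as it sounds.

# MCMC

`runMcmc()` runs Metropolis-coupled MCMC with chain heats
`1/(1 + (i-1)T)` (default temperature 0.1) and random-pair state swaps.
The proposal set: free-node age slides (uniform between the node's
neighbours), calibrated-node age slides, a root window draw, a whole-tree
stretch, a joint age/rate rescale (ages × f, clock rate ÷ f — this leaves
every substitution branch length unchanged and walks along the rate–time
ridge cheaply), per-branch rate slides on the log scale, a joint
`nu`/rates kernel that redraws all branch rates from their conditional
prior at the proposed `nu` (the conditional densities cancel in the Green
ratio; this defeats the funnel between `nu` and the rates), log-scale
multipliers for `c`, `nu` and `alpha`, a reflected slide for `pInv`,
concentrated-Dirichlet proposals for exchangeabilities, frequencies and
partition multipliers, and (optionally) age-compatible
nearest-neighbour interchanges that reject moves breaking a monophyly
constraint.  All Hastings ratios are exact; the data-free (prior-only)
mode doubles as a detailed-balance test because every parameter's
sampled marginal must then match its prior, which the test suite checks
by Kolmogorov–Smirnov tests on thinned samples.

Initial states draw node ages from the calibrated prior (on the supplied
topology when one is given) and branch rates from the clock prior, and
retry until the posterior kernel is finite.  Runs derive per-run seeds
from the master seed; burn-in (default 25% per run) is removed when runs
are concatenated.  Convergence reporting: effective sample size of the
log-likelihood per run, and the average standard deviation of split
frequencies (ASDSF, population-SD convention) across runs when topology
is sampled, with a warning above the conventional 0.01 threshold.

# Stepping-stone model comparison

`steppingStoneLogml()` estimates the log marginal likelihood by running
the chain down a ladder of power posteriors `L^beta * prior` with powers
at Beta(0.4, 1) quantiles (evenly spaced when shape = 1; the default
shape concentrates rungs near the prior where the integrand changes
fastest; 49 steps in the reference configuration).  The first step is
treated as burn-in via a discarded warm-up phase at power 1; each rung
contributes `log mean exp((beta_{k-1}-beta_k) * logL)` from samples drawn
at the lower power, log-sum-exp stabilised.  `bayesFactor2ln()` reports
`2 ln BF` with Kass–Raftery interpretation bands.  The estimator is
validated against a one-dimensional quadrature oracle on a fixed-tree
toy model (the only free parameter being the clock rate).

A caveat established during development and reflected in the test
design: on strict-clock data, letting the IGR variance `nu` float under
its Exp(10) prior lets the IGR marginal collapse onto the strict
marginal (the posterior concentrates at tiny `nu`), so the two marginal
likelihoods differ by less than any desk-scale Monte-Carlo error.  The
clock-recovery experiment in the test suite therefore isolates the clock
structure: the true chronology, substitution parameters and `nu` are
held at their generating values and a tighter shared lognormal rate
prior (log-SD 0.3) is used, under which the strict-data margin is a few
`2 ln BF` units and the relaxed-data margin is in the hundreds.  The
full comparison with everything free remains the default behaviour of
`steppingStoneLogml()`.

# Summaries and gene-wise evaluation

Node identity across samples is the taxon bipartition (the sorted tip
set below a node), which is robust to topological variation.
`majorityConsensus()` keeps splits with frequency above one half;
`nodeAgeSummary()` collects a split's ages from exactly the samples that
contain it and reports the mean, median and the central (equal-tailed)
95% credibility interval using linear interpolation between order
statistics (R's default quantile rule, fixed for reproducibility; HPD
intervals are deliberately not used because the reported intervals are
central ones).  A split absent from every sample yields an NA row with
posterior probability 0 — that is how missing nodes in single-gene
analyses are detected.  `writeChronogram()` emits a NEXUS trees block
whose Newick comments carry PP, median and CI bounds, and
`readChronogram()` round-trips it.

The per-gene module compares each gene's node-age medians against the
combined analysis over matched bipartitions: Kendall's τ_b (tie-corrected,
exact p for small n without ties), per-gene mean CI widths over
recovered nodes only, a Kruskal–Wallis rank test on width groups,
pairwise CI overlap (intersection over union, plus a joint-intersection
flag), saturation tables pairing each taxon pair's combined-chronogram
MRCA median age with its uncorrected p-distance, and rate-based root
back-calculation `age = height_subs * multiplier / rate` with endpoint
propagation of the rate interval.  Median (not mean) node ages feed the
saturation table; the choice is configurable by passing a different
chronogram.

# The synthetic generator

`makePasserineFixture()` emulates the reference study design: seven
genes of lengths `scale * (622, 504, 419, 800, 749, 2947, 1152)` bp
(MOS, MYC, GAPDH, MB, ODC1, RAG1, RAG2; half-up rounding for
reproducibility), codon partitioning for the four coding genes, the
calibration configuration above, a random resolved topology honouring
the monophyly constraints, ages drawn exactly from the calibrated
uniform prior (top-down inverse-CDF sampling from the subtree-volume
polynomials), branch rates from the chosen clock, and forward simulation
under GTR+Γ₄+I.  Defaults chosen once and documented: base clock rate
`c = 0.0025` subs/site/My (the scale implied by published passerine
nuclear gene rates and a late-Cretaceous root), IGR variance
`nu = 0.1` — the mean of the Exp(10) variance prior, so that recovery
experiments draw the generating clock from a configuration the inference
priors support — a shared GTR model with transition-rich
exchangeabilities, `alpha = 0.45`, `pInv = 0.2`, and partition
multipliers 0.4 (codon positions 1+2), 2.5 (position 3) and 1.3
(introns), renormalised to length-weighted mean 1.

What the generator does *not* emulate: indels and alignment error (no
gaps are simulated), among-gene tree discordance (all genes evolve on
one species tree, as the reference analysis assumes), taxon-specific
missing data blocks, and base-composition heterogeneity across lineages.
Passing tests therefore demonstrate correctness of the inferential
machinery under the model's own assumptions, not robustness to the ways
real supermatrices violate them.

# Numerical choices and problem sizes

Tolerances: likelihood oracles at 1e-8; pattern-compression identity at
1e-10; prior-recovery and detailed-balance KS tests at p > 0.01 on
thinned samples with fixed seeds.  The test suite runs desk-scale
problems chosen as the package's own validation sizes: 13–20 taxa,
gene-length scales 0.03–0.25 of the reference lengths (about 360–1800
sites), 6,000–80,000 MCMC generations per run, 20 replicates for the
coverage experiment, and 10-step stepping-stone ladders for the toy and
recovery comparisons.  The full reference budget (tens of millions of
generations, 49-step ladders) is reached by scaling the same
configuration objects up.

Known limitations: the exact volume recursion is polynomial in the ages
and conditions poorly beyond roughly a hundred taxa in one subtree
(double precision); topology proposals are age-compatible NNIs only, so
tree-space mixing on large trees is slow compared with dedicated
tree-search software; and TK02 support treats rates as branch
quantities (no node-rate averaging).
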