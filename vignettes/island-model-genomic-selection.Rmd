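---
title: "Simulating recurrent genomic selection with island-model population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating recurrent genomic selection with island-model population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The breeding problem

Autogamous (self-pollinating) cereals such as rice and wheat are bred mostly
through inbred-line selection: a cross is made, lines are inbred to near
homozygosity, and the best line is released.  Because each program works
within one or a few bi-parental crosses, few novel allele combinations ever
arise.  Recurrent selection — repeated cycles of selection and
intercrossing — fixes this, but requires evaluating single plants, which is
inaccurate phenotypically.  Genomic selection (GS) offers a way out: a
prediction model trained once on genotyped and phenotyped inbred lines can
score any plant from its marker genotype, so selection and crossing can be
repeated every generation without further phenotyping.

islandGS simulates such programs end to end and asks a design question: how
should the breeding population be structured over the cycles?  Three
topologies are compared under matched conditions:

* **discrete** — each bi-parental family (180 lines) is improved on its own;
* **bulked** — one 180-line population admixing 30 lines from each of six
  families;
* **island** — the same six 30-line subsets kept as separate subpopulations
  under independent selection, connected by a small one-directional ring
  migration of selected plants.

The island model is borrowed from population genetics via evolutionary
algorithms: subpopulations explore different regions of genotype space,
migration spreads favourable alleles without homogenizing the whole
population at once, so genetic variance — the fuel of long-term gain — is
spent more slowly.

## Simulation components

### Genomes and meiosis

A `genetic_map` assigns every marker a chromosome and a genetic position in
cM (default: 3,102 markers on 12 chromosomes, ~1,550 cM, rice-like).
Gametes are simulated under the Haldane (no-interference) model: the
crossover count on a chromosome of length $L$ cM is Poisson($L/100$),
crossover positions are uniform on the cM scale, chromosomes assort
independently, and the starting parental strand is fair.  Two markers $d$
cM apart therefore recombine with probability $(1-e^{-2d/100})/2$, which the
tests verify empirically against this closed form.  Crossover interference
and obligate chiasmata are deliberately out of scope: the no-interference
model is standard in breeding simulation and admits exact analytic checks.

Inbreeding uses single-seed descent (`ssd_advance`): one selfed seed per
line per generation, so heterozygosity halves per generation in expectation
and an F1 advanced five generations (an F6 line) retains $(1/2)^5 = 3.125\%$
of its heterozygous loci.

### Synthetic founder panels

Real diversity panels of inbred cultivars are often proprietary, so
`generate_founders` builds a synthetic stand-in with the two features the
downstream analyses rely on: ancestry-driven cluster structure and linkage
disequilibrium decaying with genetic distance.  Each founder is a doubled
(hence fully homozygous) mosaic of `n_ancestors = 8` ancestral haplotypes;
segment lengths are exponential with mean 20 cM, each segment copies the
founder's "home" ancestor with probability 0.7 (otherwise a random one),
and ancestral allele frequencies follow a U-shaped Beta(1/2, 1/2) spectrum
truncated at a minor-allele-frequency floor of 0.05.  These defaults were
chosen once as a realistic cultivar-panel caricature — strong enough
structure for Ward clustering to recover groups, LD extending over tens of
cM as in selfing crops — and are not tuned further.  What the generator
does **not** emulate: realistic rice demography, genotyping error, missing
data, and any particular real panel's allele-frequency spectrum.  Passing
pattern tests on these panels therefore demonstrates properties of the
breeding designs under a plausible genome model, not forecasts for any
specific germplasm.

Crossing parents are chosen to represent the panel's diversity
(`choose_diverse_parents`): the panel medoid — the line with minimal summed
Euclidean distance, standing in for a predominant variety — becomes the
common parent of all crosses, and the remaining parents are a greedy
maximin set.  Distances use the 0/1 homozygote recoding customary in
diversity analysis, not the $-1/0/1$ prediction coding.

### Trait architecture

100 founder-polymorphic markers become additive QTL.  Their heritability
weights follow a truncated geometric series $w_k \propto (1-a)^{k-1}$ whose
decay $a$ is solved so the effective number $(\sum w)^2 / \sum w^2$ equals
40, and which is scaled to total $h^2 = 0.6$ — a declining-effects
architecture in the Lande–Thompson tradition.  Allele-substitution effects
are calibrated marginally, $|\beta_k| = \sqrt{w_k / \mathrm{Var}(x_k)}$,
with random signs and random weight-to-locus assignment.  Because linked
QTL covary, the sum of marginal contributions is not the variance of the
sum; the whole effect vector is therefore rescaled once so the realized
founder genetic variance equals 0.6 exactly, and $\sigma^2_E = 0.4$ makes
founder phenotypic variance exactly 1.  Under LD the per-QTL proportions
are thus geometric only approximately; the totals are exact by
construction.  Environmental deviations are Normal — the conventional
choice — and dominance, epistasis and genotype-by-environment interaction
are excluded by design.

### Genomic prediction

`gblup()` fits $y = 1\beta + u + \varepsilon$ with
$\mathrm{Var}(u) = K\sigma^2_u$ and $\mathrm{Var}(\varepsilon) =
I\sigma^2_e$.  The residual covariance is the identity, the standard G-BLUP
formulation that makes the model exactly equivalent to ridge regression on
centred marker covariates — an equivalence the test suite asserts to
numerical precision on every random instance, using a primal-ridge solve as
the independent oracle.  $K$ is the VanRaden-type centred cross-product
$WW^\top / \sum_j 2p_j(1-p_j)$ over the 3,002 non-QTL markers, with markers
monomorphic in the training set removed, training-mean centring, and a
$10^{-6}$ diagonal jitter.  Variance components come from REML profiled
over $\lambda = \sigma^2_u/\sigma^2_e$ via the spectral decomposition of
the projected $K$ — deterministic, no starting values, one 1-D
optimization.  Candidates are scored by the conditional expectation
$K_\text{cross} K^{-1} \hat u$, algebraically identical to carrying them as
unobserved levels of the joint mixed model but without rebuilding a growing
system each cycle; in marker form this is simply ridge marker effects, so
per-cycle scoring is a single matrix-vector product.

### The breeding engine

Each replicate starts from six F1s (common parent × six others), advanced
by SSD to six families of 180 F6 lines.  All 1,080 lines are phenotyped
once; the model is trained once and reused for all 20 cycles unless a
model-update schedule is configured.  Per cycle and breeding unit:

1. predict GEBVs for all candidates;
2. truncation-select the top 10% (18 of 180, or 3 of 30 per island
   subpopulation), ties broken uniformly at random;
3. (island only) migrate: subpopulations are placed in a fresh random ring
   order each event and each sends one randomly chosen selected plant to
   its successor, the emigrant's slot filled by the immigrant, so selected
   sets keep size 3 and the multiset of plants is conserved;
4. mate in a single round robin — an RNG-shuffled chain
   $p_1\times p_2,\dots,p_S\times p_1$, 10 progeny per cross, every parent
   in exactly two crosses, no selfing — the practical substitute for random
   mating in an autogamous crop;
5. record metrics: attained genotypic value (the maximum true genotypic
   value among the selected plants), population mean/max/variance of true
   genotypic values, prediction accuracy (Pearson correlation of predicted
   and true values among candidates), heterozygous-locus proportion,
   fixed-locus proportion, and per-family selected counts.

Design choices made where the design was genuinely open: island
subpopulations hold 30 lines (six equal subpopulations of a 180-line
program with three selected each at 10% intensity); the island initial
subsets are the very subsets pooled by the bulked run, so the two schemes
are matched line for line; the ring order is re-randomized at every
migration event to avoid a fixed-topology artifact; migration is a swap
along the ring so set sizes never change; the chain order in round-robin
mating is re-shuffled every cycle.

### Randomness and matched pairs

Every source of randomness derives hierarchically from a root seed:
root → replicate → operation (architecture, SSD, phenotypes, subsets) →
scheme stream → (cycle, unit, step).  Consequences: all schemes of a
replicate start from identical initial populations (so between-scheme
comparisons are matched pairs, as the Wilcoxon machinery in
`wilcoxon_matched_pairs` expects); adding a scenario never perturbs the
others; and an island run with migration disabled reproduces, value for
value, six independent discrete runs of the same 30-line subsets — a
degenerate-equivalence identity the tests assert exactly.

### Statistics

`wilcoxon_matched_pairs` drops zero differences and uses the exact
signed-rank null distribution for up to 25 informative pairs — computed by
convolution over (doubled) ranks, so exactness survives ties — and the
tie-corrected normal approximation beyond; two-sided by default.
`family_bias_chisq` is the equal-proportions goodness-of-fit test.
Genotype PCA fixes component signs by making each loading vector's
largest-magnitude entry positive, so scores are reproducible across BLAS
implementations.

## Model updating

An optional schedule models the real lag between deriving new training
material and deploying a refit model: at a derivation cycle the selected
plants are selfed (10 or 30 progeny each) and advanced four further SSD
generations (five selfing cycles in total); the resulting lines are
phenotyped and the model refit on the concatenated training set replaces
the current one at the paired deployment cycle.  Monomorphy screening is
redone on the combined set.

## Numerical choices and degenerate inputs

* Genetic positions estimated from physical positions
  (`estimate_genetic_positions`) use raw-polynomial least squares per
  chromosome; non-monotone fits are monotonized by a running maximum and
  negative fits clamped to zero with a warning.
* A zero-heritability architecture yields all-zero effects and
  $\sigma^2_E = 1$; selection then produces no genetic response (asserted
  in the tests).
* Markers at identical cM positions never recombine; fully homozygous
  parents transmit their haplotype unchanged.
* Zero-variance phenotypes abort the REML fit; zero-variance prediction
  sets report accuracy as missing with a warning.

## Problem sizes in the shipped tests

The packaged checks run the full default geometry (112 founders, 3,102
markers, 1,080 training lines) with 10 matched replicates of 20 cycles for
the scheme-pattern properties, 100,000 gametes for the recombination
oracle, and 20 seeds at $n = 500$ for REML recovery — sizes chosen to make
majority-vote pattern assertions stable while keeping a full run of the
suite in the minutes range on a single core.  Scheme-level conclusions
(bulked beats the best discrete family late; the island model overtakes
bulked and is still gaining at cycle 20; prediction accuracy peaks at the
first selection, when the candidates are the training lines themselves,
and erodes as the population drifts away from the training set; genetic
variance collapses fastest in unconnected subpopulations) are asserted as
majority votes across matched replicates, not as exact values.

## Known limitations

* No mutation during breeding: all alleles trace to the founder parents
  (audited in the tests), so very long programs understate new variation.
* No crossover interference, no sex-specific maps.
* Single trait, purely additive; no dominance, epistasis or G×E.
* The synthetic founder generator is a structural caricature; absolute
  gain values depend on the panel and should be read comparatively, not
  as forecasts.
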