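---
title: "Cross-population genomic prediction with Fst-screened reference sets: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-population genomic prediction with Fst-screened reference sets: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genomic prediction trains a statistical model on a *reference* population
(animals with both genotypes and phenotypes) and predicts the additive
genetic merit — the genomic estimated breeding value (GEBV) — of
*validation* animals whose phenotypes are withheld. Accuracy collapses when
reference and target populations differ in allele frequencies and in
linkage-disequilibrium (LD) phase between markers and the causal loci
(QTL). A practical middle ground between single-population evaluation and
naive data pooling is to admit only the donor individuals that are
genetically closest to the target.

This package implements that strategy end to end, in simulation:

1. **simulate** three livestock populations with distinct demographic
   histories, a shared polygenic trait, and truncation selection on
   pedigree-BLUP EBVs;
2. **screen** markers differentiated between the target (PopA) and a donor
   (PopB or PopC) by the Weir–Cockerham fixation index, keeping loci with
   Fst strictly above a threshold (default 0.1);
3. **rank** donor individuals by the Euclidean distance between their
   genotype vector over the screened loci and the target's mean genotype
   vector, and keep the closest 10/15/20%;
4. **predict** with pedigree BLUP, GBLUP, single-step GBLUP and
   SNP-window-weighted GBLUP on single-population ("signal") and mixed
   ("cross") reference sets;
5. **score** accuracy `r = cor(GEBV, TBV)` and dispersion bias
   `b = Cov(GEBV, TBV) / Var(GEBV)` on the target's final generation,
   whose true breeding values (TBV) are known by construction.

## The simulator

### Genome and trait

The genome is a set of autosomes whose map lengths sum to a configured
total; markers and QTL are placed uniformly at random, with counts
apportioned to chromosomes by map length (largest remainder). Meiosis draws
a Poisson number of crossovers per chromosome with mean equal to the map
length in Morgans, uniform crossover positions, alternating parental
origin, and a fair-coin starting strand. Recurrent mutation toggles each
allele with a per-locus, per-generation probability (default 2.5e-5).

The trait is strictly additive: QTL effect magnitudes are gamma(shape 0.4)
draws with random signs, rescaled by a single constant so that the variance
of the TBVs over the founder cohort equals `h2 * Vp` (defaults 0.42 and
1.0; the residual variance is then 0.58). Phenotypes are
`y = mu + TBV + e`, `e ~ N(0, 0.58)`, and each record is missing with
probability 0.05. Markers are neutral and never enter the TBV.

### Demography

Each population passes through three stages:

* a **common ancestral phase** shared by all populations (desk default: 60
  generations at a constant size of 80). This phase builds the LD that
  related populations still share after they split. The study's
  populations must descend from common ancestors: were they simulated
  fully independently, they would share no marker–QTL phase at all, a
  donor-only reference would carry no transferable information, and the
  cross-population design would have nothing to find. We treat the three
  populations as related breeds;
* a **population-specific divergence phase** (desk defaults: A 25
  generations growing 100 to 450; B 25 generations growing 60 to 450;
  C 8 generations at 25 followed by 17 generations growing 25 to 450).
  Population sizes interpolate linearly within a phase. C's tight
  bottleneck gives it the slowest LD decay and the strongest
  differentiation from A; B is intermediate;
* a **recent selected phase** (desk default: 5 generations). Initial
  breeders (A: 20 sires / 200 dams; B: 21/210; C: 22/220) are drawn from
  the founders; every dam produces one offspring per generation by random
  sire–dam pairing; EBVs for all recorded animals come from pedigree BLUP
  with the sparse inverse numerator relationship matrix and the true
  variance ratio; then the worst 60% of sires and 30% of dams (A; B 50/30,
  C 50/20) are culled and replaced by the best same-sex offspring of the
  current generation.

The final generation is the validation set; the four generations before it
form the genotyped, phenotyped reference block. A multi-generation
reference matters beyond sample size: restricted maximum likelihood on a
single cohort of a population under selection, with the selection history
ignored, is biased far downward (the classic result that REML is unbiased
under selection only when the data used for selection are modelled).
Spreading the reference over four generations restores the
between-generation contrasts that identify the genetic variance.

### Desk versus full scale

The shipped `desk` configuration is what the tests, the worked examples and
the acceptance battery run; its problem sizes are a deliberate design:

* 2,000 markers on a 220 cM map. A desk marker panel scattered over the
  full 2715.85 cM bovine map would leave adjacent markers ~1.4 cM apart —
  at the simulated effective population sizes the marker–QTL r² would be
  ~0.15, markers would barely tag QTL, and GBLUP would be both inaccurate
  and overdispersed for structural rather than statistical reasons. The
  desk map is compressed so that marker density per cM is about half the
  full design's, preserving the LD regime genomic prediction depends on.
* 725 QTL, the full design's count, not a scaled-down one. With few QTL
  under a gamma(0.4) effect distribution, one or two loci carry much of
  the genetic variance and truncation selection fixes them within a few
  generations, collapsing Var(TBV) and making parameter recovery
  meaningless. Many small QTL keep the trait polygenic at desk scale.
* 5 selected generations with 20+ sires per herd. Longer or more intense
  desk selection erodes genetic variance through drift and the Bulmer
  effect; these sizes keep the genotyped generations representative of the
  founder-scaled trait architecture while still producing a clear
  selection response (the `selection = "random"` switch demonstrates it).

The `paper.yaml` profile keeps the full design (2715.85 cM, 50k markers,
1095 historical generations, 100 selected generations, five replicates);
it runs for many hours and has not been exercised end to end here.

What the desk generator does *not* emulate: genotyping error and marker
missingness (Table-style rates exist in real panels; downstream matrices
require complete genotypes, so these are not simulated), X chromosomes,
overlapping generations, migration, non-additive gene action, and any
environmental fixed-effect structure beyond a single overall mean — in
this simulation the only "fixed effect" is the population mean itself.
Passing desk-scale tests therefore says nothing about, e.g., dominance or
genotype-by-environment robustness on real data.

## The prediction machinery

All four methods solve Henderson's mixed-model equations

$$\begin{bmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda K^{-1} \end{bmatrix}
\begin{bmatrix}\hat b\\ \hat u\end{bmatrix}
= \begin{bmatrix}X'y\\ Z'y\end{bmatrix},
\qquad \lambda = \sigma_e^2/\sigma_a^2,$$

with `K` the relationship matrix of the random effects:

* **PBLUP**: `K = A`, the numerator relationship matrix (tabular method;
  its sparse inverse is assembled directly by Henderson's rules with
  inbreeding from the tabular diagonal).
* **GBLUP**: `K = G* = (1 - w) G + w I` with
  `G = Z Z' / sum(2 p_i (1 - p_i))`, `Z` the allele counts centred by
  `2 p_i`. Monomorphic markers are dropped. The blend weight `w = 0.05`
  guarantees an invertible matrix; allele frequencies come from the
  genotyped (reference + validation) set, since the base-population
  frequencies are unobservable in practice.
* **ssGBLUP**: `K^{-1} = H^{-1} = A^{-1} + [0\;0; 0\;(G^{*-1} -
  A_{22}^{-1})]`, the single-step matrix combining genotyped and
  non-genotyped animals. When the target's whole reference generation
  block is in the reference set, the target's earlier non-genotyped
  generations contribute phenotypes through `H` (that is the point of
  single-step); donor populations contribute only their selected
  individuals' records, because the rest of the donor herd is not part of
  the constructed reference set.
* **wGBLUP** (two steps): a first fit with unit SNP weights; SNP effects
  back-solved as `alpha = W Z' G^{-1} u / sum(2p(1-p))`; per-SNP variance
  weights `W_j` equal to the mean squared effect over the window of
  `2S + 1` SNPs centred on `j` (truncated at chromosome ends, divisor
  equal to the SNPs actually available), rescaled so the mean weight is 1;
  one refit with the weighted matrix `G_w = Z W Z' / sum(2p(1-p))`. The
  default window half-width is `S = 20` SNPs. The SNP-ridge model is
  solved with centred (not variance-standardised) genotype columns so that
  the `W = I` case is algebraically identical to GBLUP — an identity the
  test suite checks exactly, alongside the dual-route check of the
  SNP-space solver against a V-matrix-form GBLUP oracle.

Variance components default to the true simulated values
(`lambda = 0.58/0.42`); an EM-REML estimator (expectation–maximisation on
the mixed-model equations) is provided and is cross-checked in the tests
against an independent eigen-rotation profile-likelihood oracle.

Numerical choices: dense Cholesky factorisation for `G*`-sized matrices,
sparse Cholesky (Matrix) for pedigree-dimension systems with the dense
genomic block added as a sparse triplet batch; every accepted solve is
verified against a relative normal-equation residual below 1e-8;
rank-deficient fixed-effect designs fall back to a pseudo-inverse with a
warning; EM-REML iterates until both components change by less than the
relative tolerance (default 1e-6, cap 500 iterations — near-boundary
heritabilities converge slowly, which is inherent to EM).

## Reference-set construction

Distances use the screened-marker subset only. The target is summarised by
its per-marker mean allele count (centroid): under squared Euclidean
distance the centroid ranking equals the mean-pairwise ranking up to a
constant, at a fraction of the cost; `mean_pair` and `min_pair` are
available for comparison. Selection keeps `k = max(1, floor(fraction n))`
candidates, ties broken by ascending id. Screening is donor-specific
(A-vs-B markers for B scenarios, A-vs-C for C). The single-population
"signal" baseline uses the same selected donors alone (configurable to the
full donor herd), so signal and cross groups differ only by the presence
of the target reference. Validation animals never enter any reference set;
a leakage check runs on every scenario.

Negative Fst estimates are kept (screening uses a strict threshold and is
unaffected); loci monomorphic in both populations are undefined and
reported as 0 with a flag. The Weir–Cockerham two-population
variance-component estimator is the default; Hudson's estimator is behind
a switch.

## What the evaluation grid shows

`run_grid()` repeats the whole pipeline per replicate seed and emits a tidy
record per scenario x model x replicate. At desk scale (10 replicates) the
qualitative structure of the full-scale study reproduces: cross-population
reference sets beat the matching single-population sets for every model at
every fraction; cross-group accuracy increases from the 10% to the 20%
donor fraction; donor C's largest gains arrive by 15%; and the
population-genetic diagnostics behave (Fst(A,C) > Fst(A,B), LD decays with
distance, PopC slowest, populations separate on the first two principal
components). Absolute accuracies at desk scale are smaller than full-scale
ones — a 220 cM/2,000-marker panel tags QTL less tightly than 50k markers
— and per-cell dispersion-bias values are noisier than any single
full-scale realisation; neither magnitude is a target here.

## Known limitations

* The full-scale profile is shipped untested at that scale.
* EM-REML is slow near the heritability boundary; the profile-likelihood
  oracle in the tests is the cross-check, not a shipped alternative.
* Dispersion bias of GBLUP under truncation selection sits slightly below
  1 (validation animals are offspring of selected parents); this is a
  property of the design, not a solver defect, and is shared by the
  methods literature.
* The distance ranking assumes complete genotypes; genotyping error and
  missingness handling are out of scope.
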