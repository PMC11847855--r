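---
title: "Simulation models and methods in polybreed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation models and methods in polybreed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polybreed simulates breeding programs forward in time at arbitrary even
ploidy, with quantitative-trait loci (QTL) that may carry more than two
alleles. This vignette describes the genotypic models, the stochastic
machinery around them, the statistical evaluation used for selection, the
design choices made where several reasonable options existed, and the
limits of what the shipped experiments demonstrate.

## Genotypic models

Consider a QTL with alleles $B_1,\dots,B_{n_B}$ in a genome of ploidy $k$
(2 for diploids, 4 for tetraploids). Let $t_i \in \{0,\dots,k\}$ be the raw
dosage (copy count) of allele $i$, with $\sum_i t_i = k$. Dosages are
mapped to scaled covariates

$$t^a_i = \Bigl(t_i - \frac{k}{2}\Bigr)\frac{2}{k}, \qquad
  t^d_i = t_i\,(k - t_i)\Bigl(\frac{2}{k}\Bigr)^2 .$$

$t^a$ runs from $-1$ (allele absent) to $+1$ (allele fixed in the
genotype) and is antisymmetric in $t \mapsto k - t$; $t^d$ is 0 for the
homozygous dosages, 1 at the balanced dosage $k/2$, and symmetric. The
locus-level additive and dominance values are covariate-weighted sums of
per-allele effects, $a = \sum_i t^a_i a_i$ and $d = \sum_i t^d_i d_i$
(digenic dominance: one dominance effect per allele, shared across
partners). For a designated pair of loci $(p, q)$ the epistatic values are
bilinear forms in the two loci's covariate vectors,

$$aa = (t^a_{q} \otimes t^a_{p})\cdot \mathbf{aa}, \quad
  ad^{+} = (t^d_{q} \otimes t^a_{p})\cdot \mathbf{ad}
         + (t^a_{q} \otimes t^d_{p})\cdot \mathbf{da}, \quad
  dd = (t^d_{q} \otimes t^d_{p})\cdot \mathbf{dd},$$

with effect vectors of length $n_B^2$. The Kronecker ordering is fixed so
that the allele index of the *first* locus of the pair runs fastest; the
exhaustive double-sum oracle in the test suite pins this convention. An
individual's total genetic value $g$ sums the locus values over all QTL and
the epistatic values over all pairs; phenotypes add independent
environmental noise, $y = \mu + g + e$, $e \sim N(0, \sigma^2_e)$.

With $n_B = 2$ these models collapse to the familiar bi-allelic
parameterization: the additive values of the three diploid genotypes are
$-(a_2-a_1), 0, +(a_2-a_1)$, i.e. the substitution effect, and the
dominance and epistatic tables of the bi-allelic special case are
reproduced row by row in the tests.

## Functional effects: sampling, centering, rescaling

Effect sizes are *functional* (biological): frequency-independent
quantities attached to alleles, held constant over generations. They are
generated against a founder population in three steps:

1. **Sampling.** Additive effects are drawn i.i.d. normal. Dominance
   effects are a dominance degree $\delta \sim N(\mu_\delta,
   \sigma^2_\delta)$ (defaults 0.19 and 0.097) times the magnitude of the
   allele's additive effect, $d_i = \delta_i\,|a_i|$, so a positive mean
   dominance degree yields positive heterozygote effects. Epistatic effect
   vectors are drawn i.i.d. normal.
2. **Centering.** Additive effects are centered per QTL so that the
   founder-frequency-weighted mean allele effect, $\sum_i p_i a_i$, is
   zero. (Centering the locus *genotypic value* itself is not attainable
   for bi-allelic loci: the two scaled covariates are exact negatives of
   one another, so constant shifts of the allele effects cancel; the
   frequency-weighted form is the centering that a constant shift can and
   does achieve.) Dominance and epistatic effects are not centered;
   instead the intercept $\mu$ re-centers the founder mean of $g$ at zero.
3. **Rescaling.** Each component is multiplied by
   $\sqrt{\sigma^2_{\text{target}}/\sigma^2_{\text{realized}}}$ so its
   realized functional variance in the founders equals the target. The
   realized variance is computed `by_individual` by default (the empirical
   variance of the component total, which includes LD covariance between
   loci); `by_locus` (a sum of per-locus variances) is available. The
   additive-dominance components $\mathbf{ad}$ and $\mathbf{da}$ are
   rescaled jointly against the variance of their summed value.

A component with a positive target but zero realized prior variance (for
example a founder panel of clones) cannot be rescaled and raises an error.

## Founder genomes

Linkage disequilibrium (LD) between QTL and markers is built by simulating
a historical population: candidate loci are placed uniformly on a genome
of 12 chromosomes totalling 888.6 cM, every locus starts at equal allele
frequencies, and the population mates randomly for 1,000 discrete
generations at effective size 200 with a bottleneck (size 100 in
generations 901-950, configurable). Meiosis uses bivalent chromosome
pairing at every ploidy: homologs pair two-by-two at random, each bivalent
contributes one recombinant chromatid with a Poisson($L$ Morgans)
crossover count and uniform positions (Haldane mapping, no interference),
which excludes double reduction in polyploids.

Pure drift at these parameters fixes most loci: measured on 3,000
simulated loci, only ~9% of diploid bi-allelic loci remain segregating at
MAF $\ge 0.05$ and essentially none retain four alleles. A design that
draws thousands of segregating markers and quad-allelic QTL from candidate
pools of a few tens of thousands therefore requires a diversity-maintaining
force during the historical phase. The simulator supports a K-allele
mutation rate (a gene copy is replaced by a uniformly drawn allele of its
locus, historical phase only); the shipped experiment configurations use
$\mu_m = 2.5\times10^{-3}$ per copy and generation ($\theta = 4N_e\mu_m =
2$), which reproduces the locus-class yields the experimental design
implies (~86% of bi-allelic candidates and ~15% of quad-allelic candidates
usable for diploids). The default of the simulator itself is no mutation.

Founders (100 individuals) are drawn as fresh offspring of the final
historical generation. QTL and marker panels are then selected: markers
must carry exactly two alleles, both at frequency $\ge 0.05$ in the
founders; a QTL assigned $c$ segregating alleles must carry exactly $c$
alleles above that threshold, with class counts following the scenario's
allelism profile.

## Genomic evaluation

Selection from generation 6 onwards uses GBLUP with generation as the only
fixed effect. The additive relationship matrix is VanRaden-type at the
scenario's ploidy, $G_u = WW^\top / (k \sum_j p_j(1-p_j))$ with $W$ the
counted-allele dosages centered by $k p_j$; allele frequencies are
recomputed from all genotyped individuals at each evaluation. Digenic
dominance matrices use the heterosis coding ($-2p^2, 2pq, -2q^2$) for
diploids and, for tetraploids, the digenic heterozygous-pair count
$t(4-t)$ centered by its Hardy-Weinberg expectation $12pq$ and normalized
by its HWE variance $36pq - 120p^2q^2$; both have zero HWE mean and unit
expected diagonal. Epistatic matrices are Hadamard products
($G_u \odot G_u$, $G_u \odot G_v$, $G_v \odot G_v$).

Variance components are estimated once, at generation 6, on the 4,000
phenotypes of generations 1-5, by average-information REML with
expectation-maximization fallback steps (step-halved so the restricted
likelihood never decreases), a relative log-likelihood tolerance of
$10^{-8}$, at most 200 iterations, and variances clamped at a small
positive floor and flagged when they collapse. With a single relationship
matrix the problem is rotated once to the eigenbasis of $G_u$, making
every REML iteration O(n). Estimates are reused for prediction in
generations 6-13. Should a model with non-additive terms fail to converge
— common for the epistatic model, whose components are barely separable in
data of this size — the scheme falls back to the additive-only model and
records that in the trajectory details.

For the additive prediction model the per-generation BLUP solve is
performed in marker space: the augmented normal equations of the
equivalent ridge (SNP-BLUP) model are assembled from incrementally
maintained marker statistics and solved by Cholesky factorization in
O($m^3$) for $m$ markers, instead of O($n^3$) in the ever-growing number
of records. The two routes are algebraically identical and the test suite
checks they agree to $10^{-8}$. Prediction models with dominance or
epistatic terms use the dense matrix route. Selection is always truncation
on the additive BLUP $\hat u$; accuracy is the Pearson correlation of true
and predicted additive values of the 800 generation-6 candidates, and the
rate of gain is (mean at generation 13 − mean at generation 5)/8, on the
additive scale for the additive-only experiment and on the total genetic
value for the full-model experiment.

## Breeding scheme

Each generation, 80 parents are crossed pseudo-randomly into 80 families
of 10 full sibs (800 offspring): parents are replicated up to the
contribution cap of 4, shuffled and paired, and self-pairs are repaired by
swapping partners between families. Every offspring is genotyped and
phenotyped. Parents of generations 2-6 are selected at random from the
previous 800 offspring; thereafter the top 80 by $\hat u$ (ties broken by
id order). The founder-to-scheme handoff selects 80 of the 100 founders at
random. All stochastic steps draw from R's RNG, so one seed per replicate
reproduces a run bitwise; nested replication (founder population x scheme)
derives per-replicate seeds from the master seed.

## Problem sizes of the shipped experiments

The full experimental design (2,000 QTL and 10,000 markers drawn from
candidate pools of 10,000 and 50,000, 50 founder replicates x 10 scheme
replicates) is larger than is sensible for a package check, so the shipped
`scale = "desk"` configurations keep the breeding design, genome length,
historical parameters and trait model unchanged and reduce the panels and
replication: 2,000 QTL, 5,000 markers (candidate pools 4,000/8,000), and 5
founder replicates with one scheme replicate each. Marker density was kept
at or above half the reference density because the within-family component
of selection accuracy — the part that drives genetic gain — degrades
noticeably below ~5 markers/cM, while the generation-6 accuracy (driven
largely by family relationships) is insensitive to it.

## What the simulations do and do not show

The synthetic founder populations emulate drift-mutation-recombination
equilibrium with a recent bottleneck. They do not emulate real potato LD
(domestication history, selective sweeps, variable recombination along
chromosomes), genotyping error, allele-calling uncertainty in
autotetraploids, or non-collinear marker ascertainment; conclusions about
absolute accuracies in real programs do not follow. Two quantitative
caveats measured during development are worth knowing. First, the REML
additive variance estimated through the *marker*-based G is attenuated
roughly 10% relative to the simulated functional variance because markers
tag the QTL imperfectly; the parameter-recovery acceptance test therefore
uses a relationship matrix built from the causal QTL dosages at founder
frequencies, for which the estimates center on the simulated values.
Second, realized genetic variance differs appreciably between founder
replicates (SD ~0.1 at these sizes), which is the dominant term in the
replicate SD of accuracy and gain.

## Numerical choices

Relationship matrices receive $10^{-6}$ on the diagonal before
factorization (marker-based G is frequently singular with full-sib
families). Fixed markers are excluded from G construction with a warning;
dominance codings additionally exclude markers without dosage variation.
The REML variance floor is $10^{-8}\,\mathrm{var}(y)$; boundary flags use
$10^{-3}\,\mathrm{var}(y)$. Crossing-plan sampling retries up to 1,000
times before reporting the constraints infeasible (a deterministic
counting pre-check rejects impossible designs outright). Haplotypes are
stored as raw bytes (alleles 0-3), so a tetraploid historical population
of 50,000 loci fits comfortably in memory.

## Known limitations

Only bivalent pairing is modeled — no multivalents and no double
reduction, which real autotetraploids show at low rates. Dominance
relationship matrices are implemented for ploidy 2 and 4 only. The
epistatic simulation model is limited to disjoint locus pairs (no
higher-order interactions), and no transformation between functional and
statistical variance parameters is provided. Multi-trait simulation,
overlapping generations and optimum-contribution selection are out of
scope.
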