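---
title: "Methods: gene flow, parentage and spatial genetic structure from mapped SSR genotypes"
author: "palmflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene flow, parentage and spatial genetic structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmflow)
```

# Scope and data model

`palmflow` analyses a single mapped sample of diploid, codominant
microsatellite (SSR) genotypes from a natural plant population in which every
individual carries an ontogenetic stage label (typically `reproductive`,
`immature`, `young`, `seedling`) and planar coordinates in meters. The
central container is the S4 class `GenotypeDataset`: two integer matrices of
allele codes (individuals x loci; a call is complete or fully missing), plus
the id/stage/x/y metadata. Allele codes are opaque positive integers —
fragment sizes are fine — and no binning is attempted: binning is an upstream
concern. Readers exist for a flat CSV dialect
(`id,stage,x,y,<locus>.1,<locus>.2,...`) and for GenePop 4/6-digit files with
a coordinate side file; `0`, `0000` and `000000` are the missing codes, the
de facto GenePop convention. GPS input can be projected to local planar
meters with an equirectangular projection about the plot centroid
(`projectLonLat()`); at the ~10 ha extents this package targets the
projection error is far below GPS error. Field datasets sometimes analyse a
few fewer plants than were collected without stating the rule; every analysis
function therefore accepts an explicit exclusion list (`exclude =`) rather
than guessing at a filter.

# Diversity and inbreeding

Per stage the package reports the allele count per locus $k$, mean alleles
per locus $A = \sum_l k_l / L$, private alleles $A_p$ (alleles seen in
exactly one stage), observed heterozygosity $H_o$, Nei's unbiased expected
heterozygosity $H_E = \frac{2n}{2n-1}(1 - \sum_a p_a^2)$, and rarefied
allelic richness by hypergeometric rarefaction,
$A_r(g) = \sum_a [1 - \binom{G - N_a}{g}/\binom{G}{g}]$, evaluated at a gene
count $g$ no larger than the smallest per-locus gene count among the stages
compared, so that richness is comparable across unequal samples. The unbiased
$H_E$ is used because it is the default of the standard R tooling for these
indices; the choice matters only at small $n$.

The fixation index is the multilocus ratio
$F = \sum_l (H_{E,l} - H_{o,l}) / \sum_l H_{E,l}$ — summed components rather
than a mean of per-locus ratios, which weights loci by their diversity and is
robust to near-monomorphic loci. Its null distribution is built by Monte
Carlo permutation of the $2n$ allele copies among individuals within each
locus (the Hardy–Weinberg null used by the standard SGS software), 1,000
permutations by default, two-sided. Permutation p-values use the
$(1 + \#\{|F^*| \ge |F|\})/(1 + B)$ estimator, which is valid and slightly
conservative; stage-level tests are Bonferroni-adjusted across the stages
tested.

# Spatial genetic structure

Pairwise coancestry is the Loiselle et al. (1995) kinship estimator. With
$p_{i,a}$ the dosage/2 of allele $a$ in individual $i$, $\bar p_a$ the
reference frequency and $n_l$ the *gene count* at locus $l$:

$$f_{ij,l} = \frac{\sum_a (p_{i,a}-\bar p_a)(p_{j,a}-\bar p_a) +
  \sum_a \bar p_a(1-\bar p_a)/(n_l-1)}{\sum_a \bar p_a(1-\bar p_a)},$$

combined over loci as a weighted mean with the polymorphism weights
$w_l = \sum_a \bar p_a(1-\bar p_a)$ (monomorphic loci drop out; loci missing
in either member of a pair drop out of both sums). Two numerical conventions
deserve a note. First, the bias-correction denominator $n_l - 1$ uses the
gene count ($2\times$ genotyped individuals): with that convention the
sample-centred estimator averages almost exactly zero over all pairs, which
is the property the downstream permutation tests rely on; using the
individual count instead shifts every pair upward by about $1/(2n)$. Second,
sums run over *all* alleles of a locus in both numerator and denominator, so
the estimator's expectation is 0.25 for parent–offspring pairs and 0.5 for
clones, the classical calibration.

Reference frequencies default to the analysed stage itself, because each
stage is analysed independently; any `AlleleFrequencyTable` can be
substituted.

The correlogram uses 10 distance classes with approximately equal pair
counts (empirical quantile bounds; pairs tied exactly on a bound fall in the
lower class — a deterministic tie-break that keeps the partition unique).
The null envelope per class comes from permuting the individuals' spatial
positions against their genotypes (10,000 permutations by default),
reassigning pairs to the *fixed* class bounds, and taking the 2.5%/97.5%
percentiles of the permuted class means; a class is flagged when its observed
mean falls outside. The envelope is built on the per-class mean coancestry
itself (not on ranks), which is what the usual correlogram figures display.

The intensity summary is $Sp = -b_k/(1-\theta_1)$, where $b_k$ is the
least-squares slope of the pairwise $\theta_{ij}$ on $\ln d_{ij}$ over all
individual pairs (not class means — the all-pairs slope is the definition
the $Sp$ statistic was introduced with), $\theta_1$ the first-class mean,
and the $b_k$ test permutes positions exactly as above. Zero-distance pairs
are excluded from the regression with a warning. The identity
$Sp = -b_k/(1-\theta_1)$ holds by construction to machine precision.

# Group coancestry and effective size

For a group of $n$ plants,
$\Theta = [\,0.5\,n(1+F) + \sum_i\sum_{j\ne i}\theta_{ij}\,]/n^2$, with the
double sum over ordered pairs (each unordered pair twice) — this
normalisation makes an unrelated, non-inbred group reduce exactly to
$\Theta = 1/(2n)$ — and negative $F$ floored at zero. The status effective
size is $N_e = 0.5/\Theta$; an unrelated non-inbred group gives $N_e = n$, a
clonal group ($\theta = 0.5$) gives $N_e = 1$. Because printed $\Theta$
values are typically rounded to 3 decimals, $N_e$ back-computed from them is
faithful only when $0.5/\Theta$ lands on the printed value exactly.

# Categorical parentage

Parent pairs are assigned by the categorical maximum-likelihood method. Per
offspring, each candidate pair (including every self-pair, since the species
is monoecious and selfing is possible) receives a LOD score
$\sum_l \ln[T_e(g_o \mid g_1, g_2)/P_{HWE}(g_o)]$ with the error-tolerant
transition $T_e = (1-e)T + e\,P_{HWE}(g_o)$; $e$ is a per-locus class-I
genotyping error rate (an erroneous genotype is a fresh Hardy–Weinberg
draw), default $e = 0.01$ and configurable, applied to the offspring
genotype. At $e = 0$ a Mendelian impossibility gives $-\infty$, i.e. a hard
exclusion. A mismatch cap completes the tolerance: "three mismatches" is
read as three mismatching *loci* per comparison (a per-locus count above one
is meaningless for a single diploid locus, and this is how the standard
parentage software uses the cap).

The acceptance threshold on $\Delta$ — the LOD gap between the best and
runner-up pair — is calibrated by simulation: offspring are generated from
frequency-drawn parents, the mother is in the candidate set, the father with
probability equal to the assumed sampled proportion of pollen donors (0.5 by
default), genotypes are perturbed by the same error model, and the critical
$\Delta$ is the smallest threshold at which the fraction of correct
simulated assignments above it reaches the confidence level (80% by
default; a 95% "strict" level can be computed the same way but the rates use
the 80% threshold). Offspring whose pair is rejected fall back to a
single-parent assignment with its own simulated threshold; an accepted
single parent is labelled the mother and the father deemed unsampled.

Classification then drives the gene-flow rates, all exact count ratios:
selfing $s$ = selfed/total; pollen immigration $m_p$ = (total − pairs −
selfed)/total; seed immigration = offspring with no accepted parent/total.
For an accepted outcross pair the spatially *nearer* member is labelled
mother (seed distances should be short relative to pollen distances), the
other father; pollen distance is the between-parents distance and seed
distance the offspring-to-mother distance. Selfing events (pollen distance
0) are excluded from the pollen-distance distribution so they cannot distort
the kernel comparison. The realised pollen-distance distribution is compared
with the all-pairs intermate distance distribution by a two-sample
Kolmogorov–Smirnov test, and the mating-frequency/distance association is
the squared Pearson correlation of per-class mating counts against class
mean distance over the same 10 equal-frequency classes (the binning is not
standardised anywhere; classes shared with the intermate histogram are the
least arbitrary choice). The effective pollination neighbourhood is
$A_{ep} = 2\pi\sigma_p^2$ with circular radius $\sqrt{A_{ep}/\pi}$; the
axial variance $\sigma_p^2$ is taken as half the variance of the pollen
dispersal distances under isotropy (when a printed axial SD is available it
can be supplied directly to `pollinationNeighborhood()`).

The parent-pair exclusion probability uses the closed form in allele
frequency power sums $S_k = \sum_a p_a^k$
($Q_l = 1 + 4S_4 - 4S_5 - 3S_6 - 8S_2^2 + 8S_2S_3 + 2S_3^2$, combined as
$1 - \prod_l(1-Q_l)$), which the test suite verifies against exhaustive
enumeration over genotype trios.

# The neighborhood mating model

The spatially explicit model decomposes each offspring's paternity into
selfing ($s$), pollen immigration ($m_p$) and within-plot siring
($1-s-m_p$) weighted by an exponential-power dispersal kernel

$$p(r) = \frac{b}{2\pi a^2\,\Gamma(2/b)}\,e^{-(r/a)^b},\qquad
  \delta = a\,\frac{\Gamma(3/b)}{\Gamma(2/b)},$$

with scale $a$ (m) and shape $b$ ($b<1$ fat-tailed, $1$ exponential, $2$
Gaussian). Per offspring $o$ with mother $m$:

$$L_o = s\,T_e(g_o|g_m,g_m) + m_p\,P_{bg}(g_o|g_m) +
 (1-s-m_p)\sum_{f\ne m} w_{mf}\,T_e(g_o|g_m,g_f),$$

where $w_{mf} \propto p(d_{mf})$ normalised over the candidate fathers
(every sampled adult; the neighbourhood is the whole plot) and the
background term draws the paternal gamete from the reference allele pool.
The mixture weights sum to one before any genotype likelihood is applied,
and the likelihood is invariant to rescaling all distances and $a$ together.

Regenerated plants have no observed mothers, so two modes are provided: the
default marginalises over all candidate mothers with seed-kernel weights
$v_{om} \propto p_s(d_{om})$ (the seed kernel $(a_s, b_s)$ is then fitted
jointly — this is what lets the model report seed-kernel estimates), and a
`known` mode that takes a supplied mother per offspring, e.g. the nearer
member of a categorical assignment. Maximisation is derivative-free
Nelder–Mead on transformed parameters — multinomial logit for $(s, m_p)$ so
$s + m_p \le 1$ holds by construction, $\log a$, and a logistic map
confining $b$ to $(0.05, 10)$ to keep the normalising $\Gamma(2/b)$ finite —
with 8 jittered restarts because the likelihood surface can be multimodal in
$(a, b)$; the best start is returned together with all start log-likelihoods
and a convergence flag. Genotypic transition products are precomputed once
(`nmPrecompute()`), so a likelihood evaluation is a handful of matrix
products and the fit takes seconds at a few hundred offspring.

# The synthetic-data generator

`simulatePopulation()` is the package's ground-truth instrument, a forward
simulator of exactly the generative process the neighborhood model assumes
plus an observation layer. Its defaults are the study conditions this
package is built around: 59 reproductive adults and 189 offspring
(stage-labelled 70/60/59) in a ~10 ha plot, 18 loci with 4–18 alleles
(symmetric-Dirichlet founder frequencies, concentration 1), selfing
$s = 0.04$, pollen immigration $m_p = 0.4$, exponential pollen kernel
$a = 200$ m, seed kernel $a = 50$ m, class-I genotyping error 0.01 and 2%
missing calls. The plot is deliberately elongated (1500 m x 70 m): a square
10 ha plot caps distances at ~450 m, whereas the field population this
emulates shows intermate distances up to ~1.5 km, consistent with a
riverside strip. Kernel draws use the exact radial representation
$r = a\,\Gamma^{-1}$draw$(2/b)^{1/b}$, so the simulated distances follow the
kernel without discretisation error; offspring positions are reflected at
the plot boundary, keeping the sample in-plot as a field sample would be.
Immigrant fathers share the plot's allele frequencies by default — the
conservative choice that makes immigration hardest to detect — with a
divergence knob (Dirichlet resampling) to create private immigrant alleles.

What the generator does *not* emulate: real SSR mutation, null alleles and
allele-specific dropout (the error model is class-I only), overlapping
generations, temporal variation in the mating system, clustered recruitment
beyond the seed kernel, and selection. Tests that pass on these simulations
therefore demonstrate estimator correctness under the stated model, not
robustness to null alleles or demographic history.

# Calibration checks and problem sizes

The test suite ties every estimator to an oracle or a known truth: the
Loiselle estimator to an independent exhaustive implementation at 5
individuals x 2 loci (agreement to 1e-12); the pair-exclusion closed form to
genotype-trio enumeration; kernel means to 10^6 Monte Carlo draws (0.5%);
parent–offspring coancestry to 0.25 +/- 0.03 on pedigree simulations; the
F and slope permutation tests to ~5% type-I error over 200 null panels
(199 permutations each, so the nominal level is attainable exactly);
parentage to +/-0.03 (s) and +/-0.07 (mp) over 20 study-sized replicates;
and the neighborhood fit to the same bands plus +/-25% on delta at 500
offspring over 10 replicates (4 optimizer starts there; 8 remain the
user-facing default). Delta-criterion simulations in tests use 500–1,000
replicates — the threshold is a quantile of a well-behaved distribution and
stabilises quickly — while 10,000 remains the analysis default. The
full-pipeline check runs the complete default-permutation analysis
(1,000 F / 10,000 SGS / 10,000 Delta) on a full study-sized simulation.

# Known limitations

Single-parent versus parent-pair bookkeeping follows one convention (pair
first, single-parent fallback labelled mother); datasets with known maternity
should instead fix mothers in the neighborhood model's `known` mode. The
CERVUS-style error model treats the offspring genotype as the error-bearing
observation; candidate errors are absorbed by the same mixture only
approximately, which is why the mismatch cap matters at high error rates.
Confidence of assignment uses the single 80% threshold for rates; the strict
level is computable but intentionally not used for the headline rates.
Anisotropic kernels, fractional paternity and sibship reconstruction are out
of scope.
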