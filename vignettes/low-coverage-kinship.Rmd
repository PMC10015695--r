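---
title: "Kinship inference from low-coverage data: models, simulator and benchmark design"
author: "kinlow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship inference from low-coverage data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinlow)
```

## The problem

The kinship coefficient $\varphi$ between two individuals is the probability
that one allele drawn from each at an autosomal locus is identical by
descent (IBD): 0.5 for identical genomes, 0.25 for parent–offspring and
full siblings, 0.125 for second-degree pairs (grandparent, avuncular,
half-siblings), 0.0625 for third-degree pairs, and 0 for unrelated,
outbred individuals. Sequencing of degraded material yields *low* (< 2x)
or *ultra-low* (< 0.5x) mean genome coverage, so most sites are covered by
zero or one read, diploid genotypes cannot be called directly, and kinship
must be estimated from sparse, noisy pairwise overlap. Two families of
estimators are in wide use:

* **pseudohaploid methods** sample a single random read per site and work
  with haploid calls — robust to depth but blind to call uncertainty;
* **genotype-likelihood (GL) methods** retain a likelihood triple per site
  over diploid genotypes 0/1/2 and propagate the uncertainty.

This package implements both families behind one simulation and
benchmarking framework, so that their contrasting failure modes as
coverage drops — spurious extra relationships (type I) for pseudohaploid
methods versus vanishing calls (type II) for GL methods — can be
reproduced and studied on pedigrees with known truth.

## The synthetic cohort generator

The generator replaces external sequence data with forward simulation
whose statistical structure is exactly what the estimators assume.

**Site panel.** `simulatePanel()` builds a biallelic SNP panel spread over
the 22 autosomes at regular 2,500 bp spacing, emulating (at reduced size)
an ascertained capture panel of sites known to be polymorphic, such as the
widely used "1240k" set. Population alternative-allele frequencies are
drawn uniformly on [0.05, 0.95] by default: ascertained panels exclude
near-fixed sites, and keeping frequencies away from 0/1 keeps every site
informative. The regular spacing yields exactly 400 sites per 1 Mbp
window, so window statistics are predictable.

**Genotypes.** `simulateGenotypes()` draws founder alleles independently
as alternative with probability equal to the site frequency
(Hardy–Weinberg equilibrium) and transmits one uniformly chosen allele
from each parent per site, independently across sites. Individuals
flagged `duplicate_of` receive a bitwise copy of another genome
(monozygotic twin or resequenced library). Pedigree truth
(`trueKinship()`, `truthTable()`) uses the standard recursion
$\varphi(a,b) = \tfrac12[\varphi(\mathrm{mo}(a),b) +
\varphi(\mathrm{fa}(a),b)]$; inbred pedigrees are rejected because the
estimators' outbred expectations would not apply.

**Reads.** `simulateReads()` draws per-site depth as Poisson with mean
$\lambda$ (`mean_coverage`, fold units). Poisson is the simplest model
matching a mean-coverage parameterisation; overdispersed (negative
binomial) depth is deliberately out of scope. Each read copies one of the
two alleles uniformly and flips to the other with probability
$\varepsilon$ (`base_error`, default 0.001, capped at 0.1). At sites whose
ref/alt pairing is C/T or G/A in either orientation, each read
additionally flips ref$\to$alt with probability $\delta$
(`deamination_rate`, capped at 0.3) — a strand-agnostic scalar stand-in
for terminal deamination damage. A scalar suffices because damage mainly
perturbs the same allele-flip channel as sequencing error and its impact
is secondary to coverage; position-in-read damage profiles are not
modelled.

**Thinning.** `downsampleReads()` retains each read independently with
probability $f$, the exact analogue of downsampling a BAM to $f$ of its
reads. Thinning is unbiased ($E[\text{coverage}] = f \lambda$) and
composable ($f_1$ then $f_2$ equals $f_1 f_2$ in distribution); both
properties are tested. Coverage (`meanCoverage()`) is defined as reads
per panel site, since every computation here is panel-restricted; this
matches the proportional behaviour of whole-genome coverage without any
BAM dependency.

All stochastic steps take a mandatory integer seed and restore the
caller's RNG state; pipelines derive named sub-seeds with `subSeed()`, so
every result is bit-reproducible from one root seed.

## Genotype representations

`callPseudohaploid()` draws one read per covered site (alternative with
probability $n_\mathrm{alt}/d$), leaving zero-depth sites missing. The
random draw, rather than majority consensus, avoids reference bias.

`genotypeLikelihoods()` uses the per-read binomial error model: for
genotype $g \in \{0,1,2\}$ the per-read alternative probability is
$\tfrac{g}{2}(1-\varepsilon) + (1-\tfrac{g}{2})\varepsilon$, and the
likelihood triple is the product over reads, normalised to sum to one.
Likelihoods are computed in log space and zero-count terms contribute
zero even at $\varepsilon = 0$, so the triples are exact at the
boundaries (one alternative read at $\varepsilon = 0$ gives
$(0, \tfrac13, \tfrac23)$). The default $\varepsilon$ equals the
simulator's, but mis-specification experiments can pass any value below
0.5.

## Pseudohaploid estimators

**Windowed mismatch with cohort normalisation** (`windowP0()`,
`readClassify()`). The genome is cut into 1 Mbp half-open windows and the
pairwise mismatch proportion P0 computed per window over shared
non-missing calls. Each pair's mean P0 is divided by the cohort mean of
all pairs' mean P0 — the expected level of an unrelated pair when most of
the cohort is unrelated — giving a statistic with expectation $1-\varphi$.
Degrees are assigned by nearest expectation among
$\{0.5, 0.75, 0.875, 1.0\}$ with midpoint boundaries (0.625, 0.8125,
0.9375), and a pair is called related (second degree or closer) only when
$z = (1-\text{normalised P0})/\mathrm{SE} > 1.96$, with the SE from a
delete-one-window jackknife. Pairs with fewer than 10 windows are flagged
insufficient.

**Genome-wide mismatch with max-rate normalisation** (`kennettMismatch()`,
`kennettScreen()`, `kennettR()`). The highest observed pairwise mismatch
rate is taken as the unrelated level and each pair scored
$r = 2(1 - m/m_{\max})$, with expectation $2\varphi$. Because the
reference point is an extreme order statistic, the method first screens
whether any pair differs significantly from the maximum: the package uses
a two-sample binomial $z$ against the maximum pair and a
Bonferroni-adjusted threshold at base level $z = 3$. The adjustment
matters: the gap between the maximum and the other pairs, in units of the
per-pair standard error, is roughly scale-free (its expected maximum sits
near 3 for cohorts of this size at *any* panel size), so an unadjusted
per-pair cutoff of 3 would flag relatives in roughly half of all-unrelated
cohorts. With `apply_screen = TRUE` (default) a cohort that fails the
screen is reported relative-free; switching it off exposes the
characteristic over-prediction of max-rate normalisation on unrelated
groups. A manual normalisation value can replace the observed maximum
when a reliable population mismatch rate is known.

**Frequency-based halved relatedness coefficient** (`hrcEstimate()`).
With $S_s$ the agreement indicator of the two haploid calls and
$u_s = p_s^2 + (1-p_s)^2$ the agreement probability of an unrelated pair
under the supplied frequencies, $\mathrm{HRC} = \sum_s (S_s - u_s) /
\sum_s (1 - u_s)$, with expectation $\varphi$ for outbred pairs. Because
the unrelated baseline comes from the frequency panel rather than the
cohort, the estimator needs far fewer shared sites (floor: 500), but
frequencies unrepresentative of the population shift it bodily — a
mis-calibrated panel (e.g. frequencies drawn from a narrower
distribution) inflates unrelated pairs to HRC $\approx$ 0.2 and
fabricates relatives. Related calls use the threshold 0.09375, the
midpoint between the second- and third-degree expectations.

## Genotype-likelihood estimators

**Maximum-likelihood IBD coefficients** (`ibdJointTables()`,
`mlKEstimate()`, `phiFromK()`). At a site with frequency $p$, the joint
probability of the pair's genotypes conditional on sharing $m \in
\{0,1,2\}$ alleles IBD is the standard table set: HWE-margin product for
$m=0$, diagonal HWE for $m=2$, HWE margin times a one-shared-allele
transition for $m=1$. The composite likelihood
$\sum_s \log \sum_m k_m A_m(s)$, with $A_m(s)$ the likelihood-weighted
table mass, is maximised over the probability simplex by EM with the IBD
class as latent variable. The EM is run from three starts (unrelated
vertex, parent–offspring-like interior point, barycentre), tolerance
$10^{-6}$ in log-likelihood, at most 500 cycles; each cycle may take a
SQUAREM-style extrapolated step, accepted only when it does not lower the
log-likelihood, so ascent is strictly monotone (asserted on every
iteration) while convergence near simplex boundaries stays fast. The
kinship coefficient is $\varphi = k_1/4 + k_2/2$. Only the outbred
three-coefficient parameterisation is estimated: on non-inbred pedigrees
it coincides with the general nine-coefficient model, at a fraction of
the complexity.

**Allele-sharing statistics** (`alleleSharingStats()`). Joint genotype
class masses $X(a,b)$ accumulate posterior products, with the per-site
posterior proportional to likelihood times HWE prior — a deliberate
simplification of joint-SFS estimation that is unbiased under this
generator. From the masses: $R_0 = \mathrm{IBS0}/\mathrm{HETHET}$,
$R_1 = \mathrm{HETHET}/(\mathrm{IBS0} + X_{01} + X_{10} + X_{12} +
X_{21})$, and the KING statistic $(\mathrm{HETHET} - 2\,\mathrm{IBS0}) /
(\mathrm{HET}_i + \mathrm{HET}_j)$, with expectation $\varphi$ under the
null-calibrated posterior. Degrees follow the standard powers-of-two KING
bins (0.354, 0.177, 0.0884, 0.0442); the binary related call is KING
$\ge$ 0.0884. The KING-based call, not the $R_0/R_1$ ratio route, feeds
the benchmark, because the ratios' variance grows quickly with missing
data.

Both estimators require 500 co-covered sites (configurable); pairs below
the floor return flagged insufficient-data results rather than noisy
numbers, and never count as related.

## The benchmark

`runSweep()` thins a pileup to each retention fraction (defaults 1, 0.5,
0.25, 0.1, 0.05, 0.01), regenerates pseudohaploid calls and GLs, and runs
every requested method, recording for each (method, fraction, pair) the
raw statistic, a relative kinship score, the binary related call
(threshold: second degree), and an ok/insufficient flag. The relative
score maps every statistic to the $\varphi$ scale ($1-$normalised P0,
$r/2$, HRC, $\varphi$, KING) and divides by 0.5 so identical pairs score
1 — making methods directly comparable on one axis.

`evaluateCalls()` scores each reduced fraction against the same method's
full-retention reference set: accuracy (consistent / called), consistency
(consistent / reference), false positives (called but not in reference)
and false negatives (reference but not called), plus the same counts
against pedigree truth when available. Insufficient pairs are excluded
from the accuracy/consistency numerators and denominators — "no data" is
not evidence of unrelatedness — but an insufficient pair makes no call,
so a reference relationship it fails to reproduce still counts as a false
negative. At full retention accuracy and consistency are identically 1.

`mantelTest()` correlates the upper triangles of two distance matrices
and assesses significance by jointly permuting rows and columns of the
second, two-sided on $|r|$, $p = (1 + \#\{|r_\pi| \ge |r_\mathrm{obs}|\})
/ (n_\pi + 1)$; for matrices of size $\le 6$ the full permutation
distribution is enumerated exactly. `buildMantelMatrices()` forms the
matrices from the sweep: observations are (pair, fraction) tuples, one
matrix of absolute score differences, one of absolute differences in
pairwise mean coverage (mean of the two individuals' panel coverage at
that fraction). No multiple-testing correction is applied to per-pair
calls, and the Mantel p is reported raw.

## Shipped pedigrees and study conditions

Four pedigree constructors cover the cohort archetypes: five independent
trios (15 ids), a 15-id extended family containing identical, first-,
second-, third-degree and unrelated pairs, an all-unrelated group
(default 5), and a 28-id cohort with a handful of relatives. The test
suite runs parameter recovery at 50,000 sites and 5x coverage
($\varepsilon = 0.001$), the closed-form pseudohaploid limits at 50,000
sites and 10x, and the coverage-asymmetry experiment on the extended
family at 25,000 sites, 2x base coverage, retentions 1.0 and 0.01, over
20 replicate seeds — sizes chosen so the whole suite runs on a laptop in
a few minutes while keeping Monte-Carlo error well inside the assertion
tolerances (3 standard errors for simulation checks; ±0.02 on $\varphi$).

## What the simulator does and does not emulate

Passing tests demonstrate correct behaviour under the generator's
assumptions: panel-restricted biallelic sites in linkage equilibrium,
HWE founders from a single population, Poisson depth independent across
sites, error and damage acting per read and independently. Real ancient
data violate several of these — linkage disequilibrium between panel
sites, reference and ascertainment bias, contamination, batch-varying
error, UDG-treatment differences, and population structure mismatching
the frequency panel. Results here quantify the *statistical* behaviour of
the estimator families as a function of coverage; they do not certify
performance on any particular archaeological dataset. Admixture-aware
estimation is explicitly out of scope, as is anything requiring raw
reads (alignment, duplicate removal, quality filtering).

## Numerical and degenerate-input conventions

Positions are 1-based; windows are half-open $[s, s + 10^6)$. Degree
boundaries sit at midpoints between adjacent theoretical expectations
(ties resolve toward the lower class). Likelihood triples are normalised
to sum to 1 within $10^{-9}$; zero-depth sites are missing, not zero
triples. The EM clamps negative extrapolated coordinates to the simplex.
A mismatch matrix whose maximum is 0 (all calls identical) is a
degenerate input and raises an error, as do frequencies outside (0, 1),
retention fractions outside [0, 1], and pedigrees with a single recorded
parent or a parent cycle. Methods failing on degenerate thinned data
inside a sweep contribute insufficient-flagged rows instead of aborting
the run. TSV outputs serialise floats at 6 significant digits and
round-trip losslessly at that precision; gzip is handled transparently.

## Known limitations

Pseudohaploid estimators that normalise within the cohort (windowed P0,
max-rate r) assume most pairs are unrelated; cohorts dominated by
relatives bias the baseline and shift every estimate. The HRC estimator
is only as good as its frequency panel. The GL estimators assume the
error rate passed to them; strong mis-specification biases $\varphi$.
The screen's Bonferroni adjustment is conservative for strongly
correlated pairs (shared individuals). None of the estimators model
inbreeding, contamination or admixture.
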