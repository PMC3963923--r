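---
title: "Admixture fine-mapping: models, statistics and design choices"
author: "admixfine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture fine-mapping: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixfine)
```

## The problem

In a recently admixed population such as African Americans, a disease that
is more common in one ancestral population leaves a footprint in the genome
of affected individuals: near a risk locus, cases carry more alleles of the
higher-risk ancestry than their genome-wide average predicts. Admixture
mapping finds such regions; the harder question this package addresses is
*fine-mapping within them* — deciding which specific variant (if any single
one) accounts for the ancestry signal, and how much of the heritable risk
local ancestry explains overall.

The package works with two-way admixture. At each marker an individual
carries $a \in \{0, 1, 2\}$ alleles of African origin (their *local
ancestry*), and genome-wide they have an African ancestry proportion
$\theta$ (*global ancestry*). Cohorts are case-control with sibship family
structure.

## Association with ancestry adjustment

Single-marker association uses logistic regression under the
multiplicative (log-additive) model, fitted by maximum likelihood — which
is the estimating-equation solution with an independence working
correlation — with a cluster-robust sandwich variance treating each family
as a cluster (`geeLogistic()`, `snpAssociation()`). Global ancestry
$\theta$ and sex enter every model; local ancestry $a$ is an optional
covariate. Confounding by local ancestry is quantified as
$|\beta_{adj} - \beta_{unadj}| / |\beta_{unadj}|$
(`confoundingRatio()`). Wald intervals $\exp(\hat\beta \pm 1.96\,SE)$
match the usual presentation of odds ratios; no small-sample cluster
correction is applied by default (available via `smallSample = TRUE`),
since the intended cohorts have hundreds of clusters.

The coded allele is oriented to the cohort minor allele by default. At the
tested marker, individuals with a missing genotype are dropped for that
marker only. Forward selection (`forwardSelect()`) adds the most
significant conditional marker until the best conditional p exceeds a
threshold, skipping perfectly correlated candidates; ties break by genomic
position so the procedure is order-invariant.

## The admixture-signal scores

Four 1-df likelihood-ratio statistics dissect a region
(`admixtureScores()`):

- **ADM** (affected-only admixture): in cases,
  $a \sim \mathrm{Bin}\!\left(2, \frac{\lambda\theta}{\lambda\theta + 1 - \theta}\right)$,
  testing the ancestry odds multiplier $\lambda = 1$.
- **SNP1** (ancestry-conditional allelic): under a rare-disease
  retrospective likelihood, a case haplotype whose origin has ancestral
  allele frequency $p$ carries the allele with probability
  $p r / (1 + (r-1) p)$; a control haplotype with probability $p$. The
  two unphased allele-to-origin assignments of ancestry-heterozygous
  individuals are summed over. Tests $r = 1$.
- **MIX**: the single-causal-variant test. One causal allele with odds
  ratio $r$ and ancestral frequencies $(p_A, p_E)$ *induces* the ancestry
  odds multiplier
  $\lambda(r) = \frac{1 + (r-1)p_A}{1 + (r-1)p_E}$,
  so the joint likelihood $\ell_{ADM}(\lambda) + \ell_{SNP1}(r)$ is
  maximised along the one-dimensional curve $\lambda = \lambda(r)$.
- **DIFF** $= ADM + SNP1 - MIX$: the test of the single-causal
  constraint. A small DIFF p-value says the marker cannot alone explain
  the ancestry signal.

All four are implemented as likelihood-ratio statistics (asymptotically
equivalent to score tests); the LRT form makes the DIFF identity exact by
construction — the three maximisations share one null likelihood and
identical individual sets, so $DIFF = ADM + SNP1 - MIX$ holds to machine
precision and $MIX \le ADM + SNP1$ by nesting.

### Ancestral frequencies are profiled, not plugged in

The ancestral allele frequencies $(p_A, p_E)$ are unknown and must be
estimated from the admixed sample itself (`estimateAncestralFreqs()`, an
EM over the unphased ancestry-heterozygotes). A consequential design
choice: if frequencies estimated from controls are *plugged in and treated
as known*, the SNP1/MIX likelihood-ratio statistics ignore the estimation
variance and reject far too often (about 0.19 at nominal 0.05 in our
simulations with 750 cases and 750 controls). The package therefore treats
$(p_A, p_E)$ as nuisance parameters maximised under both hypotheses: the
null maximum is the pooled EM estimate, the alternative a three-parameter
maximisation over $(\log r, \mathrm{logit}\,p_A, \mathrm{logit}\,p_E)$
(bracketing grid plus Brent in the 1-D starts, Nelder-Mead for the joint
step). This restores 1-df chi-square calibration, which the test suite
verifies by simulation. The fixed-frequency mode remains available
(`profileFreqs = FALSE`) for the algebraic collapse identities — with
$p_A = p_E$ the constraint gives $\lambda(r) \equiv 1$, MIX coincides
with SNP1 and DIFF with ADM.

Optimisation over $r$ is confined to $[1/50, 50]$ on the log scale with a
41-point bracketing grid followed by Brent search (tolerance $10^{-9}$);
the grid guards against the rare multi-modal profile near degenerate
frequencies, and a dense-grid oracle in the tests confirms the argmax to
$10^{-4}$.

Because the MIX framework assumes unrelated subjects, `averagedMix()`
draws repeated random subsamples of unrelated cases and controls (the
reimplemented analysis used 100 draws of 933 cases and 846 controls) and
averages the *statistics*, not the p-values; p-values are recomputed from
the averaged statistics. Region boundaries come from the first and last
marker with affected-only admixture p below 0.05
(`regionBoundaries()`), and only markers with association p below 0.05
and confounding ratio below 0.15 proceed to MIX testing
(`tieredScreen()`); "minimal confounding" is not quantified in the source
analysis, so 0.15 is a documented, configurable default.

## Heritability from local ancestry

`ancestryGRM()` builds a relationship matrix with the African-allele
count in place of the genotype:
$A_{jk} = \frac{1}{M}\sum_m \frac{(a_{jm} - 2\bar p_m)(a_{km} - 2\bar p_m)}{2 \bar p_m (1 - \bar p_m)}$.
Locus-wise standardisation mirrors genotype GRM practice; whether the
original analysis standardised or used raw covariance is not stated, so
the unstandardised mode is available by flag. `remlFit()` estimates
$(\sigma^2_a, \sigma^2_e)$ on the observed 0/1 scale. With a single
relationship matrix the REML log-likelihood can be profiled exactly over
$h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$ after one eigendecomposition
of $K$, and the 1-D profile is maximised globally by a bracketing grid
plus Brent search; we chose this over the average-information iteration a
general multi-component tool needs because it cannot diverge, handles the
$h^2 = 0$ boundary naturally, and makes refitting many phenotypes on one
matrix cheap (pass `eig =`). The SE of $h^2$ comes from the numerical
curvature of the unprofiled REML likelihood in $(\sigma^2_a, \sigma^2_e)$
via the delta method, and the test of $\sigma^2_a = 0$ is a 1-df LRT.

Observed-scale estimates are transformed to the liability scale with the
ascertainment-corrected threshold-model factor
$h^2_{liab} = h^2_{obs}\, K^2 (1-K)^2 / (z^2 P (1-P))$ at prevalence
$K = 1/1000$ and sample case proportion $P$. Individuals are pre-filtered
to pairwise pedigree relationship $< 0.125$ (first cousins), the same
restriction the source analysis applied, and `dropRegionHeritability()`
re-estimates after excluding all markers in a closed interval to measure
a locus's contribution. One caution that the simulations make vivid:
ancestry tracts are long (mean $1/g$ Morgans), so markers flanking a
dropped window still tag the window's ancestry unless the window is wide
relative to the tract length — narrow drops understate a locus's
contribution.

## Kinship

`pedigreeRelationship()` computes recursive kinship with self-kinship
fixed at 0.5 (the generator produces outbred pedigrees, so the inbreeding
term would be identically zero anyway); `kingKinship()` implements the
robust identity-by-state estimator
$\hat\varphi = (N_{Aa,Aa} - 2N_{AA,aa}) / (N_{Aa}^{(i)} + N_{Aa}^{(j)})$,
which is exactly 0.5 for self-comparisons. `unrelatedSubset()` removes
the highest-degree individual repeatedly (ties: largest id) — greedy
rather than an exact maximum independent set, which is standard practice,
deterministic, and near-optimal on the sparse relatedness graphs that
arise here; retained pairs are strictly below the threshold.

## The synthetic cohort generator

No individual-level data accompany the analysis this package
reimplements, so `simulateCohort()` generates cohorts with the structure
the methods assume:

- $\theta_j \sim \mathrm{Beta}$ moment-matched to mean 0.823, SD 0.10 —
  the published sample means (82.7/82.3%) and a pooled SD; the true
  $\theta$ distribution shape is unknown, Beta is a conventional choice
  and both moments are configuration knobs.
- Haplotype ancestry follows a two-state Markov chain with stationary
  distribution $(\theta, 1-\theta)$ and redraw rate $g$ per Morgan
  (default $g = 7$ generations, the standard African-American
  admixture-pulse figure); base pairs map to Morgans at $10^{-8}$, the
  constant rate the source local-ancestry estimation assumed. Note the
  *observed* switch rate is $2\theta(1-\theta)$ times the event rate,
  because a redraw may land on the same ancestry.
- Alleles are Bernoulli($f_{AFR}$) on African-origin and
  Bernoulli($f_{CEU}$) on European-origin haplotypes, independent across
  markers given ancestry (no within-ancestry LD — a deliberate non-goal);
  $f_{CEU} = 0$ reproduces alleles private to the African background.
- Sibships come from two simulated, un-genotyped parents via meiosis at 1
  crossover per Morgan, giving the GEE and kinship modules realistic
  clusters; disease follows a multiplicative logistic model with global
  ancestry and sex effects, optional direct local-ancestry effects, and
  subphenotypes (resolved 0.331 / Stage I–III 0.465 / Stage IV 0.204
  among cases with follow-up, with 26.8% of cases missing follow-up).
- `simulateScoreMarker()` generates single markers directly under the
  retrospective haplotype model — the exact model the scores assume —
  for calibration and power studies without whole-chromosome simulation.

What passing tests on these data do and do not show: calibration and
recovery results certify the estimators under their own assumptions
(correct retrospective model, no within-ancestry LD, exact local-ancestry
calls, Beta-distributed $\theta$). Real cohorts violate all four to some
degree — local ancestry is itself estimated, ancestral haplotypes carry
LD, and case-control ascertainment is more complex — so simulation-green
here does not certify behaviour on real data, only correctness of the
implemented statistics.

## Numerical choices and degenerate inputs

- Ancestral-frequency EM: tolerance $10^{-10}$, 1000 iterations;
  frequencies clamped to $[10^{-6}, 1-10^{-6}]$ only inside the logit
  reparameterisation.
- Majority-vote ties go to the smallest ancestry count; equidistant
  nearest-marker ties to the lower position; both rules exist purely for
  determinism, the source description being silent.
- Coordinates are 1-based and intervals closed on both ends everywhere.
- The Hardy-Weinberg test is the exact conditional-on-allele-counts
  enumeration, two-sided by summed mass of configurations no more
  probable than observed; monomorphic markers give $p = 1$.
- Genotype-posterior calling applies the 0.9 threshold inclusively.
- REML clamps tiny negative eigenvalues to zero and floors variances at
  $10^{-6}$ of the total for the curvature evaluation; an identity
  relationship matrix is rejected as non-identifiable.
- DIFF values negative within $10^{-6}$ (optimiser round-off) are
  clipped to zero; larger negatives raise an error, as they indicate an
  optimisation failure rather than noise.

## Problem sizes used in the checks

The packaged simulations use 2,000 replicate markers at $n = 1500$ (750
cases / 750 controls) for score calibration, 300 replicates for the
single-causal explanation property, and one $n = 2000$, 400-marker cohort
with 30 phenotype replicates per heritability cell — sizes chosen so the
Monte-Carlo error is well below the tolerances being asserted while the
whole suite stays comfortably runnable on a laptop. Heritability recovery
simulates the phenotype on the observed scale (Gaussian
$y = g + e$) because an exactly known observed-scale $h^2$ cannot be
constructed for a thresholded binary trait; binary phenotypes are
exercised by the null-calibration and region-removal checks.

## Known limitations

- Two-way admixture only; no three-way models, no selection.
- The local-ancestry HMM itself is out of scope — local ancestry arrives
  as data (or from the simulator), and only the downstream majority-vote
  and nearest-marker imputation rules are implemented.
- Single-component REML; no partitioned heritability or bivariate
  genetic correlations.
- Genotype imputation is out of scope; imputation-quality columns can be
  thresholded but are never recomputed.
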