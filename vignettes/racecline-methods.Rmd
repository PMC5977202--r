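---
title: "racecline: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{racecline: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`racecline` analyzes a recurring design in the population genomics of
host-race formation: two partially isolated host races sampled in sympatry at
several latitudinally ordered sites, genotyped at thousands of SNPs by
low-coverage reduced-representation sequencing, together with paired
experiments (an eclosion-time contrast and prewinter-survival selection
experiments in each race) that probe selection on diapause life-history
timing. The question throughout is how local host-associated differentiation
compares with broader geographic (clinal) differentiation, and how much of
both is explained by the experimental responses. This vignette records the
models the package implements, the defaults and why they were chosen, and
the limitations a user should know about.

## Genotype likelihoods and allele frequencies

All estimation starts from per-individual genotype likelihoods
$L_i(g)$, $g \in \{0, 1, 2\}$ alternate-allele copies (VCF `GL`/`PL`). At
3--6x coverage hard genotype calls are unreliable, so frequencies are
estimated by maximum likelihood under a Hardy--Weinberg prior via EM
(`estimate_allele_freq()`):

$$ w_i(g) \propto L_i(g)\,\mathrm{HWE}(g \mid p), \qquad
   p \leftarrow \frac{\sum_i \sum_g g\, w_i(g)}{2 n}. $$

Entries are *informative* when non-missing and non-flat; frequencies are
computed over informative individuals only, and a SNP with none is `NA`.
With certain likelihoods the estimator reduces exactly to allele counting.
Convergence is `|dp| < 1e-6` (at most 100 iterations); the observed-data
log-likelihood is non-decreasing across iterations (asserted in the tests).
Posterior mean dosages $\sum_g g\,P(g \mid L, p)$ (`posterior_dosages()`)
are the working genotype representation downstream; a flat entry falls back
to the prior mean $2p$, and at convergence the mean posterior dosage equals
$2\hat p$.

Signed frequency differences (`frequency_difference()`) use fixed
orientations, recorded in output attributes: experiments are first group
minus second (early − late eclosion; 7-day − 32-day prewinter), geography is
first site minus last along the transect, and host contrasts are ancestral
(hawthorn) minus derived (apple). `polarize_to_reference()` re-signs a
frequency matrix to the reference population's major allele (ties at 0.5
left unflipped, so the operation is idempotent).

## Composite linkage disequilibrium and LD classes

With unphased genotypes the package uses the Burrows composite
disequilibrium (`composite_ld()`):

$$ \hat\Delta = \frac{1}{2n}\sum_i X_i Y_i - 2\hat p_A \hat p_B, \qquad
   \hat r = \frac{\hat\Delta}{\sqrt{(\hat p_A \hat q_A + \hat D_A)
   (\hat p_B \hat q_B + \hat D_B)}}, $$

with $\hat D_A$ the within-locus Hardy--Weinberg disequilibrium.
$\hat\Delta$ is half the (population-normalized) dosage covariance and
$\hat r$ is the dosage Pearson correlation; the tests verify both against
the brute-force genotype-count formula. Pairs with fewer than two complete
observations or a monomorphic locus return `NA` with a reason.

LD classes summarize a SNP's association with inversion-like structure: a
SNP is **high** iff its maximum within-chromosome $r^2$ strictly exceeds
0.6, **low** iff that maximum is strictly below 0.15, otherwise
**intermediate**; boundary values are intermediate. High SNPs are grouped
into connected components of the $>0.6$ graph. A SNP alone on its chromosome
is low (the "below threshold with every linked SNP" condition holds
vacuously); an all-`NA` row is unassigned. `mean_linked_ld()` supplies the
per-SNP mean $r^2$ to all other linked loci, the "LD" covariate of the
multiple-regression models (mean $|\hat r|$ is available behind a flag).

**Attenuation caveat.** On posterior dosages at ~4x coverage, measurement
noise multiplies between-SNP $r^2$ by roughly the squared dosage
reliability, so pairs whose true $r^2$ is ~0.85 are often observed near or
below the 0.6 threshold. Threshold classes estimated from low-coverage data
are therefore conservative for the high class; the class-recovery tests run
on true genotypes (the simulator's hard-call output) to test the classifier
rather than the attenuation.

## Whole-genotype Monte Carlo tests

Per-SNP allele-frequency differences are tested non-parametrically
(`mc_difference_test()`): both null groups are drawn *with replacement* from
the pooled individuals of the two samples, as whole multi-locus genotypes —
preserving LD among loci and each individual's missingness pattern — and
$|\Delta p|$ recomputed per replicate. A SNP is significant iff its observed
$|\Delta p|$ strictly exceeds the 95th percentile (type-7 linear
interpolation) of its own null draws; per-SNP critical values require at
least 100 available draws. To avoid refitting EM in every replicate,
per-individual genotype posteriors are computed once from the pooled sample
and replicate frequencies are posterior-dosage means — the observed contrast
is computed the same way, keeping observed and null statistics exchangeable
under the null. The table-wise test (`tablewise_excess_test()`) compares the
observed percentage of significant SNPs with the replicate percentages
(each replicate scored against the same critical values).

Two calibration properties, both computed by the test suite on null data:
the per-SNP rejection rate is at its nominal 5% level; the table-wise p is
*conservative*, concentrating mid-range rather than uniform. The
conservativeness is intrinsic to with-replacement resampling: the
bootstrap duplication of individuals makes each replicate's effective
dispersion factor $\sum_i (w^{(1)}_i - w^{(2)}_i)^2$ random, which couples
exceedances across all SNPs within a replicate and overdisperses the
replicate percentages relative to the observed split. The procedure
essentially never false-alarms at the table level; a permutation
(without-replacement) split would restore uniformity but is not the
procedure implemented here, which follows the field's established
whole-genotype bootstrap.

`mc_regression_significance()` applies the same machinery to regressions of
one per-SNP response contrast on a fixed predictor vector from an
independent experiment: the response is rebuilt from resampled pooled
genotypes, the predictor held fixed, and p is the fraction of null
$r^2$ values at or above the observed one.

## Regression models

`fit_simple_regression()` is ordinary least squares reporting the signed
correlation (it matches the Pearson correlation to machine precision).
`stepwise_aic()` searches in both directions from the full Gaussian model
with $\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2k$ ($k$ counting all fitted
coefficients, the convention of R's `step()`), over complete-case rows — in
the pipeline, the mapped SNPs, since the mean-linked-LD covariate is
undefined for unmapped SNPs. Exactly duplicated predictor columns are
reduced to the first occurrence before fitting, so collinear duplicates
cannot both be retained. Classical coefficient and model tests are reported
for the selected model and labeled as such; Monte Carlo p-values are
attached only to the simple regressions, where the resampling null is
well-defined. Per-SNP observations are treated as independent in these fits;
LD-induced dependence among SNPs is acknowledged, not modeled, so the
classical standard errors are optimistic in the way such genome-wide
regressions usually are.

## Clustering layer

**Nei's standard distance** between populations is computed from allele
frequencies per pair over loci non-missing in both:
$D = -\ln(J_{XY} / \sqrt{J_X J_Y})$ with biallelic gene identities
$J_{XY} = \overline{xy + (1-x)(1-y)}$. Opposite fixation gives $D = \infty$,
flagged rather than silently dropped.

**Neighbor joining** uses the standard Saitou--Nei agglomeration; additive
metrics are recovered exactly (asserted to 1e-10). Negative branch lengths,
which NJ can produce on non-additive inputs, are clamped to zero with the
deficit transferred to the sister branch, preserving the path length between
the two daughters. Bootstrap supports (`bootstrap_nj()`) resample loci with
replacement and count recovery of each observed bipartition; replicates with
non-finite distances are skipped and counted.

**DAPC** (`dapc_fit()`) imputes missing dosages with per-SNP means, centers
(unit-variance scaling is off by default and exposed as a flag), reduces by
PCA, and runs linear discriminant analysis on the retained PC scores with
equal priors and pooled within-group covariance; Gaussian posteriors give
membership probabilities and the mean probability of correct self-assignment
is the headline statistic. The number of PCs is chosen by the a-score
(`optimize_a_score()`): observed reassignment success minus its mean over
label-randomized runs (10 per candidate by default), smallest number of PCs
on ties. Significance (`cluster_significance()`) permutes labels with group
sizes preserved and refits the discriminant step on the same PCs.
Self-reassignment (no cross-validation) is used throughout, so absolute
assignment probabilities are optimistic; all comparisons are within-design,
against permutation nulls or between contrasts of equal size.

**Mantel tests** (`mantel_test()`) correlate upper-triangle distances and
permute the genetic matrix jointly by rows and columns; the test is
one-tailed for positive association because isolation-by-distance and
-by-ecology are directional hypotheses. Geographic distance between
populations is the difference in latitudinal site order; ecological distance
is the 0/1 host indicator — with paired sampling of both races at every
site, the two predictors are orthogonal by design.

## The synthetic study generator

`sim_config()` + `simulate_study()` generate the full study the pipeline
consumes, with known truth for every recovery test.

*Clines.* The true alternate-allele frequency in the population at site
order $s$ (0-based) and host $h$ is
$\mathrm{logistic}(\alpha + \beta s + \gamma[h = \mathrm{apple}])$.
Geography enters as an ordered 4-level transect, not kilometres, because the
analysis itself only uses latitudinal order.

*Inversion-like blocks.* Each chromosome carries a high-LD and an
intermediate-LD block. A block has one biallelic latent orientation whose
frequency follows its own cline; each haplotype of a member SNP matches the
latent orientation with probability $1 - m$. Two member SNPs then have true
$r^2 \approx (1-2m)^4$: the defaults $m = 0.02$ (high) and $m = 0.13$
(intermediate) give ~0.85 and ~0.30, the middles of the high and
intermediate class ranges. This single-latent-variable mechanism is the
simplest that produces the three LD strata tied to inversion polymorphism.

*Reads.* Depth is Poisson (default mean 4, the low end of the 3--6x range
such surveys report); alternate-read counts are binomial with a symmetric
base error (default 0.01); likelihoods are the binomial read likelihoods;
zero depth is missing. `PL` is written as rounded phred-scaled normalized
likelihoods.

*Experiments.* Each experiment contrasts two groups whose frequencies are
the base population's truth shifted by $\pm\delta/2$ — applied at *block*
level for block SNPs (members shift by $(1-2m)\delta$), preserving
within-block LD. Survival and phenotype are not modeled; the analysis only
consumes frequency contrasts. Default responses (magnitude ~0.25) sit on
blocks of chromosomes 1--3 for the eclosion contrast, chromosomes 2--3 for
the apple prewinter experiment, and on unlinked SNPs of chromosomes 3--5 for
the hawthorn prewinter experiment, echoing the chromosome-specific
concentration of responses such studies report; response signs are aligned
with the latitudinal slope, reflecting the consistently positive
experiment-geography associations that motivate the design.

*Key scale defaults.* 2,000 SNPs (~41% mapped across 5 chromosomes, the
mapped fraction of the motivating panel) and 30 individuals per population —
a deliberate desk-scale reduction of a ~10,000-SNP, ~1,300-fly study; the
tests and scripts state their problem sizes explicitly. Cline slopes default
to $\beta = 0.4$ per site step and $\gamma = 0.5$ host effect on the logit
scale, making the geographic extreme contrast ~2.4x the sympatric host
contrast on the frequency-difference scale, the regime of interest.
`coupling_fraction = 0.5`: the *sign* of a locus's host effect is
independent of its latitudinal slope by default, because in this system
local host divergence shows chromosome- and site-dependent sign reversals
against the cline (crossing patterns) and no isolation-by-ecology — a fully
aligned host effect would contradict that phenomenology.

*What the generator does not emulate.* (i) No migration or shared local
drift: populations are independent draws from the cline. Real sympatric
pairs are homogenized by local gene flow, which is what makes host pairs
cohere as terminal sisters in real NJ networks; on the simulator's noiseless
ladder geometry, interior-site host pairs are geometrically prevented from
being NJ sisters whenever the geographic:host divergence ratio is in the
2--3x range, so NJ-topology results on synthetic data probe the cline
geometry, not local cohesion. (ii) No LD decay with physical distance and no
recombination map — LD is block-structured or absent. (iii) No read-level
artifacts (FASTQ, mapping error) beyond the symmetric base error. Passing
recovery tests on this generator therefore validates the estimators and the
inference machinery, not robustness to demographic or technical structure
absent from the model.

## Numerical and reproducibility choices

EM tolerance 1e-6, max 100 iterations; per-SNP null quantiles need >= 100
draws; quantile type 7 everywhere; exceedance tests use strict `>`;
polarization ties at $p = 0.5$ do not flip; a-score ties take the smallest
number of PCs; duplicated stepwise predictors keep the first occurrence;
NJ negative branches are clamped with sister transfer. Every stochastic
stage takes an explicit integer seed; `run_pipeline()` derives per-stage
seeds from one master seed via a fixed affine map (`substream_seed()`), so
stage-level reruns reproduce pipeline-level results bit for bit, and rerun
reports are byte-identical.

## Pipeline problem sizes

`run_pipeline()` defaults to 999 Monte Carlo replicates per test and the
analysis drivers use 1,999 (4,999 Mantel permutations); the
`scripts/acceptance.R` reproduction uses 999/1,999. These are the package's
chosen desk-scale budgets; the estimators accept the 10,000-replicate
budgets of full-scale studies unchanged.
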