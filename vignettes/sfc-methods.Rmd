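---
title: "Structure-function coupling analysis: models, choices and limits"
author: "sfcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function coupling analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistic

Structure-function coupling (SFC) asks how closely a brain region's pattern
of functional interactions follows its anatomical wiring. For region $i$ with
structurally connected partner set $E_i = \{j : \mathrm{SC}_{ij} > 0\}$, the
regional SFC is the Pearson correlation across $j \in E_i$ between the
structural profile $\log(1 + \mathrm{SC}_{ij})$ and the functional profile
$z_{ij} = \operatorname{artanh}(r_{ij})$, the Fisher-z transformed Pearson
correlation of the two regions' resting-state time series. The same
correlation pooled over all structurally connected region pairs gives the
whole-brain SFC, and pooling within each unordered pair of canonical
networks gives the network-block level. Three analysis levels, three
correction families.

Group inference at every level is a single ordinary-least-squares model

$$y = \beta_0 + \beta_g\,\mathrm{group} + \beta_1\,\mathrm{age} +
\beta_2\,\mathrm{education} + \beta_3\,\mathrm{FD} +
\beta_4\,\mathrm{handedness} + \varepsilon,$$

with the patient group coded 1 and left-handedness coded 1; the reported
statistic is the $t$ of $\beta_g$ on $n - 6$ degrees of freedom. We fit the
joint model rather than residualizing the outcome on the covariates first:
the two coincide exactly when group is orthogonal to the covariates (a case
the test suite constructs and checks), and the joint model avoids bias when
it is not. Bonferroni correction is applied per level — the whole-brain
scalar is its own family of 1, the 28 unique blocks of a seven-network
partition form one family, and the regions form a third.

## Choices the SFC definition leaves open

The coupling recipe has three knobs that the literature does not fix
uniformly, so they are explicit flags rather than silent defaults:

* **Edge set.** Only $\mathrm{SC} > 0$ edges enter the correlation
  (default). A zero fiber count carries no profile information, and at
  realistic structural densities the zeros would dominate the correlation.
* **Count transform.** `log_transform = TRUE` applies $\log(1+x)$ to fiber
  counts before correlating; tract-count distributions are heavy-tailed and
  the raw-count correlation is otherwise driven by a few large bundles.
  Setting it off reproduces the raw-count reading.
* **Degenerate inputs.** Fisher-z clipping is off by default: a pair of
  identical time series is an error, not a silently truncated value.
  `clip = TRUE` truncates at $|r| = 1 - 10^{-7}$ for pipelines that prefer
  robustness.

Regions with fewer than `min_edges = 3` structural partners get a missing
SFC — a correlation on two points is meaningless — and missing units are
dropped from their correction family with a logged message, not imputed.

## The synthetic cohort

No imaging data ship with the package; every downstream stage is instead
validated against a generator with planted, known structure.

**Structural backbone.** One symmetric fiber-count matrix per cohort:
Bernoulli support at the requested density, rounded-lognormal counts
(heavy-tailed, like tract counts), at least three edges per region. Each
subject resamples the counts (Poisson around the backbone, support
preserved), so subjects share anatomy but not exact weights.

**Functional matrices with planted coupling.** For target regional coupling
$c_i$, the target correlation matrix blends the standardized log-SC profile
matrix $B$ with a symmetric noise matrix $N$:

$$F_{ij} \propto \sqrt{c_i c_j}\, B_{ij} +
\left[(1 - c_i^2)(1 - c_j^2)\right]^{1/4} N_{ij},$$

so a uniform target $c$ yields an expected profile correlation of exactly
$c$. The off-diagonal amplitude is scaled to $0.42/\sqrt{n}$: a symmetric
matrix with effectively independent off-diagonal entries of standard
deviation $\sigma$ has smallest eigenvalue near $1 - 2\sigma\sqrt{n}$, so
this is the largest amplitude at which the construction stays near the
positive-definite cone. The matrix is then projected by one eigenvalue
clipping step and rescaled to unit diagonal, and the subject's time series
are multivariate-normal draws from it. We deliberately do not simulate
neural dynamics: the target-covariance construction is the simplest
mechanism whose SFC is controllable and provable.

Two consequences are worth knowing. First, because the amplitude is small,
finite runs attenuate measured SFC toward zero by the factor
$\sigma_F / \sqrt{\sigma_F^2 + 1/T}$; at $T = 10{,}000$ the planted targets
are recovered to within 0.05 (a property test), at $T \approx 200$–$500$
the cohort operates at roughly 60–80% of the target scale, uniformly across
regions, which leaves group contrasts and rank-based analyses untouched.
Second, mixed-sign target vectors use the signed geometric mean as the
blend weight, which zeroes the structural weight on opposite-signed pairs —
exact planted levels are guaranteed only for same-signed targets, the case
every shipped default uses.

**Between-subject variability** has three sources: finite-run sampling
noise, the Poisson count resampling, and a per-subject global coupling
shift (`subject_sigma`, default 0.12 on the target scale). The global shift
mirrors the well-known subject-level component of coupling variance
(vigilance, residual motion, global signal), makes regional outcomes
positively dependent within subject — as they are in real cohorts — and
sets the between-subject SD of regional SFC near 0.1–0.15, the range
reported for whole-brain SFC spreads.

**Cohort defaults** emulate a two-group OCD-style design: 96 patients and
84 controls (a post-QC cohort of that shape), a 400-region / 7-network
parcellation, 240 functional volumes (a typical ~8-minute run), structural
density 0.25, baseline coupling 0.45, and a single right-hemisphere
"temporoparietal-junction-like" region carrying a patient deficit of
−0.3. Covariates (age, education, framewise displacement, handedness) are
drawn from plausible ranges and enter the target SFC additively with
configurable coefficients — zero by default, so the null is exactly
exchangeable; nonzero values make covariate adjustment testable against
known truth. Clinical scores are noise except one configurable score
(default: the compulsion subscale) tied to the *measured* SFC of one
region in patients at a configurable correlation (default 0.218); tying it
to the measured rather than the target value is what makes the downstream
correlation estimate consistent, since both sides then see the same
realization.

**Expression and receptor maps.** The expression generator stacks six
donors; the first `n_coupled` genes track the standardized planted
group-difference map at a set loading with independent per-donor residuals,
30% of the remaining genes get a donor-consistent but map-independent
spatial profile (so the differential-stability filter has real structure to
keep), and the rest are per-donor noise. Receptor maps are a
strength-weighted linear transform of the planted map plus noise —
Spearman-coupled by construction — with two maps (serotonin-1b- and
serotonin-transporter-like, columns 2 and 9 of the 19-map set) coupled at
−0.22 by default. Expression coverage defaults to all regions; left-only
coverage (the usual situation for donor tissue) is one flag away, but the
shipped default keeps the default right-hemisphere planted effect inside
the expression frame.

## Transcriptomics: PLS1, permutation, bootstrap

Differential stability is the mean over donor pairs of the Spearman
correlation of a gene's regional profile; the top half by DS is retained
(ties at the boundary are all kept). The retained matrix and the regional
t-map are column-standardized, and the first PLS component is taken in its
classical NIPALS form: weights $w \propto X^\top y$, regional score
$Xw$, variance explained defined on the response side as the squared
score–response correlation, sign flipped so that correlation is positive.
One component is modeled and tested; with a univariate response the later
components are rarely interpretable and are not reported.

Significance is two-fold. The component's variance explained gets an
add-one permutation p-value from uniform region relabelings (a hook accepts
user-supplied orderings for spin-style, autocorrelation-preserving nulls —
uniform permutation is deliberately the default, matching the common
practice of the PLS-transcriptomics lineage). Gene-level inference
bootstraps regions with replacement, re-fits, aligns each replicate's
sign by its correlation with the original weights (PLS weights are
sign-indeterminate, and unaligned replicates would inflate the SE), and
forms $z = w/\mathrm{SE}_{boot}$; two-sided normal p-values are BH-FDR
corrected at $q < 0.05$ and the survivors split by weight sign into PLS+
and PLS− lists.

One definitional point: with $w \propto X^\top y$, a response equal to a
single gene's profile inside a wide noise-gene pool does *not* yield a
response variance explained near 1 — the thousand near-zero noise weights
contribute score variance of order $p/n$ and dilute the score–response
correlation. The planted gene still takes the largest weight, which is the
property that matters for gene ranking; the suite checks the
variance-explained behaviour where the definition implies it (narrow
pools, strongly loaded designs).

## Network topology

Functional graphs are built by binary proportional thresholding of the
positive Fisher-z edges over a sparsity sweep (default 0.10–0.34 in steps
of 0.01, the GRETNA-style convention), with exact tie-breaking by edge
index so that graphs are reproducible. Per sparsity we compute clustering
(Watts–Strogatz local coefficient, zero for degree < 2), characteristic
path length (mean over connected pairs; disconnected pairs are excluded
and counted), global efficiency (mean inverse distance; disconnected pairs
contribute zero), local efficiency (mean global efficiency of neighbor
subgraphs), and the small-world ratios gamma, lambda and sigma against
`n_rand = 100` degree-preserving rewirings. Each metric curve is collapsed
to a trapezoidal area under the sparsity sweep before group inference, so
no single arbitrary threshold drives the result; the seven global AUCs form
one Bonferroni family and each nodal metric is corrected over regions. All
deterministic metrics are verified against an exhaustive Floyd–Warshall
oracle on every graph of up to eight nodes in a 200-graph randomized suite.

## Neurotransmitter maps

The unthresholded regional t-map is compared with each receptor/transporter
density map by Spearman correlation (average ranks for ties), with a
two-sided add-one permutation p from uniform region relabeling — 5000
permutations by default, one shared permutation stream across the family —
and BH-FDR across all maps tested in one run. Whether a spatial null should
preserve autocorrelation is an open question in this literature; uniform
permutation is the default and spin-style orderings can be supplied.

## Determinism and numerical conventions

Every stochastic component draws its seed through a labelled splitter from
one master seed, so stages are independently reproducible and an identical
config + seed reproduces byte-identical stat tables (an acceptance-level
test). Permutation and bootstrap p-values use add-one estimators, hence
never zero. Add-one estimators, QR-based least squares, and eigenvalue
clipping at $10^{-8}$ are the only numerical tolerances in play; Fisher-z
matches `atanh` to $10^{-12}$ in the suite.

## Problem sizes used by the shipped checks

The acceptance-style checks run the full method at reduced,
power-calculated scale rather than at the 400-region cohort size: planted
recovery uses 100 cohorts of 40 + 40 subjects, 60 regions, 500 volumes and
a −0.3 deficit; null calibration uses 200 null cohorts of the same shape at
40 regions; PLS recovery uses 50 replicates of a 200-region, 1000-gene,
50-planted design at loading 0.8 with 500-replicate bootstraps; the
receptor-map check uses 50 replicates of a 19-map family with one map
planted at 0.6. These sizes were chosen so each check has comfortable
analytical power (planted effects sit at 4–6 standard errors) while the
whole suite stays routine to run.

## What passing does and does not show

The generator produces linear-Gaussian data with exactly the planted
structure and none of the confounds of real cohorts: no spatial
autocorrelation in expression or receptor maps beyond the planted signal,
no scanner or site effects, no motion-coupling artifacts, no
autocorrelated BOLD noise, and donor stacks that differ only by
independent noise. Recovery and calibration on this cohort validate the
*implementation* — that the statistics compute what their definitions say
and that their null behaviour is correct — not the biological claims of
any particular applied analysis. In particular, uniform-permutation p-values
on spatially smooth real maps are known to be optimistic; that is exactly
why the spin-null hooks exist.

Known limitations: negative planted coupling targets are only
approximately honored in mixed-sign vectors (see above); the generator's
receptor maps are monotone-linear in the planted map, so Spearman and
Pearson analyses coincide on them; and the clinical-score generator plants
at most one score–region association per cohort.
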