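---
title: "Consensus metabolite ranking and time-course analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus metabolite ranking and time-course analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaborank)
```

# The problem

Untargeted plasma metabolomics of a factorial animal study — two age groups,
surgical interventions (sham laparotomy vs cecal ligation and puncture, a
standard polymicrobial sepsis model), and several post-intervention sacrifice
times, with a paired retro-orbital (RO) pre-intervention sample per animal —
produces a samples-by-metabolites peak-area matrix. The analytical questions
are (i) which metabolites best distinguish two sample classes (aged vs young
at baseline; CLP vs sham within an age group), (ii) which metabolic pathways
those metabolites concentrate in, and (iii) how individual pathway members
move over the time course in each group.

No single feature-selection method is trustworthy on its own: supervised
methods can overfit class labels, and unsupervised ones are blind to them.
`metaborank` therefore implements a consensus workflow: four independent
importance rankings are aggregated by their per-metabolite **median rank**,
the top *K* (default 100) metabolites form the feature set, and downstream
inference (superfamily distribution test, pathway over-representation,
per-metabolite two-way ANOVA) is run on that set.

# Preprocessing

The chain is order-fixed and recorded in the result's `provenance()`:

1. **Annotation filter** — only metabolites carrying a KEGG or HMDB
   identifier are retained (in a typical commercial panel of 834 identified
   compounds, 566 have such ids); the annotated set is also the enrichment
   universe.
2. **Pooled-reference normalization** — each metabolite is divided by the
   median of its values over the reference samples, computed within
   analytical batch. The default reference set is all RO samples: they are
   the only shared pre-intervention state of the design and so play the role
   of pooled controls. An explicit sample list can be supplied instead.
   Metabolites whose reference median is zero or not estimable are excluded
   and logged.
3. **Imputation** — the rankers need complete data. The default replaces a
   metabolite's missing entries by half its minimum observed value, the
   usual limit-of-detection surrogate for MS peak areas; row-mean and a
   k-nearest-sample average are available alternatives.
4. **Autoscaling** — mean-centering and division by the per-metabolite
   standard deviation (sample convention, *n* − 1; stated explicitly because
   conventions differ). No log transform is applied by default — the
   workflow scales raw normalized peak areas — but `log2 = TRUE` is
   available.

`autoscale()` is idempotent to numerical precision, and scaled columns
satisfy |mean| < 1e-8, |sd − 1| < 1e-8 (tested properties).

# The four rankers

All four return a score and a rank per metabolite; every ranking is a
permutation of 1..*p* with a fully deterministic tie-break (higher absolute
secondary score, then lexicographic metabolite id), so that the consensus
step is reproducible bit for bit.

**PCA (unsupervised).** With eigenvalues $\lambda_a$ and loadings $l_{aj}$
of the scaled matrix, and $A^\*$ the smallest leading component set reaching
a cumulative explained variance of 80% (exposed as `var_threshold`),

$$\mathrm{score}_j = \sqrt{\sum_{a \in A^\*} \lambda_a l_{aj}^2 \Big/ \sum_{a \in A^\*} \lambda_a}.$$

PCA loadings are agnostic to group assignment and respond only to total
variance, so this ranker acts as a counterweight to the three supervised
ones.

**PLS-DA VIP.** A univariate-response PLS model is fitted by NIPALS with
class membership coded ±1 and centered; two latent components by default
(two-component score plots are the field's standard view). With unit-norm
weights $w_a$, scores $t_a$ and y-loadings $q_a$, the per-component
explained-y sum of squares is $SSY_a = q_a^2\, t_a^\top t_a$ and

$$\mathrm{VIP}_j = \sqrt{p \sum_a SSY_a w_{aj}^2 \Big/ \sum_a SSY_a},$$

which enforces $\sum_j \mathrm{VIP}_j^2 = p$ (tested to 1e-8). Components
are dropped once the residual $X^\top y$ vanishes.

**EBAM.** The empirical Bayes mixture construction in the microarray
tradition, built from scratch because no installed implementation exists:
a moderated statistic $z_j = (\bar{x}_A - \bar{x}_B)/(s_j + a_0)$ with
$s_j$ the pooled two-sample standard error and the fudge factor $a_0$ a
quantile (default median) of the $\{s_j\}$; the marginal density $f(z)$
estimated by Lindsey's method (101 equal-width bins spanning the observed
range, Poisson regression of bin counts on a natural-spline basis with 5
df); a null $f_0$ estimated from 100 label permutations pooled through the
identical estimator (a theoretical N(0, 1) null is used when
`n_permutations = 0`); the null proportion
$p_0 = \min(1, \min_z f(z)/f_0(z))$ taken over the central 50% z-interval;
and the posterior $\max(0, 1 - p_0 f_0(z_j)/f(z_j))$. Densities are floored
at 1e-12 to keep ratios finite. Metabolites with posterior ≥ 0.9 (`delta`)
are flagged; ties in posterior are resolved by |z|. Calibration is
property-tested: on pure-null data the flag rate stays at or below 5%.

**Random forest.** Out-of-bag permutation importance (unscaled mean
accuracy decrease) from a 500-tree classification forest with
`mtry = floor(sqrt(p))`, computed by the `randomForest` package behind the
module surface, seeded for determinism.

For CLP-vs-sham comparisons all post-intervention timepoints are pooled
with class = intervention; pooling maximizes per-class sample size and
matches the one-selection-per-comparison structure of the workflow.
Stratified per-timepoint runs can be composed from the same functions if
wanted.

# Consensus, superfamily test, enrichment

`median_rank_consensus()` takes the median of the four integer ranks;
ordering ties resolve by mean rank, then id. The consensus is monotone
(improving one method's rank never worsens the consensus) and reduces to
the common ranking when all four agree — both are tested exactly.

The **superfamily test** compares the selection's composition over coarse
metabolite classes (lipid, amino acid, cofactor, ...) to the universe
proportions by a goodness-of-fit chi-squared: the universe is fixed and
fully known, which is why goodness-of-fit is preferred over a contingency
formulation (available as `contingency = TRUE` for sensitivity). Expected
counts below 5 are pooled into `"other"` per standard chi-squared validity
practice.

**Over-representation analysis** uses the one-sided hypergeometric upper
tail $P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, m, K)$, with the
annotated filtered set as universe $N$, and Benjamini–Hochberg q-values
across pathways. Under-representation is not reported. Topology-based
pathway "impact" scores are deliberately out of scope; the reported outcome
is pathway identity and significance. The closed-form tail is verified in
the test suite against exhaustive enumeration of all $\binom{N}{K}$
selections for every instance with $N \le 15$.

# Time-course ANOVA

Each metabolite is tested with a two-way ANOVA over **group** (the four
age-by-intervention combinations) and **time** (the post-intervention
sacrifice hours, treated as a factor). RO samples precede group assignment
and are excluded from the time factor by default (`include_baseline` adds
them as the earliest level). Attrition makes the design unbalanced, so
Type II sums of squares (nested model comparisons, via `car::Anova`) are
used; they are well-defined without contrast-coding choices and reduce
exactly to the classical decomposition when balanced — the balanced identity
$SS_{tot} = SS_G + SS_T + SS_{GT} + SS_E$ is tested. When empty cells make
the interaction inestimable the mains are reported from the additive model
with a warning. Significance flags G/T/I use α = 0.05 (configurable).

Post-hoc contrasts follow the "compare groups at each timepoint"
convention: within each timepoint,
$q = |\bar{x}_i - \bar{x}_j| / \sqrt{MSE\,(1/n_i + 1/n_j)/2}$ with the MSE
and residual df of the full two-way fit, referred to the studentized-range
distribution with $k$ = number of groups (4), so the family is all
$k(k-1)/2$ pairwise group comparisons within the timepoint even though only
the requested pairs are emitted. The defaults are the two comparisons of
primary interest in an aged/young sepsis design: aged CLP vs young CLP, and
aged CLP vs aged sham. F statistics are location- and scale-invariant, so
running the ANOVA on normalized-but-unscaled values (the default choice
here) gives the same flags as any rescaled version; unscaled values keep
the cell means interpretable for plotting.

# The synthetic generator

Because the motivating data type (a commercial untargeted panel) is rarely
released, the package ships a first-class generator so every stage has a
recovery-testable input with known ground truth.

* **Design**: animals per (age, intervention, timepoint) cell, each with a
  paired RO sample; immediate-sacrifice animals exist only at 0 h.
  Attrition is implemented as removal of the post-intervention sample
  (death before sacrifice), not value censoring, which exercises the
  unbalanced-ANOVA path; per-(age, intervention) probabilities allow the
  differential frailty pattern (e.g. 30.2% vs 17.4%).
* **Abundances**: log-normal — MS peak areas are positive and right-skewed,
  and multiplicative noise is the standard assumption; effects are additive
  on the log2 scale with residual sd 0.5 log2 units by default (2-fold
  scatter at ±1.4 sd, a realistic mid-range for plasma panels). Baselines
  are uniform on log2 ∈ [10, 20].
* **Effects** live only in designated *active pathways*: an age effect
  (applies to aged samples everywhere, including RO), a linear time drift
  in t/12, an age-by-time interaction, and a sepsis effect applied to
  post-intervention CLP samples. The sepsis term extends the minimal
  (group, time, interaction) parameterization so that CLP-vs-sham
  comparisons can carry planted signal too — without it only the baseline
  age contrast would be recoverable, and cross-comparison intersection
  logic would be untestable. A metabolite belonging to several active
  pathways takes the effect of the first one containing it, keeping the
  affected set exactly the union of active member sets (a tested
  invariant).
* **Missingness** is completely at random. Intensity-dependent missingness
  is a real phenomenon in MS data that the generator does not emulate;
  passing tests therefore say nothing about imputation behaviour under
  detection-limit censoring. Likewise the generator makes no attempt at
  raw spectra, retention times, or batch drift beyond batch labels.

The time effect is linear by design simplicity; the sham spike-and-recovery
trajectories seen in real studies are qualitative, and richer shapes can be
plugged in through per-pathway effect overrides.

# Numerical choices and problem sizes

* Tie-breaks everywhere: score descending, then |secondary| descending,
  then lexicographic id — total determinism is a prerequisite for a
  reproducible consensus and the bundle digest.
* Density floors at 1e-12 (EBAM), pooling threshold 5 (chi-squared),
  sample-sd convention (n − 1), BH for pathway multiplicity.
* Reproducibility: every stochastic step takes a seed; `run_pipeline()`
  returns a content digest that is bit-identical across reruns of the same
  inputs and seeds (tested).
* The test suite exercises: exhaustive ORA oracle equivalence for all
  N ≤ 15; a 2×2×2 worked ANOVA cell set with closed-form F = (9, 36, 4);
  PCA against a direct eigendecomposition to 1e-10; VIP and autoscale
  identities over 100 random datasets; null calibration with 1000
  metabolites (ANOVA interaction) and 20 × 200 metabolites (EBAM);
  and 20 seeded end-to-end runs at 320 metabolites / 20 pathways / n = 8
  per cell with a 1.5 log2 group effect, requiring the two active pathways
  to head the enrichment table in at least 18. These sizes are the
  package's chosen reference conditions for calibration and recovery.

# Known limitations

* Two-class comparisons only; multi-class rankings are out of scope.
* EBAM has no installed reference implementation to cross-check against, so
  its guarantees are Monte-Carlo (calibration and recovery) rather than
  oracle equivalence.
* The ORA universe is the annotated set, not all identified metabolites;
  pathway coverage of sparsely detected pathways is reported (`m` per
  pathway) but not filtered on — pathway-quality judgements are left to the
  user.
* Repeated-measures structure (the paired RO sample per animal) is not
  modelled in the ANOVA; each timepoint is a distinct animal in this
  design, so a mixed model would add little and is not implemented.
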