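---
title: "Models and methods in dhgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dhgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`dhgp` implements a complete analysis chain for quantitative traits in a
biparental doubled haploid (DH) population — simulation, marker quality
control, phenotype analysis, QTL mapping, and four genome-wide prediction
models under a common cross-validation engine. This vignette explains the
models, the numerical choices, and the design decisions that were
genuinely open, and states what the synthetic-data generator does and does
not emulate.

## 1. The DH population simulator

A DH line is produced by one meiosis of the F1 of two fully homozygous
parents, followed by genome doubling. The simulator fixes the parents as
opposite homozygotes at every marker — only markers polymorphic between
the parents are represented, mirroring a post-QC marker set — and samples
one gamete per line. Crossovers follow the **Haldane model** (no
interference): the recombination fraction between adjacent markers at map
distance $d$ cM is $r = (1 - e^{-2d/100})/2$, applied independently per
interval. The resulting lines are fully homozygous by construction; the
call coding is 2 (parent-1 homozygote), 0 (parent-2), 1 (heterozygote,
never produced by the simulator but tolerated downstream), `NA` (missing).
Haldane was chosen because it has a closed-form map function that an
independent oracle can check directly (the test suite verifies the
recombinant fraction of a 50 cM interval against $(1-e^{-1})/2$ at
10,000 lines).

Missingness and genotyping error are *not* baked into the population
simulator — phenotype simulation requires complete genotypes — but are
injected by `inject_missing_and_errors()` (defaults: 2% missing, 0%
error) so the QC filters have realistic work to do.

### Trait architectures

`sample_qtl_architecture()` provides three presets spanning the regimes
seen for rapeseed seed-quality traits:

* **major-QTL-like** — two large loci on different chromosomes jointly
  carrying 75% of the genetic variance in a 45:31 ratio (the erucic-acid
  regime, where two QTL explain ~77% of phenotypic variance), plus an
  8-locus small-effect background.
* **polygenic-like** — 25 QTL with geometrically decaying variance shares
  (ratio 0.92² per rank); the largest share is ≈ 0.155, below the ~0.16
  maximum observed for seed oil content, and the majority of loci are
  minor. This is the regime in which FDR-controlled QTL detection misses
  most of the genetic variance.
* **epistatic-like** — a polygenic additive base plus **20
  additive×additive pairs** contributing a stated fraction (default 25%)
  of the genetic variance. The pair count is deliberately polygenic: an
  additive×additive *kernel* (Section 5) models the average digenic
  relationship over all marker pairs, and a trait whose epistasis is
  concentrated in a handful of pairs generates a pairwise covariance
  essentially orthogonal to that kernel — no kernel method could be
  expected to exploit it. Twenty dispersed pairs emulate the polygenic
  digenic epistasis the kernel model class assumes.

Effect sizes are relative: `simulate_phenotypes()` rescales the line
genetic values so their empirical variance equals `genetic_var_target`
*exactly* (the rescaling is linear, so relative shares are preserved).

### Trial simulation

Plot values follow the RCBD-across-environments model
$$y_{ijr} = \mu + G_i + E_j + (GE)_{ij} + R_{jr} + \varepsilon_{ijr},$$
with environment main effects, genotype-by-environment deviations,
replicate-within-environment effects (drawn per environment, matching the
`environment:rep` model term), and plot residuals all independent
Gaussians with the design variances. `trial_design_for_h2()` splits the
non-genetic variance between G×E and plot error in the 0.71 : 1.17
proportion reported for seed oil content and scales both to hit a target
entry-mean heritability — a convenience for constructing calibrated
scenarios.

### The validation panel

`simulate_validation_panel()` emulates a genetically distant panel:
inbred lines with per-marker allele frequencies drawn from a spread
distribution around 0.5, markers segregating independently (no shared LD
phase with the DH map), and only a fraction `shared_qtl_fraction` of the
DH architecture's QTL effective; the remainder are replaced by
panel-private QTL of equal magnitude so total genetic variance is
comparable but does not transfer. The published study does not
characterize its validation panel's LD or allele-frequency structure, so
these are modeling choices, not reproductions; tests use only the
monotonicity they imply (transfer accuracy increases with the shared
fraction and is ≈ 0 at zero sharing).

## 2. Marker quality control

Markers are removed if monomorphic, > 5% missing, < 5% minor allele
frequency, or > 5% heterozygous (all thresholds configurable; MAF counts
a heterozygote as one copy of each allele). **Genetic bins** are sets of
markers separated by no observed recombination — pairwise $r^2 = 1$,
computed as the squared Pearson correlation on jointly observed lines.
Because missingness can make that relation non-transitive, bins are the
connected components of the $r^2 = 1$ graph, built per chromosome (a
genetic bin is a recombination-local object). Each bin contributes one
**representative**: least missing rate, ties broken by presence of a
physical position, then smallest bp, then marker id (the first two
criteria are the published rule; the rest make the choice deterministic).

`prune_ld()` walks markers in map order and keeps a marker only if its
$r^2$ with every previously kept marker on the chromosome is ≤ the
threshold (default 0.95); exact duplicates are dropped even at a
threshold of 1. `encode_finf()` produces the F∞ metric: reference-parent
homozygote +1, other homozygote −1, heterozygote 0; missing entries are
imputed with the column mean of observed codes.

## 3. Entry means, variance components, heritability

BLUEs come from the fixed two-way model `value ~ genotype + environment`
with sum-to-zero environment effects; on balanced data this equals the
plain line mean (verified to 1e-10), and with missing cells it applies
the environment-effect correction of the least-squares solution.

Variance components treat all effects as random. For **balanced** data
the estimator is the closed-form method of moments on the expected mean
squares of the two-way ANOVA with replicates nested in environments:
$$\hat\sigma^2_E = MS_{err},\quad
\hat\sigma^2_{G\times E} = (MS_{GE} - MS_{err})/N_R,\quad
\hat\sigma^2_G = (MS_G - MS_{GE})/(N_E N_R),$$
negative solutions truncated at zero. This is exactly unbiased before
truncation, has no tuning, and is oracle-checkable. **Unbalanced** data
are fitted by REML (`lme4::lmer`) with the same random-effects structure
— the standard tool for the job rather than a hand-rolled EM iteration.
Single-environment data cannot separate G×E from error; the G×E component
is returned as 0 with a warning flag.

Broad-sense heritability on the entry-mean basis is
$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{G\times E}/N_E +
\sigma^2_E/(N_E N_R)},$$
with $N_R$ the *average* replicate count per environment. No shrinkage or
adjustment is applied. The replicate-within-environment variance is
estimated internally but — following the formula — excluded from $H^2$.

## 4. QTL mapping

Cofactors are selected on the representative markers by **stepwise
multiple linear regression under BIC** ($n\ln(RSS/n) + k\ln n$): forward
selection with backward elimination after each inclusion, accepting only
strict improvements, capped at $\lfloor n/5\rfloor$ cofactors. Note that
forward BIC selection under a pure-noise trait is not exactly empty — the
maximum of $m$ independent score statistics exceeds the $\ln n$ penalty
with appreciable probability — so the null behavior is "near-empty"
(≤ 10% of candidates), which the test suite verifies.

The genome scan tests each marker by a **partial F-test** of the full
model (marker + cofactors) against the cofactor-only model. Cofactors
with $r^2 > 0.8$ to the tested marker (or in the same bin) are dropped
from both models for that test; markers that leave the design
rank-deficient are skipped with a flag. Significance is controlled by
**Benjamini–Hochberg step-up FDR at q = 0.1**. PVE is reported as 100 ×
adjusted R² of the joint regression on the significant set, and
per-marker PVE as the *last-in* increment of adjusted R² (the published
per-marker PVE is not given an explicit partition; last-in is
deterministic and sums to at most the joint PVE).

MAS (`mas_fit_predict`) reruns the whole detection chain inside each
training set, fits OLS on the training-significant markers (exact
collinearity resolved by QR pivoting), and predicts test lines; an empty
significant set predicts the training mean.

## 5. Genome-wide prediction models

**GBLUP** uses the VanRaden method-1 kernel on the ±1 coding:
$G = ZZ^\top / (2\sum_k p_k(1-p_k))$ with observed frequencies and
column-centered $Z$. Note that for fully inbred lines the column variance
of $Z$ is $4p(1-p)$, so $\mathrm{diag}(G)$ averages ≈ 2 rather than 1;
variance components on the phenotypic scale are $\sigma^2_g \cdot
\overline{\mathrm{diag}(G)}$. Single-kernel REML maximizes the
eigen-rotated profile likelihood over the ratio
$\delta = \sigma^2_e/\sigma^2_g$ (bracketed scalar search on
$\log\delta \in [-25, 25]$, tolerance 1e-10), a formulation with no
matrix inversions inside the optimizer.

**RR-BLUP** is ridge regression with the shrinkage implied by the GBLUP
fit: $\sigma^2_\beta = \sigma^2_g / (2\sum p(1-p))$,
$\lambda = \sigma^2_e/\sigma^2_\beta$, and effects
$\beta = \sigma^2_\beta Z^\top V^{-1}(y-\mu)$, which equals
$(Z^\top Z + \lambda I)^{-1}Z^\top(y-\mu)$. RR-BLUP and GBLUP are the
same model in different coordinates; the test suite enforces agreement of
fitted and out-of-sample predictions to 1e-6 at the 180 × ~1,400 scale.
Kernel-model prediction for new lines uses the cross-kernel with
*training* centering and frequencies,
$\hat g_{new} = G_{new,train}(G_{train} + 10^{-8}I)^{-1}\hat g$; the
ridge is kept at 1e-8 precisely so it does not erode the equivalence.

**EG-BLUP** adds a digenic epistatic kernel $H$: the Hadamard square of
$G$, rescaled so its mean diagonal equals that of $G$. (Hadamard
epistasis kernels are coding-dependent; this one is defined on the F∞ ±1
coding.) The two-kernel REML surface over
$(\sigma^2_g/\sigma^2_e, \sigma^2_h/\sigma^2_e)$ is maximized by
Nelder–Mead on the log-ratios. With full-rank kernels this surface can be
nearly flat along a ridge where $\sigma^2_e \to 0$; that is a property of
the model, not the optimizer, and is the main reason EG-BLUP's gains over
GBLUP are small and occasionally negative fold-by-fold — matching the
published experience that modeling digenic epistasis helps only
marginally.

**BayesCπ** is the variable-selection regression
$y = 1\mu + \sum_k Z_k\beta_k\delta_k + e$, $\beta_k\mid\delta_k{=}1 \sim
N(0,\sigma^2_\beta)$ common to all markers, $\delta_k \sim
\mathrm{Bern}(1-\pi)$, $\pi \sim U(0,1)$. The Gibbs sampler (compiled,
driven by R's RNG so a seed fixes the chain bit-for-bit) updates $\mu$,
each $(\delta_k, \beta_k)$ from the marginal inclusion odds, the two
variances from scaled-inverse-χ² full conditionals (df 4), and $\pi$ from
its Beta conditional. The $\sigma^2_\beta$ prior scale is **tied to the
current $\pi$** — the assumed genetic variance (half of $\mathrm{var}(y)$
at an initial genomic $h^2$ of 0.5) spread over the markers currently
expected to be included. With a fixed scale, $\pi$ is unidentified on
null data (inclusion becomes cost-free as $\sigma^2_\beta \to 0$); the
adaptive scale restores the sparse solution, and the suite checks
$1-\pi < 0.1$ on pure-noise traits. Default chain: 20,000 iterations,
6,000 burn-in, thinning 1; cross-validation tests use a 2,000/600 chain,
and one full-length chain is verified against the short one. Markers are
LD-pruned at $r^2 \le 0.95$ before sampling.

## 6. Cross-validation and sweeps

`make_cv_splits()` draws 100 independent random 4:1 splits (144/36 at
n = 180) — the operational procedure described for the reference study —
rather than a rotating 5-fold partition; per-replication seeds derive
deterministically from the master seed so any single replication is
reproducible in isolation. Splits are *shared across methods* for paired
comparisons (variance reduction); accuracy is
$\mathrm{cor}(\hat y, y)/\sqrt{H^2}$ computed on test lines only.

The sweeps hold everything fixed but one factor: training size (random
subsets, all remaining lines tested), marker density (evenly spaced
subsets along the map), or number of environments (per replication, a
random environment subset recomputes the *training* entry means, while
test lines are always evaluated against their all-environment entry
means — emulating reduced phenotyping intensity). Environments are
sampled without replacement, a choice the source procedure leaves open.

Independent validation fits RR-BLUP on the full training population,
predicts the panel on the common markers (≥ 50 required) with training
centering, and standardizes by the *training* heritability.

## 7. Problem sizes and what the tests show

The default test suite runs at deliberately moderate sizes — maps of
3–19 chromosomes with 20–160 markers each, populations of 40–500 lines,
10–100 cross-validation replications, Gibbs chains of 1,500–20,000
iterations — chosen so the full suite exercises every code path at the
study's structural scale (180 lines, ~1,400 representative markers for
the method-ranking checks) while remaining a routine run. The
directional method rankings (genomic > MAS on polygenic traits, BayesCπ ≥
RR-BLUP with two major QTL, EG-BLUP ≥ GBLUP under substantial
additive×additive variance) are properties of matched *synthetic*
architectures: the generator reproduces the variance structure, LD
geometry and trial design of a real biparental program, but not
assay-specific artifacts (allele-calling error structure, segregation
distortion, selection during line production) or environmental
correlation structure. Passing these tests therefore demonstrates that
the estimators behave correctly under the assumed model, not that the
published accuracy values would be reproduced on the original
(undeposited) data.

## 8. Known limitations

* The scan inherits the representative-marker resolution: member markers
  of a bin share their representative's evidence, and QTL positions are
  resolved only to the bin.
* The EG-BLUP REML surface can be flat near $\sigma^2_e = 0$; variance
  components from two-kernel fits should be interpreted cautiously at
  n ≲ 150.
* Mean imputation is adequate at the ≤ 5% missingness the QC admits, but
  attenuates LD slightly; no haplotype-based imputation is provided.
* `estimate_variance_components()` with unbalanced data relies on lme4;
  heavily unbalanced single-replicate designs may fail to converge.
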