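---
title: "Individualized pathway analysis of blood transcriptomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized pathway analysis of blood transcriptomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsig)
```

# The problem

Patients with preclinical systemic sclerosis (PreSSc) present with
Raynaud's phenomenon and disease-specific autoantibodies or capillaroscopy
changes, but no overt fibrosis. A fraction of them progress to definite
disease within a few years. Whole-blood RNA-seq of such a cohort — healthy
controls sampled once, patients sampled at baseline and again at the end of
follow-up — raises four questions this package answers in turn: do
individual patients carry pathway-level expression signatures that separate
them from controls; do those signatures stratify the cohort into clinically
meaningful subgroups; can baseline signatures predict who will progress;
and do the signatures of progressing patients change over time while stable
patients' signatures stay put?

The unit of analysis is the *pathway score of one sample*, not a gene-level
contrast, so every subject gets an interpretable molecular profile.

# Single-sample pathway scoring

For one sample, genes are ranked by expression in ascending order (ties get
the average rank). The weight of the gene at rank $r$ among $N$ genes is

$$ w(r) = r \, e^{-r/N}, $$

a rank-exponential scheme that up-weights highly expressed genes smoothly
rather than through a hard cutoff; $w$ is non-decreasing on $[0, N]$. The
score of a gene set $S$ in that sample is the difference of mean weights

$$ \mathrm{score}(S) = \frac{1}{|S|}\sum_{g \in S} w_g \;-\;
   \frac{1}{N - |S|}\sum_{g \notin S} w_g . $$

Two consequences shape everything downstream. First, the score depends on
the expression column only through its ranks, so it is exactly invariant to
any strictly increasing within-sample transform — whether scoring runs on
normalized counts or on log-normalized values is immaterial, and the test
suite asserts this as an identity rather than an approximation. Second, the
statistic is *competitive*: because the total weight over all ranks is
fixed, a pathway's score can only move when its own members move through
the rank distribution, and a strong coordinated shift of one gene group
necessarily displaces the ranks of everything else. The limitations section
returns to this.

Pathways mapping fewer than `min_genes = 5` genes of the expression
universe are dropped (intersection semantics: set members absent from the
data are ignored). The weighting lives in one function, `rank_weights()`,
so a variant scheme can be substituted in a single place; all reported
statistics are conditional on the scheme above.

A per-pathway min–max rescaling to $[-1, 1]$ (`minmax_normalize()`) exists
for heat maps and for clustering; all inferential statistics run on the raw
scores. A pathway constant across samples maps to zeros by convention.

# Preprocessing

Genes are kept when strictly more than 1 CPM is observed in at least two
samples, with CPM computed on raw library sizes; filtering therefore
precedes normalization. Size factors are then the classical
median-of-ratios: the pseudo-reference of a gene is the geometric mean of
its counts across samples, computed over genes positive in every sample,
and a sample's factor is the median of its ratios (midpoint convention at
even counts). When no gene is positive everywhere the function fails by
default and offers a positive-counts fallback flag rather than silently
switching estimators. Expression is $\log_2(\text{count}/s_j + 1)$; the
pseudo-count is irrelevant to the rank-based scores but keeps the matrix
finite for inspection and export. The alternative order — size factors
before filtering — is available behind `filter_after_normalization`.

# Robust differential-pathway statistics

Group comparisons of pathway scores use trimmed/winsorized statistics with
$\gamma = 0.2$ per tail, the convention under which the effect-size cutoff
below is calibrated. With $k = \lfloor \gamma n \rfloor$, winsorization
replaces the $k$ smallest values by the $(k{+}1)$-th order statistic and
the $k$ largest by the $(n{-}k)$-th.

The effect size is

$$ d_R = 0.642 \; \frac{\bar{x}^{t}_A - \bar{x}^{t}_B}{s_W}, $$

with trimmed means in the numerator and the pooled winsorized standard
deviation (winsorized sums of squares over $n_A + n_B - 2$ df) in the
denominator; the constant $0.642$ rescales the 20%-trimmed statistic to
match Cohen's $d$ under normality. A pathway is called significant only
under the dual rule: Benjamini–Hochberg $q < 0.05$ *and* $|d_R| > 0.62897$
(the conventional moderate-effect boundary). The effect-size arm is what
makes the caller conservative: on null cohorts the empirical count of
significant pathways is essentially zero, well below what FDR control alone
would permit.

The test is Yuen's: Welch-type on trimmed means with squared standard
error terms $d_i = (n_i - 1)\, s^2_{W,i} / (h_i (h_i - 1))$, where
$h_i = n_i - 2\lfloor \gamma n_i \rfloor$, and Welch–Satterthwaite degrees
of freedom. A pooled-variance $t$ on winsorized values is available behind
`variant = "pooled"` for comparison; Yuen is the default because it is the
standard companion of $d_R$ and robust to unequal spread. Degenerate
inputs follow fixed conventions: zero pooled winsorized variance with equal
trimmed means gives $d_R = 0$ and $p = 1$; with unequal means it gives a
signed infinity so the caller can flag rather than mask the degeneracy.

A vectorized row-wise implementation backs the per-fold hot paths; the
suite asserts its exact agreement with the scalar reference functions.

# Clustering and clinical association

Samples are clustered on the min–max view of the significant pathways'
scores — the same representation a reader of the heat map stratifies by
eye — with Euclidean distance and Ward's linkage (`ward.D2`, which applies
Ward's criterion on squared distances), cut at $k = 4$. The choice of
$k$ is a fixed default, not automatic model selection; the cohort design
anticipates a gradient from control-like to patient-like profiles, and the
composition table orders clusters by ascending patient fraction to make
that gradient explicit. Categorical covariates are tested against cluster
membership by chi-square (no continuity correction; expected-count
warnings are suppressed, not hidden behind Yates), numeric covariates by
one-way ANOVA; a constant covariate is reported as degenerate with
$p = 1$ rather than an error, so covariate sweeps do not abort.

For 2×2 clinical tables both the two-sided Fisher exact $p$ and the
Pearson chi-square $p$ (no correction) are returned. On the cohort's
aspirin-by-outcome table (19/0 vs 9/5) the exact test gives $p = 0.0084$
and Pearson gives $p = 0.0047$; with expected counts below 5 the exact
test is the defensible choice, and reporting both makes the discrepancy
visible instead of leaving the reader to guess which "chi-square" a
printed value came from.

# Cross-validated classification

The baseline control-vs-patient model is an L2-penalized logistic
regression over 20 runs of stratified 10-fold cross-validation. Folds are
stratified because 16-vs-33 imbalance makes unstratified folds frequently
single-class. Pathway selection — the same dual rule as above — is re-run
inside every training fold; held-out samples never touch selection or
fitting. When a training fold selects nothing, the single best pathway by
$|d_R|$ is used and the fallback is counted in the report. The ridge
penalty is fixed at $\lambda = 1/n_{\text{train}}$ (the common
unit-cost-parameter convention) rather than tuned, since this task's
design names no inner tuning loop. The summary is the mean ± SD of AUROC
over all completed run × fold entries.

Progression prediction from baseline runs as nested cross-validation over
three model families (ridge logistic, Gaussian naive Bayes, random forest)
crossed with univariate selection of the top 1/5/10/20% of pathways.
Ranking is by Yuen $p$ with ties broken by $|d_R|$, consistent with the
differential analysis. Within each outer training fold an inner 5-fold CV
tunes the one free hyper-parameter — the ridge $\lambda$ over a log grid,
or the random forest's `mtry` over $\{\sqrt{p}, p/3, p\}$; Gaussian naive
Bayes has no comparable knob and skips the inner loop. Selection is
re-done inside every inner training fold too, so the tuning estimate is
itself leakage-free.

Two behaviors of this design deserve flagging. Selecting features on the
full data *before* cross-validating — the classic leakage error — inflates
the null AUROC by several tenths; the package implements that variant
behind `select_in_fold = FALSE` purely so the inflation can be
demonstrated and rejected. Conversely, for one fixed null dataset the
honestly nested estimate with top-1 fallback is not centered at 0.5: the
handful of pathways that happen to look strongest in that dataset dominate
selection in every fold, and their held-out behavior is a property of the
realized noise, so single-dataset null means wander widely (both below and
above 0.5). Chance level is recovered exactly under label permutation —
by exchangeability the held-out expectation is then 0.5 — which is why the
package's null calibration checks permute labels rather than reuse one
fixed labeling.

# Longitudinal change analysis

For the paired patients, each pathway's change $\Delta_i =
\text{post}_i - \text{pre}_i$ is modeled by ordinary least squares as

$$ \Delta_i = \beta_0 + \beta_1 [\text{evolving}]_i + \beta_2\,
\text{pre}_i + \text{cluster terms} + \varepsilon_i, $$

the ANCOVA change formulation: the baseline term absorbs
regression-to-the-mean, and the baseline clinical cluster enters as
categorical indicators because the degree of biological shift is expected
to differ across the baseline strata. Each pathway is adjusted for its own
baseline score; a multivariate baseline profile adjustment would add 200
covariates to 33 observations and is deliberately not implemented.
Clusters with a single patient are dropped from the adjustment with a
warning. Significance is $q < 0.05$ across pathways; no effect-size arm is
added here, mirroring the FDR-only convention of change analyses. A
degenerate fit (zero residual variance, as with noiseless input) reports
$\beta_1$ as computed, $p = 1$, and a flag. Classical standard errors are
used; the group term's null $p$-values are verified uniform by simulation.

Root-category enrichment of the change-associated pathways is a 2×2
chi-square of (root = target) × (significant), reported with both
proportions so the direction of "exceeds" is checkable, and flagged
degenerate (with $p = 1$) when a margin is empty.

# The synthetic cohort generator

Because the original cohort's raw data cannot ship with a package, every
claim above is exercised on a generator that emulates the study design:
16 controls with baseline samples only; 19 stable and 14 evolving patients
each with a baseline and a follow-up sample; 200 pathways of 8–60 genes
over a 4000-gene universe, with a synthetic hierarchy into 18 root
categories. Counts are negative binomial with mean
$\mu_{gs} = 2^{b_g + \delta_{gs}} L_s$: gene baseline log2 means
$b_g \sim \mathcal{N}(5, 2)$, log-normal library factors
$L_s \sim \text{logN}(0, 0.25)$, and a fixed dispersion of 0.2 — a
deliberate simplification over a gene-wise dispersion trend, chosen as the
simplest model that still exercises the robust statistics.

$\delta_{gs}$ carries the injected truth: a ±1 log2 shift on the genes of
20 *affected* pathways in every patient sample, and a ±1 log2 shift on the
genes of 15 *progression* pathways in the follow-up samples of evolving
patients only. Stable patients' follow-up samples are fresh draws from
their baseline distribution — biological stability plus sampling noise.
Signs alternate across pathways (shifts go both up and down, as real
differential pathways do) and are recorded in the truth record.

Two generator choices exist purely to keep the ground truth identifiable
under a competitive score. The effect-eligible pathways are drawn from a
reserved, mutually disjoint block of the gene universe, because a "null"
pathway sharing genes with an affected one would genuinely carry signal
and false-discovery proportions against the truth record would be
ill-defined. And the alternating signs are assigned by greedily balancing
the total number of up- versus down-shifted genes, because an unbalanced
shift displaces the within-sample ranks of *every* gene and leaks signal
into all 180 null pathways. Even balanced, a small residual coupling
remains — rank displacement cancels only on average across expression
strata — and this, not test miscalibration, is what an occasional
borderline false call on effect cohorts traces back to; on fully null
cohorts the dual-criterion caller is empirically silent.

All generation is deterministic given the spec: one Mersenne–Twister
stream per stage, seeded from the spec's seed, with the caller's RNG state
restored afterwards.

What the generator does not emulate — and what passing tests therefore do
not establish about real data: batch and globin-depletion artifacts,
gene-wise dispersion trends, correlated co-expression beyond shared
pathway membership, identifier aliasing, and any real biological pathway
structure. Recovery rates on this generator are statements about the
pipeline's statistics, not about scleroderma.

# Problem sizes and reproducibility

The packaged checks run the full design — 82 samples, 4000 genes, 200
pathways — for single-cohort analyses; calibration sweeps use 50 null
cohorts for the type-I property and 20 label permutations for the
classification null; pipeline determinism is asserted on a reduced cohort
(800 genes, 40 pathways), where two runs under one configuration must
reproduce every output file hash-identically. The nested-CV drivers in
`analysis/` use 5 outer runs; the machinery accepts the full 20. These
sizes are the package's own choices for its checks and scale up linearly.

# Known limitations

The competitive-score coupling described above is intrinsic to
set-vs-complement scoring, and on cohorts with many strong effects it can
nudge unaffected pathways past an FDR-only threshold; the dual criterion
protects the baseline analysis, while the change analysis relies on FDR
alone. The "official gene symbol" rule in the GMT reader is a syntactic
stand-in (a configurable regex; by default bare numeric tokens are
dropped) for a symbol authority the package deliberately does not bundle.
Gene identity is the case-sensitive symbol string — no aliasing. And the
single-dataset behavior of selection-inside-CV estimates discussed above
means a chance-level *point* estimate on one small cohort should be read
with its SD, not alone.
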