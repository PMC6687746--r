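---
title: "Identifying brain-behaviour modes of covariation with ccamodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying brain-behaviour modes of covariation with ccamodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccamodes)
```

## The problem and the model

Resting-state fMRI yields, for each subject, a functional connectome: the
matrix of Pearson correlations between the time-series of every pair of
brain regions. A 348-region parcellation gives 60378 unique connections per
subject. Alongside, each subject contributes hundreds of behavioural items —
questionnaire responses, IQ measures, demographics. The scientific question
is whether individual differences in the connectome and individual
differences in behaviour co-vary along a small number of latent axes.

Canonical correlation analysis (CCA) addresses this directly. Given a brain
view $X \in \mathbb{R}^{n \times p}$ and a behaviour view
$Y \in \mathbb{R}^{n \times q}$ over the same $n$ subjects, CCA finds pairs
of weight vectors $(u_k, v_k)$ maximizing
$\mathrm{cor}(X u_k, Y v_k)$, each pair uncorrelated with the preceding
ones within its view. Each pair — a *mode of covariation* — consists of the
canonical variates $P_X = X u_k$ and $P_Y = Y v_k$ (per-subject brain and
behaviour scores) and their canonical correlation $q_k$.

Because $p, q \gg n$ in connectome data, CCA cannot be applied directly:
both views are first reduced to $d$ principal components, and $d$ itself is
selected by the permutation procedure described below. Interpretation does
not use the weights (which live in PCA space and are notoriously unstable)
but *loadings*: the Pearson correlation of each original, preprocessed
variable with the corresponding canonical variate.

## The pipeline

`preprocessPipeline()` applies, in order:

1. **Motion exclusion.** Subjects with maximum framewise displacement (FD)
   strictly above 1.3 mm or mean FD strictly above 0.3 mm are removed.
   Values exactly at a threshold are retained. Subject exclusion runs before
   any variable-level step so that all later estimates use the analysed
   sample only.
2. **Near-constant filtering.** A behavioural item whose modal value
   accounts for strictly more than 95% of the *observed* (non-missing)
   entries is removed. The share is computed before imputation, matching the
   declared order of the two rules; imputation can only inflate a modal
   share, so filtering first is the conservative choice.
3. **Median imputation.** Missing behavioural entries are replaced by the
   per-item median of the observed values (even counts: mean of the two
   middle values).
4. **Confound regression.** Mean FD and one-hot scanner site are regressed
   out of every brain and behavioural variable by ordinary least squares.
   The design always contains an intercept, so the last one-hot column is
   dropped to keep it full rank; a remaining rank deficiency is an error
   rather than a silent repair. A degenerate column (single site, zero FD
   variance) is constant, already absorbed by the intercept, and is dropped
   with a note — with no informative confounds the pipeline gracefully
   reduces to filter + impute + standardize.
5. **Standardization.** Every variable is centred and scaled to unit sample
   standard deviation. A zero-variance column at this point indicates an
   upstream problem and errors.

After the pipeline every column of both views has mean 0 and SD 1, and is
exactly orthogonal to every confound column — OLS residuals are orthogonal
to the design by construction, so the planted site and motion effects of the
synthetic generator are removed *exactly*, not approximately.

Two further QC rules operate upstream of the bundle, at the
connectivity-construction stage: `computeConnectivity()` turns regional
time-series into full Pearson correlation matrices (a constant series is an
error naming the region), and `excludeLowSignalRegions()` drops any region
whose mean signal, z-scored across regions within a subject, falls strictly
below −1.96 in at least one subject. The z-score uses the sample (n−1)
standard deviation; a subject with zero signal variance across regions
contributes no exclusions and is logged. Connectivity values enter the
analysis as raw correlations; no Fisher z-transform is applied, matching
the full-correlation definition of the connectome used throughout.

### Hold-out replays

For hold-out validation the pipeline must be *fitted* on training subjects
and *replayed* on test subjects: `preprocessPipeline()` therefore returns a
parameter model (kept variables, training medians, confound coefficients,
centring and scaling), and `preprocessApply()` applies it to new subjects
without re-estimating anything. For the permutation workflow, which is an
in-sample procedure, confound coefficients are estimated on the full
analysis sample.

## Permutation inference and choosing d

For a candidate dimensionality $d$, both views are reduced once (PCA on the
unpermuted data) and the CCA is fitted, giving true correlations
$q_1 \ge \dots \ge q_d$. The rows of the reduced behaviour matrix are then
permuted uniformly and the CCA refitted, $N$ times. The FWE p-value of mode
$i$ compares $q_i$ against the null distribution of the *first* (largest)
permuted correlation:

$$p_i = \frac{1 + \#\{b : \max_k q^{*(b)}_k \ge q_i\}}{1 + N}.$$

This is the maximum-statistic construction: it controls family-wise error
across modes, makes the p-values non-decreasing in $i$ (so the significant
modes always form a prefix), and the smallest reportable value is
$1/(N+1)$ — at $N = 10000$ a zero-exceedance mode is displayed as
"< 0.0001" by `formatPermutationP()`. The add-one convention avoids zero
p-values. Permuting the reduced rows is equivalent to permuting the raw
behaviour rows before projection, because row permutation commutes with a
fixed linear map; computationally, each permutation costs one small SVD
because centring and QR-orthonormalization are also row-permutation
equivariant.

The dimensionality grid defaults to nine candidates,
$d \in \{5, 10, 25, 50, 75, 100, 125, 150, 200\}$, and each candidate's
first-mode p-value is Bonferroni-corrected over the grid
($0.05/9 \approx 0.0056$). The chosen $d$ is the significant candidate with
the lowest corrected p; ties go to the smaller $d$ (a deliberate
parsimony tie-break, relevant in practice because strong signals drive
several candidates to the $1/(N+1)$ floor). When nothing is significant the
result is a flagged "no significant mode", not an error.

## Multiple hold-out validation

`holdoutRun()` draws `nSplits = 10` random splits holding out
`testFraction = 0.2` of subjects, fits everything (preprocessing, PCA, CCA,
optionally the choice of $d$) on training subjects only, and projects test
subjects through the trained model. The out-of-sample statistic is the
correlation of the first pair of test variates; its permutation p-value
shuffles the test subjects' behaviour rows (one-sided, since training
orients the pair toward a positive training correlation). The omnibus rule
is Bonferroni over splits: the mode replicates if any split's p-value falls
below $\alpha/\text{nSplits}$. These defaults follow the structure of the
published multiple hold-out framework; the exact split counts and omnibus
rule of any particular study are configuration, and all of them are
arguments.

Two properties are enforced by tests rather than assumed: perturbing a
held-out subject leaves that split's trained model bit-identical (no
leakage), and training correlations exceed test correlations on average
(the overfitting direction).

## The synthetic generator

`generateDataset()` draws two views linked by $K$ planted modes:
$$x_i = \textstyle\sum_k a_{xk} w_{xk} z_{ik} + B_s^\top s_i + b_m f_i +
\sigma_x \varepsilon_i,$$
with shared latent scores $z_{ik} \sim N(0,1)$, orthonormal loading
directions (QR of a Gaussian matrix), a 3-level multinomial site $s_i$,
log-normal motion $f_i$ (median 0.1 mm, so motion QC rarely triggers at the
default thresholds), and isotropic Gaussian noise. Near-constant columns
(modal share ≈ 0.97) and completely-at-random missing entries are injected
into the behaviour view only. Under this model the population canonical
correlation has the closed form
$$\rho_k = \frac{a_{xk} a_{yk}}
{\sqrt{(a_{xk}^2 + \sigma_x^2)(a_{yk}^2 + \sigma_y^2)}},$$
which the test suite validates against an empirical CCA oracle on
$10^5$ generated subjects (tolerance 0.01).

Defaults mirror the shape of the motivating cohort where the pipeline
defines it — 306 subjects, a 372-item behaviour view with 8 near-constant
items (leaving 364 after filtering), three sites — and use 300 brain
variables with signal strengths $a = (1.5, 1.0)$ against unit noise, a
scale at which simulations stay fast while the estimator's sampling
behaviour is faithful. MCAR missingness is the right companion to median
imputation, which presumes no informative missingness; the orthonormal
loading directions are a simplification relative to the heavy dependence
among real connectome edges and are what makes the closed form exact.

What passing tests therefore show: the pipeline recovers planted linear
modes at realistic $n/p$ ratios, controls family-wise error under the
null, and removes additive confounds exactly. What they cannot show:
robustness to the non-Gaussian, dependent, nonlinearly confounded structure
of real connectomes.

## Numerical choices

- **PCA** is computed by SVD of the centred matrix; component signs are
  fixed by making each basis vector's largest-magnitude element positive,
  so results are reproducible across platforms.
- **CCA** is solved via the SVD of the whitened cross-covariance, realized
  through thin QR of each centred view ($Q_x^\top Q_y$), the numerically
  stable equivalent of the generalized-eigenvalue formulation; the test
  suite checks agreement with a directly solved generalized-eigenvalue
  oracle to $10^{-8}$. Rank deficiency is an error, correlations are
  clipped to $[0, 1]$ against roundoff, and variates are normalized to unit
  sample variance.
- **Mode signs** are arbitrary in CCA; `fitCca()` fixes them
  deterministically via the y-weights, and `orientModes()` re-orients each
  mode for reporting so that the behavioural variable with the largest
  absolute loading is positive ($u, P_X$ flip jointly with $v, P_Y$).
- **Symmetry tolerance** for connectivity matrices is an absolute
  $10^{-8}$; anything larger is an error, never silently averaged.
- **Fraction-to-count selection** rounds half away from zero
  ($0.005 \times 60378 = 301.89 \to 302$); ranking ties break
  lexicographically by variable id.
- Seeds: every stochastic routine takes an explicit integer seed and is
  bit-reproducible under it; derived seeds stay below $2^{31}$.

## Validation scale

The packaged checks run at deliberately modest sizes chosen to exercise the
estimators' sampling behaviour rather than to mimic full connectome
dimensions: oracle agreement on 50 instances at $n = 60$; planted-mode
recovery at $n = 300$, $p = q = 60$, $\rho = 0.6$ averaged over 20 seeds
(expected within $\pm 0.1$ — out-of-sample attenuation from estimating
directions at these $n/p$ ratios is real and visible, which is exactly what
the hold-out framework is designed to quantify); family-wise error over 200
null datasets at $n = 120$, $p = q = 40$, $d = 5$ with 200 permutations
each; and byte-level determinism of a full rerun.

## Known limitations

- Permutations are uniform row shuffles; exchangeability blocks (family or
  site structure) are not implemented.
- Sparse or regularized CCA variants are out of scope, as are ICA- or
  partial-correlation-based connectivity definitions.
- The loading-based interpretation inherits the usual caveat that
  structure coefficients do not imply conditional importance.
- Reading neuroimaging file formats is out of scope: the pipeline starts
  at regional time-series or connectivity values in delimited text.
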