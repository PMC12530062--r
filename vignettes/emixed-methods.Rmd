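---
title: "EMixed: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMixed: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EMixed)
```

EMixed estimates the cell-type composition $\theta_n$ of bulk tissue
samples from two molecular layers — RNA-seq counts and DNA methylation —
under a shared modelling idea: every sequenced unit (an RNA read, a DNA
molecule) originates from one cell, and that cell's type is a draw from
$\theta_n$. This vignette documents the two models, the estimation
procedure, every tunable parameter, what the bundled simulator does and
does not emulate, and the design decisions taken where more than one
reasonable choice existed.

## The RNA allocation model

For sample $n$ with sequencing depth $R_n$, each read draws a cell type
$Z_{rn} \sim \mathrm{Multinomial}(1, \theta_n)$ and then a gene from the
type-specific emission column $A_{\cdot k}$ of the profile matrix $A$
($I$ genes $\times$ $K$ types, each column a probability distribution
over genes). Only gene totals $X_{in}$ are observed. Summing reads per
gene, the latent per-gene allocations are multinomial given $X$, which
yields closed forms for both EM steps:

$$\psi_{in,k} = X_{in}\,\frac{A_{ik}\theta_{nk}}{\sum_{k'}A_{ik'}\theta_{nk'}},
\qquad
\hat\theta_{nk} = \frac{\sum_i \psi_{in,k}}{\sum_i\sum_k \psi_{in,k}}.$$

The observed-data log-likelihood (up to a $\theta$-free constant) is
$\ell(\theta) = \sum_i X_{in}\log(A_{i\cdot}\theta)$, a sum of logs of
affine functions of $\theta$ — concave on the simplex. Consequences we
rely on: the EM iteration is monotone in $\ell$, the maximizer is unique
up to flat directions, and initialization cannot change the answer. We
initialize at the uniform vector $1/K$ as the neutral choice and expose
no initialization knob.

`fit_rna()` collapses the two steps into the equivalent multiplicative
update $\theta \leftarrow \theta \odot A^\top\!\big(x / (A\theta)\big) /
R_n$, which avoids materializing $\psi$ ($I \times K$ per iteration);
`rna_e_step()` / `rna_m_step()` expose the textbook forms, and the test
suite checks the two routes agree.

### Transcript fractions versus cell fractions

$\theta_n$ as fitted is the share of *transcripts* per cell type. Cell
types differ in RNA content per cell, captured by the cell-size vector
$S \in \mathbb{R}_+^K$ (average transcripts per cell, estimable from
per-type average library sizes; only ratios matter). Cell fractions are

$$\theta^{cell}_{nk} = \frac{\theta_{nk}/S_k}{\sum_{k'}\theta_{nk'}/S_{k'}}.$$

This is a deterministic bijection of the converged $\theta_n$ and does
not enter the E/M updates, so we apply it once after convergence;
applying it inside the loop would produce the identical final
$\theta^{cell}$ while conflating the two scales in intermediate output.
Both matrices are reported.

## The methylation allocation model

Each DNA molecule $d$ covering locus $g$ draws its type
$M_{ngd} \sim \mathrm{Multinomial}(1, \theta_n)$ and a methylation status
$y_{ngd} \sim \mathrm{Bernoulli}(\pi_{g\delta})$, with $\pi_{gk}$ the
known signature methylation probability of type $k$ at locus $g$. The
E-step conditions on the observed status, splitting methylated and
unmethylated molecules separately:

$$\psi_{gk,1} = \frac{\theta_k \pi_{gk}}{\sum_i \theta_i \pi_{gi}},\qquad
  \psi_{gk,0} = \frac{\theta_k (1-\pi_{gk})}{\sum_i \theta_i (1-\pi_{gi})},$$

and the M-step pools them weighted by methylated count $m_g$ and
unmethylated count $D_g - m_g$. When coverage $D$ is a large constant
across loci, dividing numerator and denominator by $D$ leaves only the
methylated fraction — the array beta value — so the array update is the
same formula with weights $\beta_g$ and $1-\beta_g$. The package keeps
both code paths and tests that they produce *identical iterates* when fed
consistent inputs; the array path is exact for constant coverage and an
approximation otherwise (the simulator's Poisson-coverage option exists
to probe that approximation).

The DNAm $\theta$ is a molecule-level fraction. Since every cell carries
essentially the same number of DNA copies, molecule fractions are already
cell fractions: no size correction is applied on this modality.

Two modelling decisions that the formulas alone do not settle:

- **$\pi$ is fixed and known.** The signature enters the E-step at every
  iteration but receives no M-step update: re-estimating a reference from
  the bulk being deconvolved is poorly identified and easily degenerate,
  so the signature is treated as data, not parameter.
- **Zero-coverage loci are skipped per sample**, not imputed: they
  contribute zero weight to both M-step sums, which the implementation
  realizes by dropping them; the tests verify the fit equals the fit on
  the reduced locus set exactly.

### Joint quantile normalization

Array betas and reference signatures often come from different platforms
with different intensity distributions. Before fitting array data the
package pools the $K$ signature columns with the $N$ bulk columns and
quantile-normalizes all $K+N$ columns together: each value is replaced by
the mean of the pooled order statistics at its rank, ties receiving the
mean of the quantiles they span (delegated to
`limma::normalizeQuantiles(ties = TRUE)`), after which values are
re-clipped to $[0,1]$. This is applied only in array mode (sequencing
counts are on a common scale already) and is switchable off
(`quantile_norm = FALSE`), since forcing a common distribution is a
heuristic: it stabilizes platform mismatch but distorts a signature that
was already on the bulk scale.

## Tunable parameters

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `tol` | `1e-6` | max-norm change in $\theta$ per iteration | fraction changes below 1e-6 are far under any biological resolution |
| `max_iter` | `1000` | iterations | generous for the multiplicative update's linear convergence; hitting it flags, never errors |
| `epsilon` | `1e-6` | probability | clips $\pi$ into $[\epsilon, 1-\epsilon]$; signatures routinely contain exact 0/1, which would zero an E-step denominator |
| `quantile_norm` | `TRUE` | flag | see above; array mode only |
| `weight` (integration) | `0.5` | share on RNA | equal weighting; data-driven weights are deliberately not fitted |

## Multi-omics integration

Both layers of a sample share one true composition, so the integrated
estimate is the mean of the RNA-derived (cell-size-adjusted) and
DNAm-derived fractions per sample, renormalized over the shared cell
types. Averaging $\theta^{cell}$ rather than the transcript fraction is
deliberate: the DNAm estimate lives on the cell scale, and averaging
mixed scales would bias toward large-celled types
(`use_cell_fractions = FALSE` switches this). Renormalization only
matters when the two modality estimates cover different type sets — with
identical sets the mean of two simplex vectors is already a simplex.
Samples present in one modality keep that modality's estimate, flagged in
the output. A `weight` argument exists but defaults to the plain average;
learning weights from data is out of scope by design.

## Evaluation metrics

Lin's concordance correlation coefficient is implemented with
*population* ($1/n$) moments, matching its original definition:
$\mathrm{CCC} = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$.
Implementations using $1/(n-1)$ moments give identical values (the factor
cancels) except through the uncancelled mean-difference term; we document
the choice so the constant-offset case reconciles. CCC, unlike Pearson
correlation, is not invariant to location or scale shifts of one input —
that sensitivity is the reason it is used to compare fraction estimates,
which must agree in value, not merely co-vary. MAE is on the fraction
scale; Spearman uses average ranks for ties via `stats::cor`.

## The simulator

`simulate_dataset()` draws, per dataset: $\theta_n \sim
\mathrm{Dirichlet}(\alpha\mathbf{1})$; an RNA reference with a shared
Gamma baseline per gene and $I/K$ marker genes per type elevated
`marker_strength`-fold; a methylation signature with $G/K$ marker loci
per type drawn $\mathrm{Beta}(0.3, 0.3)$ (bimodal near 0/1, as CpG
methylation is) against a near-0.5 baseline for the other types; then
bulk RNA counts $X_{\cdot n} \sim \mathrm{Multinomial}(R_n,
A\tilde\theta_n)$ with $\tilde\theta \propto \theta S$ (so the cell-size
correction is exercised end to end) and methylated counts
$m_{gn} \sim \mathrm{Binomial}(D_{gn}, \pi_{g\cdot}\theta_n)$ — the exact
marginals of the generative models above. A molecule-by-molecule sampling
path is retained as a slow reference implementation, and a
goodness-of-fit test checks the two paths agree in law.

What it emulates: sampling noise at realistic depth and coverage, cell
size asymmetry, informative-marker structure, platform-style reference
mismatch (truncated Gaussian perturbations of $A$ and $\pi$, applied to
the estimator's copy while bulk data come from the clean reference), and
variable coverage.

What it does **not** emulate, hence what passing tests do not show about
real data: batch and probe effects beyond a global distribution shift,
correlated (rather than independent) reference errors across features,
within-type expression heterogeneity and condition-dependent reference
shifts, missing cell types in the reference, and array measurement error
beyond binomial-like noise. Recovery numbers on simulated data are
therefore best-case; the reference-noise scenario is the simulator's
closest analogue to real mismatch.

### The reference-noise stress level

The multi-omics checks use `noise_rna = 3.0` (sd in units of the mean
reference entry, truncated at 0) and `noise_dnam = 0.2` (sd on the
probability scale, clamped to $[0,1]$). The calibration principle:
degrade both modalities to a comparable, moderate accuracy, because the
integration average is informative exactly when neither modality
dominates — with one modality near-perfect the average can only dilute
it, and with both near-perfect there is nothing to integrate. These
levels leave each single modality clearly degraded but well above chance
on the scenario's mixtures, with errors independent across modalities.

## Numerical choices and degenerate inputs

- **No pseudocounts on $A$.** A gene with observed reads but zero
  reference mass across all types under the current $\theta$ is an error
  naming the gene — it signals a reference/bulk mismatch the user must
  see, and silent clipping would hide it. ($\pi$ is clipped instead
  because 0/1 entries there are legitimate biology colliding with a
  division, not a mismatch.)
- **Feature matching is exact-string intersection**, kept in reference
  order, with dropped counts logged; profile columns are renormalized on
  the shared set so the column-stochastic invariant holds on the features
  actually used. No alias resolution: symbol maps are reference-specific.
- **Missing values** (NA cells) drop the feature row with a logged count;
  the EM has no missing-data mechanism, and imputing references is out of
  scope.
- **All-identical reference columns** make every $\theta$ a fixed point
  (flat likelihood); detected and warned, not errored, since near-flat
  references are a continuum.
- **Convergence** is declared on the max-norm change of $\theta$, not the
  log-likelihood, because fraction scale is what users interpret; the
  log-likelihood trace is stored for diagnostics and the monotonicity
  guarantee is asserted in tests with slack 1e-8 for float error.
- **Ties in quantile normalization** get the mean of their spanned
  quantiles — the single canonical variant — so normalization is
  permutation-equivariant and idempotent on identical-multiset columns.
- **Samples are fitted independently**; results are identical under any
  sample ordering (tested).

## Problem sizes used by the test suite

The suite exercises, among smaller cases: RNA recovery with $K=3$,
$I=200$ genes, $N=50$ samples at depth $10^5$ with non-uniform cell
sizes; DNAm recovery with $G=500$ loci at coverage $10$–$1000$;
exhaustive grid searches at step $10^{-4}$ against the EM optimum for
$K=2$; 100 random EM instances per modality for the monotonicity
property; and 20 replicates of the matched multi-omics noise scenario
($N=20$ each). These sizes are chosen to make sampling error a
second-order concern for each assertion while keeping the full suite in
tens of seconds.

## Known limitations

- Accuracy is bounded by reference quality; the method estimates
  fractions of the types the reference contains and silently absorbs
  unrepresented types into the nearest represented ones.
- The array M-step assumes approximately constant coverage; heavily
  locus-dependent coverage belongs in sequencing mode.
- The integration is a fixed average: it cannot down-weight a modality
  that is systematically wrong, only dilute it.
- Cell sizes $S$ are taken as given (or from library sizes); errors in
  $S$ propagate directly into $\theta^{cell}$.
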