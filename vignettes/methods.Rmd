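---
title: "Methods: rate–body-size association across a carnivoran phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rate–body-size association across a carnivoran phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carnsize)
```

carnsize tests whether a gene's molecular evolutionary rate tracks body
size across a clade of species. This vignette is the package's own account
of the statistical machinery: the model each stage fits, the assumptions
it leans on, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data tests do and do not establish about
real data.

## The rate statistic: root-to-tip ω

The per-gene input is a table of per-branch estimates of dN (non-synonymous
substitutions per site), dS (synonymous substitutions per site) and their
ratio ω = dN/dS, as produced upstream by a free-ratio codon model. For each
species, the package averages ω over the branches on the path from the root
to that species' tip:

$$\bar{\omega}_i \;=\; \frac{1}{|P_i^{\text{valid}}|} \sum_{b \in P_i^{\text{valid}}} \omega_b ,$$

an unweighted arithmetic mean, and then takes log10 to improve normality
for regression. A branch enters the average only when both dN ≥ 2×10⁻⁴ and
dS ≥ 2×10⁻⁴ ("less than" the threshold is excluded, the boundary is kept):
at lower divergence the ratio is numerically unstable, and a single branch
with dS ≈ 0 can send ω to the hundreds and dominate the whole path. Invalid
branches are dropped individually rather than invalidating the species;
only a species whose path has *no* valid branch becomes `NA` and is
excluded from regression. A branch absent from the table is treated as
invalid. The mean is unweighted — no branch-length weighting, no pooling of
dN and dS sums — because the statistic is meant to give every evolutionary
episode on the lineage equal voice; root-to-tip averaging makes the value
cumulative over the lineage's history, which is what makes it comparable
against a present-day phenotype.

## The regression: PGLS with Pagel's λ

Species values are not independent observations: close relatives inherit
both their rates and their phenotypes from recent common ancestors.
The package therefore fits, per gene and per phenotype,

$$\log_{10}\bar{\omega}_i = \beta_0 + \beta_1 \log_{10} x_i + \varepsilon,
\qquad \varepsilon \sim N\!\left(0,\; \sigma^2 V(\lambda)\right),$$

where $x_i$ is body mass (g) or head–body length (cm) and $V(\lambda)$ is
the Brownian-motion covariance of the species used — $C_{ij}$ = shared
root-to-MRCA path length — with off-diagonal entries multiplied by Pagel's
λ ∈ [0, 1]. λ = 1 is pure Brownian structure, λ = 0 independent species;
intermediate values attenuate the phylogenetic correlation. λ is estimated
per gene by maximizing the profile log-likelihood (coefficients and σ²
profiled out in closed form; ML, not REML). Slope inference uses the usual
GLS t-test: σ̂² with the n − 2 divisor, t = β̂₁/SE, two-sided p on n − 2
degrees of freedom.

Numerical choices:

* The profile likelihood in λ can be flat or multi-modal near the
  boundaries, so the maximizer is located by a coarse grid (step 0.05)
  followed by bounded scalar refinement (`optimize`, tolerance 10⁻⁶) around
  the best grid point, snapping to 0 or 1 when within tolerance of a
  boundary.
* Fits are computed by Cholesky whitening, never by forming V⁻¹; the
  explicit-inverse formula survives only as an independent oracle in the
  test suite.
* The covariance is rebuilt on exactly the species used in each fit —
  including every leave-one-out refit — so missing species never distort
  the correlation structure.
* Both phenotypes are log10-transformed, matching the transform of the
  response.
* A gene needs at least `min_species` (default 10) species with defined
  values to be fit at all; regression on fewer points is too unstable to
  interpret. Trees that are only approximately ultrametric are accepted
  with a warning, since time-calibrated trees exported from dating
  resources routinely carry rounding error.

## The decision rule: two-step calibration and BSAGs

Instead of a multiple-testing correction across genes, each candidate is
stress-tested for dependence on single species:

* **P.all** — the PGLS p-value over all usable species;
* **P.robust** — the p-value after refitting without the species with the
  largest absolute residual of the full fit;
* **P.max** — the *maximum* p-value over refits that each drop one species.

A gene is a body-size-associated gene (BSAG) when all three values fall
below α = 0.05 for *both* phenotypes — six thresholds in total. Its
direction (positive/negative) is the sign of the body-mass slope; when the
two phenotype slopes disagree the record is flagged discordant rather than
silently dropped. P.max is the teeth of the procedure: a signal carried by
one influential species cannot survive the refit that removes that species.
Note that high-leverage species typically have *small* residuals, so the
P.robust step alone would not catch them — the leave-one-out family is what
makes the calibration robust.

Two readings of the leave-one-out step are defensible: dropping each
species from the full set (default, `drop-from-full`) or from the already
reduced robust set (`drop-from-robust`, fits of size n − 2). Both are
implemented; the default is the plainer reading and is what all reported
numbers use. Similarly, "largest residual" defaults to the raw scale, with
covariance-whitened residuals available behind an option.

## REGs: branch-model likelihood-ratio records

Whether a gene evolved faster in a designated foreground group (here:
small-bodied species, mass < 12 kg and length < 1 m, or extremely large
species, mass > 350 kg; extremely small species, mass < 1 kg, form a
focal subset of the small group) is judged from upstream codon-model fits:
a two-ratio model with separate foreground/background ω against a
one-ratio null. The package consumes the two log-likelihoods,
forms 2Δ lnL against χ² (df = 1 by default, the one extra ω; overridable
via free-parameter columns), applies Benjamini–Hochberg FDR within each
foreground group separately (the two groups are separate hypothesis
families with separately reported lists), and calls a rapidly evolving
gene (REG) when the foreground ω exceeds the background ω with raw
p < 0.05 — with a second, stricter flag for records that also survive FDR.
Optimizer noise can leave lnL₁ a hair below lnL₀; differences within 10⁻⁶
are clamped to zero, anything larger is treated as a failed upstream
optimization and rejected.

## Fixed amino acid changes

Columns of a protein alignment where a focal body-size group is fixed for
one residue and the other carnivores carry a different one are candidate
molecular correlates of the phenotype. The default `strict` mode requires
the background to be uniform as well — the pattern behind substitution
labels like "S513L" — because "consistently different" read loosely would
admit polymorphic background columns; the `relaxed` mode (focal fixed,
focal residue absent from the background) is retained for that reading.
Columns with a gap in any scanned row are excluded, and `X`/`*` are
treated like gaps: an ambiguous column cannot certify fixation. Rows
outside the focal and background sets — outgroups, reference sequences —
are ignored by the scan. Reported positions are mapped to ungapped
reference (human) coordinates by counting non-gap reference characters up
to the column, 1-based, so labels match human protein numbering; domain
intervals, supplied as input in those coordinates, annotate covered sites.

## The synthetic-data generator

The generator is the package's instrument for validating the analysis, and
its defaults are the study conditions all reported numbers refer to: 20
species on a unit-height Yule chronogram; log10 body mass by Brownian
motion from a 10-kg root state (rate 1 per unit height, giving roughly the
two-orders-of-magnitude mass spread of a real carnivore panel); log10
head–body length as ⅓·log10 mass + ⅔ (geometric similarity through 100 cm
at 10 kg) plus independent Brownian noise (rate 0.01); per-gene tip-level
log10 root-to-tip ω linear in log10 mass (planted slope 0.4 for effect
genes, 0 for nulls, baseline −0.7 at the mean mass ≈ ω 0.2) with residuals
drawn from σ² = 0.09 times the λ = 0.9 transformed covariance; per-branch
dS log-normal with median 0.05; 30 effect and 170 null genes.

Tip-level targets must be realized as *branch-level* ω, and that inverse
problem is under-determined (more branches than tips) and sign-indefinite.
The package solves it by box-constrained minimum-norm least squares on the
path-incidence system: expand around a per-branch baseline (the mean
target of the tips descending through the branch), apply the
pseudoinverse correction, and repair any bound violations by freezing them
at the bound and re-solving over the free branches. The working box
[0.02, 10] matters: an unconstrained minimum-norm solution routinely
drives a fifth of the branches negative, and clipping those to a tiny
positive value silently pushes them below the dN validity threshold, so
they drop out of the path average and the achieved tip means no longer
resemble the targets (in development this attenuated planted slopes by
half). With the box, dS additionally floored at 0.011 so dN = ω·dS stays
observable, every branch not deliberately forced sub-threshold passes the
validity rule, and the achieved tip means — recomputed from the final
table and stored as the ground truth that recovery tests are held to —
coincide with the targets. A configurable fraction of branches (default
5%) is forced below the dS threshold to exercise the outlier rule.

Alignment fixtures are a random consensus protein with independent
per-cell substitution noise (rate 0.05), planted focal/background residues
at chosen columns, and gap characters in single random rows; LRT fixtures
draw 2Δ lnL from central (null) or noncentral (alternative,
noncentrality 10) χ²₁ with the foreground made faster only under the
alternative. Every generator is reproducible bit-for-bit under a fixed
seed.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: estimation noise in the per-branch ω
values themselves (real codeml output carries substantial sampling error,
which attenuates regressions), correlated rates across genes, alignment
error, selection heterogeneity along a branch, non-Brownian trait
evolution, and phenotype measurement error. Results on this generator
certify the *procedure*, not the biology.

## Measured behaviour

Problem sizes here are the package's validation design: 500 replicates for
λ recovery and type-I rates, 200 genes for slope recovery, 2,000 draws for
distributional checks — large enough that Monte Carlo error is small
against the margins tested, small enough to run routinely. At these sizes
(one CPU, a few minutes; `scripts/acceptance.R` recomputes all of them
from scratch):

* GLS estimates match an explicit-inverse oracle to ~10⁻¹⁴; BH-FDR matches
  the step-up definition exactly; root-to-tip ω matches naive path
  enumeration exactly.
* λ recovery: mean λ̂ ≈ 0.92 under pure Brownian signal, ≈ 0.05 under
  independent noise (fresh 20-tip tree per replicate — conditioning on a
  single topology makes the mean hostage to tree-shape luck).
* Planted slopes (β = 0.4) are recovered with |bias| < 0.02 through the
  full rate pipeline.
* The full two-step calibration is *conservative*: type-I proportion ≈
  0.02 at nominal α = 0.05 under the null.

## Known limitations

* **Per-gene ML estimation of λ inflates the raw PGLS type-I error.** At
  n = 20 species the p-value of the slope t-test ignores the uncertainty
  in λ̂; measured over nulls, `p_all` < 0.05 occurs for 8–12% of genes
  rather than 5%. This is a known small-sample property of PGLS with
  estimated λ, not an implementation defect — with the covariance held at
  its true value, the same fit's p-values are exactly uniform, and the
  test suite asserts precisely that contrast. The two-step calibration
  absorbs the inflation (measured joint rate ≈ 0.02), which is the
  operational justification for using it instead of a per-gene correction;
  `p_all` alone should not be treated as calibrated.
* λ̂ itself is biased toward the interior at small n (mean ≈ 0.92 under
  λ = 1); per-gene λ estimates on 20 species are noisy and should be read
  qualitatively.
* The direction of a BSAG follows the body-mass slope by convention; with
  discordant phenotype slopes (flagged, not dropped) the label is a
  tie-break, not an inference.
* The package never estimates codon models: dN/dS tables and
  log-likelihood pairs are inputs, and their quality bounds everything
  downstream.
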