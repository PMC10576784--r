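---
title: "Methods: reproducibility of relative binding free energies and graph-based benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reproducibility of relative binding free energies and graph-based benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepbench)
```

## The problem

Alchemical free energy methods predict the *relative* binding free energy
ΔΔG between two structurally related ligands of the same protein. Judging
how good such predictions are requires knowing how reproducible the
experimental numbers themselves are: two competent assays measuring the
same compounds rarely agree perfectly, and the disagreement sets a floor on
the error any prediction method can meaningfully beat. `fepbench`
implements both halves of that comparison:

1. an **experimental reproducibility survey**: pair up assays that measured
   the same congeneric series, convert affinities to free energies, and
   quantify their agreement; and
2. a **prediction benchmark**: take a perturbation graph of edge ΔΔG
   predictions, infer a consistent set of per-ligand ΔG values, and score
   them against experiment with the same metrics.

## From affinities to free energies

For a measured affinity X (a Kd, Ki or IC50, in molar units),

- absolute: ΔG = kT · ln X, with k = 1.9872×10⁻³ kcal·mol⁻¹·K⁻¹ and
  T = 300 K by default (`thermo_constants()`); both are configurable, but
  every published conversion the package reproduces (0.41, 0.95, 0.77
  kcal·mol⁻¹ from 0.3, 0.69, 0.56 pKi units) assumes 300 K.
- relative: ΔΔG_ab = −kT · ln(X_b / X_a), so that ΔΔG_ab = ΔG_a − ΔG_b.

The ratio assumption — IC50, Ki and Kd *ratios* within one assay agree —
holds for a wide range of inhibitory mechanisms and is what makes
functional IC50 data usable for relative free energies without a
Cheng–Prusoff correction (deliberately out of scope). IC50-derived ΔG
values carry an unknown additive constant per assay; every metric in the
package is offset-invariant, so this constant is harmless for relative and
rank comparisons, and the sign convention itself cancels in all
symmetrized quantities.

One pKi unit is ln(10)·kT ≈ 1.37 kcal·mol⁻¹ at 300 K (`pki_to_kcal()`).
If per-compound ΔG errors are unbiased, Gaussian and independent, a
difference of two such values has √2 times their standard deviation:
`abs_rmse_to_pairwise_rmse()` implements that propagation.

### The √2 law, precisely

A point worth spelling out because it is easy to mis-state: let d_i be the
per-compound difference between two assays' ΔG values, with sd σ_d. The
pairwise error for a compound pair (i, j) is d_i − d_j, whose sd is
√2·σ_d. That is the √2 law the tests embody: noise of sd σ on **one**
assay against a noiseless reference gives σ_d = σ and pairwise
RMSE → √2·σ. If instead **both** assays carry independent noise of sd σ,
then σ_d = √2·σ and the pairwise RMSE converges to 2σ — the √2 law applied
twice. Both limits are asserted in the test suite (σ = 0.6, N = 2000:
0.8485 and 1.2 kcal·mol⁻¹ respectively).

## Graph-consistent ΔG inference

A perturbation graph rarely simulates all N(N−1)/2 ligand pairs; edge
predictions also need not be mutually consistent (the ΔΔG sum around a
cycle need not vanish). `infer_node_dgs()` resolves this by weighted least
squares: it minimizes

> Σ_edges w_e (ΔG_a − ΔG_b − ΔΔG_pred,e)²

which is the normal-equations formulation of cycle closure. Several
algorithms exist for constructing cycle-consistent ΔΔG sets; weighted
least squares on the graph is adopted here because it is exactly the
minimum-variance linear estimator under independent Gaussian edge errors
and uses nothing proprietary. Design choices:

- **Gauge fixing.** Only differences are observable, so ΔG is defined up
  to a constant. We report the mean-centered solution (the minimum-norm
  least-squares solution obtained from the pseudo-inverse of the weighted
  graph Laplacian), which is symmetric under node relabeling, rather than
  pinning an arbitrary reference node.
- **Weights.** 1/SE² when *every* edge reports a positive standard error;
  otherwise unit weights, with a warning if SEs were present on only some
  edges — silently mixing weighted and unweighted edges would let the
  reported-SE scale leak into the solution.
- **Duplicate edges** are independent repeat observations and accumulate
  weight; they are not pre-averaged.
- **Node SEs** come from the diagonal of the pseudo-inverse; with unit
  weights the residual variance is estimated from the cycle residuals with
  m − (n − 1) degrees of freedom, so a tree (or a perfectly consistent
  graph) reports zero.
- **Connectivity** is checked up front; a disconnected graph is an error
  listing its components, because ΔG values in different components share
  no gauge.

Fitted edge values `consistent_edge_ddgs()` are potential differences, so
their signed sum around every cycle is zero to machine precision. Pairwise
metrics are computed from the inferred node ΔGs; edgewise metrics always
use the raw edge predictions (whether published edgewise errors used raw
or corrected edges is ambiguous; raw is the conservative, topology-honest
choice). For display against experiment, `align_offset()` fixes the
constant by matching means — this changes no relative or rank metric.

## Metrics and aggregation

Per comparison (assay pair or graph): pairwise RMSE and MUE over all
N(N−1)/2 pairs, squared Pearson correlation R², and Kendall τ-b.
R² is the squared correlation rather than agreement with the identity
line because inter-assay offsets are explicitly irrelevant for rank
ordering; τ-b corrects for the ties that assay-precision rounding
produces. Correlations require at least 3 compounds and defined variance.

Across M comparisons, RMSEs aggregate as a weighted quadratic mean,
RMSE = √(Σ wᵢ RMSEᵢ² / Σ wᵢ), with weights equal to compound counts
(pairwise) or edge counts (edgewise). MUE, R² and τ aggregate with the
linear weighted mean — the quadratic form is specific to RMSE. The
aggregate therefore recomposes exactly over any partition of the
comparisons, a property the tests assert.

**Uncertainty.** 95% intervals are percentile bootstrap over whole
comparisons (the comparison's weight travels with it); resampling
individual compounds would ignore the strong within-series correlation of
pairwise errors. Default 10,000 replicates; the seed is a required
argument everywhere randomness occurs. At small M the percentile interval
can exclude the point estimate and is known to undercover mildly; the test
suite measures 93% empirical coverage at M = 20 over 500 fixed-seed
replications (n_boot = 2000 in that experiment to keep the suite fast).

## The error distribution

Pairwise errors over unordered pairs have an arbitrary overall sign, so
distributional analysis uses the symmetrized sample (each error and its
negation — all N(N−1) ordered pairs). Symmetrization forces mean zero and
leaves every even moment, the RMSE and the MUE unchanged.

`fit_t_errors()` fits a scaled Student-t by maximum likelihood with the
location **fixed at 0** — a free location is redundant on symmetrized data
and makes the likelihood surface needlessly flat — and the scale free. The
optimizer works on (log scale, log df) with L-BFGS-B, initialized from the
sample excess kurtosis (k = 6/(ν−4) for a t). The df estimate is capped at
1000 and flagged "effectively Gaussian" above 100, since beyond that the
likelihood is flat in ν. Small ν means fat tails: experimental
reproducibility errors are distinctly heavier-tailed than Gaussian, which
matters when deciding whether a large apparent prediction error is
evidence of a modeling failure or merely an experimental outlier.
`gaussian_expected_within()` / `t_expected_within()` give the model-implied
fractions inside a threshold for comparison with the observed
`fraction_within()`. Histogram export uses 0.25 kcal·mol⁻¹ bins centered
on zero (a presentation choice; no inferential weight).

## Survey pipeline and censoring

`compare_assays()` chains: inner-join compounds → censor → ΔG per assay →
pairwise metrics. Detection-limit censoring is described in the source
data only visually (values stacked in vertical or horizontal lines at an
assay limit), so it is formalized here as a policy:

- `qualifier_only` — drop pairs where either measurement carries a
  `lt`/`gt` qualifier;
- `qualifier_plus_plateau` — additionally drop pairs sitting at an assay's
  min or max when at least `plateau_k` (default 3) compounds share that
  extreme value, catching unflagged limit plateaus.

Every removal is logged with a reason; censoring can only reduce the pair
count. Assays are categorized `binding` or `functional`; the comparison
category (`binding vs binding`, `binding vs functional`,
`functional vs functional`) is order-independent. When one target was
measured by more than two assays, every unordered assay pair is a separate
comparison — an assumption, since the enumeration rule is not stated in
the source material. Mixed measure types across the two assays are allowed
(pairwise metrics are offset-invariant); absolute-scale output is
meaningless in that case and not produced. `repeatability_rms()`
summarizes reported repeat-measurement SDs as their RMS with a bootstrap
over assay groups, composing with the √2 propagation to give the
repeatability contribution to cross-assay RMSE.

## Synthetic data: what it does and does not emulate

`simulate_assay_pair()` draws true ΔGs once (uniform over a 5 kcal·mol⁻¹
span by default — a typical congeneric-series dynamic range, and
correlation metrics are sensitive to it — centered at −10 kcal·mol⁻¹,
about 50 nM, so back-transformed concentrations are realistic), then per
assay adds a systematic offset plus Gaussian or Student-t noise **on the
ΔG scale** (log-concentration noise, consistent with errors quoted in pKi
units), back-transforms via X = exp(ΔG/kT), and clamps values beyond the
configured concentration limits to the limit with an `lt`/`gt` qualifier —
clamped-and-flagged rather than dropped, so the censoring filter has
realistic work to do. `simulate_graph()` builds a random spanning tree
plus cycle chords with Gaussian edge noise. All randomness flows from one
seeded generator per call; identical config and seed give bit-identical
output.

The generators reproduce the statistical structure the analysis assumes:
shared truth, additive offsets, heavy or light noise, detection limits,
cycle redundancy. They do **not** emulate compound-series curation,
correlated errors between compounds (e.g. shared reference-compound
normalization), assay-specific nonlinearities, or any chemistry. Passing
tests on synthetic data therefore validate the *statistical machinery* —
estimator correctness, invariances, convergence — not the field behavior
of any particular assay technology.

## Numerical choices and problem sizes

- Laplacian pseudo-inverse via `MASS::ginv` (SVD-based); exact mean
  re-centering applied after solving to remove roundoff drift.
- t-MLE convergence failures raise an error with the optimizer code; the
  tests include a 21×21 grid-search oracle around the optimum.
- Tests use N = 2000 compounds for the √2-law checks (sampling error
  ≈ 2–3%), 50,000 symmetrized draws for t-recovery (ν̂ within ±10% of 6),
  500×(M = 20) replications for bootstrap coverage, and 50 seeds for the
  cycle-redundancy variance-reduction property. These sizes give stable
  assertions while keeping the full suite around 20 seconds.
- Report tables round to 2 decimal places in kcal·mol⁻¹; JSON exports keep
  full precision.

## Known limitations

- Weighted least squares is one of several cycle-closure constructions;
  estimators that robustify against gross edge outliers would differ on
  badly inconsistent graphs.
- The percentile bootstrap is mildly anticonservative at small M; BCa
  intervals were not implemented because the aggregate statistics are
  smooth and the source analyses used plain percentile intervals.
- The plateau censoring heuristic keys on exact value equality; limits
  reported with jitter would need a tolerance.
- No absolute-ΔG accuracy metrics across assays: systematic inter-assay
  offsets make them uninterpretable, which is precisely why the package
  works on relative quantities.
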