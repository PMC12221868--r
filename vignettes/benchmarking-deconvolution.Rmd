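---
title: "Benchmarking cell-type deconvolution with deconbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking cell-type deconvolution with deconbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deconbench)
```

## The problem

Reference-based deconvolution estimates the cell-type composition of a bulk
expression sample from a signature matrix of per-type expected expression,
under the linear model $y = Sw + \varepsilon$ with $w$ on the probability
simplex. Benchmarking such methods requires three ingredients that this
package standardizes: mixtures with *known* ground truth, noise that
resembles real count data, and a metric suite that exposes complementary
failure modes. This vignette explains the models behind each ingredient,
the parameters that matter, and the design decisions taken where more than
one reasonable choice existed.

## Simulating mixtures with known truth

Ground-truth proportions come from three generators. The
normalized-uniform generator (`gen_proportions_uniform()`) divides iid
$U(0,1)$ draws by their sum — the scheme used by training-data pipelines
that sample proportions without prior knowledge. The Dirichlet generator
(`gen_proportions_dirichlet()`) supports prior-informed simulation: the
concentration vector $\alpha$ controls both the expected composition
($\alpha_i/\sum\alpha$) and its spread. The rare-component generator
(`gen_proportions_rare()`) sets one target type to an exact gradient level
(defaults 0.001, 0.003, 0.005, 0.008, 0.01, 0.03, 0.05 — spanning the
regime where methods start predicting hard zeros) and spreads the
remaining mass over the other types, by normalized uniform draws by
default or evenly with `background = "equal"`. The spiked entry is stored
bit-exactly so downstream error metrics are not polluted by construction
noise.

Mixtures are then synthesized two ways, matching how bulk and single-cell
references are used in practice. `mix_bulk()` is the exact linear
combination $S P$. `pseudobulk_sc()` draws cells: the per-sample cell
quota is apportioned across types by the largest-remainder rule (floors
plus leftovers to the largest fractional remainders, ties broken by
cell-type order), cells are sampled uniformly within type, and their count
vectors are summed. Largest remainder was chosen over multinomial
sampling because it is deterministic given the proportions, makes the
realized-composition error bound explicit ($\le (K-1)/n_{\text{cells}}$
for $K$ types), and is therefore directly testable; sampling is without
replacement until a type's pool is exhausted, at which point the function
falls back to replacement and warns — small strata exercise this path
deliberately in the PBMC-like scenario.

Datasets are always split before any of this: 70/30 by samples for bulk,
70/30 stratified within each cell-type label for single cells. Training
partitions build references; test partitions build mixtures. The training
fraction rounds half-up per stratum (so 10 samples split 7/3), and a
stratum with fewer than two cells refuses to split rather than silently
placing a type entirely in one partition.

## The noise model

Clean mixtures are perturbed entry-wise with a Gamma–Poisson model.
Writing $r_0$ for the column-normalized clean value and $L_j$ for the
sample's library size, the expected count is $\mu_0 = r_0 L_j$, and

$$\sigma = (1.8\,p_t + 1/\mu_0)\, e^{\delta/2}, \quad \delta \sim N(0, 0.25)$$
$$\mu \sim \mathrm{Gamma}(\text{shape} = 1/\sigma^2,\ \text{scale} = \mu_0/\text{shape}), \qquad v \sim \mathrm{Poisson}(\mu)$$

The Gamma stage preserves the mean by construction
($\text{shape}\times\text{scale} = \mu_0$), so marginally $v$ is negative
binomial with mean $\mu_0$ and variance $\mu_0 + \mu_0^2\sigma^2$. The
single dial $p_t \in [0,1]$ grades noise levels NL_1 ($p_t = 0.1$) through
NL_10 ($p_t = 1$); NL_0 bypasses the sampler entirely and returns the
input bit-for-bit. The $1/\mu_0$ term makes low-expression entries
noisier, mimicking shot-noise-dominated counts, and $e^{\delta/2}$ injects
per-entry (optionally per-gene, `delta_scope = "per_gene"`) dispersion
heterogeneity.

Two conventions deserve explicit statement because the formula admits
typographic variants: $N(0, 0.25)$ is read as *variance* 0.25 (standard
notation), and $\delta$ enters as $e^{\delta/2}$. The alternatives
($e^{\delta}$, $e^{\delta^2}$) are selectable via
`noise_params(delta_exponent = ...)` for users who need to match a
different convention; every test in the suite states the form it assumes.
Library sizes are taken as the input column sums and held fixed across
noise replicates; output column sums are *not* renormalized, so observed
depths fluctuate around their expectations as they do in resequenced
libraries.

## Building references

`build_reference_bulk()` takes per-type arithmetic means of training
samples; `build_reference_sc()` averages cells within type, after scaling
each cell to counts-per-million by default so deep cells do not dominate
(`normalize = "raw_mean"` disables this). Signature genes are selected per
type by the specificity ratio — expression in the type divided by the
maximum expression in any other type plus a $10^{-8}$ pseudocount — keeping
the top `k_per_type` (default 50) genes whose within-type expression
reaches `min_expression` (default 1, filtering noise-level genes). The
ratio form makes the selection invariant to global rescaling of the
reference. This scheme is this package's own, deliberately simple choice;
it recovers planted markers essentially perfectly on the bundled
scenarios, but no claim is made that it replicates any particular
published tool's marker lists, and `method = "none"` lets users supply
their own list.

## Metrics

Six vector metrics and one composite cover complementary views:

* **PCC** and **RMSE** capture the overall linear fit of predicted to true
  proportions.
* **MAPE** (relative to the truth, entries with truth $\le$ `mape_epsilon`
  skipped) exposes cell-type bias that PCC/RMSE average away; its
  degeneracy at near-zero truths is exactly why the rare-component
  protocol reports **sMAPE** instead, whose terms $2|t-p|/(t+p)$ are
  bounded by 2 and equal 2 whenever a present component is predicted as
  zero.
* **SSIM** (single-window, population moments, inputs max-scaled to
  $[0,1]$, constants $C_1 = 0.01^2$, $C_2 = 0.03^2$ — the standard
  convention for unit-scaled data) summarizes agreement of means,
  variances, and covariance at once and is scale-free.
* **JS divergence** (base-2 logs, range $[0,1]$) compares compositions as
  probability distributions and is symmetric.
* The **accuracy score (AS)** ranks methods within each of PCC, RMSE,
  MAPE, and SSIM (rank 1 best, ties share the mean rank) and sums the
  ranks with unit weights by default. AS depends on metric values only
  through ranks, so any strictly monotone re-expression of a metric leaves
  the ordering unchanged; lower AS is better. The orientation (rank 1 =
  best) is a convention — the tested contract is the ordering, not the raw
  value.

In `evaluate_proportions()` the per-cell-type mode applies each metric to
a cell type's proportion vector across samples (the standard protocol
view); SSIM and JS are generic vectors-in/score-out functions, so users
holding reconstructed expression profiles can apply them at the gene level
as well.

## Protocols and seeding

`run_noise_protocol()` regenerates fresh proportions per noise level by
default (`shared_proportions = TRUE` reuses one set to isolate the noise
effect), mixes, perturbs, runs every method, and scores per cell type.
`run_rare_protocol()` reports both overall metrics per gradient level and
the spiked-component restriction, where sMAPE is the headline number.
`run_cellnum_protocol()` freezes one test set — 50 pseudo-bulks of 3000
cells by default, generated on a seed path independent of the sweep — and
re-trains (or re-references, via the trainer contract) at each training
cell number of 100, 500, 1000, 2000, 3000, 4000, 5000. All per-condition
seeds derive deterministically from the config seed by integer mixing, so
conditions are mutually independent yet every table is exactly
reproducible. A failing method degrades to NaN rows with a logged message
rather than aborting a sweep, since external adapters are expected to be
flaky; the echo-truth adapter (`make_echo_method()`), which returns the
ground truth, serves as an end-to-end sentinel that must score zero error
and maximal similarity in every protocol.

## Baseline solvers

The NNLS baseline solves $\min\|Sw - y\|^2, w \ge 0$ per sample
(Lawson–Hanson, via `pracma::lsqnonneg`) and normalizes to the simplex
afterwards; the CLS baseline enforces $\sum w = 1$ *during* the solve with
a primal active-set method on the KKT system (tolerance $10^{-9}$, Gram
matrix pre-scaled by its mean diagonal and ridge-escalated only if a free
block is numerically singular). Both post- and in-solve normalization
appear among published methods, which is why both baselines exist. Neither
applies log or TPM transforms by default; `normalize = TRUE` applies
column-TPM to both inputs.

## The synthetic scenarios

`make_scenario()` generates four shapes that copy the *cardinalities and
difficulty axes* of typical benchmark datasets — not any tissue's biology:
`coarse8` (8 bulk types), `fine14` (14 types as 7 correlated subtype
pairs), `tissue7` (7 single-cell types × 1500 cells), and `pbmc13` (13
types, 6 correlated pairs plus a singleton, cell counts log-spaced from 50
to 3000). Each type's expression program is a shared log-normal gene
baseline (meanlog $\log 5$, sdlog 1) plus type-specific log-deviations
(sd 0.4); subtype pairs blend a common parent's deviations with weight
`subtype_correlation` (default 0.8) *in log space*, which keeps the
planted correlation detectable on any scale. Each type additionally gets
`n_markers_per_type` (30) exclusive marker genes up-shifted by
`marker_log2fc` (4, i.e. 16-fold). Counts are negative binomial around
program × library size with dispersion 0.3 — mid-range for UMI data —
with per-cell depths log-normal around 5000 and bulk replicates at $10^6$.
These defaults were fixed once as plausible magnitudes for the data class;
`scenario_sanity()` verifies for any spec that the planted structure is
recoverable (marker recovery, program correlation, NNLS error on clean
pseudo-bulks).

What the scenarios deliberately do *not* model: gene-length/GC bias,
doublets, ambient RNA, batch effects, or platform differences. Passing
results on these fixtures therefore demonstrate correctness of the
benchmarking machinery and sensible behavior of methods under controlled
difficulty axes — they do not predict absolute performance on real
tissues.

## Numerical choices and edge cases

Proportion columns must sum to 1 within $10^{-8}$ in strict mode; the
external-method adapter uses lenient mode, which clips negatives,
renormalizes, and warns, because many tools return unnormalized weights.
Zero expected counts pass through the noise model as zeros. An NNLS
solution that is identically zero falls back to the uniform vector with a
warning. MAPE skips entries with truth below $10^{-12}$ and reports how
many it skipped; sMAPE defines $0/0$ terms as 0; JS uses $0\log 0 = 0$;
SSIM of two all-zero vectors is 1 by convention (with a warning). TSV is
the canonical exchange format (tab separation avoids decimal-comma locale
hazards; commas are sniffed on read), numbers serialize with 17
significant digits so doubles round-trip exactly, and the first header
cell is fixed to `id` to remove index-column ambiguity. Matrix Market
triplets carry single-cell counts with `genes.tsv`, `barcodes.tsv`, and a
two-column `cell_types.tsv` sidecar.

## Problem sizes used in the test suite

The unit suite runs the protocols at reduced sizes (hundreds of genes,
tens of cells and samples) because the properties under test — exactness
of the echo-truth sentinel, determinism, apportionment bounds, metric
identities — are size-independent; the protocol *defaults* (50 samples per
condition, 11 noise levels, the 7-level gradient, 50 × 3000-cell test
pseudo-bulks, the 7-value training grid) are asserted as constants and
used by `scripts/acceptance.R`, which exercises the full-size coarse
scenario. Moment checks of the noise model use $10^5$ draws; the mean
identity is verified stage-wise (the Gamma stage's mean preservation is an
algebraic identity of the parameterization, and the Poisson stage is
checked on its conditional residual), which gives the Monte-Carlo estimate
a standard error of at most 0.15% of the mean.

## Known limitations

The toolkit evaluates proportion estimates only; methods that also
reconstruct per-type expression are scored on proportions. Expression-
weight proportions are not converted to cell-count proportions (no
per-type mRNA-content scaling). The built-in baselines are deliberately
plain NNLS/CLS: they are reference points and pipeline sentinels, not
competitive methods. Counts and TPM-like inputs are tracked by a `space`
tag and mismatches warn rather than convert.
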