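---
title: "Methods: tile-wise negative binomial P-spline models for base-resolution coverage"
author: "tilegam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tile-wise negative binomial P-spline models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilegam)
```

## The model

ChIP-seq coverage is summarized as one fragment-center count per base
pair. `tilegam` models the count $y_i$ at genomic position $x_i$ in
sample $j_i$ as negative binomial,

$$y_i \sim \mathrm{NB}(\mu_i, \theta), \qquad
\log \mu_i = o_i + \sum_{k=1}^{K} f_k(x_i)\, z_{j_i,k},$$

with variance $\mu + \mu^2/\theta$. The offsets $o_i$ are known
log size factors absorbing sequencing-depth differences, constant within
a sample. The binary matrix $Z$ encodes the factorial design: $z_{j,k} =
1$ when smooth $f_k$ contributes to sample $j$. The canonical
two-condition layout is

$$\log \mu_i = o_i + f_{\text{control}}(x_i) +
  z_{j_i} f_{\text{treatment/control}}(x_i),$$

so the second smooth is directly the position-wise log fold-change of
treatment over control.

Each smooth is a penalized cubic B-spline (P-spline): $f_k(x) = \sum_r
\beta^{(k)}_r b_r(x)$ with uniformly spaced knots, and a second-order
difference penalty $S = D^\top D$ on adjacent coefficients that
approximates the integrated squared second derivative. All smooths share
knots and basis, so the full design is the Kronecker product $X = Z
\otimes X_k$, with sample-major row order (all positions of sample 1,
then sample 2, ...). Coefficients maximize the penalized log-likelihood

$$\hat\beta = \arg\max\ \ell_{\mathrm{NB}}(\beta; y, \theta)
  - \lambda\, \beta^\top (S_{\mathrm{bd}} + \epsilon I)\, \beta,$$

where $S_{\mathrm{bd}}$ is block-diagonal with one penalty block per
smooth, $\lambda$ is the smoothing weight, and the small ridge
$\epsilon$ keeps the problem strictly concave in regions of all-zero
counts (where the likelihood alone leaves the coefficients nearly
unidentified).

## Sparse Newton-Raphson fitting

The objective is concave for fixed $\theta$, and its curvature is
banded: each base is covered by at most 4 cubic B-splines (5 counting
closed supports at knots), the penalty has at most 5 nonzeros per row,
and therefore the Hessian

$$H = X^\top W X - 2\lambda (S_{\mathrm{bd}} + \epsilon I), \qquad
W_{ii} = -\,\frac{\theta \mu_i (y_i + \theta)}{(\mu_i + \theta)^2},$$

has a bounded number of nonzeros per row regardless of the tile length.
$W$ is the exact second derivative of the NB log-likelihood in the
linear predictor — full Newton curvature rather than its Fisher-scoring
expectation; both derivatives are gated by finite-difference tests. The
Newton step solves $-H\,\delta = \nabla\ell$ by a sparse Cholesky
factorization with a fill-reducing permutation (CHOLMOD through the
Matrix package); the inverse is never formed. A QR factorization of $X$
would destroy this sparsity, which is why the solver works on $H$
directly.

Numerical choices, all tested: the start value is a ridged least-squares
fit of $\log(y+1) - o$; step halving (at most 20 halvings) enforces a
monotone objective; iteration stops when the gradient max-norm drops
below $10^{-6}$ *or* the relative objective change drops below
$10^{-8}$ (whichever happens first — the natural reading of "stop when
either signal is small"), with a cap of 50 iterations; the linear
predictor is clipped at $\pm 50$ with a warning to avoid overflow. The
default ridge is $\epsilon = 10^{-3}$; it biases a constant fit by a
relative amount of order $\epsilon$, which the seamless-join tests make
visible — they use $\epsilon = 0$ where exact constancy matters.

## Standard errors by the sparse inverse subset

Pointwise variances of a smooth are
$\sigma^2_{i,k} = (X_k H_k^{-1} X_k^\top)_{ii}$, needing only entries
$(H^{-1})_{lj}$ for pairs $(l,j)$ where two basis functions overlap the
same base — exactly the nonzero pattern of $X^\top W X$, hence of $H$.
$H^{-1}$ itself is dense and is never materialized.

We factorize $A = -H$ (positive definite; the sign is handled
explicitly since Cholesky needs SPD) as $PAP^\top = LL^\top$ and run
the Takahashi recursion on the root-free form $A = L_1 D L_1^\top$:

$$Z_{ij} = \frac{\delta_{ij}}{d_i} - \sum_{k > i} (L_1)_{ki} Z_{kj},$$

evaluated over the *upper-triangular* pattern entries $(i,j)$ of each
column, from the last column backwards and bottom-up within a column.
Traversed this way, every $Z_{kj}$ the sum touches is itself on the
filled pattern: $j$ and $k$ are both off-diagonal entries of column $i$
of $L$, so the symbolic factorization places fill at
$(\max(j,k), \min(j,k))$. The implementation insists on a simplicial
CHOLMOD factor because its stored pattern is the exact symbolic fill;
the recursion raises an internal-consistency error if a lookup ever
leaves the pattern, which would indicate a pattern bug rather than a
data problem. Extra fill entries beyond $\mathrm{NZ}(H)$ are computed
and discarded — closure of the recursion requires the filled pattern.

The variance contraction forms only the row-local product
$(X_k \cdot H_k^{-1}|_{\text{pattern}})$, multiplies elementwise with
$X_k$ and sums rows — no dense $p \times p$ or $n \times n$
intermediate. The same contraction applied to differentiated basis rows
gives variances of $f_k'(x)$; only the first derivative is exposed,
higher orders being the same code path with no additional validation
here.

An independent route, $\sigma^2_i = \sum_j ((X P^\top L^{-1})_{ij})^2$
evaluated by batched triangular solves, is implemented as
`indirectVariances()` and used as a cross-method oracle in the tests
(it scales quadratically, so it is not the default path). A literature
description of this identity attributes the Cholesky factor to
$X^\top H^{-1} X$, which is dimensionally inconsistent with the
surrounding algebra; we implement the standard identity on the Cholesky
of $-H$ and validate against dense inversion rather than guess at the
intended reading.

## Tiling and assembly

Whole chromosomes are cut into overlapping tiles (default 24 kb with
3 kb overlap), each fitted independently — embarrassingly parallel, and
memory is bounded by the tile, not the genome. Each tile owns a *chunk*
bounded by overlap midpoints; terminal chunks extend to the chromosome
boundaries (a convention of this package — tile coordinates at
chromosome ends are not canonical). The final track takes every base
from its owning chunk, with no blending. Because spline influence decays
exponentially with distance, the difference between a tile fit and a
global fit is far below $10^{-4}$ everywhere outside the discarded
overlap halves — the acceptance suite verifies a two-tile 30 kb example
against a global fit. With 20 bp knots and two smooths, a 24 kb tile has
about 2400 coefficients, the parameter regime in which the sparse
solver's cost and the Hessian's nonzero count scale linearly with the
coefficient count (also asserted by test, via operation counts rather
than wall time).

The default backend keeps tracks in memory; an HDF5 backend
(pre-initialized datasets, chunk shape aligned to the layout's chunks,
serialized chunk-wise writes) is available for long genomes via rhdf5.
Outputs export to TSV, HDF5, bigWig and BED.

## Hyperparameter selection

$\lambda$ and $\theta$ are global and chosen by cross-validation on
representative tiles: 20 tiles drawn with probability proportional to
their total counts, 10 folds each (the classical configuration — one
evaluation therefore costs 200 fits). Folds are blocks of 20 bp dealt
round-robin after a seeded shuffle, so held-out positions are
interpolated by flanking data and the objective scores smoothing rather
than memorization; block length matches the knot spacing so a held-out
block removes at most a handful of basis-function supports. In-fold
fitting *drops* held-out rows rather than zeroing them (zeros would bias
$\mu$ downward). The out-of-fold unpenalized NB log-likelihood is
maximized over $(\log\lambda, \log\theta)$ by Nelder-Mead from three
seeded log-uniform starts (at most 50 evaluations each) — the surface is
deterministic but not convex, and a joint search is used since there is
no evidence an alternating scheme does better. Degenerate search ranges
short-circuit to a single evaluation, which the tests use as a fixed
point check.

## The synthetic-data generator

`simConfig()`/`simulateCounts()` generate data from the model itself —
NB counts around smooth log-occupancy functions combined through a
design matrix with per-sample size factors — except that the truth
smooths are sums of Gaussian bumps, deliberately outside the spline
family, so recovery tests cannot succeed by basis coincidence.
`simulateFragments()` inverts the ingest path: each count becomes a
fragment whose center maps back to its base (paired-end proper pairs or
shifted single-end reads, written as coordinate-sorted indexed BAM), so
ingest-of-simulation equals the original counts exactly; fragments that
would overhang the chromosome are shifted inward and reported, moving
their centers — round-trip exactness therefore holds away from the
terminal half-fragment of each end.

Default study conditions: a 30 kb chromosome; a control occupancy
smooth with three bumps over a baseline of 5 expected counts per base
(typical of a well-covered yeast-scale ChIP-seq track); a log
fold-change smooth with one positive and one negative bump of about
one log unit; dispersion $\theta = 5$ (moderate overdispersion); size
factors 0.9/1.1 (mild depth imbalance). The recovery tests use 2-4 kb
tiles and 20 replicates so the suite stays in the seconds-to-minutes
range; these sizes are stated here as the package's chosen test scale.

What the simulation does *not* emulate: read sequences, mappability and
GC artifacts, input-vs-IP background structure, or fragment-length
variability. Passing recovery tests therefore demonstrates correctness
of the estimator and its uncertainty under the stated model, not
robustness to the artifacts of real libraries.

## Parameter defaults and units

| parameter | default | units | rationale |
|---|---|---|---|
| knot spacing | 20 | bp | resolves features of tens of bp; gives the few-thousand-parameter tiles the solver is designed around |
| tile size | 24000 | bp | ~1200 coefficients per smooth per tile |
| overlap | 3000 | bp | join error far below numerical tolerance at the chunk boundary |
| $\epsilon$ | $10^{-3}$ | — | identifiability in zero-count regions; bias negligible against counting noise |
| CV tiles / folds | 20 / 10 | — | classical configuration; 200 fits per evaluation |
| fold block | 20 | bp | matches knot spacing; held-out blocks are interpolated |
| size-factor bins | 1000 | bp | median-of-ratios is robust at this bin occupancy |
| fragment length | user-supplied | bp | no cross-correlation estimator is included |

Coordinates are 0-based half-open throughout the package's numeric
interfaces (matching BAM/BED conventions); conversions to 1-based
GRanges happen only at the Bioconductor boundary (`tileRanges()`,
bigWig export). Duplicate reads are retained by default (the counting
model treats fragments as events), with a flag to drop marked
duplicates. Size factors are median-of-ratios on binned counts and are
geometric-mean-centered so offsets are mean zero in log space — fitted
baseline levels shift by the centering constant relative to uncentered
conventions.

## Known limitations

* Only the negative binomial family is implemented; quasi-binomial
  models (e.g. for methylation proportions) are not supported.
* $\theta$ is global and fixed during fitting; it is selected by CV,
  never profiled inside the Newton loop.
* Region-level significance and peak calling are out of scope; only
  pointwise Gaussian z-tests on single smooth values are provided, with
  no multiplicity handling.
* Single-end fragment length must be supplied by the user.
* Knot placement is uniform; adaptive placement is not available.

## A compact worked example

```{r example, eval = FALSE}
cfg <- simConfig(length = 30000, seed = 1)
sim <- simulateCounts(cfg)
layout <- makeTiles(30000)
fit <- fitGenome(sim@counts, cfg@Z, layout,
                 sizeFactors = cfg@sizeFactors,
                 lambda = 100, theta = 5, chrom = "chrS")
lfc <- fittedTrack(fit, "treatment_vs_control")
se <- seTrack(fit, "treatment_vs_control")
head(pointwisePvalues(lfc, se^2))
```
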