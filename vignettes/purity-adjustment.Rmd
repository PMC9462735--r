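---
title: "Purity-aware correction of tumor methylation beta values: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purity-aware correction of tumor methylation beta values: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purebeta)
```

## The model

A bulk tumor specimen with tumor cell fraction (purity) $p_j$ mixes the
methylation of the malignant compartment with that of the surrounding
microenvironment. At a single CpG $i$, if sample $j$'s tumor cells carry
methylation state $t$ and the aggregate normal background carries state
$n_i$, the observed beta value is

$$\beta_{ij} = p_j\,t + (1 - p_j)\,n_i + \varepsilon_{ij},$$

a straight line in $x_j = 1 - p_j$ with intercept $t$ (the pure-tumor
state) and value $t + (n_i - t)$ at $x = 1$ (the normal state). Crucially,
somatic methylation changes usually affect only a subset of tumors: at a
promoter silenced in some samples but not others, the cohort splits into
latent *populations*, each on its own line with its own intercept but all
sharing the same normal endpoint. `purebeta` therefore models each CpG as a
finite mixture of $K \in \{1,2,3\}$ linear regressions of beta on
$1 - p$,

$$\beta_j \sim \sum_{k=1}^{K} \pi_k\,
  \mathcal{N}\!\left(a_k + b_k (1 - p_j),\ \sigma_k^2\right),$$

fitted by EM, with $K$ chosen by BIC. After discovery, each population is
detrended twice by ordinary least squares on the *original* (noise-free)
betas — against $1 - p$ for the purified-tumor state and against $p$ for
the inferred normal state — and the residuals of each fit are added back to
its intercept so that biological sample-to-sample variation survives the
correction. Finally values outside $[0, 1]$ are clamped. Because the two
regressions describe the same line in two parametrizations
($a + b(1-p) = (a+b) - bp$), the pre-clamp difference between a sample's
normal and tumor value is constant within a population and equals the
tumor-fit slope; the package's tests assert this identity to $10^{-10}$.

The approach needs no reference normal samples: the normal background is an
extrapolation of each population's line to $p = 0$, and the cohort-level
agreement of those extrapolations is itself a quality check.

## Parameters that matter

* `noise_sd = 0.005` — SD of Gaussian noise added to a working copy of the
  betas before population discovery (never before the regressions). Without
  it, a population with near-zero variance (e.g. fully unmethylated
  samples) lets one mixture component collapse onto a tiny residual SD and
  the model splits it spuriously; the small jitter removes that degeneracy
  while leaving the fits untouched. Units are beta (fractions), so 0.005 is
  well below array noise.
* `k_max = 3`, `nrep = 3` — at most three populations per CpG and three
  random EM restarts per candidate $K$. More populations are rarely
  identifiable from one covariate; restarts protect against bad random
  initial partitions.
* `min_weight = 0.05` — mixture components whose weight drops below 5% are
  removed and EM continues; this is how transient, spurious populations
  vanish rather than distort the fit.
* `tol = 1e-6`, `max_iter = 200` — EM stops when the relative
  log-likelihood change falls below `tol`. These defaults make desk-scale
  fits deterministic and fast; non-convergence is recorded, not fatal, and
  the fit still competes by its achieved likelihood.
* Residual SDs are floored at `1e-4` so a zero-variance population cannot
  send the likelihood to infinity.
* BIC uses $3K + (K-1)$ free parameters (intercept, slope, residual SD per
  component; $K-1$ free weights). Ties within $10^{-9}$ go to the smaller
  $K$ (parsimony).

## Determinism and parallelism

Every CpG row is paired with its own seed derived from
`(global_seed, row_index)` by a double Lehmer (minstd) mix
(`derive_cpg_seed()`); discovery noise and EM restarts for that CpG use
only that seed. Results are therefore bit-identical for any worker count
and any scheduling order — the package's tests byte-compare 1-worker and
4-worker output files. Restart sub-seeds come from the same splittable
counter scheme, so `nrep` fits are independent yet reproducible.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws, per CpG, a population count $K$ (default
40/40/20% for $K = 1/2/3$), pure-tumor states from $\{0, 0.5, 1\}$
(distinct states at least 0.2 apart when $K > 1$), a shared normal state
from $\{0, 0.3, 0.7\}$, purities uniform on $(0.2, 0.95)$, and observed
betas via the mixing equation plus $\mathcal{N}(0, 0.03^2)$ measurement
noise, clamped to $[0, 1]$. The defaults mirror a purity-confounded
breast-cancer-like cohort of 630 samples: populations well separated in
their tumor states, a wide purity range, and noise at the scale of array
replicates. The purity distribution is a deliberate choice — wide and
bounded away from 0 so the regression geometry is exercised — since real
cohort purity distributions vary by tumor type.

The generator does *not* emulate Infinium probe chemistry or the
beta-value heteroscedasticity near 0 and 1, batch effects, purity estimate
bias (only unbiased noise via `perturb_purity()`), or cell-type structure
within the microenvironment (one aggregate normal compartment). Passing
tests on these cohorts therefore demonstrates correctness of the model,
the estimation machinery and the bookkeeping — not performance on any real
cohort, which additionally depends on how well real CpGs satisfy the
linear-mixing assumption.

`simulate_subtype_cohort()` adds a binary sample subtype and makes a
fraction of CpGs subtype-linked (population membership equals subtype), so
that clustering of adjusted vs unadjusted matrices can be compared against
a known truth: purity dilution drags low-purity samples towards the normal
state and blurs the subtype contrast, which the correction removes.

## Numerical choices and degenerate inputs

* Weighted least squares uses the closed form; if a population's covariate
  variance is below $10^{-12}$ (e.g. all purities equal) the slope is 0 and
  the intercept is the weighted mean.
* Populations with fewer than 3 members after hard assignment cannot
  support a line fit; they are merged into the population with the nearest
  mixture intercept before detrending.
* Samples with missing beta at a CpG are excluded from that CpG's fits and
  emitted as missing.
* Purity exactly 1 is valid (the sample sits at the tumor intercept);
  purity 0 is rejected — there is no tumor signal to recover.
* Clamping to $[0, 1]$ happens after residual re-addition and is the only
  nonlinearity in the pipeline.
* Constant rows survive: discovery sees only the injected jitter, one
  population is selected, and the row passes through essentially unchanged.
* In `hierarchical_split()` (1 − Pearson distance, Ward linkage,
  `ward.D2`), constant sample profiles would make the distance undefined;
  they are jittered by a deterministic $10^{-9}$ ramp with a warning. Ward
  linkage on a correlation distance is not Euclidean-exact; it is kept
  because it is the field's standard recipe for methylation subtyping.

## Open design points, decided

* Discovery noise is drawn once per CpG, before model selection, not
  re-drawn per restart — restarts should explore initializations of the
  same data, not different data.
* The per-CpG seed depends only on the global seed and the row position,
  not on the CpG identifier, so renaming probes never changes results but
  reordering rows does (documented on `derive_cpg_seed()`).
* `split_metrics()` evaluates both cluster-to-class mappings and reports
  the accuracy-maximizing one (accuracy is then $\ge 0.5$ by
  construction); the positive class is a parameter.
* Population-call concordance between two runs matches labels by the best
  injective mapping (labels are arbitrary); with at most three populations
  exhaustive enumeration is exact.
* Trimodal binning cut points default to (0.25, 0.75). These are an
  assumption, not an estimate: they split the theoretical hypo / Xi /
  hyper peaks at 0, 0.5 and 1 symmetrically and are configurable.
* Perturbation grids are inclusive arithmetic sequences; a grid starting
  at 0 includes the identity perturbation, so both the 25-point
  (0.02–0.5) and a 26-point (0–0.5) reading of the high-noise experiment
  are expressible.

## Problem sizes used in the shipped tests

The test suite and the acceptance script regenerate everything from code:
parameter recovery uses a 630-sample × 500-CpG cohort with $K \in \{1,2\}$;
model-selection rates use 200 CpGs per scenario at 200 samples;
perturbation decay uses a 120 × 60 cohort over the 10-point grid
(3 replicates) plus a single 235-sample two-population CpG over the
25-point grid (10 replicates); the clustering comparison uses a 200-sample
× 700-CpG two-subtype cohort with 20 random 500-CpG draws. These sizes
were chosen so the whole verification runs comfortably on a laptop while
keeping every estimate's Monte-Carlo error far from the asserted margins.

## Known limitations

* The correction assumes linear mixing in purity with one shared normal
  state per CpG; focal copy-number change under a methylation difference,
  or multiple normal compartments, violate it.
* Population discovery needs a reasonable spread of purities; a cohort
  with near-constant purity leaves tumor and normal states unidentifiable
  (the regression degenerates to its mean).
* At most three populations per CpG are modelled, which matches the
  motivating biology but is a hard cap.
* Purity estimates are taken as given; the package is agnostic to their
  source and does not estimate purity itself.
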