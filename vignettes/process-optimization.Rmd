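---
title: "Two-stage process optimization: combined weighting, orthogonal designs and response surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage process optimization: combined weighting, orthogonal designs and response surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procopt)
```

## The problem

Formulation development for herbal preparations routinely optimizes two
processes in sequence. First, an **extraction** step is tuned over a small
number of process factors (water-to-material ratio, number of extractions,
extraction time), judged not by a single response but by several quality
criteria at once — a dry extract ratio and the contents of several marker
compounds. Second, a **granulation** step is tuned over its own factors
(diluent amount, binder amount, ethanol volume fraction) against a single
response, the molding rate. `procopt` implements the statistical machinery
for both stages: multi-criteria weighting and scoring with orthogonal-array
analysis for the first, Box–Behnken response-surface methodology for the
second, plus the RSD statistics used to validate the analytical method in
between.

## Stage one: weighting, scoring, and the orthogonal array

### Subjective weights: the analytic hierarchy process

Expert judgment enters as a tier assignment: criteria of equal importance
share a tier, and the judgment matrix compares tiers by a fixed verbal
scale. `build_judgment_matrix()` fills the reciprocal pairwise matrix
$\alpha_{ef}$ from a tier-gap map — by default ratio 1 within a tier, 3 one
tier apart ("slightly more important"), and 5 two tiers apart
("significantly more important"). Note that the gap-2 ratio is the scale
value 5 itself, not the quotient 5/3 of the tier scores: the tier scores
label positions on the verbal scale, they are not multiplicative strengths.

Weights are the normalized principal right eigenvector of the judgment
matrix, computed by power iteration (tolerance $10^{-12}$, at most 10,000
iterations); the row geometric mean is available as an alternative and
agrees with the eigenvector to well under a percentage point whenever the
matrix is acceptably consistent. Consistency is reported the standard way:
$\lambda_{\max}$ as the mean of $(J w)/w$, $CI = (\lambda_{\max} - n)/(n-1)$,
and $CR = CI/RI(n)$ with Saaty's random indices (overridable via
`ri_table`); $CR < 0.1$ is the conventional bar.

```{r ahp}
criteria <- list(
  criterion_spec("Albiflorin", 1), criterion_spec("Paeoniflorin", 1),
  criterion_spec("Liquiritin", 2), criterion_spec("Glycyrrhizic acid", 2),
  criterion_spec("Ganoderic acid A", 3), criterion_spec("Dry extract ratio", 3))
ahp <- ahp_weights(build_judgment_matrix(criteria))
ahp
```

### Objective weights: the entropy method

`entropy_weights()` rewards dispersion: each column is min–max standardized
(cost criteria inverted), converted to column proportions
$p_{ij} = C_{ij}/\sum_i C_{ij}$, and scored by Shannon entropy
$e_j = -\tfrac{1}{\ln m}\sum_i p_{ij}\ln p_{ij}$ with the usual convention
$0\ln 0 := 0$; the weight is the normalized divergence $1 - e_j$. No epsilon
shift is added to the standardized values — the minimum row simply
contributes nothing to the entropy sum, which is the plain-min-max reading
of the standardization formula. A zero-dispersion column gets divergence 0
(weight 0) and a warning rather than an error, so a degenerate criterion
cannot silently dominate.

### Combined weights and comprehensive scores

`combine_weights()` multiplies the two vectors criterion-wise and
renormalizes, $W_j = W_{jS} W_{jO} / \sum_k W_{kS} W_{kO}$.
`comprehensive_score()` then scores each run as
$\mathrm{score}_i = 100 \sum_j C_{ij} W_j$. The weighted sum of standardized
values lies in $[0,1]$ by construction; the package reports it on a 0–100
scale (configurable via `scale`), the convention under which published
comprehensive-score tables in this field are printed.

Published score tables are frequently *not* exactly re-derivable from the
published raw measurements and weight tables — the upstream software's
exact standardization and rounding conventions are rarely stated. The
downstream functions therefore accept any externally supplied score vector
(`run_pipeline()`'s `scores` entry, or simply passing the published scores
to `range_analysis()`), so a published analysis can be reproduced from its
own printed scores. The same applies to published entropy columns, which is
why `combine_weights()` takes any objective vector rather than insisting on
the internally computed one.

### Range analysis and ANOVA

For a balanced orthogonal array, `range_analysis()` tabulates per-level
response sums $K$, means $k$, and ranges $R = \max k - \min k$; factors rank
by descending $R$ (ties keep design order), and the recommended level per
factor is the one with the highest mean. `orthogonal_anova()` computes
$SS_{\text{factor}} = \sum_{\text{levels}} K^2/r - (\sum y)^2/m$ and takes
the unassigned remainder of the total SS as the error term — for an L9
array with three assigned factors this is the empty fourth column with 2
degrees of freedom. P values come from the upper tail of the F
distribution; no multiplicity adjustment is applied (three planned factor
tests against a common error term). With zero error degrees of freedom the
table still reports SS but flags F and P unavailable rather than invent a
denominator.

## Stage two: the Box–Behnken response surface

`generate_bbd()` produces the canonical 3-factor Box–Behnken point set —
the 12 edge midpoints of the coded cube plus replicated center points
(default 5, i.e. 17 runs). Natural units code as
$\text{coded} = (\text{natural} - \text{center})/\text{half-range}$, and
the round trip is exact to machine precision.

`fit_quadratic()` fits the 10-term full quadratic by QR-based least
squares. On the coded design the linear and interaction columns are
mutually orthogonal, so those coefficients equal their closed-form
contrasts ($(\sum y_+ - \sum y_-)/8$ for linear terms, the 4-point cross
contrast for interactions) — a property the test suite checks on every
input, and a useful hand check on any fitted surface.

`rsm_anova()` reports the Design-Expert-style table: the 9-df model row,
one row per term, and the residual split into lack of fit and pure error
using the center replicates, with $F_{\text{lof}} = MS_{\text{lof}} /
MS_{\text{pe}}$. Per-term SS are partial (Type III) sums of squares,
$\beta_j^2 / [(X'X)^{-1}]_{jj}$. For the orthogonal linear and interaction
columns partial and sequential SS coincide; the three pure-quadratic
columns are *not* orthogonal to the intercept or to each other, so their
partial SS do not (and should not) sum with the rest to exactly the model
SS — the additivity identities that do hold on every input, and that the
tests assert, are model + residual = total and lack-of-fit + pure error =
residual.

### The constrained optimum

A fitted quadratic need not have an interior stationary point of the right
curvature, so `optimize_surface()` optimizes over the closed coded cube
$[-1,1]^3$ by exact face-lattice enumeration: for each of the $3^3$
patterns of coordinates fixed at $\pm 1$ versus free, it solves the reduced
stationary system and keeps feasible solutions; the cube's vertices
complete the candidate set. The best candidate is the exact global
constrained optimum — no grid refinement step is needed, and the test suite
verifies agreement with a dense grid search on random surfaces. The raw
optimum is always retained; `natural_rounded` additionally reports each
coordinate at whole-unit granularity, the precision at which process
settings are actually implemented (whole parts of diluent, whole percent).

```{r bbd}
factors <- read_bbd_factors(system.file("extdata",
  "granulation_bbd_factors.yaml", package = "procopt"))
bb <- read_bbd_data(system.file("extdata",
  "granulation_bbd_runs.csv", package = "procopt"), factors)
model <- fit_quadratic(bb$design, bb$y)
optimize_surface(model, "maximize")
```

## Method validation

`rsd()` and `validate_batches()` implement replicate-set validation
statistics: the sample ($n-1$) standard deviation — the convention under
which published RSD rows reproduce — and RSD% $= 100\,s/\bar{x}$, with
inclusive threshold comparisons (a set exactly at its limit passes, since
published "all below x%" statements are made from rounded values). Default
limits follow common chromatographic practice: 2% for peak-area precision,
repeatability and stability, 0.3% for retention times, 5% for batch
consistency.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable without laboratory data,
and their defaults mirror the study conditions the analysis functions
expect:

* `gen_judgment_matrix()` perturbs a consistent matrix multiplicatively,
  $\alpha_{ef} = (w_e/w_f)e^{\varepsilon_{ef}}$ with Gaussian
  log-noise on the upper triangle and reciprocity enforced — the natural
  error model for ratio judgments. At `perturbation_sd = 0.05` on a
  6-criterion matrix, recovery error stays below 0.02 mean absolute and CR
  stays under 0.1 in well over 95% of draws (checked by Monte Carlo in the
  tests, 200 fixed seeds).
* `gen_orthogonal_response()` is additive in factor-level effects plus
  Gaussian noise — exactly the model under which range analysis and the
  orthogonal ANOVA are unbiased. Effect spans of (10, 5, 2) score units
  against unit noise reproduce the true factor ranking in >95% of 500
  seeded draws.
* `gen_bbd_response()` evaluates a known coded quadratic plus Gaussian
  noise; at unit noise over 200 seeds the coefficient estimates are
  unbiased and the pure-error mean square estimates $\sigma^2$ within 20%.

All generators take an explicit seed, use a private RNG stream, and restore
the caller's random state, so identical configurations are bit-reproducible.
Gaussian noise is used throughout because it is the error model under which
the downstream least-squares and ANOVA machinery is exact; what the
generators deliberately do **not** emulate are the failure modes of real
laboratory data — heteroscedastic measurement error, drift between runs,
rounding of recorded values, and correlated criteria arising from shared
sample preparation. Passing recovery tests on synthetic data therefore
demonstrates correctness of the computations, not robustness of the study
design to such artifacts.

## Numerical choices and edge cases

* Power iteration: tolerance $10^{-12}$ on the weight vector, max 10,000
  iterations; a positive reciprocal matrix has a simple dominant
  eigenvalue, so failure to converge indicates corrupted input and is an
  error, not a warning.
* For $n \le 2$ the consistency index is 0 by construction and CR is
  reported as 0 (the random index is 0, so the ratio is taken as its
  limit).
* Zero-range criterion columns: normalized to 0 with a warning, entropy
  divergence 0; an all-degenerate matrix is an error.
* Factor-importance ties in range analysis break by design column order,
  deterministically.
* Negative computed sums of squares beyond $-10^{-9}$ raise an error;
  tiny negative values from cancellation clamp to 0.
* The problem sizes throughout (9-run arrays, 17-run designs, matrices up
  to order 10, Monte-Carlo loops of 200–500 seeds) keep the full test
  suite and the analysis scripts in the seconds range on a single core.

## Reproducing a published two-stage analysis

`run_pipeline()` chains the stages — weights, scores, range/ANOVA, response
surface, validation — reading the packaged CSV/YAML transcriptions of a
published granulation study and writing one CSV per analysis table plus a
JSON summary with both optima. Because that study's printed score table is
not exactly re-derivable (see above), the packaged configuration feeds the
published scores and the published objective-weight column to the
downstream stages, which then reproduce the published range table, ANOVA,
regression equation, and optima; the internally computed entropy weights
remain available by simply omitting those two config entries.

## Limitations

* Only 3-factor Box–Behnken designs are generated; no central-composite or
  D-optimal designs, and no multi-response desirability optimization.
* Orthogonal-array support covers balanced single-response designs; no
  alias/confounding analysis for general fractional factorials.
* One standardization (min–max) and one weighting combination rule
  (multiplicative) are provided; z-score or vector normalizations and
  other MCDM schemes (TOPSIS, CRITIC, fuzzy AHP) are out of scope.
* The AHP random-index table ships for orders up to 10; larger matrices
  require a user-supplied table.
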