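---
title: "Methods: demographic amplification, inertia bounds, and the phylogenetic comparison"
author: "demamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic amplification, inertia bounds, and the phylogenetic comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demamp)
```

## The scientific question

Some plant species become invasive when they establish outside their native
range while most do not, and quarantine policy would benefit from predictors
of invasiveness that can be measured *before* a species is exported — i.e.
in its native range. Classical comparative demography focuses on the stable
population growth rate $\lambda$, but $\lambda$ describes an undisturbed
population at its stable stage structure. Invasion is intimately tied to
disturbance: a propagule arriving in a new range is, almost by definition, a
population far from stable structure. `demamp` implements a comparative
pipeline built around *transient* demography: how much a population can
amplify (or attenuate) relative to stable growth after a disturbance of its
stage structure, and whether that capacity differs between invasive and
non-invasive species once phylogeny is accounted for.

## Demographic metrics

A population projection matrix (PPM) $A$ is a non-negative $k \times k$
matrix whose entry $a_{ij}$ is the annual per-capita contribution of stage
$j$ individuals to stage $i$, optionally split as $A = U + F$ into survival
($U$, column sums $\le 1$) and recruitment ($F$). For an irreducible,
primitive $A$, Perron–Frobenius theory gives a simple real dominant
eigenvalue $\lambda$ (stable growth rate), a positive right eigenvector $w$
(stable stage structure) and a positive left eigenvector $v$ (reproductive
values). A population started at $w$ grows exactly geometrically:
$\log N_t = \log N_0 + t \log \lambda$.

A population started away from $w$ carries a permanent multiplicative
offset — *demographic inertia*. For initial structure $\hat n_0$
(normalised to unit density) the projected density satisfies
$\log N_t \to \log N_0 + t\log\lambda + \log \rho_\infty$, with
$\rho_\infty = v^\top \hat n_0 \, \lVert w\rVert_1 / (v^\top w)$. Over all
non-negative initial structures this is bounded by

$$\bar\rho_\infty = \frac{v_{\max}\lVert w \rVert_1}{v^\top w}
\qquad\text{and}\qquad
\underline\rho_\infty = \frac{v_{\min}\lVert w \rVert_1}{v^\top w},$$

attained on the basis vectors of the stages with the largest and smallest
reproductive value. $\bar\rho_\infty \ge 1$ measures the potential for
demographic amplification (recovery after disturbance), and
$\underline\rho_\infty \le 1$ the potential for attenuation. Both are
invariant to any positive rescaling of $v$, $w$, or of $A$ itself — so they
are comparable across species with very different $\lambda$.

`eigen_analysis()` extracts the eigen-pair by full eigendecomposition,
selecting the eigenvalue of largest real part and requiring it to be real
with strictly positive eigenvectors. We deliberately avoid power iteration:
near-imprimitive matrices make it converge arbitrarily slowly, while a
dense eigendecomposition of a $k \le 8$ matrix is exact and cheap.
Primitivity is *checked* (Wielandt bound in `is_primitive()`), not assumed:
a merely periodic matrix still has a well-defined Perron root (with damping
ratio 1), but its projections never settle, which surfaces as a
non-convergence error in the brute-force oracle `inertia_bruteforce()`
rather than in the eigendecomposition.

Normalisation conventions ($w$ sums to one, $v$ scaled so $v^\top w = 1$)
are internal choices; every reported metric is provably invariant to them,
and the tests assert this invariance directly.

The transient envelope (`transient_envelope()`) draws
$N_0\lambda^t\bar\rho_\infty$ and $N_0\lambda^t\underline\rho_\infty$
around the central line $N_0 \lambda^t$ from $t = 0$ onward. The
asymptotic inertia multipliers are used for the whole curve — no
short-term amplification index (reactivity or first-step bounds) enters,
so the envelope has constant width $\bar\rho_\infty/\underline\rho_\infty$
on the log scale. This is the simplest object whose boundaries are
functions of $t$, $\lambda$ and inertia alone; short-term transient
indices are an explicit non-goal.

"Mean recruitment per life stage" (`recruitment_per_stage()`) is defined
as the mean over **all** $k$ stages of the per-capita column sums of $F$;
stages that do not reproduce contribute zeros. The alternative — averaging
over reproductive stages only — is available via `reproductive_only =
TRUE`. We default to the all-stages form because it preserves the
interpretation of the denominator (life-cycle length) across species whose
reproductive allocation differs; the choice is config-switchable and only
the log of the value is used downstream. A species with zero recruitment
has an undefined log and is recorded as missing, not offset-adjusted.

## Quality control and standardisation

Structural diagnostics: `is_irreducible()` (strong connectivity of the
life-cycle graph), `is_primitive()` (Wielandt bound
$A^{k^2-2k+2} > 0$), and `is_ergodic()` (strict positivity of the dominant
left eigenvector).

**The seed problem.** Some published matrices force every newly produced
seed to wait a full projection interval in the seed stage before it can
germinate, which distorts generation time and inflates the transient
response of the seed stage. Detection (`detect_seed_problem()`) is
metadata-driven: a designated seed stage that receives all recruitment,
with germination transitions leaving it, is flagged. The correction
(`correct_seed_problem()`) composes the seed column of $U$ into
recruitment: $F'_{ij} = U_{is}\,F_{sj}$, so germinants flow into seedling
stages in their year of production and only genuine seed-bank survival
($U_{ss}$) retains seeds. The survival component is untouched, so column
survival bounds are preserved, and the first-generation recruit flow of
the corrected model at time $t$ equals the uncorrected flow at $t+1$ — a
property the tests verify by explicit projection. The published studies do
not print their correction algebra; this rule is our declared
interpretation, and it is overridable per record.

**Census conversion.** On a post-reproductive census, recruitment entries
compound parental survival with fecundity ($F^{\text{post}}_{1j} =
\sigma_j \phi_j$), which inflates recruitment and hence measured
amplification relative to the pre-reproductive convention
($F^{\text{pre}}_{ij} = \phi_j g_i$, fecundity times first-year recruit
survival). `convert_post_to_pre()` recovers $\phi_j =
\sum_i F^{\text{post}}_{ij} / \sigma_j$ (with $\sigma_j$ the survival
column sum) and rebuilds $F^{\text{pre}} = g\,\phi^\top$, with $g$
supplied or taken from the recruit-stage column of $U$. This re-expresses
$F$ only; an exact census shift would in general also re-time $U$, which
cannot be reconstructed from the matrix alone. The conversion is exact —
$\lambda$ is preserved to machine precision — on the *consistent* family
in which all stages share a common per-capita fecundity $\phi$ and
$g = U e_1$: there $A^{\text{post}} = (I + \phi e_1 \mathbf 1^\top)U$ and
$A^{\text{pre}} = U(I + \phi e_1 \mathbf 1^\top)$ share their non-zero
spectrum (a product-commutation identity). The acceptance checks use this
family; records whose metadata cannot support the conversion are passed
through flagged, never silently altered.

**Inclusion rules** (`filter_config()`, `filter_records()`): annual or
integer-multi-annual timestep; no pooling across sites; no laboratory or
greenhouse populations; no mean matrices when individual constituents
exist; no reducible matrices; no experimental manipulation (burning,
herbicide, harvesting, grazing, nutrient supplement — keyword match on the
treatment field). A record missing a field needed by an enabled rule is
excluded conservatively with reason `missing_metadata:<field>`, rather
than imputed: the original filters were applied with full metadata in
hand, and silent imputation would make exclusions unreproducible. The
engine is deterministic, order-independent, and idempotent. Multi-annual
matrices are kept only when an exact integer timestep is recorded; no
matrix-root annualisation is attempted (ill-posed for general non-negative
matrices).

## Aggregation

Within each spatial population, yearly matrices are averaged elementwise
to a *temporal mean matrix* and all metrics are computed **on that mean
matrix** — not as means of yearly metrics (the tests include a case
constructed so the two differ). Metrics are natural-log-transformed (they
describe geometric processes; the log base only shifts all contrasts by a
constant factor, and natural logs are used consistently everywhere), then
averaged across populations to species means within each range category.
A species studied in both its native and naturalised range yields one row
per range. The five categories combine global status (restricted /
introduced / invasive) with study range (native / naturalised);
restricted × naturalised is rejected as a definitional contradiction.
Populations are unweighted within species: the source studies provide no
principled weights. Replicate matrices within a year are averaged
uniformly with the other years.

## The phylogenetic mixed model

Species values are non-independent under shared ancestry. For a species
metric $y$ the model is

$$y = X\beta + u + e,\qquad u \sim \mathcal N(0, \sigma^2_p C),\qquad
e \sim \mathcal N(0, \sigma^2_e I),$$

with $X$ the 5-level category design (one mean per category), and $C$ the
Brownian-motion covariance from the phylogeny (shared root-to-MRCA path
lengths; `vcv_from_tree()`), rescaled to unit tree depth so that
$\sigma^2_p$ is comparable across trees (switchable).

Fitting is by Gibbs sampling (`fit_phylo_mixed_model()`), with proper
weakly-informative inverse-gamma priors, shape = scale = 0.001, on both
variances, diffuse $\mathcal N(0, 10^8)$ priors on $\beta$, and
*parameter expansion* on the phylogenetic effect: $u = \alpha\eta$ with a
redundant working multiplier $\alpha \sim \mathcal N(0, 10^3)$, which
rescues mixing when $\sigma^2_p$ is near zero. These constants are our
declared defaults — the technique, not the constants, is standard.

Two implementation choices matter:

- **Eigen-rotation.** With one observation per species the model is
  rotated into the eigenbasis of $C$: $y^* = E^\top y$, where
  $C = E\Lambda E^\top$. The phylogenetic effect then has diagonal
  covariance $\sigma^2_p\Lambda$ and every Gibbs update is a vector
  operation, making a full chain $O(n)$ per iteration after one
  eigendecomposition. This is exact, not approximate.
- **Chain defaults.** The default `model_spec()` runs 110,000 iterations
  (10,000 burn-in, thinning 100). Simulation studies in the tests use
  shorter chains (1,500–6,000 iterations), chosen so that Monte-Carlo
  error is small relative to the quantities asserted: e.g. the coverage
  study stores 4,000 draws per fit so that the Monte-Carlo noise of the
  2.5%/97.5% interval endpoints is negligible against the interval width.
  Longer chains are a config change, not a code change.

With both variances fixed, the posterior mean of $\beta$ equals the
generalised-least-squares estimator (up to Monte-Carlo error) — the
sampler is tested against that closed form, against the ordinary linear
model in the $\sigma^2_p = 0$ reduction, against nominal 95% coverage of
null contrasts over 500 replicates, and for recovery of injected effects
and variances on 200-tip trees.

**Contrasts and signal.** `category_contrasts()` reports, for each
non-reference category, the posterior mean difference from the reference
(default: invasive species measured in the naturalised range) with its
central 95% interval; a contrast is credible when the interval excludes
zero. `phylo_signal()` summarises $\sigma^2_p$ and the ratio
$h = \sigma^2_p/(\sigma^2_p + \sigma^2_e)$. Because a variance posterior
is always positive, "credibly above zero" is operationalised as the lower
95% HPD bound of $h$ exceeding a threshold (default 0.05, reported and
configurable, never hidden).

**Robustness variants.** The same operation fits (i) a non-phylogenetic
model ($C = I$, by passing `C = NULL`), and (ii) a population-level model
(`nested = TRUE`) with species as an additional exchangeable random
effect beside the phylogenetic one; the nested sampler works in the
original basis with per-iteration Cholesky solves, since observation
counts per species break the diagonalisation.

**Inertia–recruitment relationship.** `metric_regression()` regresses the
species log upper inertia bound on log mean recruitment per stage with
the same machinery, reporting the slope posterior and whether it is
credibly positive.

## Ancestral states

For the phylogram of amplification across the tree, internal-node states
are maximum-likelihood Brownian-motion estimates: the GLS root-state
estimate $\hat x = (\mathbf 1^\top C_r^{-1} x)/(\mathbf 1^\top C_r^{-1}
\mathbf 1)$ of the tree rerooted at each node. `ancestral_states_bm()`
computes all of them in one pass of Gaussian message passing (upward and
downward combination of precision-weighted means along edges), which is
algebraically identical to rerooting everywhere but never inverts a
matrix. Tests verify equality with the explicit rerooted-GLS formula on
random six-tip trees (relative error $< 10^{-8}$) and agreement with an
independent rerooting-ML implementation. Non-positive branch lengths are
rejected (they make the rerooted covariance singular), with the offending
node named.

## The synthetic data generator

No raw study data ships with the package; a seeded generator
(`generate_dataset()`) emulates the statistical structure the analysis
assumes, so every stage is testable end to end with known truth.

- **Life cycles** (`generate_ppm()`): $k \in [2,8]$ stages; per-stage
  survival in $[0.2, 0.95]$ allocated over destination stages by a
  Dirichlet draw weighted towards stasis and progression; log-normal
  recruitment from the later (reproductive) stages into stage 1
  (pre-reproductive convention); rejection-sampled to irreducibility and
  primitivity.
- **Phylogeny** (`generate_tree()`): Yule pure-birth tree, all extant
  tips retained, hence ultrametric.
- **Species values**: $y = X\beta + u + e$ exactly as the model assumes.
  Default category means of log $\bar\rho_\infty$ are 1.2 for the three
  non-invasive categories and 1.7 for both invasive categories (a 0.5
  log-unit invasiveness effect), with $\sigma^2_p = 0.2$,
  $\sigma^2_e = 0.1$ on the depth-1 tree and population-level noise with
  sd 0.1. These sit inside the empirically displayed range of log
  amplification (about 0 to 5) and keep essentially all population
  targets above the hard floor $\log\bar\rho_\infty \ge 0$; targets that
  would fall below are clamped at 0.05 (rare under the defaults, and
  noted here because frequent clamping would bias recovery).
- **Matrices that carry the signal**: each population's mean matrix is
  built by root-finding on a recruitment scale factor applied to a random
  base life cycle until $\log\bar\rho_\infty$ matches the population's
  target (to $10^{-8}$); low targets that a heterogeneous base cannot
  reach fall back to bases with homogeneous survival, whose near-equal
  column sums pull the bounds towards 1. Yearly matrices rescale each
  column by positive factors averaging exactly to 1, so the temporal mean
  is exactly the designed matrix, the zero pattern (and hence
  primitivity) is preserved, and survival sums stay below 1.
- **Pathologies**: reducible matrices, greenhouse settings, pooling,
  redundant mean matrices, treatment keywords, post-reproductive
  censuses and seed-problem structures are injected at configurable
  per-record rates, with ground-truth bookkeeping of which records must
  survive filtering.
- **Seeding**: one master seed drives everything through a documented
  splitting scheme, so sub-generators are independently reproducible and
  a dataset is bit-identical across runs.

What the generator does *not* emulate: demographic stochasticity or
sampling error in matrix entries, density dependence, non-Brownian trait
evolution, covariation between life-cycle structure and category beyond
the injected inertia effect, and the empirical stage-count and fecundity
distributions of real compilations. Passing tests therefore demonstrate
the correctness and calibration of the *pipeline* under its assumed model,
not the field validity of those assumptions.

## Numerical choices and degenerate inputs

- Brute-force inertia projections renormalise by $\lambda$ each step
  (avoiding overflow at $T = 2000$) and error if the ratio changes by
  more than $10^{-8}$ between the half-way checkpoint and $T$ — the
  symptom of imprimitivity.
- Eigenvalues with imaginary part above $10^{-8}$ (relative), or
  eigenvectors with non-positive entries, raise structured errors naming
  the offending matrix property.
- $C$ eigenvalues are floored at $10^{-10}$ of the maximum before
  inversion in the sampler; a matrix failing positive semi-definiteness
  beyond $-10^{-9}$ is rejected.
- Empty categories, single-draw posteriors (interval width zero), all-zero
  recruitment (missing log), and records with missing metadata all take
  defined, tested paths rather than propagating NaNs.
- All tabular outputs are written with 12 significant digits so that
  pipeline regression tests can compare files byte-for-byte.

## Problem sizes used by the checks

The test-suite and the acceptance script run: 100 random matrices
($k = 2..8$, horizon 2000) for the inertia oracle; 40 matrices for
bracketing/invariance; 25 consistent life cycles for census conversion;
20 fixtures (30 species) for GLS equivalence; 500 null replicates
($n = 200$) for interval coverage; 100 replicates on a 200-tip tree for
effect recovery; 10 six-tip trees (all internal nodes) for ancestral
states; and 20 end-to-end replicates at 200 species for pipeline-level
recovery. These sizes were chosen once to make Monte-Carlo error small
relative to each assertion while keeping the whole suite comfortably
re-runnable on a single CPU.

## Known limitations

- The seed-problem and census-conversion algebra are declared
  interpretations of procedures whose exact algebra is not printed in the
  source literature; both are config-documented and flag rather than
  force questionable records.
- The census conversion re-expresses recruitment only; outside the
  consistent family it changes $\lambda$ slightly, which is why
  inconsistent records are flagged.
- The five-category comparison retains very small categories (the
  introduced-in-naturalised-range category is tiny in the real data); with
  few species a category's posterior mean is prior-sensitive, which is
  visible in its interval width rather than hidden.
- Reproducing the published credible intervals requires the archived
  database-derived dataset, which is not redistributable here; the
  dataset-count check runs only against a locally supplied copy.
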