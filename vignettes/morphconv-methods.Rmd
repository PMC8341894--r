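---
title: "Models and methods behind morphconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind morphconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`morphconv` asks whether lineages that independently adopted a derived
ecological regime — the motivating system is selective zooplanktivory in
butterflyfishes, a family of benthic small-prey specialists — have
converged morphologically, and whether any convergence exceeds what
undirected Brownian evolution would produce. This vignette is the
package's own account of its models, conventions, and numerical choices.
It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Regime histories: Mk models and stochastic maps

Foraging regime is a 4-state discrete character (`bi`, `fc`, `oc`, `zp`)
evolving by a continuous-time Markov chain with generator `Q` (rows sum to
zero; `ER`, `SYM`, `ARD` symmetry classes). The likelihood is computed by
Felsenstein pruning with a matrix exponential per branch, with partial
likelihoods rescaled branch-wise to avoid underflow; missing tips enter as
uniform partials. The root prior defaults to the stationary distribution
of `Q` (explicit, because it changes ancestral states); `uniform` and
fixed priors are available.

Stochastic maps are drawn empirical-Bayes style: `Q` is fit by bounded
quasi-Newton on log rates from three deterministic starting magnitudes,
node states are then sampled from their joint conditional distribution by
a pre-order sweep over the pruning partials, and each branch receives an
endpoint-conditioned path sampled by uniformization (jump count from the
Poisson-weighted power series of the uniformized transition matrix, jump
times as uniform order statistics, virtual jumps collapsed). The original
analysis used a Bayesian mapper with priors that are specific to a legacy
program and under-documented for four states; empirical-Bayes mapping
reproduces that procedure's structure while remaining fully specified, and
an optional mode multiplies `Q` by a Gamma-distributed rate factor per
draw for users who want rate-prior spread. Uniformization is exact, so no
rejection fallback is normally exercised; a jump-count cap of 10⁴ guards
pathological inputs.

Transition-type percentages are reported as (mean count of the ordered
pair) / (mean total count), matching how the study reports the share of
gains and reversals.

## Trait models on painted trees

Five models of continuous trait evolution are fit per trait and per map:
`BM1`, `BMS` (per-regime rates), `OU1`, `OUM` (per-regime optima), `OUMV`
(per-regime optima and rates; a single attraction `alpha`, as in the
five-model set — no regime-specific `alpha`). With node depth measured
from the root and segments ordered rootward-to-tipward, the OU tip mean is

    E[y_i] = sum_k theta_k W_ik,
    W_ik  = int over lineage i's time in regime k of alpha e^{-alpha (T - s)} ds,

with the root mass `e^{-alpha T}` assigned to the root regime's optimum.
This is the stationarity-at-root convention: it drops a separate root
parameter while keeping each row of `W` summing to one, which stabilizes
optimum estimates exactly as dropping the root state is meant to. The tip
covariance integrates the regime-dependent diffusion along the shared
root path:

    V_ij = e^{-alpha (d_i + d_j)} int_0^{d_a} sigma2(s) e^{2 alpha s} ds,

with `a` the MRCA of tips `i` and `j`; BM models use the `alpha -> 0`
limit (shared path length weighted by `sigma2(s)`). Both integrals are
accumulated per node in one pre-order pass, so a likelihood evaluation is
O(n²) plus one Cholesky factorization. The `expm1` forms of the segment
integrals keep the `alpha -> 0` limit accurate to ~1e-12, which the
nesting tests exercise.

**Fitting.** Location parameters (`theta`, or the BM mean) are profiled
out by GLS; a single diffusion scale is profiled analytically where the
model allows (BM1 is fully closed-form). The attraction parameter is
optimized from 8 deterministic starts log-spaced over
`[1e-6, 10 / tree height]` (OU likelihoods are multimodal in `alpha`),
with box bounds `[1e-8, 50 / tree height]` — the upper bound keeps
`e^{2 alpha T}` finite — and ties broken by the higher log-likelihood,
then the lower `alpha`. The optimizer, starts, and bounds are this
package's declared choices; the source analysis does not state its own.

**Screening and averaging.** The Hessian of the negative log-likelihood
over the full parameter vector is evaluated by central differences (step
`1e-4` times the parameter scale). A fit is retained only if no
eigenvalue of the symmetrized Hessian is below `-1e-8` and the inverse
Hessian has positive diagonal (those diagonals are the per-parameter
variances used for unconditional standard errors). AICc uses the tip
count as `n`. Delta-AICc is computed within each map iteration across the
models retained there, then averaged per model over its retained
iterations; weights are `exp(-mean delta / 2)` renormalized. The 95%
confidence set is the smallest prefix of weight-ordered models whose
cumulative weight reaches 0.95; adjusted weights renormalize over it.
Model-averaged `theta` and `alpha` are taken over the OU members of the
confidence set (with weights renormalized over those members — BM models
have no optimum in the OU sense, which is also why the study declined to
average the one trait whose set was BM-led); `sigma2` averages over all
members. Unconditional standard errors follow
`sum_m w_m sqrt(var_m + (p_m - p_bar)^2)`. `sigma2 / (2 alpha)` is
reported as the stationary variance, the drift-versus-constraint summary.

## Allometry

Size correction regresses each trait (except maximum body size, which is
never corrected) on log standard length by PGLS under strict BM
correlation, and keeps the response-scale residuals: positive means
larger than the allometric expectation. The slope-heterogeneity test fits
`trait ~ size * regime` (reference regime = the most frequent, ties
alphabetical; regimes under 2 species dropped with a warning) and reports
both each interaction contrast's t statistic and the overall interaction
F against the common-slope model — the source reports an F-style df pair
alongside a t, so both conventions are provided. The slope test also
offers an ML-lambda mode; the residual procedure itself is BM-only, the
one fully specified common denominator of the two fitting tools the
original analysis names.

## Phylogenetic PCA

The evolutionary covariance is the GLS cross-product about phylogenetic
means under `C(lambda)`, with Pagel's lambda scaling only the shared
(off-diagonal) history and optimized by maximum likelihood on `[0, 1]`
(boundaries checked explicitly; values above 1 can break positive
definiteness on some trees, so the box stops at 1). The *correlation*
matrix is decomposed, as specified; scores project the evolutionarily
standardized, phylogenetically centered traits on its eigenvectors, so
score units stay interpretable. Eigenvector signs are fixed
deterministically (largest-magnitude loading positive). Axes with
eigenvalues below `1e-10` are flagged as beyond the matrix rank rather
than dropped silently. Ancestral points for plots project trait-space
reconstructions rather than refitting on scores; model fitting on score
axes simply reuses the trait-model machinery (with the usual caveat that
PC axes inherit the reconstruction model's bias, which is why the package
treats score-space model fits as visualization support, not evidence).

## Convergence metrics and their null

For each focal pair, candidate points for `Dmax` are the reconstructed
states at the *nodes* on each lineage's MRCA-to-tip path, tips included —
not interpolations along branches, which the metric descriptions do not
license. Including the tips makes `Dtip` itself a candidate, so
`C1 = 1 - Dtip/Dmax` is clamped into `[0, 1]` by construction; a
divergence-only pair gives exactly 0, and `C2 = Dmax * C1` holds as an
algebraic identity. "Total evolution" in C3/C4 is the sum over branches
of the Euclidean distance between the reconstructed states at the
branch's two ends (C3: both focal lineages; C4: every branch of the
smallest clade containing all focal tips). Metrics average over focal
pairs. A pair with `Dmax = 0` flags C1 as undefined instead of
propagating NaN.

Reconstructions come in two flavours: per-trait GLS (maximum likelihood)
under BM, and best linear unbiased predictions under a single-regime
multivariate OU with one shared `alpha` and a full trait covariance —
because that joint covariance is a Kronecker product with a common tree
kernel, the node predictions are separable across traits, and `alpha` is
the only searched parameter (optimum and trait covariance profile out
analytically). At `alpha -> 0` the OU predictions reduce to the BM ones,
a tested identity.

The null always simulates correlated Brownian motion — `n_sim` datasets
with tip covariance `kronecker(R_hat, C)`, `R_hat` the evolutionary
covariance estimated from the observed data (ridged with a logged jitter
if near-singular) — regardless of which reconstruction scores the
replicates, mirroring the study's design of scoring one BM null under
both reconstruction models. The p-value is the proportion of null values
`>=` the observed (observed excluded from the null); the cutoff is the
empirical 95th percentile (type-7 quantile), the reading consistent with
cutoffs that sit just below significant observed values. The whole
procedure is seed-deterministic; reruns reproduce p-values bit-exactly.
The trait space is the 7 size-corrected residuals plus log maximum body
size, unstandardized — exactly the matrix the rest of the pipeline
consumes.

## The synthetic study and what it does (not) show

`make_fixture("paper-like")` emulates the study conditions with known
truth: a 79-tip pure-birth tree scaled to 42 My; a 4-state generator
whose relative rates concentrate on the benthic modes with rarer
zooplanktivory gains (mostly from benthic invertivory) and fast reversal,
scaled so the expected transition count over the realized tree is 28 —
yielding a dwell fraction of a few percent in `zp`, with roughly a tenth
of transitions being gains; and 8 traits built as allometric slope x
Brownian log standard length plus residual processes with regime
optima (`eye_diameter` higher for zp, `body_width` and `caudal_fin_ratio`
lower, the rest regime-independent), magnitudes chosen to be of the order
of the residual spread so that detection is possible but not trivial. The
regime draw is conditioned (rejection-sampled) on the documented preset
card — at least 3 independent zp origins among at least 4 zp tips — and
the preset seed is part of the preset definition, so the bundle is
byte-reproducible.

What the generator does **not** emulate: measurement error and
intraspecific variation (species means are exact), fossil or non-extant
tips, correlated residual evolution across traits (an optional
Cholesky-correlated BM mode exists for the convergence null), topology
uncertainty with real posterior structure (pseudo-posterior trees are
independent draws), or the biased regime sampling of real specimen
collections. Passing tests therefore certify the *machinery* — that every
estimator recovers the truth its model class defines — not that real
butterflyfish data would behave this way.

## Problem sizes and numerical choices in the tests

The suite chooses desk-scale sizes that keep each oracle sharp: exhaustive
enumeration against pruning on trees of 4–7 tips; Monte-Carlo moment
checks with 10⁵ exact-kernel simulations on a 6-tip painted tree (3
standard-error bands); uniformization versus rejection sampling with
2 x 10⁴ conditioned paths; OUM recovery and model selection with 20
seeds on a 150-tip two-regime painting (`alpha = 2`, `sigma2 = 0.5`,
optima 0 and 1, tree height 3 so `alpha T = 6` is comfortably
identifiable); null calibration with 200 meta-replicates of 100
simulations each on a 50-tip tree, checking that `P(p <= 0.05)` stays in
`[0.01, 0.10]` under a Brownian truth. Round-trip identities run over a
few hundred random trees and paintings; simmap durations are serialized
with 17 significant digits so parse-and-rewrite is bit-identical.

Degenerate inputs are handled explicitly rather than by accident:
zero-length branches carry zero-duration segments and drop out of the
integrals; polytomies are rejected (the OU weight algebra assumes binary
merges; resolution is the user's choice); `alpha = 0` passed to an OU
model is an error (use the BM model — the limit is available through the
nesting identities); `stationary_variance(0, s2)` returns a flagged
infinity; a single observed regime state drives Mk rates to the lower
bound rather than erroring.

## Pipeline conventions and limitations

`run_pipeline()` derives every stage's seed as `global seed + a fixed
stage offset`, never from the clock, so manifests (which record input
MD5 hashes, package version, and per-stage iteration counts) are
reproducible bit-for-bit. Iterations failing the Hessian screen are
excluded per trait and per model before averaging, and the retained count
is reported, mirroring the study's retained-iterations column. Map
summaries are computed on the primary (consensus) tree's draws, since
dwell and transition summaries require a common topology.

Known limitations, deliberately out of scope: multivariate (correlated-
trait) OU *fitting* (the mvOU reconstruction shares one `alpha`);
regime-specific attraction (OUMA/OUMVA); measurement-error models;
frequency-based convergence counts and time-sliced convergence; Mk models
with hidden states; reversible-jump searches over model space. The
allometric ML-lambda mode caps lambda at 1 even though some empirical
fits sit slightly above; on trees where that matters the BM mode is the
comparable default.
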