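# morphconv

Do lineages that adopt the same derived ecology converge on the same
morphology? `morphconv` implements, as a tested R package plus a sequence
of analysis scripts, the full phylogenetic comparative workflow used to ask
that question for selective zooplanktivory in butterflyfishes
(Chaetodontidae): a clade of benthic small-prey specialists in which
zooplanktivory arose several times recently, so any convergence must be
judged against strong ancestral effects.

The pipeline has six stages, each backed by package functions:

1. **Regime history** — fit an Mk (continuous-time Markov) model to a
   4-state foraging character (`bi` benthic invertivory, `fc`/`oc`
   facultative/obligate corallivory, `zp` zooplanktivory) and draw
   stochastic character maps: node states sampled from their joint
   conditional distribution via Felsenstein pruning, branch paths from the
   endpoint-conditioned chain by uniformization.
2. **Allometry** — phylogenetic size correction by PGLS residuals
   (`trait ~ log10 standard length` under Brownian covariance; positive
   residual = larger than the allometric expectation) and a
   `size x regime` interaction test for heterogeneous allometric slopes.
3. **Trait models** — maximum-likelihood fits of five models of continuous
   trait evolution on each regime-painted tree: BM1, BMS (per-regime
   rates), OU1, OUM (per-regime optima), OUMV (per-regime optima and
   rates, shared attraction). For an OU process
   `dX = alpha (theta - X) dt + sigma dW`, the tip mean is
   `sum_k theta_k W_ik` with `W_ik` the exponentially discounted time
   lineage `i` spent in regime `k` (root mass `exp(-alpha T)` assigned to
   the root regime: no separate root optimum), and the tip covariance
   integrates the regime-dependent diffusion along shared root paths.
   Fits are screened by the eigen-decomposition of the Hessian, ranked by
   AICc averaged over map iterations, and model-averaged over the 95%
   confidence set with unconditional standard errors; `sigma2 / (2 alpha)`
   is reported as the stationary variance.
4. **Phylogenetic PCA** — eigen-decomposition of the evolutionary
   correlation matrix with maximum-likelihood Pagel's lambda, plus PGLS of
   the leading axes on size.
5. **Convergence** — the distance-based metrics C1–C4: for each focal
   pair, `Dtip` is the tip-to-tip Euclidean distance in the residual
   morphospace and `Dmax` the maximum distance between reconstructed
   states (BM or multivariate-OU ancestral reconstructions, tips included)
   on the two lineages back to their MRCA; `C1 = 1 - Dtip/Dmax`,
   `C2 = Dmax - Dtip`, and C3/C4 scale `C2` by the summed branch-wise
   evolution of the two lineages / of the smallest clade containing the
   focal tips. Significance comes from 500 correlated-Brownian
   simulations parameterized by the evolutionary covariance of the data
   (p = proportion of null values >= observed; cutoff = empirical 95th
   percentile).
6. **Synthetic data** — because the original specimen measurements are not
   published, a first-class generator (`make_fixture("paper-like")`)
   reproduces the study conditions with known truth: a 79-tip, 42-My
   ultrametric tree, a regime history whose generator is calibrated to ~28
   expected transitions with a few percent of time spent zooplanktivorous
   and ≥3 independent zp origins, and 8 traits with known allometric
   slopes and regime-dependent optima. All trait simulation uses exact
   Gaussian transition kernels segment-by-segment (no SDE discretization).

## Worked example

```r
library(morphconv)

fx <- make_fixture("paper-like")          # synthetic study, known truth
fit <- fit_mk(fx$tree, fx$tip_states, model = "ER")
maps <- sample_maps(fx$tree, fx$tip_states, fit$Q, n_draws = 100, seed = 42)
s <- summarize_history(maps)
round(c(transitions = s$mean_transitions, zp_time_pct = s$time_pct[["zp"]]), 1)
#> transitions zp_time_pct
#>        24.2         9.4

res <- size_correct(fx$tree, fx$traits)   # 7 residual traits + max body size
y <- res[, "body_width"]
f <- fit_model(maps[[1]], y, "OUMV")
round(f$theta, 3)
#>     bi     fc     oc     zp
#>  0.011  0.065 -0.006 -0.094
```

The fitted zooplanktivore optimum for residual body width is distinctly
negative — slimmer than the allometric expectation — while the benthic
regimes sit near zero, recovering the planted truth
(`theta_zp = -0.12`). The numbered scripts under `analysis/` run the six
stages end to end and write tables (model-average tables shaped like the
study's, a convergence table with cutoff/observed/p per regime and metric)
under `results/`.

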