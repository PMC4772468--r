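---
title: "Birth–death–innovation models of gene-family copy number on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Birth–death–innovation models of gene-family copy number on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famflux)
```

## The model

`famflux` models the copy number of a gene family as a homogeneous
continuous-time Markov chain on the truncated state space `0..N_max`.
Duplication ("birth") and deletion are copy-proportional: from state
`k >= 1` the birth rate is `b·k` and the deletion rate `d·k`, both in units
of events per gene copy per million years (My). *Innovation* is the
`0 -> 1` transition at rate `i` per gene family per My; it stands in for
processes that (re)introduce a family on a chromosome — transposition from
another chromosome, recombination-arrest capture, or resuscitation of a
pseudogenized family. Birth is suppressed at the truncation boundary
`N_max`, so the generator is tridiagonal and rows sum to zero.

Four canonical forms tie these parameters:

| form    | constraint            | free rates |
|---------|-----------------------|------------|
| `L`     | `b = d = λ`, `i = 0`  | 1          |
| `L_I`   | `b = d = i = λ`       | 1          |
| `BD`    | `i = 0`               | 2          |
| `B_I_D` | `i = b`               | 2          |

Without innovation, state 0 is absorbing: any family observed anywhere must
then have been present in the most recent common ancestor, and the root
prior excludes state 0. A fifth form (`L_indI`, innovation estimated
independently of `λ`) is implemented but excluded from the canonical model
space: reconstructions under independently estimated innovation tend to
re-derive anciently present families as recent innovations (poor ancestral
sensitivity), which external Y-assembly evidence contradicts. The
`presence_call_metrics()` helper supports exactly this style of audit
(MAP presence versus reference presence, as sensitivity/specificity).

Two kinds of rate heterogeneity are expressible. *Gene heterogeneity*
assigns different forms/rates to blocks of gene categories (autosomal
singletons `AutS`, autosomal multicopy `AutM`, Y singletons `YS`,
ampliconic `AG`); the ten canonical partitions of these four categories,
crossed with 8 per-block variants (4 forms × lineage heterogeneity on/off),
give the 6408-model space that `enumerate_model_space()` produces
(8 + 4·64 + 4·512 + 4096). *Lineage heterogeneity* gives each branch class
(canonically `Hominini` versus `OWM`) its own copy of a block's free rates;
the class map is a per-branch labeling built by `assign_clade_class()`.

## Tip observation models

Tips carry likelihood profiles over `0..N_max`, not fixed states:

- **qPCR** (`qpcr_profile`): the continuous estimate is treated as
  Normal(mean, SE) and integrated over intervals with cut points
  `(0, 1.5, 2.5, ...)`, assigning each positive integer its interval mass.
  State 0 gets likelihood 0 — an amplifying assay implies presence. The top
  state absorbs all density above `N_max − 0.5` by default, keeping total
  mass 1 and making truncation conservative; a strict finite-interval mode
  exists for exactness testing and is the mode in which the
  "99.9% of density must fit" error applies (in absorbing mode nothing is
  discarded, so the guard would be vacuous). With SE = 0 the limit of the
  rule is a point mass on the nearest integer ≥ 1, ties rounding half up.
  Whether interval probabilities should be renormalized after truncation is
  not settled; profiles are likelihoods, so we leave them unnormalized and
  normalize only posteriors.
- **Sequence counts** (`sequence_min_profile`): `n` distinct sequences are
  a lower bound; states `< n` get 0, states `≥ n` get 1. A count of 0 is
  uninformative and additionally allows state 0.
- **Missing** (`missing_profile`): all ones, including state 0. Failed
  assays are treated as missing — presence cannot be asserted from a failed
  amplification.
- **Exact counts** (`count_profile`): a point mass, zero allowed. This
  fourth type is this package's representation for assembly-derived copy
  numbers: none of the three assay-driven types can express an observed
  count of exactly 0, yet genome-based autosomal data contain real zeros.
  The simulator uses it for the autosomal categories, which also keeps the
  generative process and the fitted likelihood consistent in validation
  experiments.

Coefficients of variation (`summed_cv`) use the sample (n−1) standard
deviation, matching the small per-assay sample sizes (≈7–13 individuals)
such panels typically have.

## Likelihood, fitting, and intervals

`family_log_likelihood()` runs Felsenstein pruning leaf-to-root with a
per-edge `P(t) = exp(Qt)` chosen by the edge's class (`Matrix::expm`;
matrices are cached per unique (class, length) pair, and partial
likelihoods are rescaled per node to avoid underflow). The root prior is
uniform over the support (`1..N_max` without innovation, `0..N_max` with),
the least-informative choice; a point-mass alternative is available and is
what the simulation-validation experiments use, since there the generating
root state is known. Block fits (`fit_block`) maximize the summed
log-likelihood over families on the log-rate scale with bounds
`[1e-8, 1e3]` and a deterministic list of five log-spaced multistarts —
tied-parameter surfaces can be flat, and multistarts are cheap insurance.
One-dimensional problems use golden-section search directly. Likelihood
values that underflow to `-Inf` in extreme corners of rate space are
clamped to a large finite penalty so bounded quasi-Newton search can
proceed.

`profile_ci()` inverts the likelihood-ratio statistic:
`{θ : 2(logL_max − logL_profile(θ)) ≤ χ²₁(level)}`, re-maximizing the other
free rates at each profile point, bracketing by doubling/halving on the log
scale, and clipping the lower bound at 0 when the likelihood never falls
off toward zero rate.

`fit_model_space()` fits each enumerated model as the sum of its block
fits; blocks share no parameters, so fits are cached by (category set,
form, heterogeneity) — the ten partitions touch only 12 distinct category
subsets, i.e. 96 block fits for the full 6408-model space. BIC uses
`n` = the total number of gene families, identical for every model: models
are compared on the same data, and a per-block `n` would make BICs
non-comparable across partitions (a per-block mode exists for sensitivity
analysis). Ranking ties break by enumeration order, so output is
deterministic.

## Ancestral reconstruction and event expectations

`ancestral_marginals()` runs the inside–outside (up–down) pass: a node's
posterior is proportional to the product of its inside partial likelihood
and its outside vector, with per-node normalization cancelling the scaling
constants. A warning fires when any node puts more than `1e-4` posterior
mass on the boundary state — the sign that `N_max` should grow. MAP states
break ties toward the smaller copy number and flag the tie.

`expected_branch_events()` computes the expected number of births,
deletions or innovations on one branch conditioned on all data. The joint
posterior of the branch's endpoint states comes from the inside/outside
quantities and the branch's `P(t)`; within an endpoint pair `(a, c)` the
conditioned expectation is exact:
`E[N | a→c] = M[a,c] / P(t)[a,c]` with
`M = ∫₀ᵗ e^{Qs} R e^{Q(t−s)} ds`, where `R` holds the rates of the counted
transitions. `M` is read off the top-right block of
`exp([[Q, R], [0, Q]] · t)` — the block-matrix (Van Loan) construction —
so the pipeline stays fully deterministic; the Monte-Carlo stochastic
mapping sampler exists only as a test oracle. `model_averaged_events()`
weighs per-model summed expectations by BIC weight; models below `1e-8`
weight are skipped, a bias bounded above by the skipped weight itself.

## The simulator and the study fixture

`simulate_branch()` is an exact, ensemble-vectorized Gillespie simulator of
the *uncapped* process: keeping the generative process exact deliberately
exposes truncation bias in the inference, which the validation suite
exploits (comparisons against the truncated chain must use an `N_max`
large enough that boundary mass is negligible). `simulate_dataset()` gives
each family its own deterministic substream of the global seed, so adding or
reordering families never perturbs other families' draws, and per-branch
event logs satisfy exact flux conservation (births − deletions +
innovations = state change).

`study_fixture()` emulates the motivating study's data shape: a 17-leaf
tree (human, chimp, nine macaque species, six of them with a second
intra-specific sample), calibrated at 6 My (Hominini), 30 My (root) and
8.5 My for the macaque crown — the latter a declared stand-in, since the
real study calibrated 8.5 My at the papionin divergence and published no
macaque-internal ages; remaining internal nodes come from the
deterministic proportional-depth interpolation of
`build_calibrated_tree()`. Autosomal families are observed as exact counts
only at human/chimp/rhesus (the other macaques' autosomal cells are
missing); Y singletons are observed as unique-sequence counts at every
leaf; ampliconic families are observed by qPCR with per-assay SEs drawn
uniformly from 0.05–0.5, the scale such panels report. Default rates make
the ampliconic category fast (λ = 0.13 per copy per My, the reported
magnitude of ampliconic turnover) and the autosomal categories 1–2 orders
slower, with modest Hominini acceleration. A simulated family that
outgrows `N_max` is excluded with a message rather than truncated,
mirroring how an exceptionally amplified outlier family is dropped from a
real analysis; a noisy qPCR mean drawn just above `N_max` for an in-range
count is clamped to `N_max`, which the absorbing top interval makes exact.

Defaults are `N_max = 50` for autosomal-scale analyses and 25 for
msrY-scale ones (the fixture's default); the boundary-mass warning above
is the guard against choosing them too small.

What the fixture does *not* emulate: gene conversion and its homogenizing
effect on paralogs, linkage among msrY families (families are independent
in both simulator and likelihood), multi-copy jump events, amplification
efficiency artifacts, and ascertainment of families. Passing validation on
fixtures therefore demonstrates correctness of the inference machinery
under the model's own assumptions, not robustness to these violations.

## Validation design and problem sizes

The verification suite (and `scripts/acceptance.R`, which recomputes it
end-to-end and writes JSON) is built on independent oracles:

- pruning versus exhaustive enumeration over all internal-node states
  (trees of 2–5 leaves, `N_max ≤ 4`, 100 random draws, agreement to
  `1e-10`);
- transition matrices versus the two-state closed form
  (`P₀₀(ln 2) = 0.625` at `i = d = 1`), row-stochasticity (`1e-10`) and
  Chapman–Kolmogorov (`1e-8`);
- the Gillespie simulator versus `exp(Qt)` rows (total variation < 0.02 at
  10⁵ replicates — the repository's central cross-validation loop, since
  simulator and matrix exponential are implemented independently);
- profile-CI coverage: 40 replicate datasets of 500 families simulated
  under `L` with λ = 0.13 on the fixture tree, coverage expected ≈95%
  (accepted at ≥88%);
- model recovery: 20 fixtures with tenfold-faster ampliconic rates, an
  AG-separating partition must rank first in ≥80% (run at reduced
  model-space scale — form `L`, no lineage heterogeneity — which leaves the
  partition structure fully identifiable while keeping the experiment
  proportionate);
- conditioned event expectations versus rejection-sampled stochastic
  mapping on 20 random two-leaf instances (3·10⁵ proposed histories each).
  A hard per-instance 2-standard-error bound across 20 independent
  standard-normal deviates would reject a *correct* implementation about a
  third of the time, so the suite applies the calibrated equivalent: at
  least 90% of instances within 2 SE and every instance within 3 SE, with
  a Poisson floor on the SE estimate for rare-event cases;
- qPCR threshold profiles versus numerical integration of the Normal
  density (1000 random (mean, SE) pairs, `1e-9`).

These sizes keep the whole suite within a few minutes on one core while
leaving wide statistical margins; they are stated here so that anyone
scaling them up knows what was actually run.

## Known limitations

- The time unit is My throughout by default. Rates per generation are an
  explicit, logged conversion (`convert_time_units`, 5 years/generation
  for primates); nothing converts silently, because published rate tables
  are ambiguous between the two conventions often enough that a silent
  default would be a trap.
- The chain is tridiagonal: no multi-copy duplication bursts or
  chromothripsis-like jumps.
- Families are independent in the likelihood even where they are
  physically linked (msrY); BIC weights inherit that approximation.
- The root prior shape is a modeling choice, not data; both uniform and
  point-mass modes are exposed, and analyses sensitive to it should say
  which they used.
- `L_indI` is available but off by default, for the ancestral-plausibility
  reason above.
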