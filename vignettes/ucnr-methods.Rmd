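---
title: "Censored normal regression for qPCR differential expression: models and methods"
author: "UCNR package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored normal regression for qPCR differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(UCNR)
```

## The problem

RT-qPCR reports expression as a quantification cycle (Cq): the earlier the
amplification curve crosses the detection threshold, the more abundant the
target.  A reaction that never crosses the threshold before the instrument's
maximum cycle — the limit of detection (LOD) — is reported as
*undetermined*.  Undetermined values are not missing at random: they say the
true Cq is at least the LOD, i.e. the observation is **right-censored**.
Common pipelines either delete these wells or impute them (at the LOD, at
the target's maximum normalized value plus one cycle, or by k-nearest
neighbours), then normalize, then run per-target t-tests.  Deleting throws
information away; imputing fabricates data; and carrying a normalization
step's uncertainty silently into the tests distorts their size.

This package instead fits one latent linear model to the raw Cq values in
which undetermined wells enter the likelihood as censoring terms, so
normalization and differential expression testing happen simultaneously and
the undetermined wells contribute exactly the information they carry.

## The model

Let $C^*_{ijk}$ be the latent Cq of target $i$ in sample $j$ of group $k$;
the instrument reports $C = \min(C^*, \mathrm{LOD})$.  The latent process
is modelled as

$$C^*_{ijk} = \mu + \alpha_i + \beta_j + (\alpha\gamma)_{ik} +
  \varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma_i^2),$$

with a per-target noise scale $\sigma_i$ (heteroskedastic by default; a
common-$\sigma$ option exists for small designs).  $\beta_j$ is a
per-sample technical effect — a normalization factor — and the
target-by-group interactions carry differential expression.  An expressed
well contributes a normal density term, an undetermined well the survival
probability $1 - \Phi\{(\mathrm{LOD} - m)/\sigma_i\}$ of its latent mean
$m$; survival terms are evaluated on the log scale, stable to standardized
distances of $\pm 40$.

For reference-gene normalization the model becomes

$$C^*_{ijk} = \mu + \alpha_i + \beta_j + R_i \zeta_j +
  (1 - R_i)(\alpha\gamma)_{ik} + \varepsilon_{ij},$$

where $R_i$ flags reference genes: they get per-sample effects
$\zeta_j$ instead of group interactions (they are assumed non-differential),
and $\mu + \beta_j + \zeta_j$ is the per-sample normalization factor.

### Identifiability and the meaning of $\delta$

As written the model is over-parameterized.  The package fits one fixed
full-rank coding — $\alpha$ sums to zero over targets, $\beta$ sums to zero
within each group, first-group interactions are zero, $\zeta$ sums to zero
over samples — and reports only estimable functionals, which are invariant
to this choice (a property the test suite checks by refitting permuted
datasets).

The per-target log2 fold change $\delta_i$ (one Cq cycle = one log2 unit;
lower Cq = higher expression) is defined relative to the normalization the
variant implies:

* **Global variant.** Global-mean normalization cannot distinguish a
  group-level shift common to all targets from technical variation, and
  attributes it to the factors.  Consequently $\delta_i$ is the target's
  latent group difference *centered over targets*.  With no censoring this
  reduces exactly to the group-mean difference of MOD-normalized values
  (verified to $10^{-6}$ in the tests), and the identifying assumption is
  the usual one for global-mean methods: differential expression is
  balanced across the panel.  The simulator follows suit by splitting
  injected effects equally between up- and downregulation.
* **Reference-gene variant.** $\delta_i$ is the target's group difference
  in excess of the reference genes' group difference (a $\zeta$ contrast),
  i.e. reference genes anchor the between-group normalization.

Estimates use the averaged design rows of the relevant cells, so they are
well defined under any coding; standard errors come from the corresponding
quadratic form in the observed-information covariance.

### Testing and intervals

$H_0: \delta_i = 0$ is tested with a generalized Wald statistic
$\hat\delta_i / \mathrm{se}_i$ against the standard normal (maximum
likelihood asymptotics).  The standard errors carry the
residual-degrees-of-freedom correction $\sqrt{N/(N-p)}$ by default
(`smallSample = TRUE`): ML noise estimates divide by $N$, and the
uncorrected Wald test is mildly anticonservative at small sample sizes;
the correction also makes the no-censoring Wald statistics agree with the
pooled-t statistics of the sequential pipeline.  `smallSample = FALSE`
gives the plain asymptotic errors, and a `df` argument switches the
reference to a t distribution.  Benjamini–Hochberg adjustment is
applied across targets (via `stats::p.adjust`).  Fold-change confidence
intervals for the selected targets use the false coverage rate
construction: with $R$ of $m$ targets selected at FDR level $q$, each
selected target receives a $1 - Rq/m$ normal-theory interval for $\delta$,
transformed to the linear fold-change scale as $2^{(\cdot)}$.

## Fitting: numerical choices

* **Removal rule.** Targets whose overall censoring fraction reaches the
  removal threshold (default 0.8, the common practice for mostly-missing
  features) are removed before fitting and recorded with per-group
  censored counts.
* **Initialization.** Censored wells sit at the LOD; a sparse least-squares
  fit of this completed matrix initializes the mean parameters, and
  per-target residual SDs (floored at 0.05 cycles) initialize
  $\log\sigma_i$.  Deterministic, and close to the basin of attraction.
* **Two-stage optimization.** The heteroskedastic likelihood is unbounded:
  if the sample effects can interpolate one target's expressed wells, that
  target's $\sigma_i \to 0$ while the sample effects chase it (a degenerate
  spike, not a useful solution).  The optimizer therefore first fits a
  common-$\sigma$ model (which has no spikes), then releases the
  per-target scales from that solution; L-BFGS-B with the analytic score
  does the work, and Newton steps on the observed information (restricted
  to the subspace of inactive bounds, step length capped) polish the
  optimum to a gradient infinity-norm of $10^{-6}$ where the geometry
  allows.
* **Noise floor.** $\sigma_i$ is bounded below at 0.05 cycles — qPCR
  technical noise below a twentieth of a cycle is not measurable, and the
  floor keeps the degenerate spikes shallow.  A fit ending on the floor is
  a legitimate constrained optimum (convergence is judged by the KKT
  projected gradient) and is flagged with a warning; the floor is
  adjustable via `control$sigma_floor`.
* **One-sidedly identified cells.** If one group of a target has no
  expressed well at all, the likelihood increases monotonically in that
  group's latent mean: the MLE sits at infinity and any finite stopping
  point is arbitrary.  The package pins such a cell's reported mean at the
  plausibility boundary $\mathrm{LOD} + z_0 \hat\sigma_i$ with
  $z_0 = \Phi^{-1}(0.95^{1/n})$ — the smallest standardized excess under
  which observing all $n$ wells censored has probability at least 95% —
  via a strong quadratic pull added to the objective.  The covariance is
  still computed from the *unpenalized* observed information, so these
  targets keep their honest, very large standard errors.  The target
  remains in the fit (its censored wells inform the sample effects and its
  noise scale) and a note is attached.
* **Covariance.** Inverse of the observed information, computed by central
  differences of the analytic score with step $10^{-5}(1 + |\theta|)$.
  Parameters held at an active bound are treated as fixed (zero
  rows/columns): through the bound the likelihood is not at a maximum, so
  no asymptotic variance exists along that direction.
* **Degenerate designs.** With a single target the per-sample effects are
  confounded with the noise (the mean model would be saturated), so the
  design reduces to a two-group location model.  Single-sample groups are
  allowed for estimation but flagged low-information.

## Normalization factors

`modNormalize()` implements modified global mean (MOD) normalization: center
within each target (equal weight per target), then within each sample
around the mean over expressed targets — optionally only over the targets
expressed in every sample.  "Expressed" means uncensored; censored wells
are excluded unless explicitly imputed.  `lmnFactors()` returns the
model-based latent mean normalization (LMN) factors: under the global
variant $\hat\beta_j$ plus the group-average interaction (the part of the
group difference the normalization owns), under the reference-gene variant
$\hat\mu + \hat\beta_j + \hat\zeta_j$.  With no censoring and a common
noise scale the global LMN factors equal the MOD factors up to one additive
constant; under censoring the MOD factors are computed from a shrinking
subset of wells and drift, while the LMN factors keep using the censored
wells' likelihood contribution.

## Baseline pipelines

The three classical imputation strategies are provided as comparators,
each followed by per-target two-sample tests (pooled-variance t by
default, Welch or tie-corrected Wilcoxon rank-sum optionally) and BH
adjustment:

* **LOD**: impute undetermined wells at the LOD on the raw scale, then MOD
  normalize the completed matrix.
* **MNV+1**: MOD normalize the expressed wells, then fill each target's
  undetermined cells with its maximum normalized value plus one cycle
  (undetermined wells stay jointly "worst", as ties).
* **KNN**: MOD normalize, then fill cell $(i, j)$ with the mean of the $k$
  (default 10) nearest targets expressed at sample $j$; distances are
  Euclidean over pairwise-complete samples, rescaled by
  $\sqrt{J/n_\text{complete}}$.  When fewer than $k$ neighbours are
  expressed at a sample all available ones are used (with a warning).
  Distances are computed on the original normalized matrix, not updated as
  cells get filled.

## The simulator and the censoring sweep

`simulateCqExperiment()` draws data from the latent model itself: target
baselines uniform on 24–34 cycles (a typical miRNA panel range), per-sample
technical shifts $N(0, 0.8)$ centered within group (so they equal the
model's estimand), per-target noise scales uniform on 0.3–1.2 cycles, and
log2 effects of $\pm 2$ (a linear fold change of 4) injected into a random
40% of targets, split equally up and down.  The defaults mirror a
two-group study of 61 samples (39 + 22) on 50 targets.  What the simulator
does **not** emulate: amplification-efficiency differences, plate and
batch structure, heavy-tailed or skewed noise, correlated targets, and
technically failed wells; passing tests therefore demonstrate correctness
under the model's own assumptions, not robustness to violations of them.

`censoringSweep()` reproduces the stress experiment used to compare the
methods: starting from fully observed data it repeatedly censors the
current maximum uncensored Cq (ties together, so the LOD stays a strict
upper bound), refits every method, and records estimates, p-values and
removal events; `sweepSummary()` turns the trace into bias and RMSE
curves, and `robustnessProportion()` reports the fraction of a truly
differential target's wells that can be censored before a method first
fails to reject at the 5% level (raw p-values).  Steps where a method
itself fails are recorded as missing, not as acceptances.  Refitting at
every single step is the full design; the `stride` argument evaluates
every m-th step for desk-scale runs.

`nullifyGroups()` creates negative-control data by shifting one group of
every target until the MOD-normalized group means coincide; because the
two centering passes couple targets and samples, the shift is iterated to
a $10^{-12}$ tolerance.

## Data-driven LOD selection

`selectLod()` compares candidate LODs by refitting the model with the data
re-censored at each candidate and scoring a *fixed* evaluation set — the
wells below the smallest candidate, expressed under every candidate — by
cross-validated log-density: wells are split into folds (default 5), each
fold is held out of the fit (as missing, not censored), and held-out
evaluation wells are scored under the fitted means and df-corrected noise
scales.  Candidates above the true detection boundary admit late-cycle
noise into the likelihood and predict worse; candidates below it discard
informative wells and predict less precisely.  The cross-validation is
essential: scored in-sample, the same quantity is maximized by the
*smallest* candidate, because heavier censoring lets the fit concentrate
on the very wells being scored.  The criterion is a pluggable function for
users who want a different score.

## Problem sizes used in the checks

The test suite works at deliberately small scales chosen to finish on one
CPU: likelihood oracles on 2–4 targets; equivalence checks at 10 targets
and 40 samples; Monte-Carlo bias/RMSE and type-I studies at 50 targets
with 100–200 replicates; sweeps on 24 targets with stride-20 refits;
consistency checks up to 250 samples per group with single-digit
replicates.  The methods vignette states these as the package's own
choices for reproducible desk-scale verification; the same machinery runs
unchanged at larger sizes.

## Known limitations

* The Wald tests rely on ML asymptotics; at very small sample sizes they
  are mildly anticonservative (the null simulations at 20 samples per
  group sit near 6% rejection at nominal 5%), and the `smallSample`
  correction only partly closes the gap.
* Heavily censored targets approaching one-sided identification have
  essentially unbounded uncertainty; their reported point estimates follow
  the plausibility-boundary convention above and should be read as bounds,
  not estimates.
* The global variant's $\delta$ is defined relative to the panel average;
  panels with strongly unbalanced differential expression violate the
  identifying assumption, and removal of heavily censored targets shifts
  the average (visible as slow bias drift late in censoring sweeps).
  Reference-gene normalization avoids this when trustworthy reference
  genes exist.
* One observation per (sample, target) pair is assumed; replicate wells
  should be averaged (or modelled) upstream.
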