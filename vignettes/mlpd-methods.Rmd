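---
title: "Joint linear-programming discriminants for block-missing multi-source data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint linear-programming discriminants for block-missing multi-source data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpd)
```

## The problem

Multi-modality cohort studies routinely produce feature tables in which
whole modality blocks are absent for many subjects: every subject may have
regional MRI volumes, but an expensive second modality (PET, CSF assays)
exists only for a subset. The missingness is *block-wise* — a subject has
either all of a source's features or none — so entry-wise imputation is a
poor fit, and complete-case analysis discards much of the sample.

`mlpd` treats each observed combination of sources as its own
classification **task**: all subjects in a task share a feature set, and a
new subject is scored by the task that matches its availability pattern.
The package fits all tasks jointly, which is where the statistical gain
over task-by-task fitting can come from.

## Model and estimator

Within task $i$, the two classes are modelled as Gaussian with common
covariance: $x \sim N(\mu_{i1}, \Sigma_i)$ or $N(\mu_{i2}, \Sigma_i)$.
The optimal (Fisher) rule classifies by the sign of
$(x - \mu_i)^\top \Sigma_i^{-1} \delta_i$ with
$\delta_i = \mu_{i1} - \mu_{i2}$ and midpoint
$\mu_i = (\mu_{i1} + \mu_{i2})/2$. Rather than inverting an estimated
covariance — ill-posed when $p$ is not small relative to $n$ — the
discriminant direction $\beta_i \approx \Sigma_i^{-1}\delta_i$ is estimated
directly by constrained $\ell_1$-minimisation:

$$\hat\beta_i = \arg\min \|\beta\|_1 \quad \text{s.t.} \quad
\|\hat\Sigma_i \beta - \hat\delta_i\|_\infty \le \lambda_i ,$$

a Dantzig-type program that only assumes the *product*
$\Sigma_i^{-1}\delta_i$ is (approximately) sparse. `pooled_stats()` uses
the maximum-likelihood pooled covariance (divisor $n$, not $n-2$),
matching the sparse-discriminant literature this estimator descends from;
the difference is absorbed by a rescaling of $\lambda$.

The joint (multi-task) estimator couples the per-task programs through the
features shared between tasks. Because $(\hat\Sigma_i \beta_i)_k$ is an
estimate of the population mean difference of shared feature $k$, tasks
that share feature $k$ should agree about it. The joint objective is

$$\sum_i \|\beta_i\|_1 + \gamma \sum_{i<j}\sum_{k \in S_{ij}}
|(\hat\Sigma_i\beta_i)_k - (\hat\Sigma_j\beta_j)_k|,$$

subject to each task's own fidelity constraint. Three design points are
deliberate:

* **Penalty, not constraint.** The linking term is a $\gamma$-weighted
  penalty: at $\gamma = 0$ the program decouples exactly into independent
  single-task fits (verified to $10^{-6}$ in the test suite). A hard
  equality at zero weight would instead force agreement, the opposite
  behaviour.
* **Per-feature $\ell_1$ linking.** Agreement is encouraged feature by
  feature; an $\ell_\infty$ variant (one slack per task pair, penalising
  only the worst shared feature) is available via `link_norm = "linf"`.
* **All pairs.** Every task pair with a nonempty shared set is linked; the
  canonical two-task instance has a single pair.

Everything is piecewise linear, so the fit is one exact linear program:
each $\beta_i$ splits into nonnegative parts ($2p_i$ columns), each
fidelity constraint contributes $2p_i$ rows, each linked shared feature one
slack column and two rows. `build_joint_lp()` exposes this assembly with
labelled rows and columns; `solve_lp()` solves it with the two-phase
simplex in the `boot` package.

### The linking weight $\gamma$

$\gamma$ trades per-task fidelity against cross-task agreement. The
default, $\gamma = 1/\max_i p_i$, scales the linking sum (up to
$\min(p_i,p_j)$ terms) to be comparable to a single task's $\ell_1$ term;
it can be overridden or included in the cross-validation grid
(`gamma_policy` in the pipeline configuration). In our synthetic
experiments the fitted models are insensitive to $\gamma$ over two orders
of magnitude, and very large $\gamma$ (near-hard agreement) degrades the
scarce task rather than helping it — consistent with the observation below
that partially anchoring a Dantzig constraint set is not automatically
beneficial.

## Feature prescreening

Before fitting, obviously uninformative features are removed by two-sample
t-tests computed on training subjects only. The keep rules are
asymmetric. Each task screens its own features (pooled-variance t-test,
two-sided p-values); a task keeps feature $j$ if $p \le \tau$ in its own
screening **or in the screening of any task whose source pattern contains
its own**. For the canonical two tasks this is: task 1 (both modalities)
keeps $j$ iff $p^{(1)}_j \le \tau$; task 2 (first modality only) keeps $j$
iff $p^{(1)}_j \le \tau$ *or* $p^{(2)}_j \le \tau$. The modality-poorer
task thus keeps more features, borrowing significance from the richer
task, whose screening pools a different subject set. Ties $p = \tau$ are
kept (the boundary feature is evidence, not noise). $\tau$ defaults to
0.01 and is fixed, not tuned; the pooled-variance test is the default with
Welch behind a flag. Degenerate zero-variance features follow an explicit
contract: equal constant samples give $(t, p) = (0, 1)$, differing
constant samples $(\pm\infty, 0)$ with a warning.

The screening error "removed all features; raise tau" is raised rather
than silently refusing to fit: an empty model is a configuration problem
the analyst must see.

## Evaluation protocol

* **Stratified folds.** Outer k-fold partitions are drawn independently
  within every task × class stratum, so fold sizes within a stratum differ
  by at most one and each training set preserves the task and class
  composition. All assignments derive from one integer seed.
* **Nested selection.** Fidelity bounds (and optionally $\gamma$) are
  chosen by inner 5-fold cross-validation *within each outer training
  set*, re-running screening on every inner split — test subjects never
  touch p-values or parameter choices (asserted by recomputation in the
  test suite). The selection criterion is mean inner accuracy; ties break
  toward the smallest bounds (sparsest model), then the smallest $\gamma$.
  Parameter points whose LP is infeasible on any inner split are skipped.
* **Grids.** Log-equispaced, endpoints inclusive: 20 points on
  $[0.01, 1]$ for the single-task bound, 20 points on $[0.01, 10]$ per
  task for the joint fit (the upper endpoint matters: a scarce task can
  only lean on a linked task by loosening its own noisy constraint). The
  full per-task product is faithful but expensive; examples and tests pass
  coarser grids through the `grids` argument.
* **Metrics.** Accuracy, sensitivity (true-positive rate in the positive
  class) and specificity from confusion counts; a metric whose denominator
  is zero is reported as `NA`. Repetition $r$ of a repeated experiment
  uses seed `base_seed + r` and re-randomises both outer and inner folds;
  means and standard deviations are reported overall and per task.
* **Classification tie.** A score of exactly zero (including the all-zero
  discriminant) goes to the negative class — the conservative choice
  toward the majority class in the motivating cohort, and a deterministic
  contract for the degenerate fit.

## The synthetic generator

`sim_config()` / `simulate_dataset()` emulate the *statistical* structure
of a two-modality cohort: two-class Gaussian data with two feature blocks,
a sparse mean shift, controllable cross-block dependence, and block-wise
missingness. Cross-block dependence pairs feature $k$ of block 1 with
feature $k$ of block 2 through a shared latent factor with correlation
$\rho$, so the canonical correlations between blocks are exactly $\rho$
for each pair — matching the diagnostic (`canonical_correlation_diagnostic()`,
`plot_canonical_correlations()`) used to motivate joint fitting. A full
user-supplied covariance is also accepted.

Defaults are chosen once: pattern counts 76/126 (both blocks) and 91/100
(block 1 only) per class — the shape of the motivating cohort — at toy
feature scale 10+10 so the entire nested-CV suite runs in seconds;
$\rho = 0.7$ ("strong" cross-modality correlation); mean shift 0.5 on the
first five block-1 features, giving a Bayes accuracy of
`r round(bayes_accuracy(sim_config()), 3)` via the closed form
$\Phi(\Delta/2)$, $\Delta^2 = \delta^\top\Sigma^{-1}\delta$
(`bayes_accuracy()`). A full-scale design (93+93 features) is a
`block_dims` argument away.

What the generator does *not* emulate: real ROI-level intensity
distributions, inter-regional correlation structure within a block,
unequal class covariances, or informative missingness (availability is
independent of the features). Passing tests therefore certify the
estimator and protocol machinery, not clinical performance.

## Numerical choices

* LP backend: two-phase simplex (`boot::simplex`), iteration cap
  $50(\text{rows}+\text{cols})$, pivot tolerance $10^{-10}$. Degenerate
  vertices (exact-zero right-hand sides, tied ratio tests) can stall a
  simplex; `solve_lp()` retries with a deterministic relative relaxation
  of the bounds of at most $10^{-7}$, far below any comparison tolerance
  used here.
* Infeasibility (possible when $\hat\Sigma_i$ is singular and
  $\lambda_i$ too small) raises a typed condition that parameter tuning
  treats as "invalid point"; outright solver failure is an error carrying
  the solver status.
* LP solutions may be non-unique. Tests compare objectives and constraint
  residuals rather than raw coefficients, except where uniqueness is
  forced (identity-covariance cases, where the fit equals componentwise
  soft-thresholding of $\hat\delta$).
* Features are not standardised by default (`z-score` your table first if
  scales differ wildly); labels are recoded to $\pm 1$ internally with an
  explicit positive-class declaration.

## Verification problem sizes

The test and acceptance suites run at deliberately small scale, chosen so
the full suite completes in about a minute on one CPU: closed-form and
oracle checks at $p \le 10$ with 50–1000 random instances per property;
Bayes-consistency at $p = 10$, 500 subjects per class, 10 seeds;
the multi-task-versus-complete-case comparison at $p = 10{+}10$ with 40
complete-pattern and 500 single-block training subjects per class over 30
paired repetitions; protocol checks on the 76/126/91/100 pattern shape.

## Known limitations

* The direct joint LP is exact but not scalable: with many sources the
  number of tasks (and pairwise linking blocks) grows combinatorially.
  Decomposition methods for that regime are out of scope; the
  implementation is required to be *correct* for three or more tasks, not
  fast.
* At the verification scale above, the measured benefit of joint fitting
  for the scarce complete-pattern task is small — of the order of the
  repetition noise (the acceptance script reports the paired delta). This
  is a property of the regime, not a bug: with $n$ comfortably above the
  (screened) dimension, the complete-case single-task fit is already near
  its plateau, and improving a *subset* of the constraints of a Dantzig
  program (which is all cross-task linking can do) has little headroom.
  The advantage of joint fitting is expected to matter in the
  high-dimensional, correlated-feature regime of real cohorts, which
  desk-scale synthetic checks deliberately do not reproduce.
* Screening ignores feature correlations; a correlation-aware prescreen is
  a possible extension, not implemented.
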