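# mlpd: multi-task linear programming discriminant analysis

`mlpd` implements sparse linear discriminant classification for two-class
data collected from several feature **sources** (modalities) where whole
source blocks are missing for many subjects — the typical situation in
multi-modality neuroimaging cohorts, where e.g. every subject has regional
MRI volumes but only half have PET intensities. Instead of discarding
incomplete subjects or imputing whole missing blocks, the classification
problem is decomposed into **tasks**, one per observed combination of
sources, and all tasks are fitted **jointly by a single linear program**.

## The method

For task *i* with class means $\hat\mu_{i1}, \hat\mu_{i2}$, mean difference
$\hat\delta_i = \hat\mu_{i1} - \hat\mu_{i2}$ and pooled (maximum-likelihood)
covariance $\hat\Sigma_i$, the single-task linear programming discriminant
(SLPD) estimates the discriminant direction by constrained
$\ell_1$-minimisation with a Dantzig-type fidelity constraint,

$$\hat\beta = \arg\min_\beta \|\beta\|_1 \quad \text{s.t.} \quad
\|\hat\Sigma_i \beta - \hat\delta_i\|_\infty \le \lambda_i ,$$

and classifies a subject $x$ to the positive class iff
$(x - \hat\mu_i)^\top \hat\beta > 0$, where $\hat\mu_i$ is the midpoint of
the class means. The multi-task generalisation (MLPD) solves all tasks in
one program, coupling them through a linking penalty on the **shared
features** $S_{ij}$ of every task pair:

$$\min_{\beta_1,\dots,\beta_T} \sum_i \|\beta_i\|_1
 + \gamma \sum_{i<j} \sum_{k \in S_{ij}}
 \bigl| (\hat\Sigma_i \beta_i)_k - (\hat\Sigma_j \beta_j)_k \bigr|
 \quad \text{s.t.} \quad
 \|\hat\Sigma_i \beta_i - \hat\delta_i\|_\infty \le \lambda_i \ \ \forall i .$$

Since $(\hat\Sigma_i \beta_i)_k$ estimates the population mean difference of
shared feature $k$, the penalty makes the tasks agree about a quantity they
estimate in common, letting a data-poor task borrow strength from a
data-rich one while still selecting its own feature subset. With
$\gamma = 0$ the program decouples into independent SLPD fits. Everything
is piecewise linear, so the whole fit is one exact LP (positive/negative
variable splits, $2p_i$ fidelity rows per task, one slack per shared
feature).

The package also provides the surrounding protocol: two-sample t-test
feature prescreening with asymmetric keep rules (a task with fewer sources
keeps a feature if it is significant in *its own or a richer task's*
screening), stratified k-fold cross-validation by task × class, inner
5-fold grid selection of $\lambda_i$ (and optionally $\gamma$), and
accuracy / sensitivity / specificity reporting — plus a synthetic generator
of correlated two-block Gaussian data with block-wise missingness so the
whole pipeline is testable without any external data.

## Worked example

```r
library(mlpd)

cfg <- sim_config(seed = 42)        # two-block cohort with block-missing PET
ds  <- simulate_dataset(cfg)
ds
#> <multisource_dataset> 393 subjects, 20 features in 2 source(s)
#>   MRI: 10 features, available for 393 subjects
#>   PET: 10 features, available for 202 subjects
#>   classes: +1 (1) n=167; -1 (-1) n=226

tasks     <- decompose_tasks(ds)               # task 1: MRI+PET, task 2: MRI
screening <- screen_tasks(tasks, tau = 0.01)   # t-test prescreen on p-values
fit <- fit_mlpd(apply_screening(tasks, screening), lambdas = c(0.3, 0.3))
fit
#> <mlpd_fit> 2 task(s), gamma = 0.2
#>   task 1 [MRI+PET]: p = 4, lambda = 0.3, nonzero = 4
#>   task 2 [MRI]: p = 5, lambda = 0.3, nonzero = 5
#>   objective = 2.59741 (l1 2.51189 + gamma * linking 0.427582)
```

The fitted object is tidyverse-friendly: `tidy(fit)` returns one row per
(task, feature) coefficient, `glance(fit)` a one-row summary, and
`autoplot(fit)` a per-task coefficient plot. Subjects are scored by their
availability pattern:

```r
classify_mlpd(fit, newx, pattern = "MRI")
#> # A tibble: 3 × 3
#>   task_id  score label
#>     <int>  <dbl> <int>
#> 1       2 0.433      1
#> 2       2 1.89       1
#> 3       2 0.0447     1
```

A positive score places the subject in the positive class (e.g. the
progressive-MCI group); the score is the signed distance along the
discriminant direction from the class-mean midpoint. The full repeated
nested-CV protocol runs from a single call (or from a YAML config via
`run_pipeline()`, or the `exec/mlpd` command line):

```r
summary <- repeated_cv_experiment(ds, k = 10, method = "mlpd", reps = 30,
                                  base_seed = 1)
tidy(summary)     # mean/sd accuracy, sensitivity, specificity per scope
```

`bayes_accuracy(cfg)` returns the closed-form ceiling of the generating
model (0.783 for the default configuration), the oracle used by the
consistency checks.

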