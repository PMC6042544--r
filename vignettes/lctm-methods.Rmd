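---
title: "Latent class trajectory models in trajmix: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent class trajectory models in trajmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmix)
```

## The model

`trajmix` fits latent class trajectory models (growth mixture models) to
long-format repeated measures: each subject $i$ contributes observations
$y_{ij}$ at times $t_{ij}$, and belongs to one of $K$ unobserved classes
with prior probabilities $\pi_1, \dots, \pi_K$. Conditional on class $k$,

$$y_{ij} = x_{ij}^\top \beta_k + z_{ij}^\top b_i + \varepsilon_{ij},
\qquad b_i \sim N(0, B_k), \quad \varepsilon_{ij} \sim N(0, \sigma_k^2),$$

where $x_{ij}$ is a polynomial basis (default quadratic) in a transformed
time $t' = (t - 45)/10$ and $z_{ij}$ its leading columns. Integrating the
random effects out gives, per subject and class, a multivariate normal with
mean $X_i \beta_k$ and covariance $V_{ik} = Z_i B_k Z_i^\top + \sigma_k^2 I$,
and the marginal log-likelihood
$\ell = \sum_i \log \sum_k \pi_k\, \phi(y_i; X_i\beta_k, V_{ik})$.

Seven covariance structures form a ladder of assumptions about $B_k$ and
$\sigma_k^2$:

| Code | Description | $B_k$ | residual |
|------|-------------|-------|----------|
| A | Homoscedastic fixed effects | none | common $\sigma^2$ |
| B | Heteroscedastic fixed effects | none | class $\sigma_k^2$ |
| C | Random intercept | shared $1\times1$ | common |
| D | Random slope | shared $2\times2$ | common |
| E | Random quadratic, equal | shared $3\times3$ | common |
| F | Random quadratic, proportional | $\omega_k^2 B$ | common |
| G | Random quadratic, unrestricted | class $B_k$ | common |

The free-parameter count used in the BIC penalty adds per-class fixed
effects, $K-1$ mixing proportions, the covariance block
($q(q+1)/2$ entries shared, $K-1$ extra scales for F, $K$ blocks for G) and
the residual variance(s); for quadratic model F this is $5K + 5$.

### Identifiability conventions

A mixture likelihood is invariant to class relabelling, so fitted classes
are stored in canonical order of descending $\pi_k$, with the posterior
columns permuted to match; reports are thereby deterministic. For model F
the scales and $B$ are confounded ($\omega_k^2 B$ is unchanged by
$\omega \mapsto c\omega$, $B \mapsto B/c^2$), so the last canonical class is
pinned at $\omega_K = 1$. Mixing proportions are free probabilities on the
simplex (no membership covariates; stratified analyses are the caller's
loop). The default time transform $(t-45)/10$ centres mid-adulthood age and
rescales to roughly decade units so that the quadratic design is well
conditioned; any affine transform can be supplied, and trajectories are
always reported on the natural time axis.

## Estimation

`fit_lctm()` maximises $\ell$ by EM. The E step computes posterior class
probabilities $p_{ik}$ in log space (per-class Cholesky factorisations,
log-sum-exp across classes). The M step updates $\pi_k$ as posterior column
means and $\beta_k$ by posterior-weighted generalised least squares under
the current covariances; the covariance block is updated by a short BFGS
run on the expected complete-data objective, parameterised without
constraints (Cholesky factor with log-diagonal for $B$, logs for variances
and scales). A partial conditional maximisation from the current point is
sufficient for monotone ascent (generalised ECM), which the test suite
asserts on every fit. Because the objective depends on the data only
through per-pattern weighted residual scatter matrices, its evaluation cost
is independent of the number of subjects; subjects sharing an
observation-time pattern also share design and covariance factorisations,
which makes near-balanced designs (a common visit grid) fast.

Structures A and B bypass the optimiser: their M step is closed-form
weighted least squares with pooled (or per-class) residual variance.

**Initialisation and multi-start.** Start 1 clusters per-subject OLS
polynomial coefficients by k-means; subsequent starts draw random subjects
as cluster centres. All randomness is derived from `fit_config(seed=)`, so
refitting is bit-identical. The best converged start wins (ties to the
lowest start index); if no start converges the best is returned flagged,
because non-convergence is treated as an informative, reportable state —
the class-enumeration table carries explicit failure rows rather than
dropping candidates.

**Numerical safeguards.** Marginal covariances are factorised exactly when
possible; an escalating diagonal ridge (`ridge`, default `1e-8`) is applied
only as fallback. Degenerate solutions (a class proportion collapsing to
zero, or repeated factorisation failure) terminate a start with a
diagnostic status. Convergence is declared when the relative
log-likelihood change falls below `tol` (default `1e-6`).

**Tunable parameters.** `n_starts` (default 20) trades robustness against
time; `mstep_maxit` (default 10 BFGS iterations) trades per-iteration cost
against EM iteration count; neither changes the maximiser, only the path.

## The eight-step workflow

`run_lctm()` chains the steps; each is also callable alone.

1. **Scoping** (`step1_scoping`). A fixed-effects model at a provisional
   $K$ is fitted and per-subject residual profiles are polynomial-fitted.
   Under a fixed-effects truth, the across-subject variance of the order-c
   coefficient equals the within-subject noise level times the average of
   $[(X_i^\top X_i)^{-1}]_{cc}$. The noise level is estimated from the
   per-subject residual mean square *beyond* the subject polynomial, which
   is free of any smooth subject effect; this matters because the scoping
   model's own residual variance absorbs random-effect variance and would
   attenuate the signal. An order counts as present when the
   variance-inflation ratio exceeds a threshold (default 1.5) in any class;
   the suggestion is the highest present order. The traditional version of
   this step is a by-eye judgement of residual-profile shape; the numeric
   rule makes it reproducible, and it is overridable.
2. **Class enumeration** (`sweep_classes`): one fit per candidate $K$,
   lowest BIC marked, $BIC = -2\ell + p\log N$ with $N$ the number of
   subjects.
3. **Structure refinement** (`sweep_structures`): one fit per structure
   A–G at the chosen $K$, reported in ladder order.
4. **Adequacy** (`adequacy_report`): APPA (mean maximum posterior among a
   class's members; threshold 0.70), OCC (posterior odds over chance odds,
   $[\mathrm{APPA}_k/(1-\mathrm{APPA}_k)]/[\pi_k/(1-\pi_k)]$; threshold
   5.0), mismatch $\pi_k - N_k/N$ (sums to zero exactly), and relative
   entropy $E_K = 1 - \sum_{ik} (-p_{ik}\ln p_{ik})/(N \ln K)$ (threshold
   0.5). The logarithm base cancels in $E_K$; natural log is used. An empty
   class's APPA is *missing*, never zero, so collapse is distinguishable
   from poor separation. Modal-assignment ties break to the lower class
   index, deterministically. `select_favoured()` takes the lowest-BIC
   candidate whose criteria all pass, records an override when a lower-BIC
   candidate was passed over, and returns the lowest-BIC candidate flagged
   when nothing passes — the trade-off is surfaced, not automated away.
5. **Graphics** (`plot_data`): class mean curves, 95% predictive bands
   ($\pm 1.96\sqrt{z^\top B_k z + \sigma_k^2}$), and a seeded spaghetti
   sample, all as plain tables ready for any plotting layer.
6. **Discrimination** (`degrees_of_separation`, `envelope_residuals`). The
   separation statistic is the smallest pairwise Mahalanobis distance
   between class mean trajectories on a grid, under the
   $\pi$-weighted average marginal covariance, normalised by $\sqrt{T}$ so
   it does not grow mechanically with grid length:
   $DoS = \min_{k<l} d_{kl}/\sqrt{T}$. The choice of the min (rather than
   the mean) over pairs is a design decision — it is the conservative
   summary, zero exactly when any two classes coincide — and the raw
   pairwise matrix is exposed so other summaries can be formed. Envelope
   residuals bin residuals by exact observation time when the design has at
   most 12 distinct times, else by fixed-width bins (default 5 time units),
   and report posterior-weighted local means and SDs; bins below an
   effective weight floor (default 1) are missing, not zero. A max/min SD
   ratio above 1.5 across bins flags a class "non-parallel"
   (heteroscedasticity).
7. **Concordance** (`concordance_vs_categories`, `weighted_kappa`,
   `model_concordance`): cross-tabulation of modal classes against a
   conventional categorisation (default cut-points: the adult BMI bands
   18.5/25/30/35, configurable), with Cohen's kappa. Because latent classes
   are unlabelled, the kappa is maximised over all row-label permutations
   (exhaustive, exact for $K \le 8$). The default disagreement weighting is
   *quadratic*: on the published five-class worked example shipped with the
   package, quadratic weights on the printed tables reproduce the printed
   weighted-kappa values (0.182 and 0.52), whereas linear weights do not;
   all three schemes remain available. Classes under 1% of the cohort are
   flagged as advisory, never deleted — small classes can be clinically
   meaningful.
8. **Sensitivity** (`sensitivity_refit`): refits on subjects with at least
   $m$ observations, comparing proportions, aligned mean-trajectory
   deviation on the grid and cross-fit kappa. Subjects always contribute
   whatever observations they have (unbalanced likelihood, no imputation).

## The simulator

`simulate_trajectories()` draws class labels from $\pi$, random effects
from the class covariance and noise around the class polynomial, on a
scheduled visit grid (default 18, 35, 50, 62.5 years) with optional
per-visit independent dropout (retention default 1.0) and time jitter. It
returns the true labels and random effects, enabling
`recovery_experiment()`: simulate, refit, align classes to truth by the
agreement-maximising permutation, and report coefficient bias, assignment
kappa and (optionally) whether a BIC sweep finds the true $K$.

`scenario_aarp_like()` is the package's cohort-like default: five classes
with proportions 68/25/4/2.7/0.4% (normalised), quadratic BMI-like mean
curves rising from the low 20s into the high-20s/30s kg/m² obtained by
least-squares fits through class-typical values at the four visit ages, a
proportional (F) covariance and unit residual variance. It reproduces the
features that make real cohort analyses hard — strong imbalance including
a sub-1% class, overlapping curves — and deliberately omits others:
self-report measurement error and recall bias, informative dropout,
non-Gaussian outcome tails, and covariate-dependent class membership.
Passing recovery tests on it therefore demonstrates correctness of the
estimator under the stated generative law, not robustness to those
real-data violations.

## Problem sizes used in the test suite

The simulation-based tests run at sizes chosen to make their conclusions
sharp while keeping the suite practical to run routinely: recovery checks
use 2000 subjects with 4 visits per structure (single seeded replicate at
well-separated, ≥2-residual-SD class means, where estimator bias is the
only thing at stake); the class-enumeration consistency check uses 20
replicates of 500 subjects, enough for a binomial assessment of the
selection rate; the Monte-Carlo likelihood oracle uses $10^6$ draws on
2-subject instances, giving standard errors far below the differences that
would indicate an implementation error.

## Known limitations

* One outcome at a time; no joint or multivariate trajectories.
* No covariates in the membership or trajectory submodels; no
  classification-corrected three-step outcome modelling.
* Standard errors of parameters are not computed (the workflow's criteria
  do not use them).
* The EM ascent can terminate at local optima; the multi-start design
  mitigates but cannot eliminate this, which is why seeds, start
  diagnostics and convergence states are always recorded.
* Exhaustive kappa assignment search is limited to $K \le 8$.
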