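---
title: "Assessing distinctiveness from summary statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing distinctiveness from summary statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(manifestFL)
```

## The problem

A multidimensional instrument posits several dimensions that should each
be internally homogeneous but empirically distinguishable from one
another. The standard evidence for the latter is the Fornell–Larcker
criterion: for every pair of latent variables $X$, $Y$,

$$\mathrm{AVE}_x > \varphi_{xy}^2 \quad\text{and}\quad
  \mathrm{AVE}_y > \varphi_{xy}^2,$$

where $\mathrm{AVE}_x = \sum_i \lambda_{x.i}^2 / K_x$ is the average
variance extracted (mean squared standardized loading) and
$\varphi_{xy}$ the latent correlation. Evaluating it requires loadings
and latent correlations, which published articles often omit. This
package evaluates a *manifest* version of the same comparison from the
three statistics articles nearly always report: Cronbach's alpha per
dimension, the item count per dimension, and the correlation matrix of
the manifest composite scores (unweighted item means; sums give the same
correlations).

## The manifest criterion

Two substitutions, both classical, make the criterion computable from
summaries. Under essential tau-equivalence (equal loadings within a
dimension):

1. **Alpha-implied AVE.** The standardized alpha is
   $\alpha = K\bar r / (1 + (K-1)\bar r)$ with $\bar r$ the mean
   inter-item correlation; inverting it gives
   $\mathrm{AVE} = \alpha / (\alpha(1-K) + K) = \bar r$. `ave_from_alpha()`
   is the exact inverse of `standardized_alpha()` (a property tested to
   machine precision).

2. **Disattenuation.** The observed composite correlation $r_{xy}$ is
   attenuated by measurement error; dividing by
   $\sqrt{\alpha_x \alpha_y}$ recovers the latent correlation
   ("double correction"). The comparison performed is therefore
   $\mathrm{AVE} > r_{xy}^2/(\alpha_x\alpha_y)$ on both sides of the
   pair — i.e. the *squared* corrected correlation, which is what makes
   the double-corrected manifest criterion algebraically identical to
   the original criterion in the tau-equivalent population.

Real data are congeneric (unequal loadings), where alpha underestimates
reliability. Consequently the double correction *over*-corrects and
produces false violation alarms, giving an upper bound on violation
detection. As a counterweight, the **single correction** divides by
$\sqrt{\alpha_{\min}}$ only, which provably underestimates the latent
correlation and gives a lower bound. `assess_pair()` reports both and a
combined verdict:

* `distinct_certain` — both corrections met;
* `violation_certain` — both violated (the single correction, the lower
  bound, already flags it);
* `uncertain` — only the double correction flags a violation.

The fourth combination (double met, single violated) is mathematically
impossible because $r^2/\alpha_{\min} \le r^2/(\alpha_x\alpha_y)$;
`assess_pair()` treats it as an internal error. Corrected correlations
can exceed 1 in magnitude when the attenuation model is wrong or by
sampling error; they are compared as-is and flagged
(`overcorrected_flag`), never clamped, since clamping would silently
change decisions.

### Numerical ties

The decisions use strict inequalities, but an exact tie
$\mathrm{AVE} = \hat r^2$ is resolved as *met*, using an absolute
comparison tolerance of `1e-10`. This is not an idle corner case: the
default simulation grid contains $\varphi = 0.70$, where the
tau-equivalent pattern ($\lambda = 0.70$, AVE $= 0.49$) ties exactly.
Floating-point evaluation of algebraically identical expressions lands
on either side of such a tie depending on operation order, so without a
tolerance the decision at the threshold would be round-off
path-dependent. With the tolerance, the violation region is the open set
$\{\hat r^2 > \mathrm{AVE}\}$ and the tau-equivalent population curve
flips from met to violated between 0.70 and 0.72 on the grid,
identically for the true criterion and the double-corrected manifest
criterion. The tolerance is far below any substantively meaningful
difference (sampling noise in these quantities is orders of magnitude
larger).

Negative manifest correlations are handled by the squaring itself: the
criterion is sign-symmetric.

## The two-factor population model and the CFA fitter

`factor_model()` describes the standardized population: each indicator
loads on one of two factors, unique variance $1-\lambda^2$, factors
correlated at $\varphi$. Implied indicator correlations are
$\lambda_i\lambda_j$ within and $\lambda_i\varphi\lambda_j$ across
factors. The population composite correlation has the closed form
$\varphi\,\Sigma\lambda_x\,\Sigma\lambda_y / \sqrt{v_x v_y}$ with
$v = K + \sum_{i\ne j}\lambda_i\lambda_j$, cross-checked in the tests
against a brute-force quadratic form and against large-sample empirical
correlations.

`fit_cfa()` estimates the model from a sample correlation matrix by
minimizing the normal-theory ML discrepancy
$F = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) - \log|S| - p$.
Design choices:

* **Identification.** Factor variances fixed at 1 with all loadings
  free — the standardized-solution convention the AVE formulas assume —
  rather than marker-variable identification. Reported loadings are
  completely standardized, $\lambda_i/\sqrt{\lambda_i^2+\psi_i}$, so AVE
  is computed on the standardized solution. Data are generated
  standardized, and estimates are computed from the sample *correlation*
  matrix.
* **Optimizer.** `stats::optim` L-BFGS-B with an analytic gradient
  ($\partial F/\partial\Lambda = 2G\Lambda\Phi$,
  $\partial F/\partial\varphi = 2(\Lambda' G\Lambda)_{12}$,
  $\partial F/\partial\psi_i = G_{ii}$, where
  $G = \Sigma^{-1}(\Sigma-S)\Sigma^{-1}$), convergence controlled at
  `factr = 1e4` (about `2e-12` absolute on $F$), at most 500 iterations.
  Start values: loadings 0.7, $\varphi$ 0.3, uniquenesses 0.5; up to 5
  jittered restarts on failure, after which the fit is reported
  `converged = FALSE` rather than raised as an error.
* **Heywood cases.** Uniquenesses are bounded below at `1e-6`; fits
  resting on the bound are flagged (`heywood`) but retained, mirroring
  common SEM-package behavior.
* Fitting any population-implied matrix recovers the generating
  parameters to better than `1e-4` with discrepancy below `1e-10`
  (tested for all six design patterns at $\varphi \in \{0, 0.6, 0.9\}$).

## The Monte Carlo study

`simulation_config()` defaults encode the validation design: six loading
patterns mirrored across both factors, from the tau-equivalent
$(0.70, 0.70, 0.70)$ to the strongly congeneric $(0.45, 0.70, 0.95)$,
all with mean loading 0.70; a latent-correlation grid from 1.00 down to
0.00 in 51 steps of 0.02 (stored as integer hundredths so cell labels
carry no floating-point drift); sample sizes 250 and 1,000; 1,000
replicates per cell — 612 cells and 612,000 runs in total.

Per replicate (`run_replicate()`): one multivariate-normal dataset is
drawn (`MASS::mvrnorm`); the true criterion is evaluated from a CFA fit
(AVEs of the standardized solution, estimated $\varphi$); the manifest
criteria are evaluated from the sample standardized alphas of the two
item blocks and the sample composite correlation. Standardized (not
raw-covariance) alphas are used because the data are generated
standardized; the two differ only by sampling noise here. Non-convergent
CFA replicates are excluded from the true criterion's denominator only —
the manifest criteria need no fitting and use all replicates. Per-cell
convergence counts are reported. Per-replicate seeds are a deterministic
mix of the master seed and the cell coordinates (`replicate_seed()`), so
any cell is reproducible in isolation.

`population_decision_curve()` is the noise-free analytic counterpart:
all three criteria evaluated on population quantities. It pins down the
expected step locations (e.g. the tau-equivalent flip between 0.70 and
0.72) and the identity of the true and double-corrected curves under
tau-equivalence, against which the stochastic rates are checked.

**What the generator emulates — and does not.** It produces exactly the
population the criteria reason about: multivariate-normal, standardized,
simple-structure indicators with uncorrelated errors. Passing tests
therefore show the criteria behave as derived *under that model*. Real
instruments feature ordinal items, cross-loadings, correlated errors and
non-normality, none of which the generator emulates; the bounding logic
(true criterion between single- and double-corrected manifest criteria)
is derived from the reliability ordering and is expected, but not here
demonstrated, to be robust to such departures.

**Problem sizes.** The default tests and the acceptance script exercise
a scaled-down grid — all six patterns at
$\varphi \in \{0.50, \dots, 0.90\}$, $n = 1000$, 200 replicates per cell
(6,000 fits, well under a minute) — plus the full analytic curves; the
complete 612,000-run study runs unchanged via `run_grid()` or the CLI
(`simulate` subcommand) as a long job of a few hours on one CPU.
Bounding checks on simulated rates allow two binomial standard errors at
the cell's replicate count.

## Review utilities

`review_batch()` applies `assess_instrument()` across a list of
instrument summaries; an instrument "meets" the criterion only when
*every* pair is `distinct_certain` (uncertain pairs count as not-met in
the binary summary but are tallied separately). Among instruments with
at least one certain violation, the mean violated-pair fraction is
reported. `chisq_independence()` is the Pearson test *without* Yates
correction — the convention that reproduces the published journal
contingency statistic (1.19 on the bundled 5/4, 4/5, 8/15 table,
`review_table_counts()`). `compare_structure_by_verdict()` uses the
Student pooled-variance t (df $= n_1+n_2-2$), inferred from the reported
df of 39 with 41 instruments.

## Known limitations

* The alpha-implied AVE and the disattenuation are exact only under
  essential tau-equivalence; for congeneric data the package brackets
  the truth rather than estimating it, and the `uncertain` verdict is
  irreducible without raw data or loadings.
* The CFA fitter is deliberately minimal: two factors, simple structure,
  continuous indicators, ML from a correlation matrix, no fit indices
  beyond the discrepancy. It is not a general SEM engine.
* Rule-of-thumb correlation cutoffs (0.80/0.85/0.90) and the
  one-vs-two-factor chi-square difference test are outside the package's
  scope, as are MTMM designs.
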