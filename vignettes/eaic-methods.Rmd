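---
title: "Methods behind the extended AIC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the extended AIC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaic)
```

This vignette documents the statistical model behind the package, the exact
formulas implemented, the numerical and design choices made along the way,
and the limits of validity the user should keep in mind.

## 1. Model and problem

We observe an outcome $y$ and $p$ candidate regressors $X_1, \dots, X_p$ and
fit either a Gaussian linear model or a Bernoulli logistic model on a subset
(support) $A \subseteq \{1, \dots, p\}$, always with an intercept and by
unpenalized maximum likelihood. Write $l(A)$ for the maximal log-likelihood
of the model with support $A$. A generic information criterion is

$$\mathrm{IC}(A) = -2\,l(A) + w \cdot |A|,$$

minimized over candidate supports, where $w$ is a per-variable penalty
weight. The package implements (`criterion()`, `ic_penalty()`,
`ic_score()`):

| criterion | weight $w$ |
|---|---|
| AIC | $2$ |
| BIC | $\log n$ |
| RIC | $2 \log p$ |
| mAIC | $2 + 2\log(p/c)$, default $c = 1/2$ |
| mBIC | $\log n + 2\log(p/E)$, default $E = 4$ |
| EBIC | $\log(n)\,|A| + 2\gamma \log\binom{p}{|A|}$, default $\gamma = 1$ |
| EAIC | $2\,x_{p,\alpha}$ (below) |

The EBIC penalty is not linear in $|A|$, so it is handled as a
size-dependent penalty rather than a constant weight; the binomial
coefficient is computed as `lchoose(p, k)` to stay finite at large $p$.

## 2. Distribution of the best single-variable improvement

Under the null hypothesis that a variable is independent of the outcome
given the current model, the gain in maximal log-likelihood from adding it,
$\Delta l$, satisfies $2\Delta l \to \chi^2_1$ (Wilks). Equivalently
$\Delta l$ follows a Gamma$(1/2, 1)$ law with CDF

$$F(x) = P(\chi^2_1 \le 2x) = \operatorname{erf}(\sqrt{x}),$$

implemented as `half_chisq_cdf()` via `pchisq(2x, df = 1)`. With $q$
independent candidate variables the best improvement has CDF $F(x)^q$
(`family_max_cdf()`), and the probability that a selection procedure with
per-variable threshold $x$ admits at least one null variable — the
family-wise error rate — is

$$\mathrm{FWER}(q, x) = 1 - F(x)^q,$$

implemented as `asymptotic_fwer()`. Both are computed in log space
(`pchisq(..., log.p = TRUE)` and `expm1`) so that $q$ up to $10^6$ and
beyond loses no precision: $F(x)^q$ is the exponential of $q \log F(x)$,
never a literal power of a number rounding to 1.

Solving $\mathrm{FWER}(q, x_{q,\alpha}) \to \alpha$ asymptotically in $q$
gives the **critical bound** (`critical_bound()`)

$$x_{q,\alpha} = \log q - \tfrac12 \log\log q - \log(-\log(1-\alpha)) -
\tfrac12 \log \pi,$$

and the **EAIC** is the information criterion with weight
$w = 2\,x_{p,\alpha}$ (`eaic_weight()`). The bound needs $\log\log q$, so
$q \ge 2$ is required and $q \in \{2\}$ triggers a warning ($\log\log 2 <
0$ makes the asymptotic expression unreliable at such tiny $q$); `q = 1`
is an error. The convergence of the finite-$q$ FWER at the matched bound to
$\alpha$ is from below for small $\alpha$ and is verified in the test suite
at $q = 10^3$ and $10^6$.

At $\alpha_0 = 1 - e^{-1/\sqrt{\pi}} \approx 0.4312$
(`alpha_null_cancel()`) the last two terms cancel and the bound reduces to
$\log q - \tfrac12 \log\log q$.

## 3. Coincidence levels between criteria

Setting $2\,x_{p,\alpha}$ equal to another criterion's weight and solving
for $\alpha$ expresses that criterion as an EAIC at a specific error level:

* `alpha_ric(p)` $= 1 - \exp\!\big(-1/\sqrt{\pi \log p}\big)$ — the level at
  which EAIC = RIC. The package uses this exact closed form throughout
  rather than any rounded approximation of it.
* `alpha_maic(p, c)` $= 1 - \exp\!\big(-(c/e)/\sqrt{\pi \log p}\big)$ — the
  level at which EAIC = mAIC. The default $c = 1/2$ corresponds to an
  expected one spurious AIC selection per two candidate scans and gives
  levels near $0.05$ for $p$ in the hundreds, which is why the mAIC behaves
  like an approximate 5% FWER rule.
* `c_eaic(p, alpha)` inverts the previous relation: the mAIC constant that
  reproduces a given level.
* `alpha_bic_equiv(n, p)` solves $2\,x_{p,\alpha} = \log n$, i.e. the level
  at which the EAIC penalty equals the BIC's. The closed-form inversion can
  leave $(0,1)$ in double precision when $\log n$ is far outside the range
  of attainable bounds (for example tiny $n$ with huge $p$); that case is an
  explicit error rather than a silent 0 or 1.

The null behaviour of the BIC itself is summarised by `bic_fwer_approx(n,
p)` $\approx 1 - \exp\!\big(-p/\sqrt{\pi n \log(n)/2}\,\big)$, with
`exact = TRUE` giving $1 - F(\log(n)/2)^p$. Note the approximation's own
message: the BIC's FWER decays only when $p = o(\sqrt{n \log n})$. If $p$
grows proportionally to $n$ the exponent diverges and the FWER tends to 1,
not 0 — BIC is *not* FWER-consistent in the regime $p \asymp n$, despite
informal statements to that effect. The test suite pins both regimes.

All coincidence levels and the critical bound were verified against an
independent arbitrary-precision implementation (Python `mpmath`, 30
significant digits) and those values are frozen in the test suite at
tolerances of $10^{-10}$ or tighter.

## 4. The selection procedure

Exhaustive search over $2^p$ supports is infeasible, so candidates come
from a LASSO regularization path (`lasso_supports()`, backed by `glmnet`
with `nlambda = 100`): every distinct support along the path, always
including the empty (intercept-only) model, truncated at `dfmax` (default
100) variables. Each support is then **refitted without penalty**
(`fit_glm_support()`) before scoring. The refit is essential: shrunken
LASSO coefficients put the log-likelihood below its maximum by an amount
that depends on the penalty at which the support appeared, which would
corrupt likelihood comparisons between supports from different parts of the
path.

For the linear family the refit is least squares with the error variance
profiled at its MLE, so
$l(A) = -\tfrac{n}{2}\big(\log(2\pi\,\mathrm{RSS}/n) + 1\big)$ and
differences of log-likelihoods are exactly
$\tfrac n2 \log(\mathrm{RSS}_0/\mathrm{RSS}_1)$, the classical LR
statistic. For the logistic family `glm.fit` is run with `maxit = 100`;
under complete separation the fit is kept with `converged = FALSE` rather
than dropped, so such supports still compete (their likelihood is finite at
the iteration cap).

`select_by_criterion()` takes the argmin of the criterion over the refitted
candidates. Ties (within double-precision equality) break first toward the
**smaller support**, then toward the earlier path position — a
deterministic, parsimony-favouring rule. `select_variables()` wraps the
whole pipeline behind a data-frame interface, and `tidy()`, `glance()` and
`autoplot()` expose the per-candidate table, the one-line summary and the
score-versus-size plot.

Two diagnostics shortcut the full pipeline when only the null decision is
needed. `null_scan()` answers "would this criterion select anything at
all?" by comparing the best single-variable improvement with the
per-variable threshold; for the EAIC this is exactly the event
$\max_j \Delta l_j > x_{p,\alpha}$. The per-column improvements come from
closed-form scans rather than $p$ separate model fits: for the linear
family $\Delta l_j = -\tfrac n2 \log(1 - r_j^2)$ with $r_j =
\operatorname{cor}(y, X_j)$, and for the logistic family a vectorized
per-column Newton iteration (step length capped at 2 for stability under
near-separation). Both scans are exact maximum-likelihood computations and
are tested against `fit_glm_support()` at $10^{-8}$. At very large $p$
(the drivers switch this on at $p \ge 10^4$) a univariate screen
(`univariate_screen()`) first discards the fraction of columns least
correlated with the outcome; a test verifies the screened and unscreened
decisions agree, as the maximizing column always survives a
correlation-ranked screen.

## 5. The simulation generator

`draw_design(n, p, rho)` produces rows with a Toeplitz AR(1) correlation
structure, $\operatorname{cor}(X_j, X_k) = \rho^{|j-k|}$, via the recursion
$X_j = \rho X_{j-1} + \sqrt{1-\rho^2}\,\varepsilon_j$. This is a standard
stand-in for the local correlation of ordered predictors (neighbouring
genomic markers, adjacent spectral bands) while remaining exactly
controllable; it does not model heavy tails, heteroscedasticity or
long-range dependence.

Signal strength is specified as a **signal-to-noise ratio**,
$\mathrm{SNR} = \operatorname{var}(E[Y\mid X]) / \overline{\operatorname{Var}(Y \mid X)}$
(`empirical_snr()`), evaluated empirically on the drawn design so that the
realized difficulty matches the target regardless of $\rho$ or the sparsity
pattern. `calibrate_coefficients()` rescales a given coefficient direction
to hit the target:

* *linear*: closed form — SNR scales exactly as the squared scale factor,
  so $k = \sqrt{\mathrm{target}/\mathrm{SNR}(\beta)}$, with unit error
  variance and zero intercept;
* *logistic*: no closed form exists because the conditional variance
  $\mu(1-\mu)$ changes with the scale, so a damped Newton iteration with a
  finite-difference Jacobian solves the two-equation system
  $\{\mathrm{SNR}(k\beta, b_0) = \mathrm{target},\ \overline{\mu} = 1/2\}$.
  The second equation pins the intercept so that classes stay balanced —
  without it, large signals drift the prevalence and conflate SNR with
  class imbalance. Convergence to residuals below $10^{-6}$ is enforced and
  tested at targets spanning two orders of magnitude.

Replicate streams use counter-based seeds derived from the master seed by a
Lehmer-style mixing map, so that replicate $i$ is reproducible in isolation
and independent of how many replicates run before it; all generators save
and restore the caller's RNG state. `run_null_study()` reports the
Monte-Carlo FWER next to its analytic value; `run_full_study()` runs the
seven standard criteria plus an oracle (best support of the true size on
the path) and reports FWER, FDR, mean true positives and sensitivity, with
a capped redraw-on-failure policy (at most 1% of replicates) for the rare
degenerate draws.

## 6. Limitations

* **Independence.** The FWER calibration is exact (asymptotically) for
  independent candidate regressors. Correlation makes the effective number
  of tests smaller, so the EAIC is *conservative* under positive dependence
  — the $\rho = 0.5$ null studies land slightly below the nominal level —
  but there is no finite-sample guarantee under arbitrary dependence.
* **Asymptotics.** Both the Wilks $\chi^2_1$ law and the extreme-value
  expansion of $F^q$ are limits. At $n = 100$ the realized FWER of a
  nominal 5% EAIC is typically in the 0.04–0.06 range; at $n = 1000$ it is
  near the exact finite-$p$ value 0.040 (for $p = 100$). At very small $q$
  (warned at $q = 2$) the bound formula degrades.
* **Candidate set.** The criterion is minimized over LASSO-path supports,
  not all subsets. Supports the path never visits can never be selected;
  this is the standard trade-off for computational feasibility and is
  shared by every path-based selector.
* **EBIC form.** The EBIC is implemented in its
  $\log(n) k + 2\gamma\log\binom{p}{k}$ form with $\gamma = 1$. Other
  parameterizations exist; the chosen one is the standard consistent
  variant for $p$ growing polynomially in $n$.
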