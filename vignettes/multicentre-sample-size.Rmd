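---
title: "Sample size for block-randomised multi-centre trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample size for block-randomised multi-centre trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpwr)
```

## The model

`mcpwr` plans and simulates two-arm trials in which centre `j = 1..c`
contributes `n_j` subjects and the outcome of subject `k` on arm `i` follows
the random-intercept model

$$Y_{ijk} = \mu_0 + u_j + \mu\,1\{i = 2\} + \epsilon_{ijk},
\qquad u_j \sim N(0, \tau^2),\ \epsilon_{ijk} \sim N(0, \sigma^2),$$

all effects independent. The induced covariance is block-diagonal over
centres, $\sigma^2 I + \tau^2 J$ within a centre, and the intraclass
correlation is $\rho = \tau^2/(\tau^2 + \sigma^2)$. The treatment effect is
estimated by the difference of pooled arm means
$\hat\mu = \bar Y_{2\cdot\cdot} - \bar Y_{1\cdot\cdot}$, which is unbiased
even when a centre recruits for one arm only, and tested with the
normal-approximation Wald statistic $T = \hat\mu / \widehat{SE}(\hat\mu)$.
The normal reference (rather than a t or Satterthwaite correction) is
adequate for the sample sizes this package targets (hundreds of subjects);
very small trials are outside its scope.

Under this model

$$\operatorname{Var}(\hat\mu) = \sigma^2\frac{N}{N_1 N_2}
  + \tau^2 \sum_{j=1}^c \left(\frac{n_{1j}}{N_1}
  - \frac{n_{2j}}{N_2}\right)^2,$$

so only *within-centre treatment imbalance* lets the centre variance
$\tau^2$ leak into the precision of $\hat\mu$. With centre-stratified
permuted-block randomisation, complete blocks are exactly balanced; the
imbalance comes solely from each centre's final, possibly incomplete, block.

## The exact imbalance law

A block of length $b$ under $k\!:\!1$ allocation is a uniform draw from all
orderings with $kb/(k+1)$ arm-1 labels. If a centre's final block holds
$r \in [1, b]$ subjects, the arm-1 count $j$ among them is hypergeometric
(population $b$, $kb/(k+1)$ successes, draw $r$), and the squared imbalance
is $\Delta^2 = (j/k - (r-j))^2 \in [0, m^*]$ with $m^* = b^2/(k+1)^2$.
`imbalance_distribution()` tabulates this pmf exactly; distinct $(j)$
outcomes with equal $\Delta^2$ are merged, which is done on the integer key
$k^2\Delta^2 = (j(1+k) - kr)^2$ and is therefore exact, with no floating
tolerance in the support. The expectation is the plain mean
$E(\Delta^2\mid r) = \sum_\ell p(\ell\mid r)\,\ell$; for $k = 1$ it has the
closed form $r(b-r)/(b-1)$, symmetric in $r \leftrightarrow b-r$ and
maximal at the half block $r = b/2$.

The test suite checks the hypergeometric path against an independent oracle
that enumerates all $2^b$ label sequences (kept to $b \le 12$; the exported
`enumerate_block_tuples()` refuses $b > 20$, where enumeration stops being
sensible and the hypergeometric law is the only reasonable route).

## The four sample size formulas

Equating the null and alternative quantiles of $T$ and replacing each
centre's $\Delta_j^2$ by an expectation $E(\Delta^2 \mid r_j)$ gives, with
$A = ((q_{1-\alpha/2} + q_{1-\beta})/\mu)^2$ and
$S = \sum_j E(\Delta_j^2 \mid r_j)$,

$$N = A\left(\frac{\sigma^2 (k+1)^2}{2k} +
  \sqrt{\frac{\sigma^4 (k+1)^4}{4k^2} +
        \frac{\tau^2 (k+1)^2 \mu^2\, S}{(q_{1-\alpha/2}+q_{1-\beta})^2}}
  \right)$$

(`n_mc_general()`, for caller-supplied $S$). The named methods only differ
in $S$:

| method | assumption | $S$ |
|---|---|---|
| `n_lower()` | perfect balance | $0$ (classical formula) |
| `n_mc_equal()` | all centres equal, final-block size $r_1$ | $c\,E(\Delta^2\mid r_1^*)$ |
| `n_mc_unequal()` | $r_j$ uniform on $1..b$ | $c\,\overline{E(\Delta^2\mid\cdot)}$ |
| `n_upper()` | every centre stops at $r = b/(k+1)$ | $c\,E(\Delta^2\mid b/(k+1))$ |

For any design, $N_{lower} \le N_{unequal} \le N_{upper}$, and all four
coincide when $\tau^2 = 0$.

Numerical choices, made once and fixed:

* **Rounding.** Every method returns `n_total = ceiling(n_raw)`. No forcing
  to multiples of $k+1$ or of the block length: the formulas describe the
  variance of the *analysis*, and recruitment targets are typically set per
  trial anyway.
* **Equal-centres self-consistency.** $N$ and the final-block size depend on
  each other, so `n_mc_equal()` computes $N(r_1)$ for each candidate
  $r_1 \in 1..b$ and keeps the candidate minimising
  $\lvert (N(r_1)/c \bmod b) - r_1 \rvert$, evaluated on the *unrounded*
  $N(r_1)$ with real-valued modulus. Ties (within $10^{-9}$) are broken
  toward the smallest $N(r_1)$ — the cheapest design among equally
  self-consistent candidates. With $\tau^2 = 0$ all candidates give the same
  $N$, so the tie rule is the only thing exercised and the result is the
  classical size.
* **Quantiles.** Standard-normal throughout, matching the test used in the
  analysis.

## Estimators and degenerate data

`estimate_variance_components()` uses closed-form quadratic forms, not an
iterative REML/ML fit: $\hat\sigma^2$ averages the within-cell sample
variances over all (arm, centre) cells, and $\hat\tau^2$ averages over the
two arms the variance of centre means around the arm mean. Both are
non-negative by construction and match the textbook all-cells form when
every cell is complete. Because multinomial allocation can produce empty or
singleton cells, cells with fewer than two subjects are excluded from
$\hat\sigma^2$ (divisor = number of eligible cells) and empty cells from
$\hat\tau^2$ (divisor = non-empty centre count per arm minus one). The Wald
test plugs the *estimated* components and the observed per-centre counts
into the variance formula — the natural choice, since at analysis time the
true components are unknown; the calibration simulations confirm the
resulting test holds its nominal level at the planned sample sizes.
Rejection uses the strict inequality $\lvert T\rvert > q_{1-\alpha/2}$.

## What the simulator emulates — and what it does not

`simulate_trial()` generates data exactly from the model above: normal
centre effects and residuals, a fixed intercept `mu0` (default 0 — it
cancels from every contrast), and an independent permuted-block sequence
per centre, mirroring stratified randomisation. Subject-to-centre
allocation follows the three study-condition schemes: `equal`
(floor division, remainder to the leading centres), `unequal1`
(multinomial, equal cell probabilities) and `unequal2` (multinomial with
uniformly random, renormalised probabilities). Centres drawn with zero
subjects are *retained* — the number of centres is part of the design, and
empty centres simply contribute nothing to any estimator.

The generator reproduces the randomisation mechanics faithfully but is an
idealisation of real trials: outcomes are exactly normal and homoscedastic,
the treatment effect is constant across centres (no treatment-by-centre
interaction), recruitment is not staggered in time, and there is no
contamination of the control group, no dropout and no missing data. Passing
calibration tests therefore demonstrates that the formulas and the test are
internally consistent under the stated model, not that the model fits any
particular real trial.

Determinism: each replicate, and within a replicate each centre's block
sequence, draws its seed from the master seed, so results are reproducible
and independent of evaluation order; truncation of a centre's final block
keeps the leading prefix of a permuted complete block rather than
re-drawing, which is what "incomplete block" means operationally.

## Power engine and problem sizes

`estimate_power()` repeats allocate → simulate → test and reports the
rejection fraction with its Monte-Carlo standard error
$\sqrt{p(1-p)/n_{sim}}$; multinomial allocations are redrawn every
replicate. The package default is `n_sim = 10000`, which resolves power to
about $\pm 0.004$. The test suite and the acceptance script use a reduced
2,000-replicate mode ($\pm 0.009$) — ample for the three-standard-error
bands they assert — plus a handful of smaller smoke grids (300–1,500
replicates); these sizes are stated here as the package's chosen trade-off
between resolution and desk-scale runtime. Power claims for the formulas
are property-based by design: the unequal-centres size restores the planned
power band, the upper boundary is conservative, the classical size loses
power as $b$, $c$ and $\rho$ grow.

## Known limitations

* Fixed block length only; variable/random block lengths change the
  imbalance law and are not implemented.
* Two arms, continuous outcome, no treatment-by-centre interaction, no
  mid-trial sample size re-estimation.
* The equal-centres method's self-consistency search can sit on a plateau
  (several near-equal distances); the documented tie rule makes the result
  well-defined, but small perturbations of $c$ can move $r_1^*$ by one.
* The normal approximation of the test is asymptotic; for trials with tens
  of subjects the type-I error may drift from nominal.
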