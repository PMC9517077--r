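---
title: "Negative binomial areal models with spatially varying coefficients: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative binomial areal models with spatially varying coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsvc)
```

This vignette is the package's own account of the statistical machinery it
implements: the model ladder, the neighbourhood and prior choices, the
sampler, the saturated-DIC comparison, and the synthetic-data generator
used to exercise all of it. It also records the design decisions that were
genuinely open and the limitations a user should know about.

## The model ladder

For counts $y_i$ on $n$ areal units with covariates $x_{pi}$
($p = 1, \dots, P$, including the intercept), all three variants share the
negative binomial observation model with log link,

$$y_i \sim \mathrm{NB}(\mu_i, k), \qquad
  \mathrm{Var}(y_i) = \mu_i + \mu_i^2/k, \qquad \mu_i = e^{\eta_i},$$

and differ in the linear predictor:

* **nonspatial** — $\eta_i = \sum_p \beta_p x_{pi}$: a plain NB GLM;
* **besag** — adds one structured spatial random effect,
  $\eta_i = \sum_p \beta_p x_{pi} + u_i$;
* **svc** — every design column carries its own spatial modifier,
  $\eta_i = \sum_p (\beta_p + \beta_{pi}) x_{pi}$, so the working
  coefficient of covariate $p$ at unit $i$ is $\beta_p + \beta_{pi}$. The
  intercept's modifier doubles as the structured spatial effect, making
  the besag variant a special case.

The NB size parametrization (mean $\mu$, size $k$) is the dominant count
GLM convention; $k \to \infty$ recovers the Poisson. No exposure offset is
used: population enters as a covariate, which is how block-group crime
regressions are usually specified. Covariates are used exactly as
supplied — no silent standardization — so coefficients stay on
interpretable per-unit scales.

## The neighbourhood graph

Spatial structure enters only through a labelled graph $G = (V, E)$ over
unit centroids, built with the sphere-of-influence (SOI) rule: with $r_i$
the distance from unit $i$ to its nearest other unit, $i \sim j$ iff
$d(i,j) \le r_i + r_j$. Three small decisions close the rule's edge cases:

* **Tangency counts as intersection.** "Circles intersect" is read
  inclusively; ties are decided with an absolute tolerance of $10^{-9}$
  on floating-point distances. This makes the rule deterministic and
  matches the exact-arithmetic reading.
* **Coincident points are rejected**, naming the offending ids, rather
  than merged: $r_i = 0$ makes the rule degenerate.
* **Distances are planar Euclidean.** Geographic lon/lat must be
  projected upstream; block-group analyses work in a projected local
  frame. When only polygons are available,
  `read_geojson_centroids()` derives representative interior points
  (shoelace centroids) — whether true centroids or label points are used
  upstream is immaterial to the package, which accepts any planar
  coordinates.

A useful property of SOI graphs is that every unit is a neighbour of its
nearest neighbour, so no unit is isolated and every ICAR conditional is
well defined. Graphs serialize to a plain one-line-per-unit adjacency
dialect (`write_graph_file()` / `read_graph_file()`, 1-based indices, the
common spatial-graph exchange format), and the round trip is exact.

## ICAR fields and constraints

Each spatial surface is an intrinsic CAR (Besag) Gaussian Markov random
field: $\beta_i \mid \beta_{-i} \sim N\!\big(\tfrac1{n_i}\sum_{j: j\sim i}
\beta_j,\ (n_i\tau)^{-1}\big)$, with joint log density (up to a constant)

$$\log \pi(\beta \mid \tau) = \frac{n - c}{2}\log\tau
  - \frac{\tau}{2}\sum_{i \sim j}(\beta_i - \beta_j)^2,$$

the sum over unordered neighbour pairs, equal to the quadratic form
$\tfrac12\beta^\top Q \beta$ with $Q = \tau(D - A)$. The rank is $n - c$
where $c$ is the number of connected components; the familiar "random walk
of order one with rank $n-1$" statement is the connected special case.
Because the null space is spanned by per-component constants, identifying
the intercept requires a **sum-to-zero constraint per component**, not one
global constraint. Constrained sampling (`ricar()`) works spectrally:
coordinates along eigenvectors of $D - A$ with eigenvalue
$\lambda_k > 0$ are $N(0, 1/(\tau\lambda_k))$, null coordinates are zero,
which lands exactly on the constrained subspace. During MCMC the
constraint is enforced by recentring each field within each component
after every sweep — the standard practice for intrinsic fields at this
scale.

## Priors

* **PC prior on every ICAR precision.** The penalized complexity prior
  for a precision is an exponential on the standard deviation
  $\sigma = \tau^{-1/2}$ with rate $\lambda = -\log(\alpha)/U$,
  equivalently a type-2 Gumbel on $\tau$:
  $\pi(\tau) = \tfrac{\lambda}{2}\tau^{-3/2}e^{-\lambda\tau^{-1/2}}$.
  `U` is the soft upper bound on the random-effect sd; the default is
  0.3 with 0.1 and 0.5 as first-class sensitivity presets. The tail
  probability `alpha` is not pinned down by the usual presentation of
  these priors, so the package uses the conventional 0.01 as default and
  exposes it as a configuration knob.
* **Fixed effects**: $N(0, 10^4)$, the standard non-informative choice.
* **Dispersion $k$**: a wide Gamma(0.01, 0.01). No PC-style prior is
  assumed for the dispersion; a weak Gamma is the standard default and is
  swappable through `nbsvc_priors()`.

All log priors are finite on their domains and $-\infty$ outside; the
joint prior is proper in every block except the intrinsic fields, which is
why the per-component constraints matter.

## The sampler

`nbsvc()` runs an adaptive Metropolis-within-Gibbs sampler (compiled, via
Rcpp), with blocks per iteration:

1. **Fixed effects** — per-coordinate random walks early in burn-in
   (target acceptance 0.44), then a joint proposal using the accumulated
   empirical posterior covariance, Haario-style, scaled by
   $2.38^2/P$ with an adaptive global factor (target 0.23). The joint
   block matters because areal covariates are typically correlated.
2. **Each ICAR field** — single-site random-walk Metropolis with the NB
   likelihood term of the one affected unit and the ICAR full-conditional
   prior term in the acceptance ratio; then per-component recentring.
3. **Each precision $\tau_p$** — a log-scale random walk against the PC
   prior and the ICAR quadratic form (rank $n - c$), followed by a joint
   *(field, $\tau$)* rescaling move: propose $\tau'$ and rescale the
   field by $\sqrt{\tau/\tau'}$. The ICAR quadratic form is invariant
   under this map and its rank and Jacobian terms cancel exactly, so the
   acceptance ratio reduces to the likelihood ratio, the PC prior ratio
   and the proposal Jacobian. This move decouples the precision from the
   sticky single-site updates; without it, split-$\hat R$ on
   $\log\tau$ can sit far above 1.1 at practical chain lengths, with it
   the fits used in the package's checks reach $\hat R \lesssim 1.1$.
4. **Dispersion $k$** — log-scale random walk against the Gamma prior.

All proposal scales adapt in batches of 50 during burn-in only and are
frozen afterwards, so the post-burn-in kernel satisfies detailed balance.
Initialization is a crude moment fit: intercept at $\log(\bar y + 0.5)$,
other effects 0, fields 0, $\tau$ at $(1/U)^2$, $k$ at 1; extra chains
jitter the fixed effects. Chain $j$ runs under seed $\texttt{seed}+j-1$
through R's RNG, so runs are exactly reproducible. Split-$\hat R$ and a
Geyer initial-positive-sequence effective sample size are computed for
every scalar block. Posterior tables use type-7 empirical quantiles of
the pooled post-burn-in draws.

The per-unit **pseudo-t value** reported for svc fits is the posterior
mean of the total coefficient $\beta_p + \beta_{pi}$ divided by its
posterior sd — the convention that pairs naturally with reporting `b` and
`t` side by side; $|t| \ge 2$ (configurable) flags units with significant
spatially varying association. A degenerate constant draw set yields
`t = NA` rather than an infinite value.

## Saturated DIC

Model ranking uses the deviance information criterion based on the
saturated NB deviance

$$D = 2\sum_i\big[\log p(y_i \mid \mu = \max(y_i, \varepsilon), k)
      - \log p(y_i \mid \mu_i, k)\big],$$

with $\varepsilon = 10^{-10}$ flooring the saturated mean at $y_i = 0$
(the NB log-pmf at $y = 0$ tends to 0 as $\mu \to 0$, so the floor is
numerically safe and essentially unbiased). `Dbar` averages $D$ over
draws at each draw's $\mu$ and $k$; `D_at_mean` evaluates at the
posterior mean of $\eta$ and of $k$; $p_D = \bar D - D(\bar\eta, \bar k)$
and $\mathrm{DIC} = \bar D + p_D$. A negative $p_D$ is flagged, not
hidden.

Two behaviours of this estimator are worth knowing, both computed by the
package's own checks:

* Because the saturated term moves with the per-draw $k$, the dispersion
  contributes essentially nothing (in fact slightly negatively) to the
  plug-in $p_D$: an intercept-only fit shows $p_D \approx 0$ rather than
  the $\approx 2$ an ordinary (non-saturated) deviance would give.
* On data that are *exactly* negative binomial given the fields — which
  is what the synthetic generator produces — the nonspatial model can
  absorb unexplained spatially varying structure into a smaller fitted
  $k$, and since the NB deviance scale is proportional to $k$ this keeps
  its $\bar D$ near $1.2\!-\!1.4$ per unit regardless of signal. The
  svc model's extra fields then cost more effective parameters than the
  deviance they recover, so on such synthetic data the saturated DIC
  systematically prefers the simpler models, while the nonspatial and
  besag fits remain a near-tie (median $|\Delta \mathrm{DIC}| \lesssim 1$
  under a nonspatial truth). Real data, whose misfit the NB family cannot
  fully absorb, can behave differently. The acceptance script reports
  both the svc-lowest rate and the near-tie gap so this behaviour is
  measured, not assumed.

## The synthetic generator

`sim_scenario()` / `sim_areal_data()` emulate a block-group study of
roughly a hundred units: a jittered $\lceil\sqrt n\rceil$ grid (jitter
0.3 of the spacing, keeping the SOI graph connected in well over 95% of
seeds), seven covariates built from unit-variance ICAR draws through
monotone maps — population and median household income in thousands,
ethnicity shares through a logistic map sharing a latent field with
population (so local collinearity between them is present by design),
and small Poisson counts of alcohol outlets, tobacco outlets and
abandoned properties with spatially smooth log rates. Each covariate's
neighbour autocorrelation is positive (Moran-type statistic > 0.2) at the
default smoothness. Default fixed effects are patterned on the signs and
magnitudes familiar from published block-group crime regressions
(positive for population, ethnicity shares, outlets and abandonment;
negative for income, with income in thousands so its coefficient sits
near $-0.02$); the realism is cosmetic — ranges and scales, not a claim
of matching real ACS distributions.

Two generator calibrations deserve a note:

* **Field strength.** Each svc modifier field is scaled so that its
  *contribution to the linear predictor* has sd `field_sd` (default 0.3,
  the same soft bound the PC prior encodes), i.e. the field's own sd is
  $0.3/\mathrm{sd}(x_p)$. Putting sd 0.3 on the raw field of a covariate
  measured in the tens (income in thousands) would swing $\eta$ by
  $\pm 10$ and overflow the counts; calibrating on the predictor scale
  keeps modifier effects comparable across covariates, which is the
  substantive reading of "relatively similar effects" that motivates the
  0.3 bound in the first place.
* **Dispersion.** The default generating $k = 2$ gives clearly
  overdispersed counts (variance-to-mean ratios well above 1 at
  $\mu \approx 8$), which is the regime block-group crime counts live in.

The generator retains the full generating truth (fixed effects, fields,
$\eta$, $k$), and everything is reproducible from the scenario seed.

## What the checks do and do not show

The package's test suite closes the loop generate → fit → recover:
credible intervals for fixed effects achieve near-nominal coverage under
a nonspatial truth (50 replicates of 100 units), the fitted per-unit
log-risk surface correlates strongly with the generating one under an
svc truth, and a regional signal injected into one covariate's field is
localized by the pseudo-t values (the $|t|\ge 2$ rate inside the signal
region exceeds the outside rate by well over 20 percentage points).

Two limitations should temper interpretation on real data:

* **Per-covariate surface attribution is weakly identified.** With one
  observation per unit and $P$ simultaneous modifiers, the likelihood
  identifies the total surface $\eta$ well but can redistribute spatial
  variation among covariate surfaces, especially where covariates
  overlap spatially; posterior surfaces are strongly shrunk. Varying-t
  maps should be read as evidence about *where* an association varies,
  with the understanding that collinear covariates can trade signal
  locally.
* **Synthetic data are exactly NB.** Passing recovery and localization
  checks on generator output demonstrates the machinery, not that real
  block-group data satisfy the NB-ICAR generative assumptions; real
  misfit (zero inflation, outliers, non-smooth fields) affects both fits
  and the DIC comparison in ways the generator does not emulate.

## Problem sizes and budgets

The shipped checks use the scales at which the method is meant to run:
105 units (occasionally 40–100 for speed) with 2 chains of 5,000–6,000
iterations for single fits, 50 replicates for the coverage study and 20
per arm for the model-comparison study. A single svc fit at this size
takes a few seconds on one core; the entire suite runs in minutes.
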