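---
title: "Modelling metamemory confidence as Bayesian inference: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metamemory confidence as Bayesian inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimeta)
```

## The model

`bimeta` implements a Bayesian-observer account of metamemory monitoring.
On each trial an item has an objective memory strength
$m \sim N(\mu_m, 1)$; in recall tasks the item is recalled exactly when
$m > 0$. The observer never sees $m$. They receive a *processing
experience* $e \sim N(\mu_e, 1)$, correlated $\rho$ with $m$, and infer
their latent strength $\hat m$ by conjugate normal updating of a prior
belief $N(\mu_b, 1)$ about their own memory ability, with likelihood
$N(\hat m, \sigma_l^2)$:

$$E(\hat m \mid e) = \frac{e + \sigma_l^2\mu_b}{1+\sigma_l^2}, \qquad
  \mathrm{Var}(\hat m \mid e) = \frac{\sigma_l^2}{1+\sigma_l^2}.$$

Confidence is the posterior probability of success,
$\Phi\!\big(E(\hat m\mid e)/\sqrt{\mathrm{Var}(\hat m\mid e)}\big)$. The
posterior mean is a convex combination of experience and belief with
weights

$$P_\mathrm{exp} = \frac{1}{1+\sigma_l^2}, \qquad
  P_\mathrm{belief} = 1 - P_\mathrm{exp},$$

so $P_\mathrm{exp}$ is the single number summarising how much confidence
tracks trial-wise experience rather than a stable belief anchor. Reported
confidence on a continuous 0–1 scale is the posterior probability plus
$N(0, 0.025^2)$ reporting noise, clamped to $[0,1]$; on an $n$-point scale
the noiseless posterior probability is cut at the fixed criteria $i/n$
(bin $i$ is $[(i-1)/n,\, i/n)$, top bin closed).

Because $\mu_e$ and $\mu_b$ only enter mean confidence through one linear
combination, they are not identifiable; fitting uses the mean of the
confidence distribution,

$$M_\mathrm{conf} = \Phi\!\left(
  \frac{\mu_e P_\mathrm{exp} + \mu_b P_\mathrm{belief}}
       {\sqrt{1 - P_\mathrm{exp} P_\mathrm{belief}}}\right),$$

instead. Writing $A = \Phi^{-1}(M_\mathrm{conf})$ and letting $z$ be the
standardised experience deviation, the trial-level predicted confidence is

$$p(z) = \Phi\!\left(A\sqrt{\tfrac{1-P_\mathrm{exp}P_\mathrm{belief}}
  {P_\mathrm{belief}}} + z\,\tfrac{P_\mathrm{exp}}
  {\sqrt{P_\mathrm{belief}}}\right),$$

whose marginal mean over $z \sim N(0,1)$ is exactly $M_\mathrm{conf}$
(`canonical_cell_shift()`). The free parameters of a recall fit are
$(P_\mathrm{exp}, M_\mathrm{conf}, \mu_m, \rho)$.

In recognition, stimulus strength means are $\mp d'/2$, the type I
response is S2 when strength exceeds a criterion $C$, and $d'$ and $C$ are
plugged in from the observed hit/false-alarm rates (0 and 1 rates replaced
by $1/(2N)$) rather than fitted. Confidence is the posterior probability
that the response was correct; each stimulus-by-response cell carries its
own $M_\mathrm{conf}$, and S1-response inference mirrors the experience
axis. The printed source equations are typographically ambiguous about the
sign of $C$ in the S1-response trial-level form; the likelihood is immune
to this because each cell's shift absorbs $C$, $\mu_e$, and $\mu_b$, while
the generative layer adopts the axis-mirrored form in which $C$ enters an
S1 response with a positive sign. One consequence, noted rather than
hidden: the four cell means produced by a single generative
$(\mu_e, \mu_b, C)$ set satisfy a probit-space constraint
($A_{11}+A_{12} = A_{21}+A_{22}$), whereas fitting (like the recovery
studies) treats the four cells as free.

## Numerical design

**Discrete scales.** Cell probabilities are rectangles of the standard
bivariate normal in (experience deviation, strength deviation). They are
computed by composite Gauss–Legendre integration of the conditional normal
CDF, with segment width tied to $\sqrt{1-\rho^2}$; tests verify them
against brute-force 2-D integration to $10^{-6}$ and `pbvnorm()` against a
closed form on the diagonal. All $2n$ cells sum to 1 to $10^{-10}$.

**Continuous scales.** The reporting kernel has SD $\sigma = 0.025$, two
orders of magnitude narrower than the latent scale, so no fixed Hermite
rule in the experience variable can resolve the integrand (a 61-node rule
has central spacing around $0.4\,b$, where
$b = P_\mathrm{exp}/\sqrt{P_\mathrm{belief}}$ is the probit slope; the
integrand's width is $\sigma/\varphi$, as small as 0.06). The likelihood is
therefore discretised in *predicted-confidence space*: nodes $t_j$ with
weights $W_j$ represent the joint density of predicted confidence and the
conditioning event, and each trial's likelihood is
$\sum_j W_j\,\varphi_\sigma(r - t_j)$ plus censored masses at 0 and 1.
Node placement branches on $b$: below $0.2$ the density of $p$ is nearly a
point mass and nodes follow $N(a, b^2)$ in probit space; above, nodes sit
on a $\sigma$-resolving grid in $t$ with geometric grading toward the
edges, where the density of $p$ diverges integrably whenever $b > 1$.
Sub-grid edge masses are integrated separately in probit space (bounded,
Gaussian-tailed, no truncation error). Fitted gradients are analytic at
the node level and exact to the quadrature, verified against central
differences at $10^{-4}$ relative.

A reported value of exactly 0 or 1 is treated as censored — the mass of
the noise distribution beyond the boundary — which matches the simulator's
clamping rule exactly; the test suite checks simulator and likelihood
against each other at $10^6$ trials.

**Optimisation.** Bounded quasi-Newton (`optim`, L-BFGS-B) on transformed
coordinates: logit for $P_\mathrm{exp}$ and the $M_\mathrm{conf}$ cells,
$\tanh^{-1}$ for $\rho$ (bounded at $|\rho| \le 0.994$), identity on
$[-5, 5]$ for $\mu_m$. Ten restarts jittered (SD 1 on the transformed
scale) around method-of-moments starts: $M_\mathrm{conf}$ from mean
confidence, $\mu_m$ from probit accuracy, $\rho$ from the
confidence–outcome correlation. Fits are deterministic given
`options$start_seed`. The experiment harnesses pass fewer starts (3–4) to
500-trial fits purely as a runtime measure: at that size the likelihood is
sharply peaked and extra restarts were observed to change nothing.

**Degenerate data.** When every recall outcome is identical, $\mu_m$ and
$\rho$ are unidentifiable; `fit_bim()` drops them (reporting
`dropped_params`) and fits the confidence-only model. The recovery
harness instead keeps all four parameters
(`options$drop_degenerate = FALSE`) so that, as in the published recovery
study, degenerate datasets contribute scattered estimates to the
all-datasets correlations and are excluded only in the corrected ones.

## What the simulators emulate — and what they do not

The generators reproduce the stated generative world: unit-SD latent
distributions, bivariate-normal (strength, experience), fixed recall
criterion at 0, reporting noise 0.025 with clamping, equal-width discrete
bins, and, for recognition, per-cell canonical confidence with the
response region defined by the plug-in SDT geometry. Parameter ranges in
the harnesses default to the recovery-study ranges
($\mu_m \in (-2,2)$, $\rho \in (-.9,.9)$, $P_\mathrm{exp}, M_\mathrm{conf}
\in (.1,.9)$, $d' \in (-3,3)$, $C \in (-1,1)$).

They do *not* emulate features of real data such as item-level covariates,
serial dependence other than the explicit belief-updating extension,
response times, scale-use idiosyncrasies (e.g. verbal anchors), or
participant heterogeneity within a dataset. A green test therefore
establishes internal consistency of model, simulator, and fitter — not
that any empirical dataset follows the model.

## Belief updating

The extension keeps the confidence inference unchanged but lets the belief
prior evolve: after each trial the belief distribution is conjugately
updated using the trial's experience with a (much larger) likelihood SD
$\sigma_{lb}$ — 10, 15, or 20 in the simulation study, against
$\sigma_l = 1$, $\mu_e = 0.5$, initial belief $N(0,1)$, 100 trials, with
100 simulated participants averaged in the published figures (the test
suite uses 60 for runtime). The belief SD shrinks deterministically;
smaller $\sigma_{lb}$ shrinks it faster. The extended model is not
identifiable from confidence data, so detection works by fitting the
restricted model per contiguous block (`blockwise_refit()`): falling
fitted $P_\mathrm{exp}$ together with drifting $M_\mathrm{conf}$ across
blocks is the signature. In the belief-updating simulator the outcome
column is incidental (generated from the experience mean); the confidence
dynamics are the object of study.

## Transfer prediction across conditions

`transfer_predict_confidence()` implements the parameter-free prediction
used to test the inference assumption directly: fit one condition, invert
the noiseless confidence transform at each reported value (clamped to
$[0.001, 0.999]$) to a point estimate of the trial's experience deviation,
then recompute confidence under the other condition's independently
measured prior belief (a believed proportion correct, mapped through the
probit) with the source $P_\mathrm{exp}$. Point inversion — rather than a
posterior mean of $z$ given the noisy report — is a deliberate choice: at
$\sigma = 0.025$ the two differ negligibly, and inversion makes the
identity transfer exact. Experience deviations are centred by convention
($\mu_e = 0$), so the fitted belief location absorbs the non-identifiable
mean; `implied_prior_belief()` returns the source condition's belief under
that convention.

## Desk-scale choices in the acceptance run

The recovery and cross-correlation studies are reproduced at the sizes the
acceptance plan states: 1,000 datasets for the 10-trial recall recovery,
400 (of the original 1,000) for the 50-trial lower-bound check, 200–300
datasets for the 500-trial recognition and cross-correlation studies.
These sizes keep the full report inside a 20-minute single-CPU budget;
the Monte-Carlo standard error of a correlation estimate at these sizes is
well inside the stated acceptance bands.

## Known limitations

* Cross-correlation studies between fitted parameters and reference-model
  criterion summaries measure, in part, the noise of the estimators
  involved: the SDRM criterion spread implied by a parameter set is a
  deterministic monotone function of $P_\mathrm{exp}$ alone, so with exact
  fits the Spearman correlation between the two would be $-1$. Cleaner
  optimisation therefore pushes such correlations closer to $\pm 1$ than a
  noisier fitting pipeline would report; this package's values sit a few
  hundredths beyond the reference ones for exactly that reason.
* $\rho$ in recognition fits is estimated but flagged unreliable
  (`rho_unreliable`); its recovery correlation plateaus near .4–.5 even at
  500 trials, consistent with the published study.
* The quadrature is tuned for $\sigma_\mathrm{noise} = 0.025$; the
  constant is deliberately not exposed as a free parameter.
* The restricted SDRM shares this package's rectangle machinery; the
  model-comparison result (better cross-validated fit for the Bayesian
  model on its own data) is a well-specified-model property, not evidence
  about empirical data.
* Group-level inference (t tests, mixed models over fitted parameters) is
  out of scope; the package stops at per-dataset fits and study-level
  correlation summaries.
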