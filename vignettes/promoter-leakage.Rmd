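---
title: "Promoter leakage in a two-state auto-regulatory gene circuit: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter leakage in a two-state auto-regulatory gene circuit: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promleak)
```

## The model

`promleak` studies a gene whose promoter switches between two activity
states, $D_0$ and $D_1$, and whose product $P$ (mRNA and protein collapsed
into a single species) is synthesized in *both* states:

$$D_0 \xrightarrow{\gamma_1} D_1, \quad
  D_1 \xrightarrow{\gamma_0} D_0, \quad
  D_1 + P \xrightarrow{f} D_0 + P,$$
$$D_1 \xrightarrow{\lambda_1} D_1 + P, \quad
  D_0 \xrightarrow{\lambda_0} D_0 + P, \quad
  P \xrightarrow{d} \varnothing.$$

The smaller of the two synthesis rates is the *leakage* rate: residual
transcription from the nominally inactive state, as observed for basal
transcription at open promoters and TATA-box pre-initiation complexes.
The product feeds back on the promoter catalytically (the molecule is not
consumed), raising the $D_1 \to D_0$ propensity by $f$ per molecule. The
same reaction set covers both feedback signs: with
$\lambda_1 \gg \lambda_0$, $D_1$ is ON and the feedback is negative (the
product accelerates leaving the ON state); with $\lambda_0 \gg \lambda_1$,
$D_0$ is ON and the same reaction is a positive feedback (the product
accelerates entering the ON state). `feedback_labeling()` makes that
labeling explicit; ties are "constitutive" and reduce to a Poisson model.

Two standing assumptions, both standard for this model class: binding and
dissociation of the product at the promoter are fast, so feedback acts
directly on the switching rates; and transcription plus translation are one
step, justified when the protein lifetime is much longer than the mRNA
lifetime. Both assumptions are relaxed in the simulator's variants (below)
to confirm the conclusions do not depend on them.

All rates are normalized by the degradation rate (`normalize_params()`):
time is measured in product lifetimes and $d = 1$ throughout.

## The closed-form stationary distribution

The stationary copy-number law is a finite superposition of Kummer
confluent hypergeometric functions,

$$P(n) = \frac{gA}{n!} \sum_{m=0}^{n} \binom{n}{m} \lambda_0^{n-m}
  \left[(f+1)Q\right]^m \frac{(\alpha-1)_m}{(\beta-1)_m}
  {}_1F_1\!\left(\alpha+m-1,\ \beta+m-1;\ -Q\right),$$

with $\lambda = \lambda_1 - \lambda_0$, $R = \lambda - f\lambda_0$,
$Q = R/(f+1)^2$, $\alpha = 1 + \lambda\gamma_1/R$,
$\beta = 1 + (\lambda+\gamma_0+\gamma_1)/(f+1) - R/(f+1)^2$,
$g = (\lambda+\gamma_1+\gamma_0)/\gamma_1 - R/(\gamma_1(f+1))$ and
$A = e^{-\lambda_0}[g\,{}_1F_1(\alpha-1,\beta-1;fQ)]^{-1}$
(`derived_constants()`). At $f = 0$, $\lambda_0 = 0$ only the $m = n$ term
survives and the expression collapses to the classical two-state
(telegraph) law; the test suite verifies this reduction pointwise against
an independently coded evaluation of the classical formula.

Mean and noise come from the probability-generating function
(`generating_derivatives()`, `moments()`):
$\langle n\rangle = G'(1)$,
$\sigma_n^2 = G''(1) + G'(1) - [G'(1)]^2$, and the noise intensity
(squared coefficient of variation)
$\eta_n^2 = \sigma_n^2 / \langle n\rangle^2$. The prefactor
$Ae^{\lambda_0}$ appearing in $G'(1)$ and $G''(1)$ cancels the
$e^{-\lambda_0}$ inside $A$ algebraically; the code exploits the
cancellation rather than assuming it, and the dual-route tests (moments
versus direct summation versus master-equation moments, relative error
$<10^{-6}$) confirm the printed forms are mutually consistent.

## Numerical choices

**Kummer function.** ${}_1F_1(a,b;z)$ at $z < 0$ alternates and loses
roughly $|z|\log_{10}e$ digits to cancellation — fatal at the $z = -Q
\approx -40$ arguments the distribution needs. `hyp1f1()` therefore applies
the Kummer transformation ${}_1F_1(a,b;-|z|) =
e^{-|z|}{}_1F_1(b-a,b;|z|)$ and sums the resulting positive-argument
series, whose terms are eventually all of one sign; with periodic
rescaling tracked in log space this is accurate to $\sim 10^{-13}$
relative up to $|z| \approx 700$, which covers every regime the package
targets with double precision alone. Frozen 50-digit reference values in
the test suite pin the accuracy at $10^{-10}$ or better.

**Series assembly in log space.** The $m$-indexed prefactors of $P(n)$
(binomials, $\lambda_0^{n-m}$, Pochhammer ratios) individually overflow
double precision near $n \approx 100$; they are accumulated as logarithms
with explicit sign tracking and combined by a signed log-sum-exp. The
Pochhammer ratios are built by iterated products so that negative
parameters (reached in the $\lambda < 0$ regime) keep correct signs.

**Truncation.** `n_max = "auto"` is $\lceil\langle n\rangle +
10\sigma_n\rceil$ with floor 50, computed from the generating-function
moments; for the regimes studied this captures all but $\lesssim 10^{-8}$
of the mass. The pmf is renormalized after truncation and the residual
(typically $10^{-15}$–$10^{-8}$) is recorded in attribute `"residual"`.

**Degeneracy at $R = 0$.** $\alpha$ diverges as $R \to 0$, so
`derived_constants()` refuses parameter sets with $|R| \le 10^{-10}
\max(\lambda_1, \lambda_0, 1)$ and directs callers to the
master-equation solver. The constitutive case $\lambda_1 = \lambda_0$,
$f = 0$ (where $R = 0$ for the trivial reason that the promoter state is
irrelevant) bypasses the series entirely and returns the exact Poisson
law.

**The $\lambda < 0$ regime.** The derivation's domain of validity for
$\lambda = \lambda_1 - \lambda_0 < 0$ (positive-feedback labeling) is not
established. `product_pmf()` therefore attempts the closed form there,
validates it per call against the master-equation marginal, and silently
substitutes the marginal when total variation exceeds $10^{-6}$;
`modality_scan()` goes further and always uses the master-equation path in
this regime, so modality claims never rest on the unproven domain. The
path actually used is recorded in the `"path"` attribute/column.

## The master-equation oracle

`cme_steady_state()` is the package's independent ground truth: the
stationary null space of the truncated generator over states
$\{(D_s, n): s \in \{0,1\},\ n \le N\}$ (`cme_generator()`). Truncation is
*reflecting* — synthesis out of $n = N$ is suppressed — which keeps the
matrix a proper generator and its null vector a genuine probability
distribution. The null space is found by replacing one balance row with
the normalization constraint and solving the sparse linear system
(deterministic, exact to solver tolerance, no eigen-iteration). If the
boundary mass exceeds $10^{-8}$, $N$ doubles (up to three times) before a
truncation error is raised. Stationary flow balance (production =
degradation) and promoter-occupancy balance hold to $10^{-8}$ and are
tested as invariants.

The analytic and master-equation routes share no code beyond elementary
arithmetic, which is what makes their agreement (total variation
$< 10^{-6}$ across a 34-set grid spanning all the study regimes)
meaningful; in fact the observed agreement is $\sim 10^{-11}$, limited by
the linear solver.

## Exact simulation

`simulate_gene()` implements the direct-method Gillespie algorithm in C++,
using R's RNG so that a single `seed` argument makes runs bit-reproducible.
Each run starts from $(D_0, n = 0)$ and accumulates, after a burn-in
(default 10% of `t_end`; default `t_end` $= 10^5$ lifetimes, long enough
that the slowest promoter timescale $1/\gamma_0 = 10$ is sampled thousands
of times), a *time-weighted* count histogram, the log of maximal
constant-promoter segments with per-segment synthesis-event counts, and
per-channel event counters. Storing the full event path (~$10^7$ events at
figure-scale rates) is optional and intended for short runs.

Two variants probe the standing assumptions:

* **`slow_binding`** replaces the catalytic flip by explicit
  sequestration: binding $D_1 + P \to D_0{\cdot}P$ at $f n$ removes one
  free molecule; dissociation $D_0{\cdot}P \to D_0 + P$ at `k_off`
  returns it, after which $\gamma_1$ reactivates the promoter. This
  scheme is chosen so that the fast-dissociation limit provably recovers
  the baseline model (the bound episodes and the sequestered molecule
  vanish together), a limit the test suite checks at `k_off = 500`
  (total variation $< 0.03$ against the baseline law). Slow dissociation
  (`k_off` $\lesssim 1$) is the sequestration regime proper; the package
  checks the qualitative claims there (leakage still lowers noise).
* **`two_stage`** separates transcription and translation:
  $D_s \to D_s + M$, $M \to M + P$ at `k_p`, $M \to \varnothing$ at
  `d_m`, defaults `d_m = 5` (mRNA five times shorter-lived than protein,
  a typical ratio) and `k_p = d_m` (burst of one protein per transcript
  on average), which keeps the mean protein level equal to the one-step
  model's and isolates the effect of the extra noise stage.

## Burst statistics

Bursts are delimited by the promoter state, not by product-count
heuristics, because the dwell-time relations $\langle BF\rangle =
1/\tau_{OFF}$ and $\langle BS\rangle = k_{\mathrm{transcription}}
\tau_{ON}$ define them that way and simulated trajectories carry the
promoter state exactly. `empirical_burst()` uses only dwell intervals
lying entirely inside the post-burn-in window (clipped intervals would
bias the means), requires at least 10 complete ON periods, and counts
synthesis events per ON period from the reaction-channel log. Burst
frequency is reported as $1/\overline{\tau_{OFF}}$ — the defining
relation, which at $f = 0$ estimates $\gamma_1$ directly; the plain
transition rate per unit time (one burst per full ON/OFF cycle) is kept
as the separate `burst_rate` field since the two coincide only when
$\tau_{ON} \ll \tau_{OFF}$. Without feedback the OFF dwells are
exponential with rate $\gamma_1$, a property tested by Kolmogorov–Smirnov
on thousands of intervals.

At $f = 0$ the closed forms (`theoretical_burst()`) predict that leakage
changes neither burst size nor burst frequency — leakage synthesis happens
outside bursts. With feedback, leakage acts on bursting *through* the
product level: under negative feedback more product shortens the ON
dwells, shrinking burst size at constant frequency; under positive
feedback more product shortens the OFF dwells, raising burst frequency at
constant size. Both directions are checked as monotone trends over 5-point
leakage grids with multi-seed 3-standard-error bands.

## Scans and the compensation solver

`noise_vs_leakage_scan()` traces $\eta_n^2$ along a leakage grid either
freely or at fixed mean. The fixed mean is held by adjusting one of four
parameters (`solve_compensation()`): lowering $\gamma_1$, raising
$\gamma_0$, raising $f$, or lowering $\lambda_1$. The target mean is the
base model's mean at zero leakage, which anchors all four curves at a
common origin (the study leaves the fixed value unspecified; any other
choice shifts, but does not reorder, the curves). The compensating value
is found by bracket expansion plus `uniroot` at $10^{-10}$ tolerance; at
$f = 0$ the mean is algebraic,
$\langle n\rangle = (\lambda_0\gamma_0 + \lambda_1\gamma_1) /
(\gamma_0+\gamma_1)$, and the tests check the root-finder against the
closed-form solution to $10^{-8}$. Grid points whose target is
unattainable (e.g. leakage alone already exceeds the target mean) are
recorded as gaps, not errors. A deterministic 10% subsample of analytic
scan rows is re-verified against master-equation moments (attribute
`"audit"`).

Default grids follow the study ranges: leakage $0$–$25$ for the
no-feedback modality scan, $0$–$10$ for the feedback ones; the fixed-mean
noise scans here use $0$–$15$ (20 points) so that all four compensation
modes stay feasible up to the last grid point with the anchor mean of 20,
and free scans use $0$–$20$.

**Mode counting** (`count_modes()`) uses a committed convention, since no
formal peak definition exists for discrete laws: a mode is a strict local
maximum after (i) discarding entries below $10^{-4}$ of the maximum
(floating-point ripple in the analytic tail would otherwise register as
spurious modes) and (ii) merging plateaus (adjacent values within
$10^{-12}$) to their leftmost index, which makes ties — e.g. the exact
$P(4) = P(5)$ plateau of Poisson(5) — deterministic.

## What the tests do and do not show

All distributions and trajectories here are generated by the package
itself under the study's parameter regimes (synthesis rates up to 40 per
lifetime, switching rates 0.1–0.5, feedback up to 0.1); there is no
external data. The dual analytic/master-equation route guards against
formula and implementation errors, and the simulator is checked against
both — but everything remains within the model's assumptions. Real
expression data add extrinsic noise, cell-cycle effects, multi-state
promoters and measurement error, none of which the model represents;
passing tests show the mathematics and code are right, not that the model
describes any particular gene.

Problem sizes were chosen so the full dual-route grid stays at desk
scale: 34 parameter sets for oracle equivalence, $10^5$ lifetimes per
simulation ($\approx 5\times10^6$ events, giving total-variation
agreement $\approx 0.005$ against theory and $\sim$6000 bursts per run),
4 seeds per burst-scan point. The acceptance script
(`scripts/acceptance.R`) recomputes every headline quantity from scratch
at these sizes.

## Known limitations

* The closed form is unproven for $\lambda < 0$; the package treats the
  master equation as authoritative there (routing above), at the cost of
  a linear solve per evaluation.
* `theoretical_burst()` covers only $f = 0$; with feedback, burst
  statistics are simulation-only, as no closed form is available.
* The simulator's initial condition is fixed at $(D_0, 0)$; stationary
  summaries rely on the burn-in, which is ample for the study's rates but
  should be lengthened for switching rates far below $10^{-2}$.
* Truncation auto-sizing assumes the moments exist and the tail is
  sub-Poissonian beyond $10\sigma$; pathological parameter sets outside
  the studied regimes should set `n_max` explicitly.
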