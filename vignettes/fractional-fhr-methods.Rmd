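---
title: "Methods: the fractional-order FitzHugh-Rinzel model in fracFHR"
author: "fracFHR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fractional-order FitzHugh-Rinzel model in fracFHR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracFHR)
```

## The model

The FitzHugh-Rinzel (FH-R) neuron is a three-variable fast-slow extension of
the FitzHugh-Nagumo oscillator: a membrane voltage $v$, a recovery variable
$w$, and a slow modulation $y$ of the applied current. fracFHR studies its
commensurate fractional-order generalization, in which every state equation
carries a Caputo derivative of common order $\alpha \in (0, 1]$:

$$
\frac{d^\alpha v}{dt^\alpha} = v - v^3/3 - w + y + I, \qquad
\frac{d^\alpha w}{dt^\alpha} = \delta\,(a + v - b w), \qquad
\frac{d^\alpha y}{dt^\alpha} = \mu\,(c - v - d y).
$$

$I$ is the constant applied current; $\delta$ and $\mu$ are small rate
constants making $w$ slow and $y$ very slow. $v$ lives on a mV-like scale
and $t$ on a ms-like scale, but all constants are handled as plain
dimensionless reals — the scales are documentation, not a unit system. At
$\alpha = 1$ the model is the classical ODE; for $\alpha < 1$ the Caputo
derivative weights the entire past of each variable by a power-law kernel,
so the dynamics acquire memory. That memory is the scientific point: it
reshapes bursting into mixed-mode oscillations, lowers firing rates,
lengthens first-spike latencies, and shifts the stability boundary of the
unique equilibrium as $\alpha$ decreases.

Five canonical parameter sets ship as frozen constants
(`fhr_preset("I")` … `"V"`), all sharing $a = 0.7$, $b = 0.8$, $d = 1$,
$\delta = 0.08$ with per-set values of $c$, $\mu$ and $I$. They are code
constants rather than configuration files so that the analysis and the
tests cannot drift apart.

## The L1 solver and the memory trace

The Caputo derivative is discretized with the standard L1 scheme on a
uniform grid $t_k = k\,\Delta t$. The update for each variable is

$$
x(t_N) = \underbrace{(\Delta t)^\alpha\,\Gamma(2-\alpha)\,
  f(x(t_{N-1})) + x(t_{N-1})}_{\text{Markov term}}
 \;-\; \underbrace{\sum_{k=0}^{N-2}\bigl[x(t_{k+1}) - x(t_k)\bigr]
  \bigl[(N-k)^{1-\alpha} - (N-1-k)^{1-\alpha}\bigr]}_{\text{memory trace}} .
$$

Design choices worth stating explicitly:

* **Explicit stepping.** The field is evaluated at the previous step's
  state. This makes the scheme reduce *exactly* (bit-for-bit, not just to
  tolerance) to forward Euler at $\alpha = 1$, where
  $\Gamma(1) = 1$ and every memory weight vanishes — matching the fact that
  the classical model is the $\alpha = 1$ limit. No predictor-corrector or
  implicit variant is provided.
* **Full memory.** The history sum is never truncated; cost is
  $O(N^2)$ per variable, implemented in a small C++ kernel
  (`caputo_integrate(engine = "cpp")`) with a pure-R mirror
  (`engine = "r"`) that performs the same arithmetic in the same order —
  the two agree to machine precision and serve as mutual checks.
* **Memory accounting.** `memory_decomposition()` recomputes the Markov
  term and the memory trace by the direct weighted sum, so the identity
  `state = markov - trace` is a genuine consistency check on a stored
  trajectory; `memory_trace_series()` uses the exact algebraic identity
  (Markov term minus stored state) to produce per-step traces in $O(N)$.
* **Initial conditions.** The default start is
  `equilibrium + perturbation_scale * U(0,1)^3` with a mandatory seed
  recorded in every output. The default `perturbation_scale = 1` is the
  literal uniform-(0,1) perturbation; the convergence and dichotomy tests
  use `0.01` because a unit kick to the very slow variable $y$ (relaxation
  rate $\mu = 10^{-4}$/ms at most presets) cannot relax within any
  practical horizon, whereas the stability statements concern small
  perturbations.
* **Guards.** Any state component exceeding $10^3$ in magnitude (the
  attractors live within a few units) or going non-finite aborts with a
  typed condition carrying the step index; parameter sweeps record such
  points instead of failing.
* **Defaults.** $\Delta t = 0.1$ ms and a 2000 ms horizon; both are
  configurable everywhere.

### A step-size caveat near the stability boundary

Explicit schemes anti-damp weakly stable foci. Within roughly $0.01$ of the
critical exponent $\alpha^*$ the $\Delta t = 0.1$ discretization can
sustain a spurious finite-amplitude oscillation around an equilibrium that
is (fractionally) asymptotically stable: for set III at $\alpha = 0.95$
($\alpha^* = 0.9566$) the tail amplitude is $0.66$ at $\Delta t = 0.1$,
$0.32$ at $0.05$, and $2\times10^{-4}$ at $0.025$ — vanishing under step
refinement, which identifies it as a discretization artifact rather than a
subcritical cycle. Consequently the convergence cross-checks run either at
exponents a comfortable margin ($0.05$) below $\alpha^*$, where
$\Delta t = 0.1$ is adequate, or at $\Delta t = 0.025$ when probing
exponents close to the boundary.

## Equilibrium and stability machinery

Equilibria satisfy $w^* = (v^* + a)/b$, $y^* = (c - v^*)/d$ and the cubic
$F(v^*) = v^{*3} - 3 p v^* = q$ with $p = 1 - 1/b - 1/d$ and
$q = 3I - 3a/b + 3c/d$. Under condition (A), $bd < b + d$, one has $p < 0$,
$F$ is strictly increasing, and the equilibrium is unique for every $q$.
The root is extracted from the companion matrix of the cubic (robust as
$p \to 0$, unlike Cardano), and the real root is selected.

The Jacobian at the equilibrium depends on the state only through $v^*$.
Its eigenvalues are computed by two independent routes — the roots of the
characteristic cubic with closed-form coefficients, and a direct
eigendecomposition — and the package *enforces* their agreement to
$10^{-8}$ at every call (nearest-neighbour matching of the two root sets,
since real parts of different roots can cross during continuation). One
transcription subtlety: the closed-form linear coefficient is the sum of
the principal $2\times2$ minors,
$\delta - \delta b + \mu - d\mu + b d\,\delta\mu + b\delta v^{*2} + d\mu
v^{*2}$; the dual-route check pins this down against the Jacobian itself.

Stability in the fractional setting is the argument condition: the
equilibrium is asymptotically stable iff every eigenvalue satisfies
$|\arg\lambda| > \alpha\pi/2$. `n_index()` exposes
$n_i = \alpha\pi/2 - |\arg\lambda_i|$, the fractional analogue of a real
part. When a complex pair exists this yields a critical exponent
$\alpha^* = (2/\pi)\,|\arg\lambda_{\mathrm{pair}}|$; the equivalent closed
form $(2/\pi)\arccos\bigl[(\mathrm{tr}J - \lambda_1)\sqrt{-\lambda_1} /
(2\sqrt{-\det J})\bigr]$ is evaluated as an internal cross-check
(agreement to $10^{-6}$ enforced; the arccos argument is clamped to
$[-1, 1]$ only against roundoff). A value above 1 means stable for every
admissible $\alpha$; an all-real spectrum has no fractional Hopf threshold
and is reported as `NA`. For a saddle-focus of index 2 (negative real
eigenvalue plus an unstable pair) the same angle doubles as the necessary
chaos threshold $(2/\pi)\tan^{-1}(|\mathrm{Im}\lambda|/\mathrm{Re}
\lambda)$ — necessary, never sufficient, and flagged as such.

The trace of the Jacobian vanishes at $v = \pm\sqrt{1 - \delta b - \mu d}$
(written with $\mu d$ throughout; every canonical preset has $d = 1$, for
which the expression is often quoted with a bare $\mu$).
Mapping $F$ at these voltages back to the current gives the window
$(I_{\mathrm{low}}, I_{\mathrm{high}})$ outside which stability is
independent of $\alpha$. Two classical ($\alpha = 1$) Hopf locators are
kept deliberately distinct rather than reconciled: the `trace_zero` closed
form (which ignores the real eigenvalue's contribution and yields
$0.13892 / 3.16108$ at base parameters) and the `continuation` bisection on
$\mathrm{Re}\,\lambda_{\mathrm{pair}}(I) = 0$ (tolerance $10^{-8}$ in $I$,
yielding $0.138715 / 3.161285$). Their $3\times10^{-4}$ discrepancy is the
approximation error of the trace-zero form, and seeing both is
informative. The bisection brackets are windows of half-width $0.05$
around the trace-zero estimates: the true crossing always lies slightly
*outside* the $\alpha$-dependent window (the real eigenvalue shifts it),
so a bracket starting at $I_{\mathrm{low}}$ would not straddle the root.
The fractional Hopf curve $\alpha^*(I)$ is evaluated on a user grid, with
points masked where the cubic's discriminant is positive (all-real
spectrum; at base parameters this is roughly $I \in [0.7, 2.6]$).

## Coupled pair and synchronization

Two neurons sharing one parameter set are coupled electrically
(bidirectionally) through their voltages: $+\,g_e (v_j - v_i)$ in each
voltage equation. The stacked six-dimensional system goes through the same
L1 solver. The coupling term is computed even at $g_e = 0$, so a
decoupled pair is bit-identical to two single runs, and the symmetric form
makes the synchronization manifold $v_1 = v_2, w_1 = w_2, y_1 = y_2$
exactly invariant — both properties are asserted as exact in the tests.
Heterogeneous pairs are rejected.

Synchrony is quantified by the similarity function

$$
S^2(\gamma) = \frac{\langle (v_1(t) - v_2(t-\gamma))^2 \rangle}
 {\sqrt{\langle v_1^2 \rangle \langle v_2^2 \rangle}},
$$

with averages over the post-transient overlap window. Only $\gamma = 0$
feeds the complete-synchronization (CS) diagnostic; general lags are
implemented for completeness, in integer steps of $\Delta t$. Choices the
definition leaves open, fixed here once: the transient fraction discarded
before averaging is $0.5$; CS is declared at $S(0) < 0.01$ (the
qualitative statement is only that $S(0)$ approaches zero); sweep defaults
scan $g_e \in [0, 0.6]$ at 25 points with one independently seeded run per
point. A flat-zero signal makes the normalization undefined and is
reported as `NA` rather than silently zero.

## Spike metrics

A spike is an upward crossing of $v$ through a threshold (default $0.5$,
robust across $[0.3, 0.7]$ since the model's spikes have amplitude near
2), with crossings merged within a 2 ms refractory window. Firing rates
are counts per window in Hz; first-spike latency is the time of the first
crossing. The regime labels (`quiescent`, `tonic_spiking`, `bursting`,
`mixed_mode`) are deliberately heuristic: quiescence is the only label
tied to the analytic machinery (no post-transient spikes *and* terminal
state within tolerance of the equilibrium), and it is the label used in
the stability-dichotomy tests. Burst detection splits inter-spike
intervals at $5\times$ the median; the mixed-mode label (sub-threshold
local maxima interleaved with spikes) has no standard operational
definition and is validated only on constructed synthetic traces, never
used for quantitative claims.

## What the tests do and do not show

The test suite ties the simulator to the analytic machinery at the
quantities that are reproducible: printed equilibria, spectra, critical
exponents and Hopf currents (deterministic, desk-scale); the
Euler-equivalence, telescoping-weight and memory-trace identities
(exact); and the qualitative dichotomy — quiescent at
$\alpha^* - 0.05$, oscillatory at $\alpha^* + 0.05$ — for the four
saddle-focus presets, at $\Delta t = 0.1$ over 2000 ms with small
($0.01$-scale) seeded perturbations. Problem sizes were chosen so the
whole suite runs in well under a minute: 2000 ms horizons for regime
runs, 400 ms for the coupling-strength sweep trend, $10^4$ steps for
weight identities. Longer-horizon phenomena — the full elliptic-bursting
cycle at set I (whose silent phase develops on the $1/\mu = 10^4$ ms
scale), waveform-level reproduction of specific figures, and chaotic
regimes above $\alpha^*$ — are outside what these tests certify: the
burst/mixed-mode classifiers are therefore validated on synthetic traces
with known structure. Nothing in the suite exercises incommensurate
orders, networks beyond a pair, or limit-cycle continuation; those are
out of scope by design.

## Reproducibility

Every stochastic input is a uniform perturbation drawn from an explicit
integer seed recorded in trajectory metadata, CSV sidecars and run
manifests; identical seed and configuration give bit-identical
trajectories (asserted in the tests). The command-line interface
(`run_fhr_cli()`, or the `inst/cli/fhr.R` wrapper) exposes `simulate`,
`analyze`, `hopf-curve`, `couple`, `sweep`, `spikes` and `fixtures`
subcommands, each writing a `manifest.json` sufficient to regenerate its
outputs.
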