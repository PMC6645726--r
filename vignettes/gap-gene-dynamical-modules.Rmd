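---
title: "Dynamical modules in gap gene circuits: models, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical modules in gap gene circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapdyn)
```

## The model

`gapdyn` simulates and dissects connectionist gene circuit models of the
*Drosophila* trunk gap gene system. The state of nucleus $i$ is the vector of
gap protein concentrations $g_i^a(t)$ for $a \in G = \{hb, Kr, kni, gt\}$,
governed during interphase by

$$\frac{dg_i^a}{dt} = R_a\,\phi(u_a) - \lambda_a\,g_i^a, \qquad
u_a = \sum_{b \in G} w_{ba}\,g_i^b + \sum_{m \in M} e_{ma}\,g_i^m + h_a,$$

with the sigmoid regulation-expression function
$\phi(u) = \tfrac12\!\left(u/\sqrt{u^2+1} + 1\right)$. $R_a$ is the maximal
production rate (a.u./min), $\lambda_a$ the linear decay rate (1/min),
$w_{ba}$ the regulatory weight of gap gene $b$ on target $a$, $e_{ma}$ the
weight of maternal input $m \in M = \{Bcd, Cad\}$, and $h_a$ a basal
threshold. Maternal concentrations $g_i^m(t)$ are external, time-varying
inputs obtained by bilinear interpolation of tabulated spatio-temporal
profiles; they make each nucleus a *non-autonomous* dynamical system.

The model is hybrid in time: continuous dynamics through the C13 interphase,
a C13 mitosis during which production is shut off ($R_a = 0$), an
instantaneous nuclear division, and the C14A interphase, subdivided into
eight time classes T1–T8 of equal length. There is no diffusion, so the row
of nuclei decomposes into 41 independent four-dimensional systems covering
35–75% A–P position (164 state variables in total).

### Stage timing and the division rule

Published descriptions of this model class fix the cleavage-cycle structure
but not its exact minute values, which trace back to embryological staging
work. We therefore expose all durations as arguments of `stage_schedule()`
and default to $t=0$ at C13 onset, 16 min C13 interphase, 5 min mitosis with
division at its end, and 50 min C14A (classes of 6.25 min). Only the
relative phase structure matters for every analysis in the package; the
defaults just give the time axis concrete units.

Inheritance at division is likewise under-determined: we copy the mother's
concentrations to both daughters (the minimal assumption; protein
concentration, not amount, is the model's state variable). The 21 C13 nuclei
at 2% spacing yield daughters at $p \pm 0.5\%$, rounded half-up onto the
integer C14A lattice and clipped to 35–75%, which reproduces exactly the 41
C14A nuclei. Before division a C14A nucleus's maternal input is evaluated at
its mother's position, so row simulation and per-nucleus simulation agree to
machine precision.

## Numerical integration

The integrator is a purpose-built adaptive Cash–Karp Runge–Kutta 4(5) method
(compiled, one independent solve per nucleus) with relative tolerance
$10^{-8}$ and absolute tolerance $10^{-10}$ by default, and *exact* stops at
phase boundaries and output times so the mitosis production switch is never
smeared across a step. The dynamics are non-stiff at these parameter scales
($\lambda^{-1} \approx 10\text{–}20$ min against a 71-min horizon), so an
explicit embedded pair is appropriate. The test suite cross-checks the
integrator against closed-form decay solutions and against an independent
`deSolve::lsoda` run through the package's plain-R right-hand side.

A compiled integrator matters because the analyses are integration-hungry:
basin-of-attraction censuses use $20^3$ initial conditions per circuit,
phase diagrams classify thousands of parameter cells, and the fitting
objective re-simulates all 41 nuclei at every evaluation.

## Phase-space analysis

Instantaneous phase portraits "freeze" the maternal inputs at their value at
one time point, yielding an autonomous field whose steady states are found
by Newton–Raphson from a regular seed grid (default $5$ per dimension) over
$[0, R_a/\lambda_a]$ per gene — a box guaranteed to contain all equilibria
because $\phi < 1$ — plus optional extra seeds such as trajectory endpoints.
Newton steps use the analytic Jacobian
$J_{ab} = R_a\,\phi'(u_a)\,w_{ba} - \lambda_a\,\delta_{ab}$,
$\phi'(u) = \tfrac12 (u^2+1)^{-3/2}$.

Numerical tolerances, chosen well below biological scales but well above
double-precision noise:

* root residual (infinity norm): $10^{-9}$ a.u./min;
* root deduplication: $10^{-4}$ of $R_a/\lambda_a$ per axis;
* discard roots with a coordinate $< -10^{-6}$ or $> 1.5\,R_a/\lambda_a$;
* eigenvalue real-part tolerance $10^{-6}$, imaginary tolerance $10^{-9}$.

Steady states are classified from the Jacobian eigenvalues: point attractor,
spiral sink, saddle, unstable node, or unstable focus. Eigenvalues whose
real part sits inside the tolerance band mark the state as
*near-bifurcation*; the flag is carried rather than force-resolved, because
criticality — proximity to a bifurcation — is precisely the property the
regime analyses are about, and silently misclassifying marginal states would
corrupt phase diagrams. Portraits at successive times are recomputed
independently; we deliberately do not continue (track) individual steady
states through time.

Grid seeding is this package's choice; the density default of 5 per
dimension is validated by an invariance test (denser grids never remove a
root) and by agreement with an independent census: integrating from a dense
grid of initial conditions and clustering the endpoints must find exactly
the attractors Newton–Raphson found. The census oracle clusters and matches
endpoints at a relative tolerance of $10^{-2}$ per axis over a horizon of
$200/\min(\lambda)$: attractors with a near-zero stable eigenvalue are
approached so slowly that endpoints retain an $\mathcal{O}(1\,\mathrm{a.u.})$
spread at any practical horizon, while distinct attractors sit
$\mathcal{O}(100\,\mathrm{a.u.})$ apart — the tolerance separates these
scales by two orders of magnitude in each direction.

## Dynamical regimes and limit-cycle detection

A portrait with one attractor (point attractor or spiral sink) is
*monostable*, with two or more *multistable*; the suffix
*damped-oscillatory* applies when an attractor is a spiral sink. When no
attractor exists, or an unstable focus coexists with bounded flow,
`detect_limit_cycle()` simulates from three deterministic starts over a
horizon of $50/\min(\lambda)$, discards the first half as transient, and
declares a sustained oscillation iff some gene's peak-to-peak amplitude
exceeds 1% of its $R/\lambda$ scale *and* successive per-period amplitudes
agree within 5%. Slow cycles whose period is comparable to the horizon are
re-simulated with the horizon doubled (up to $8\times$) rather than
misreported — near a Hopf bifurcation periods grow long, and a fixed window
would otherwise see "not yet stationary" and return a false negative.

Phase diagrams (`maternal_phase_diagram()`, `weight_phase_diagram()`,
`control_parameter_map()`) classify each grid cell independently with the
maternal inputs frozen at their T1 values, so cells are pure functions of
their parameters and any evaluation order gives identical labels. On a
discrete lattice the bifurcation boundary is reported as the midpoint
between the last multistable and first monostable cell. Maternal sweeps
default to the ranges used for the fly analyses (Bcd 0–30 a.u. in steps of
0.01 — the printed lower bound of that range is truncated in the available
text and we adopt 0, the only physically sensible choice — and Cad 60–120
in steps of 0.1); both are ordinary arguments, and the examples and tests
use coarser grids.

### The simplified AC/DC model and its control parameters

For regime mapping we use a reduced three-gene AC/DC circuit: equal decay
rates, constant basal activation, no auto-activation, no maternal inputs.
Its two composite control parameters are implemented as the magnitudes of
(i) the double-negative pair's two weights ("positive feedback") and
(ii) the three cyclic repression weights ("negative feedback"); the closed
forms from which such controls were originally derived are not available in
the text we work from, so the mapping is kept configurable while preserving
the controls' monotone meaning. The resulting map reproduces the expected
repertoire: monostable at the origin, multistable under strong positive
feedback, sustained limit cycles under strong cyclic repression, and damped
oscillatory variants in between. One geometric feature of this wiring worth
noting: with cyclic repression held strong, increasing the positive-feedback
control quenches the oscillation into *monostability* rather than
multistability, because the third gene — unrepressed in one of the
would-be toggle states — runs high and its strong cyclic edge destroys that
state. Multistability therefore lives along the weak-negative-feedback edge
of the map, and the switch-versus-clock contrast is between the two corners.

## Node sensitivity and dynamical modules

The node-removal screen simulates, for every C14A nucleus, the full circuit
and each three-gene circuit obtained by erasing one gap gene with all its
interactions, both started from the full model's state at C14A onset, and
compares them with

$$d = \sqrt{\frac{1}{8}\sum_{i=1}^{8}\sum_{a}
\left(g_a^{\mathrm{full}}(T_i) - g_a^{\mathrm{red}}(T_i)\right)^2},$$

summing over the four gap genes with the removed gene's concentration
entering as zero in the reduced trajectory. The placement of the root and
the $1/8$ in the source material's typography is ambiguous; we take one
global square root of the time-class mean, which makes $d$ a scaled
Euclidean metric (triangle inequality holds) and gives the clean property
that a constant offset $\delta$ in one gene yields $d = \delta$ exactly.
Because the removed gene contributes its own full-model expression to $d$,
"insensitive" regions are necessarily regions where that gene is barely
expressed *and* barely influential.

No numeric threshold for "negligible" sensitivity is published; the default
in `insensitive_regions()` is 5% of the scan's maximum $d$, exposed as an
argument. Region calls report maximal contiguous nucleus runs, closed on the
lattice. The canonical fly assignments (AC/DC1 hb–Kr–gt over 35–47%, AC/DC2
hb–Kr–kni over 49–59%, AC/DC3 Kr–kni–gt over 61–75%) leave the nuclei at 48%
and 60% unassigned, and `acdc_assignments()` preserves those gaps literally.
Subcircuit simulations cover C14A only (no mitosis or division), start from
the full model's member-gene state at T1, and keep full maternal rows and
auto-activation. Trajectory agreement is quantified by the same metric
restricted to shared genes and normalised per gene by the full model's
dynamic range, since the comparison is about the shape of expression
dynamics, not absolute scale.

## The synthetic-data module

All downstream stages are testable without external data through three
generators, whose defaults define the package's study conditions:

* `generate_synthetic_gradients()`: a Bcd-like profile
  $A e^{-(x-35)/\ell}$ (defaults $A = 60$ a.u., $\ell = 15\%$, matching the
  scale on which the fly's anterior gradient spans roughly 24→7 a.u. across
  the mid-trunk) and a Cad-like logistic profile rising to a posterior
  plateau (default 110 a.u.). Both are modulated smoothly in time (Bcd
  declining, Cad rising, 15% across the span) — the real gradients are not
  static, and time-variation in the inputs is part of what the non-autonomous
  analysis machinery must handle. The seed jitters amplitudes by ±5%.
* `generate_ground_truth_circuit()`: seeded circuits with the gap-gene
  interaction architecture — strong mutual repression between the
  non-adjacent pairs (hb, kni) and (Kr, gt) ("alternating cushions"), weaker
  asymmetric repression between overlapping neighbours, positive
  auto-activation, and broad maternal activation. Two design points matter
  for parameter recovery and were chosen deliberately. First, activation is
  broader than the final domains (Kr reaches posterior via Cad, gt anterior
  via Bcd), so the staggered arrangement is carved by cross-repression; were
  each domain set by its maternal input alone, the repressive weights would
  be near-collinear with maternal couplings and their signs unidentifiable
  from expression data. Second, turnover is slow
  ($\lambda \sim 0.055$–$0.085$/min, protein half-lives of 8–13 min, in the
  physiological range), so domain boundaries are still moving during T1–T8
  and the time courses — not just the final pattern — constrain the
  interactions. Hb also represses Kr, giving Kr a central domain whose
  non-monotone profile no maternal gradient can mimic.
* `generate_synthetic_dataset()`: simulates the circuit from zero
  concentrations at C13 onset, samples every C14A nucleus at the T1–T8
  class midpoints (midpoints are the unambiguous choice and are
  configurable), and adds zero-mean Gaussian noise truncated at zero —
  the simplest noise model consistent with concentration positivity.

What the generators do *not* emulate: measurement backgrounds and spatial
correlations of real quantified expression data, embryo-to-embryo
variability, the real data's per-record weighting scheme (which lives in
prior literature; all weights default to 1), and the measured shapes of the
real maternal gradients. Tests passing on these fixtures therefore validate
the machinery — solver, portrait analysis, screens, estimation — not any
biological claim about the fly; analyses of the real system require the
published fitted parameter set and maternal data tables as inputs.

## Fitting

`fit_circuit()` replaces cluster-scale simulated annealing with a desk-scale
multi-start bounded quasi-Newton search (`L-BFGS-B`) over any subset of
$(W, E, h, R, \lambda)$, scored by the weighted RMS
$\sqrt{\sum_k w_k (m_k - y_k)^2 / \sum_k w_k}$. Implementation choices that
matter:

* Parameters are scaled per block (weights $\sim 10^{-2}$, rates $\sim 10$)
  via `parscale`; without this the finite-difference gradient steps are
  wildly disproportionate across blocks and the search stalls.
* Start 1 is the supplied initial circuit; further starts are seeded
  Gaussian jitters of it (s.d. twice the block scale, clipped to bounds).
  Uniform draws over the full 36-dimensional box essentially never land in
  a competitive basin.
* Default bounds: $W \in [-0.05, 0.05]$ (generous against fitted fly
  weights, whose sweeps span $\pm 0.0035$), $E \in [-0.2, 0.2]$ (maternal
  inputs span a smaller concentration range than gap proteins, so their
  couplings run larger), $R \in (0, 30]$, $\lambda \in [0.01, 0.5]$,
  $h \in [-10, 10]$.
* The objective maps data records onto the simulated state array once and
  reuses the prepared lattice across evaluations; a full 41-nucleus
  evaluation costs a few milliseconds.

Parameter recovery is assessed by `parameter_recovery_report()`: an
interaction's effective strength is $|w_{ba}| \cdot R_b/\lambda_b$ (the
largest input contribution regulator $b$ can make), and interactions above
the default threshold of 3 dimensionless input units — the scale on which
$\phi$ saturates — are "strong" and judged by sign agreement with the
ground truth.

## Problem sizes used by the tests and the acceptance script

The bundled checks run at sizes chosen to exercise every claim at desk
scale: basin censuses use a $20^3$ grid of initial conditions on 20 seeded
three-gene circuits; the control-parameter map uses coarse grids (the
labels are step-refinement invariant, which is itself tested); parameter
recovery uses the full 41-nucleus, 8-class, 4-gene dataset at 5% noise with
10 seeded runs, two optimization starts each. Published-parameter analyses
(the 52% bifurcation position, the ≈15 a.u. Bcd threshold, the vanishing of
the bifurcation near a Kr→hb weight of −0.0025) require the externally
deposited fitted circuit; the corresponding checks load it from a
user-supplied file (`options(gapdyn.published_circuit = ...,
gapdyn.published_maternal = ...)`) and cannot be reproduced from synthetic
fixtures, because those numbers are properties of that particular fitted
parameter set.

## Known limitations

* No diffusion, stochasticity, or 2-D/3-D geometry — by design, matching
  the diffusion-less model class.
* Steady states are recomputed per time point; no continuation, so the
  package does not name bifurcation types (fold vs Hopf) formally.
* Limit-cycle detection is simulation-based; a cycle with basin not reached
  from the deterministic starts, or amplitude below 1% of scale, is not
  reported.
* The weighted-RMS weighting scheme of the original fits is not reproduced;
  weights default to 1 and are configurable per record.
* `fit_circuit()` is a local multi-start method: it is built for
  desk-scale recovery studies on synthetic data, not for re-deriving the
  published fly parameter set.
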