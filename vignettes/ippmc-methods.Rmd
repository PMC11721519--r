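---
title: "Modelling liquid-liquid phase separation of heterogeneously charged particles with ippmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling liquid-liquid phase separation of heterogeneously charged particles with ippmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ippmc)
```

## The model

Globular proteins and colloids with heterogeneous surface charge interact
anisotropically: oppositely charged surface regions attract while
like-charged regions repel. `ippmc` implements a minimal coarse-grained
description of such units, the *inverse patchy particle* (IPP): a hard
sphere of diameter $2\sigma_c = 1$ (the reduced unit of length) carrying a
negatively charged equatorial belt and two identical positively charged
polar patches. Three interaction sites generate this triblock pattern: a
central site of radius $\sigma_c + \delta/2$ for the belt and two
off-centre sites of radius $\sigma_p$, displaced by $\pm a$ along the
particle symmetry axis, for the patches. The screening environment imposes

$$\sigma_p + a = \sigma_c + \delta/2,$$

so all interaction spheres extend equally far beyond the surface, and the
patch angular size is the half-opening angle

$$\gamma = \arccos\!\left[\frac{\sigma_c^2 + a^2 - \sigma_p^2}{2 a \sigma_c}\right].$$

Given $\gamma$, `ipp_geometry()` solves both relations in closed form,
$a = (R^2 - \sigma_c^2) / (2(R - \sigma_c\cos\gamma))$ with
$R = \sigma_c + \delta/2$. For the default interaction range
$\delta = 0.2\,\sigma_c$ the admissible patch sizes are
$\gamma \gtrsim 5.74^\circ$ (below which the off-centre displacement would
exceed the hard-core radius); the package studies $\gamma$ between
$30^\circ$ and $55^\circ$.

The pair energy factorises into energy strengths and geometric weights,

$$U(r, \Omega) = \sum_{\alpha\beta} \epsilon_{\alpha\beta}\,
\omega_{\alpha\beta}(r, \Omega),$$

infinitely repulsive for $r < 2\sigma_c$ and zero beyond
$2\sigma_c + \delta$. Each weight $\omega_{\alpha\beta}$ is the overlap
volume summed over the site pairs of kind $\alpha\beta$ (belt-belt,
belt-patch, patch-patch). Rather than prescribing the
$\epsilon_{\alpha\beta}$ directly, the model is calibrated through the
contact energies $u = (u_{EE}, u_{EP}, u_{PP})$ in the three reference
orientations at contact — equator-equator, equator-pole, pole-pole —
expressed in units of $|u_{EP}|$ with $u_{EP} = -1$ fixed. The $3\times 3$
linear system linking contact weights to contact energies is lower
triangular at these geometries and is inverted by `epsilon_from_u()`. Two
named systems recur throughout: `ro` (*repulsions off*, $u_{EE} = u_{PP} =
0$, isolating the directional attraction) and `ref` (*reference*,
$u_{EE} = 0.5$, $u_{PP} = 2$, a polar-to-equatorial repulsion ratio of 4
typical of inverse patchy systems).

Design choices in the potential, made where the construction was open:

* **Weight normalisation.** The weights are the raw overlap volumes
  (length$^3$). Any proportionality constant would be absorbed by the
  contact-energy calibration, leaving all energies unchanged.
* **Hard-core region.** The overlap lenses are not truncated at the
  hard-core spheres. The calibration anchors the contact energies either
  way; a truncated convention would redistribute energy between weights by
  a smooth, geometry-dependent factor. This is the main convention risk
  when comparing absolute bonding-volume values with other
  implementations: ratios and trends are robust, absolute values can
  differ by a few per cent.
* **Orientation state.** One unit axis per particle suffices: the
  triblock pattern is axially symmetric and head-tail symmetric, so a full
  quaternion would be redundant. The EE reference fixes the two axes
  parallel to each other (the azimuthal degeneracy at contact does not
  affect any contact weight).
* **Hard-core energy.** `Inf` is a sentinel, never entering arithmetic;
  the sampler treats it as an unconditional rejection.

## Grand-canonical sampling

`run_gcmc()` implements Metropolis Monte Carlo in the grand-canonical
ensemble ($T$, $\mu$, $V$ fixed, $N$ fluctuating; $k_B = 1$, energies in
$|u_{EP}|$, thermal wavelength folded into $\mu$ so the activity is
$z = e^{\mu/T}$). The move mix follows the production protocol of the
study the package reproduces: with probability 0.01 a particle exchange
(insertion or deletion, 50/50), otherwise a rototranslation of one
particle — per-component displacement uniform in $\pm 0.05$, axis rotated
by an angle uniform in $(0, 0.1]$ rad about a uniform random direction.
These step sizes give rototranslation acceptance near 0.3 close to the
critical point. One *MC step* is $N_\mathrm{max}$ elementary moves. The
default schedule is the full production protocol (box $L = 8$, $N_0 =
180$ initial particles, $5\times 10^7$ steps of which $2.5\times 10^6$
equilibration, records every $10^3$ steps and snapshots every $5\times
10^4$, i.e. 47,500 records and 950 snapshots per run; 12 replicates via
`replicate_seed()`); all tests and examples scale these down.

Implementation notes: cell lists with cell edge $\ge 2\sigma_c + \delta$
(7³ cells at $L = 8$); axes renormalised after every rotation; incremental
energy bookkeeping validated against full recomputes (`drift_check_every`)
to $10^{-9}$ relative; all randomness drawn from R's generator so a single
`seed` makes runs bit-reproducible. $N_\mathrm{max}$ defaults to 1000
(comfortably above any occupancy reached at $L = 8$ near criticality);
tests use 400-450 for speed. Insertion orientations are uniform on the
sphere (Marsaglia). The 0.01 exchange probability is split 50/50 between
insertion and deletion; only mixing rates, not the stationary
distribution, depend on that reading.

## Critical-point identification

At a liquid-liquid critical point the ordering operator
$\mathcal{M} = N + sE$ — the particle number mixed with the energy
through the non-universal field-mixing parameter $s$ — follows, after
rescaling to unit variance, the universal order-parameter distribution of
the 3D Ising class. `ising_reference()` evaluates that distribution in
the standard exponential-quartic parametrization

$$p(x) \propto \exp\!\left[-\left(\frac{x^2}{m_0^2} - 1\right)^{\!2}
\left(a\,\frac{x^2}{m_0^2} + c\right)\right],
\qquad a = 0.158,\; c = 0.776,$$

with $m_0$ and the normalisation fixed numerically on a frozen quadrature
grid by the unit-variance and unit-mass constraints. The curve is
symmetric and bimodal with maxima near $\pm 1.13$.

`reweight_samples()` implements single-histogram reweighting: samples of
$(N, E)$ generated at $(T, \mu)$ acquire weights
$w \propto \exp[-(\beta' - \beta)E + (\beta'\mu' - \beta\mu)N]$ at a
neighbouring $(T', \mu')$, with an effective-sample-size guard — the
trust region of the method shrinks quickly in $\beta$ because $E$ is
extensive. `fit_critical_point()` minimises the $L_2$ norm between the
reweighted, rescaled $\mathcal{M}$-histogram and the Ising curve over
$(T', \mu', s)$ (Nelder-Mead, multi-start in $s$ seeded by the
decorrelation heuristic $s_0 = -\mathrm{cov}(N,E)/\mathrm{var}(E)$); a
fit is accepted when the residual norm is below 0.140. The histogram grid
is 100 uniform bins over $\pm 4$ standard deviations and the norm is
$\sqrt{\sum_i \Delta x\,(\hat p_i - p_i^\mathrm{ref})^2}$; the threshold
is honoured under this discretisation, and the residual varies by only a
few per cent under 75-125 bins. The critical density $\rho_c$ is the
weighted mean of $N/L^3$ at the fitted state and its quoted uncertainty
is the standard deviation of the density distribution there. Field mixing
is first order only; second-order corrections vanish in the thermodynamic
limit and are not implemented.

`locate_critical_point()` automates the search at a single box size.
Temperatures are bisected on the *hysteresis branch gap*: at each trial
$T$, the coexistence chemical potential is bracketed by bisection on
short runs (`scan_coexistence_mu()`), then a gas-started and a
dense-started run either relax to distinct branches (subcritical) or
merge (critical and above). The branch-merging temperature is a
finite-run-length estimate of $T_c$ from above; a production run there
feeds the mixed-field fit, with a restart at the fitted state when the
optimum moves materially. At the scaled-down run lengths used in the
tests (20,000-step branch runs, 50,000-step production runs, $N_\mathrm{max}
= 400$, single replicate) the absolute $T_c$ carries a systematic
finite-sampling bias of a few per cent; because the protocol is identical
across model systems, part of that bias cancels in *ratios* of critical
parameters between systems, which is how the package's tests phrase
quantitative checks — though single-replicate branch-gap classifications
remain noisy enough that ratio estimates can still move by several
percentage points between seeds, and a run that samples only one
coexistence branch biases the density estimate toward that branch. Fit errors at these sample sizes sit near or above
the 0.140 acceptance threshold (the full production protocol pools
$5.7\times 10^5$ records per state point; the scaled runs pool
$8\times 10^3$), so scaled-down fits may be flagged `REJECTED` while
still providing unbiased point estimates.

## Connectivity observables

Two particles form a *geometric bond* when their minimum-image separation
lies in the interaction shell $2\sigma_c \le r \le 2\sigma_c + \delta$; a
geometric bond with strictly negative pair energy is an *energetic bond*
(the zero threshold is the only one implied by the model; a small
negative threshold would shift the split between the two kinds but not
the trends). `bond_graph()` tabulates both kinds; `functionality()`
reports the mean bond counts $f_G$ and $f_E$ per particle, which are
state-dependent quantities here — not in-built valences.
`cluster_stats()` takes connected components of the *geometric* graph
(the weaker, more inclusive relation), unwraps each component across the
periodic boundaries along a spanning tree, and reports radii of gyration;
components broader than half the box are flagged as ambiguous to unwrap.

The *bonding volume* `bonding_volume()` is the thermodynamics-independent
connectivity measure: the orientation-averaged positional volume of the
interaction shell in which a pair is geometrically bonded with negative
energy, $V_b = V_\mathrm{shell}\,P(U < 0)$, estimated by Monte Carlo with
the separation uniform in shell volume ($r^3$-uniform) and both axes
independent and uniform on the sphere. "Physical volume" is read as
positional volume with the orientations averaged; a convention weighting
orientations differently would scale $V_b$ by a common factor across
systems, which is why the package's quantitative claims about $V_b$ are
ratios and monotonic trends.

The reduced second virial coefficient `second_virial()`,

$$b_2^*(T) = \frac{B_2(T)}{(2\pi/3)(2\sigma_c)^3}, \qquad
B_2 = -\frac{1}{2}\int \left(\langle e^{-U/T}\rangle_\Omega - 1\right)
4\pi r^2\,\mathrm{d}r,$$

normalised by the hard-sphere value of diameter $2\sigma_c$ (the
conventional reduced form), uses fixed Gauss-Legendre quadrature over the
shell and Monte Carlo orientation averaging with per-node standard
errors; non-convergence at the requested tolerance is an error reporting
the achieved estimate. The isotropic-potential entry point validates the
machinery against the closed-form square-well result
$b_2^* = 1 - (\lambda^3 - 1)(e^{1/T} - 1)$, $\lambda = 1.1$.

## What the synthetic data emulate — and what they do not

The test suite manufactures its inputs: reference dimers and trimers with
known energies and radii of gyration, seeded hard-sphere gases, ideal and
hard-sphere grand-canonical runs with known occupancy laws, and synthetic
$(N, E)$ samples whose ordering operator follows the Ising reference
exactly with a known mixing parameter (inverse-CDF sampling plus an
independent Gaussian energy). These validate the estimators — histogram
reweighting consistency, $s$-recovery to better than 10% median relative
error, rejection of unimodal (supercritical) samples — under controlled
conditions. They do not emulate the slow, correlated dynamics of a real
near-critical fluid: autocorrelation times, nucleation barriers and
finite-size interface states are exactly what makes the physical
critical-point searches expensive, and passing the synthetic checks shows
correctness of the machinery, not that a short physical run has converged.
Conversely the scaled-down physical runs in the acceptance tests probe
convergence at reduced statistics; their tolerances (a few percentage
points on critical-parameter ratios, $\pm 0.05$ on bonded-energy peak
locations) reflect that.

## Numerical choices and limitations

* Lens volumes use the closed form with exact containment/tangency
  branches; continuity at tangency is tested.
* The geometry constructor rejects $\gamma$ outside the solvable interval
  naming the admissible range; the contact-weight inversion rejects
  ill-conditioned matrices (condition guard at $10^{-10}$).
* The Ising constants are evaluated once per session on a fixed
  $[-8, 8]$/16001-point grid; results are identical across runs on a
  given platform.
* Histogram bin edges follow left-closed convention; ties of discrete $N$
  values with bin edges can move single samples between adjacent bins.
* One box size only ($L$ fixed per run): no finite-size scaling across
  $L$, no surface tension or binodal construction, no crystal phases, no
  dynamics. The critical parameters at a single finite $L$ differ from
  the thermodynamic limit by finite-size corrections that this package
  does not extrapolate away.
* Cluster moves and parallel tempering are not implemented; near- and
  sub-critical sampling relies on single-particle moves and is slow to
  tunnel between phases, which is the dominant cost in the automated
  critical-point search.

## Problem sizes used by the shipped tests

The acceptance-style tests run: bonding volumes with $10^6$ Monte Carlo
samples per system (and $2\times 10^5$ for the six-point patch-size
sweeps); four full critical-point searches (`ro`/`ref` at
$\gamma = 30^\circ, 55^\circ$) with the scaled-down protocol above; and
the property checks at the sizes stated in their test files. These sizes
are the package's own balance between statistical resolution and a test
suite that a maintainer will actually run; the full production protocol
remains available through the defaults of `gc_schedule()`.
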