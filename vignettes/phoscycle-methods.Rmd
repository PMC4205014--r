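---
title: "Modelling covalent modification cycles with retained enzyme complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling covalent modification cycles with retained enzyme complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoscycle)
```

## The model and its assumptions

A kinase K and a phosphatase P interconvert a substrate protein between its
unmodified (W) and phosphorylated (Wp) forms through two irreversible-product
Michaelis mechanisms:

$$W + K \underset{d_1}{\overset{a_1}{\rightleftharpoons}} WK
  \overset{k_1}{\rightarrow} W_p + K, \qquad
  W_p + P \underset{d_2}{\overset{a_2}{\rightleftharpoons}} W_pP
  \overset{k_2}{\rightarrow} W + P.$$

Mass action gives six ODEs with three conservation laws
($W{+}W_p{+}WK{+}W_pP = W_T$, $K{+}WK = K_T$, $P{+}W_pP = P_T$), so the
dynamics are three-dimensional. The classical Goldbeter–Koshland (GK)
analysis additionally assumes the complexes are negligible in the substrate
conservation law, which is defensible only when both enzyme totals are far
below $W_T$. This package keeps the complexes. Assumptions retained from the
underlying kinetic scheme: binding is single-step, catalysis irreversible,
no product inhibition, spatially well-mixed, deterministic concentrations.
Units are arbitrary but consistent (one nominal concentration unit, one
reciprocal-time unit); no unit conversion layer is offered because the model
is scale-free.

## The closed-form steady state

At steady state each complex satisfies its quasi-steady-state relation
($WK = K_T W/(K_{m1}+W)$ with $K_{m1} = (d_1+k_1)/a_1$, analogously for
$W_pP$) and the catalytic fluxes balance, $k_1\,WK = k_2\,W_pP$. In
normalized variables $w = W/W_T$, $\kappa_i = K_{mi}/W_T$,
$\varepsilon_K = K_T/W_T$, $\varepsilon_P = P_T/W_T$ and the maximal-rate
ratio $v = k_1 K_T/(k_2 P_T)$, flux balance fixes the free phospho-substrate

$$w_p(w) = \frac{\kappa_2 v w}{\kappa_1 + (1-v)w},$$

and substrate conservation becomes the balance

$$G(w) = w + w_p(w)
  + (\varepsilon_K + v\varepsilon_P)\frac{w}{\kappa_1 + w} - 1 = 0 .$$

$G$ is continuous and strictly increasing on the admissible domain
($G'(w) \ge 1$), with $G(0) = -1 < 0$ and $G > 0$ at the upper end, so the
steady state exists and is unique — the one-real-root property. The domain
upper end is $\min(1,\ \kappa_1/(v-1))$: beyond the second expression
(relevant for $v > 1$) the flux-balance denominator changes sign. Clearing
denominators yields the cubic $F(w) = c_3w^3+c_2w^2+c_1w+c_0$ with

$$c_3 = 1-v,\quad
  c_2 = \kappa_1(2-v) + \kappa_2 v + (\varepsilon_K+v\varepsilon_P)(1-v) - (1-v),$$
$$c_1 = \kappa_1\!\left(\kappa_1 + \kappa_2 v + \varepsilon_K + v\varepsilon_P
  + v - 2\right),\quad c_0 = -\kappa_1^2 .$$

The published derivation this reimplements was typeset as display images in
the source available to us, so the cubic above was derived independently
from flux balance plus conservation; the test suite makes the two
derivations interchangeable by checking the root against both the monotone
balance $G$ and two fully independent solvers. Note the monotonicity
statement belongs to $G$: the polynomial $F = G \cdot
(\kappa_1+w)(\kappa_1+(1-v)w)$ shares its admissible root but is not itself
monotone for small $\kappa_1$.

### Numerical choices

* **Branch selection.** The depressed-cubic discriminant selects Cardano's
  radical form (one real root) or the trigonometric form (three real
  roots). At extreme coefficient scales (large $v$, small $\kappa_1$) the
  discriminant's *sign* is itself a cancellation-prone difference, so
  whenever the three-real region is possible both branch outputs are used
  as candidates, every candidate is Newton-polished **on the polynomial**
  before the domain filter, and an extra seed $-c_0/c_1$ catches a root far
  below the coefficient scale. Spurious candidates are removed by the
  polish + filter; the admissible root is unique by monotonicity of $G$.
* **Degeneracy.** $v = 1$ makes $c_3 = 0$ (the cubic degenerates to a
  quadratic); a discriminant within $10^{-12}$ (relative) of zero or a root
  within slack of the domain boundary signals a near-double root. All
  three cases raise a `pc_degenerate_cubic` condition and
  `solve_steady_state()` falls back to the numeric solver with a notice
  (about 1–2% of draws across the widest test regime). The numeric solver
  (Brent on $G$, Newton-tightened) is well conditioned everywhere because
  $G' \ge 1$.
* **Special cases.** `k1*K_T = 0` (no phosphorylation flux) and
  `k2*P_T = 0` (no dephosphorylation flux) bypass the cubic: the former
  gives $p = 0$ with a binding quadratic for a catalytically dead kinase,
  the latter $p = 1$ with the analogous phosphatase-binding quadratic.
  When both fluxes vanish the resting (fully unphosphorylated) state is
  returned, matching the default initial condition of the integrator.
* **Reconstruction.** $W_p$ comes from the flux-balance expression (which
  makes $k_1 WK = k_2 W_pP$ hold exactly by construction), complexes from
  the quasi-steady-state relations, free enzymes from their conservation
  laws.

## What *p* counts

The per-site phosphorylation probability is defined **inclusively**,

$$p = \frac{W_p + W_pP}{W_T}:$$

a site bound to the phosphatase still carries its phosphate. This is the
convention under which the exchange symmetry of the scheme is exact — with
$a_1{=}a_2$, $d_1{=}d_2$, $k_1{=}k_2$, $K_T{=}P_T$ the solution satisfies
$W = W_p$, $WK = W_pP$ and hence $p = 1/2$ identically — and it is the
natural success probability for the multisite binomial. The *observable*
signal amplitude (the free phospho-protein available for downstream events
such as STAT3 dimerization) is the distinct quantity $W_p/W_T$, reported as
`amp_free` and carried through sweeps. The amplitude-limitation contrast
with the GK model (its fraction approaches 1 where the full model's free
amplitude saturates well below 1) is asserted on `amp_free`; with the
inclusive $p$ both models approach 1 in strongly phosphorylating
conditions, so the contrast would be invisible there. These two definitions
were genuinely open given the source material available; the package
commits to the pair above and uses them consistently.

## Multisite extension

For $n$ independent, identical sites the site pool has concentration
$nW_T$ while the enzyme totals are unchanged, so `site_probability()`
solves the single-site system with $W_T \mapsto nW_T$ (equivalently
$\kappa_i$ and $\varepsilon$ shrink by $n$). Site occupancies are then
independent Bernoulli($p$) draws and the phosphoform classes are binomial,
$[m\ \text{of}\ n] = W_T\binom{n}{m}p^m(1-p)^{n-m}$. Binomial coefficients
use the multiplicative recurrence (exact in doubles through $n = 60$). No
cooperativity, ordering or site-specific rates are exposed — fidelity to
the independent-identical-sites model, which is what produces the
bell-shaped intermediate classes peaking at $p = m/n$ and the steepening of
the fully phosphorylated class with $n$.

Steepness is quantified by the model-free effective Hill coefficient
$n_H = \log 81 / \log(\mathrm{EC}_{90}/\mathrm{EC}_{10})$, with the EC
points obtained from a monotone (Hyman-filtered) spline of response against
log-dose. Two caveats are inherent to the definition: the EC points are
relative to the response maximum *on the grid*, so the grid must approach
saturation for absolute accuracy (the self-consistency tests use grids
spanning six decades), and responses that do not span 10–90% of their own
maximum raise a coverage error rather than extrapolating.

## The ODE oracle

`integrate_to_steady_state()` is deliberately independent of the cubic: it
integrates the mass-action equations in conservation-reduced coordinates
$(W_p, WK, W_pP)$ — making conservation exact to machine precision by
construction — with adaptive backward Euler (L-stable; zero-order regimes
are stiff) and an analytic Jacobian, growing the step pseudo-transiently
toward the attractor. No stiff integrator package was available in the
target environment, which is why the stepper is self-contained. Steady
state is declared when $\max|\dot x| < \texttt{rel\_tol}\cdot W_T$
(default $10^{-9}$); the fixed point is then tightened by full-step Newton
on the right-hand side. The polish judges convergence by step size, not
residual norm: along a slow eigen-direction the correct Newton step can
*increase* the residual norm because roundoff re-excites fast components,
and a residual-based line search would stall precisely in the
ultrasensitive regimes of interest. The default horizon `t_max = 1e6`
bounds the runtime with an explicit convergence error carrying the last
state; parameter sets with rates of order $10^{-8}$ (corners of the widest
test regime) legitimately need a larger horizon, which the tests pass
explicitly.

The default initial condition (all substrate free and unphosphorylated, all
enzyme free) is an assumption — the source material states none — but it is
immaterial: the attractor-uniqueness test integrates from three different
valid initial states for 100 seeded parameter sets and finds one terminal
state.

## Synthetic data: what it emulates and what it does not

`sample_parameters()` draws log-uniform parameter sets inside named regimes
(`substrate_excess` with $\varepsilon \le 10^{-3}$, `comparable` with
$\varepsilon \in [0.3, 3]$, `phosphatase_excess`), with
$\kappa \in [10^{-3}, 10^3]$ and $v \in [10^{-3}, 10^3]$ in the widest test
configuration; concentrations are in units of $W_T$ and time in units of
$1/k_2$. Log-uniform sampling is the standard scale-free choice for
kinetic constants; the regime boundaries mirror the concentration
contrasts the model distinguishes. `make_measured_state()` adds
independent, unit-mean lognormal noise (relative sd as requested) to the
four measurable species — multiplicative noise keeps concentrations
positive, and no attempt is made to emulate any specific assay's error
structure, correlations between species, or systematic calibration error.
A green round-trip test therefore establishes that the inversion formulas
$K_{m1} = W(K_T - WK)/WK$, $K_{m2} = W_p(P_T - W_pP)/W_pP$ are implemented
correctly and are robust to idealized multiplicative noise (medians over
replicates, which resist the ratio estimator's right skew) — not that the
procedure would survive real measurement pathologies. Noise can push a
sampled complex above its enzyme total; such draws are capped at the total
to keep the synthetic measurement physically admissible.

## Scenario design

The bundled STAT3/IRF-5 sweeps are *regime-representative*: the underlying
publications print no rate constants for their figures, so the defaults
use order-unity rates with $K_m = W_T$ and document only the ratios that
define each regime (enzyme dilution $10^{-4}$–$10^{-3}$ for substrate
excess; $\varepsilon_P = 1$ or $\varepsilon_K = 1$ for the comparable
regimes; 50 log-spaced axis points spanning $10^{-2}$–$10^{2}$). Sweeps
move either the kinase total (phosphatase fixed) or the maximal-rate ratio
$v$ through the catalytic activity $k_1$ — with the association rate
rescaled so the base $K_{m1}$ is preserved, keeping the axis orthogonal to
the Michaelis geometry. The suppression comparison
(`irf5_comparable` vs `irf5_dilute`) matches sweep points by $v$; its
strict ordering is asserted on the unphosphorylated class, which remains
representable in double precision where the phosphorylated sum saturates
at $W_T$ to within one ulp.

## Known limitations

* Distributive, independent, identical sites only; no processive or
  cooperative phosphorylation, no site-specific kinetics.
* Steady state and deterministic: no stochastic simulation, no spatial
  effects, no downstream kinetics (e.g. STAT3 dimerization).
* The closed form defers to the numeric solver in a small near-degenerate
  neighbourhood (balanced maximal rates, near-double roots at the
  flux-balance pole); both solvers agree to $10^{-10}$ in the root
  everywhere else, so this is a robustness feature, not a accuracy loss.
* `estimate_michaelis_constants()` recovers the lumped Michaelis constants
  only — the individual rate constants $a_i, d_i, k_i$ are not
  identifiable from a single steady state.
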