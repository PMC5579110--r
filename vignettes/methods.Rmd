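---
title: "Stochastic phase segregation on curved surfaces: model, discretisation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic phase segregation on curved surfaces: model, discretisation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chcsurf)
```

## The physical model

`chcsurf` simulates conserved phase separation of a two-component field
confined to a static curved surface — the continuum picture of, for
example, lipid domains coarsening on a vesicle membrane.  The
concentration $f(\mathbf{x}, t) \in [0, 1]$ of one component lives on a
surface $\Gamma$ and evolves by the dimensionless Cahn–Hilliard equation
(surface gradient $\nabla_s$, surface Laplacian $\Delta_s$):

$$\frac{\partial f}{\partial t}
  = \frac{1}{\mathrm{Pe}} \nabla_s \cdot \big( \nu(f) \nabla_s \mu \big) + \xi,
\qquad
\mu = g'(f) - \mathrm{Cn}^2 \Delta_s f ,$$

with the double-well mixing energy $g(f) = f^2 (1-f)^2$, whose wells at
$f = 0, 1$ are the pure phases.  The total free energy

$$E[f] = \int_\Gamma \Big( g(f) + \tfrac{\mathrm{Cn}^2}{2}
  \|\nabla_s f\|^2 \Big)\, dA$$

decreases along deterministic trajectories; its two terms are the bulk
mixing energy and the interfacial energy.  Two mobilities are supported:
constant ($\nu = 1$, transport through the bulk) and degenerate
($\nu = 4 f (1-f)$, transport confined to interfacial regions).

Thermal fluctuations enter through the Cahn–Hilliard–Cook extension: a
Gaussian forcing $\xi$ that is white in time but *conserved* in space —
its spatial covariance is a negative surface Laplacian of a delta
function, as the fluctuation–dissipation relation requires for a
conserved field.  The noise intensity $\sigma$ and the mobility kind are
the main physical dials; $\sigma = 0$ recovers the deterministic model.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `Pe` | Peclet number scaling the diffusive flux | 1.0 | dimensionless |
| `Cn` | Cahn number; interface thickness $\propto$ Cn | 0.015 | interfaces span $2\sqrt2\,\mathrm{Cn}$; the grid must resolve this |
| `sigma` | noise intensity | 0 | study values: $10^{-9}, 10^{-7}, 10^{-5}$ |
| `mobility_kind` | `constant` or `degenerate` | `constant` | |
| `mean_concentration` | average of $f$ | 0.3 | inside the spinodal $(0.5 \pm 1/\sqrt{12})$ |
| `perturbation_amplitude` | initial random perturbation | 0.01 | i.i.d. uniform; Gaussian optional |
| `dt` | time step | $5.12 \times 10^{-3} h$ | derived from the grid spacing $h$ |

These defaults *are* the study conditions of the simulations the package
reproduces: a unit sphere in a $[-1.25, 1.25]^3$ box, mean concentration
0.3 perturbed by 0.01, and the dumbbell variant (spheres of radius 0.75
at $(\pm 1.125, 0, 0)$ joined by a cylinder of radius 0.375).

## Discretisation: the closest point method

Rather than meshing the surface, the solver embeds it in a uniform
Cartesian grid through a signed-distance function $\phi$ and works on a
*narrow band* of grid nodes with $|\phi| \le$ 5h.  Fields are kept
constant along surface normals ("extended"); for such fields, surface
differential operators coincide with ordinary Cartesian ones on the
band, evaluated at each node's closest surface point.  Concretely, the
Laplace–Beltrami operator becomes

$$M = E_1 L + \alpha (E_3 - I), \qquad \alpha = 6 / h^2,$$

where $L$ is the 7-point Cartesian Laplacian, $E_1$ and $E_3$ are
trilinear and tricubic interpolation operators that evaluate a band
field at closest points, and the $\alpha$ term is a side condition that
pins the solution to be constant along normals.  On the unit sphere this
operator reproduces the spherical-harmonic eigenvalues $-\ell(\ell+1)$
with clean second-order convergence (the operator test suite measures
error ratios of about 4 per halving of $h$).

Design choices worth recording:

* **Analytic signed distances.**  The two study surfaces are static and
  analytic, so $\phi$, $\nabla\phi$ and the closest-point map are closed
  forms (the dumbbell is a min-union of three primitives, with the
  reentrant junction circles added as explicit closest-point candidates;
  near the junction skeleton the map is validated against a brute-force
  surface sampling rather than assumed exact).  No level-set advection,
  reinitialisation or derivative-jet bookkeeping is needed.
* **Band half-width 5h.**  A tricubic stencil centred at a closest point
  reaches at most $2\sqrt3\,h \approx 3.46h$ from the surface, and the
  centred first-difference stencils applied at those source nodes reach
  at most $\approx 4.46h$; a 5h band therefore contains every stencil
  any operator assembles, with nothing to spare hoarded.  The width is a
  config key (`band$half_width_in_h`).
* **Extension by side condition, not by interpolation passes.**  The
  solved fields already satisfy the $\alpha$ side condition, i.e. they
  are constant along normals to solver tolerance.  An additional
  explicit $E_3$ pass after each step was measured to inject $O(h^4)$
  interpolation error *per step*: temporal convergence degrades to first
  order and the energy can creep upward.  The package therefore flags
  the solved fields as extended directly.  (The initial condition, which
  is raw random data, is extended once with $E_1$, whose convex weights
  preserve the perturbation bounds.)
* **Face mobilities.**  The variable-coefficient Laplacian uses
  conservative face fluxes with arithmetic face means (harmonic
  available), which reduces row-for-row to $L$ when $\nu \equiv 1$.

## Time integration and the linear solver

The fourth-order equation is split into two second-order ones in
$(\mu, f)$ and discretised with BDF2 (backward Euler with
$\hat f = f^0$ for the startup step, since only one history level
exists).  Each step solves the block system

$$\begin{pmatrix} I & \mathrm{Cn}^2 M \\
  -\tfrac{2\Delta t}{3 \mathrm{Pe}} M^\nu & I \end{pmatrix}
\begin{pmatrix} \mu^{n+1} \\ f^{n+1} \end{pmatrix} =
\begin{pmatrix} g'(\hat f) \\
 \tfrac43 f^n - \tfrac13 f^{n-1} + \tfrac23 \Delta t\, \tilde\xi^n
\end{pmatrix},$$

with the predictor $\hat f = 2 f^n - f^{n-1}$ feeding both $g'$ and the
mobility inside $M^\nu$ (the semi-implicit linearisation).  The solver
is flexible GMRES (relative tolerance $10^{-8}$, restart 30) with the
exact block-factorisation preconditioner

$$P^{-1} = \begin{pmatrix} I & -B \\ 0 & I \end{pmatrix}
\begin{pmatrix} I & 0 \\ 0 & \hat S^{-1} \end{pmatrix}
\begin{pmatrix} I & 0 \\ C & I \end{pmatrix},
\qquad S = I + C B,$$

$B = \mathrm{Cn}^2 M$, $C = \tfrac{2\Delta t}{3\mathrm{Pe}} M^\nu$.
With an exact Schur solve this *is* the inverse, so the outer iteration
converges in one step; $\hat S^{-1}$ is applied matrix-free by an inner
GMRES (the Schur complement is never formed — at production band sizes
its explicit product and factorisation are far more expensive than a
handful of matrix-vector products), or by a sparse direct factorisation
of the explicit Schur complement for small bands (`schur = "direct"`),
which the test suite uses to cross-check the matrix-free path against a
dense solve.

Mass is conserved by the global $\beta$ correction: after each solve,
$f \leftarrow \beta f$ with $\beta = M_0 / \int_\Gamma f\, dA$, the
integrals evaluated over the band with a smoothed one-dimensional delta
$\delta_\epsilon(\phi) = (1 + \cos(\pi \phi/\epsilon))/(2\epsilon)$,
$\epsilon = 1.5h$, times $\|\nabla\phi\|\, h^3$.  The kernel width is a
choice validated by the area oracle (sphere area $4\pi$ recovered at
second order; dumbbell area against the closed-form union area within
1%).  Because scaling commutes with the (linear) extension, the
corrected field conserves $\int f\, dA$ to machine precision at every
step.

## Conserved noise

At each step and each band node's closest point, two standard normals
$\rho_1, \rho_2$ build a tangential vector $\rho = \rho_1 t + \rho_2 b$
in a deterministic orthonormal tangent frame.  The forcing is

$$\tilde\xi = \sqrt{\frac{\sigma\, \nu(f)}{h^2\, \Delta t}}\;
  \nabla_s \cdot \tilde\rho,$$

with the divergence computed by centred Cartesian differences of the
tangential field and re-extended with $E_3$ (this one field is built
from raw draws, so it does need an explicit extension).  The square
root covers the whole factor $\sigma \nu / (h^2 \Delta t)$: one
divergence applied to unit-variance vectors produces the
single-surface-Laplacian covariance the conserved-noise
fluctuation–dissipation relation prescribes, with variance proportional
to $\sigma \nu / (\Delta t h^2)$.  The amplitude uses the *current*
field (Ito-style placement, matching the explicit position of $\xi^n$
in the time-discrete system), making the noise multiplicative under
degenerate mobility.  Draws are keyed by `(seed, step)` through a
counter-based seed mix, so any realization is bitwise reproducible and
ensemble members are independent.

Each band node draws at its own closest point, so nodes sharing a
normal line receive correlated but not identical values; the discrete
scheme is therefore conserved in the ensemble-mean sense and its
surface integral vanishes to quadrature accuracy per realization —
the test suite checks conservation and the $\sigma$-scaling of the
variance, not exact spectral balance, which the discretisation does not
(and is not expected to) achieve.

## Observables and statistics

* **Characteristic length** $\bar R = A / L$ with
  $A = \int_\Gamma f\, dA$ and $L = \int_\Gamma \|\nabla_s f\|\, dA$;
  for a sharp circular domain of radius $r$, $A \to \pi r^2$ and
  $L \to 2\pi r$ (the equilibrium profile integrates to one across an
  interface), so $\bar R \to r/2$.  The surface gradient is the
  projected centred Cartesian gradient $(I - n n^T)\nabla$.
* **Growth exponent** $\alpha$: least squares of $\ln \bar R$ on
  $\ln t$ over a fit window.  Defaults: $[0.1, 10]$ for sphere runs,
  $[0.1, 0.8]$ for the faster degenerate-mobility stochastic runs,
  $[0.02, 0.2]$ and $[1, 10]$ for the two deterministic dumbbell
  regimes.
* **Ensembles**: per-realization $\alpha$, mean / sample sd
  ($n-1$) / coefficient of variation, pointwise min–mean–max envelopes,
  and a lognormal fit by MLE on logs ($n$ denominator) with a
  Kolmogorov–Smirnov check at the 5% level (plain parametric by
  default; a Monte-Carlo Lilliefors-style null that accounts for the
  estimated parameters is available and is the stricter test).
* **Domain counts**: connected components of $\{f > 0.5\}$ under
  6-neighbour adjacency (0.5 is the double-well maximum; extended
  fields make each surface domain one 3-D band component).

## The flat reference solver

A pseudo-spectral periodic 2-D solver (`flat_ch_run`) provides the
curvature-free oracle: first-order semi-implicit stepping with an
Eyre-style stabilisation shift (2), identical $g'$, mobilities, and a
conserved noise built as $\partial_x \rho_1 + \partial_y \rho_2$ of
white fields (amplitude placed inside the divergence so the forcing is
conserved exactly in the degenerate case).  Flat two-dimensional
constant-mobility coarsening follows the classical
$\bar R \propto t^{1/3}$ law, which the surface solver's exponents are
compared against.  For long coarsening-statistics runs the step size
may be ramped geometrically (`dt_growth`, `dt_max`): coarsening is
self-similar with local timescale $\propto t$, so a slow ramp buys
decades of time at equal accuracy per decade.  The 1-D equilibrium
profile $f_{eq}(x) = \tfrac12[\tanh(x/(\mathrm{Cn}\sqrt2)) + 1]$ is
checked to be stationary to $10^{-6}$ under the spectral 1-D dynamics,
on a period two orders of magnitude wider than the interface so the
periodic images do not interact (the spectral Laplacian amplifies even
$10^{-9}$ interaction tails above that tolerance on tighter domains).

## Problem sizes used in the tests

The published ensembles (64 realizations, $129^3$ grids, $t = 10$) are
multi-day runs; the package ships runnable configurations for them
(`inst/configs/`) but validates on reduced problems chosen so the whole
suite completes on one CPU:

* operator convergence on $N = 33, 65$ sphere bands;
* a 500-step $N = 49$ sphere run for conservation and energy
  dissipation;
* noise contracts on the $N = 49$ band over 100 realizations, with the
  variance-scaling check evaluated through the exact linear functional
  of the draws at a single node (cheap enough for thousands of seeds);
* flat coarsening at $256^2$ with 8 seeds, run in interface units
  ($h = 1$, $\mathrm{Cn} = 1.5$) with a geometric step ramp
  (`dt_growth = 1.004`, cap 5) to $t = 10^4$, fitted over
  $[10^3, 10^4]$ — three times past the segregation minimum and before
  the droplet count falls into the finite-size regime;
* the mobility/noise growth-rate comparison on the smallest unpinned
  sphere ($N = 21$ with $\mathrm{Cn} = 0.1$, holding the interface at
  $\sim$3.6 cells), one realization per configuration to $t = 2$,
  fitted over $[1.4, 2]$.

Reduced scale is the honest price of a portable test suite, and the
growth-rate *ordering* check (constant mobility faster than
degenerate; noise accelerating degenerate-mobility coarsening) pays
most of it.  The published orderings emerge from ensembles with
hundreds of domains coarsening over two decades of time; a desk-scale
sphere carries 10–20.  Two effects limit what the small sphere can
show: at the study $\mathrm{Cn} = 0.015$ every affordable grid leaves
the interface below one cell and the deterministic dynamics grid-pin
(measured exponent $\sim 10^{-4}$), while resolving the interface caps
the domain count.  At the suite scale the orderings do hold over the
early common window $[1.4, 2]$ — partly for the physical reason (the
mobility restriction genuinely delays coarsening) and partly because
that window sits differently relative to each configuration's
segregation time; over later windows, once the constant-mobility
system has depleted its domains into the slow few-domain regime, the
measured ordering inverts.  The suite's ordering block is therefore a
qualitative check at a documented scale, not a reproduction of the
published ensemble statistics; the full-scale configurations in
`inst/configs/` are the runs that reproduce the published tables.

## What the synthetic conditions do and do not emulate

The initial condition (uniform 0.3 plus i.i.d. uniform perturbations of
0.01) and the conserved noise emulate a well-mixed membrane quenched
into the spinodal region with thermal fluctuations.  They do not
emulate: composition-dependent line tension, coupling of the phase
field back to surface shape (the geometry is static by design),
hydrodynamics, or finite-size membrane reservoirs.  Passing tests
demonstrate correctness of the discretisation and statistics machinery
under these model assumptions — not that the model captures any
particular experimental membrane.

## Numerical choices and degenerate inputs

* Interfaces narrower than the grid ($2\sqrt2\,\mathrm{Cn} < h$) are
  accepted but under-resolved; coarse acceptance-scale runs with the
  study's $\mathrm{Cn} = 0.015$ are in this regime, where rare
  domain-coalescence events can transiently raise the discrete energy
  by $O(10^{-6})$ even though the resolved dynamics dissipate
  monotonically (the same run with a grid-resolved Cahn number is
  monotone to $10^{-8}$ after startup).
* Degenerate mobility is clamped to $\max(4f(1-f), 0)$: semi-implicit
  phase-field schemes overshoot $[0, 1]$ by $O(\mathrm{Cn})$ near
  interfaces and the mobility-weighted Laplacian must stay well posed.
* Uniform fields have no interface; `characteristic_length` raises an
  error rather than returning a meaningless ratio.
* The sphere's centre (and the dumbbell's axis skeleton) have no unique
  closest point; band construction refuses grids so coarse that such
  points fall inside the band.
* Krylov non-convergence, incomplete stencils, empty bands, negative
  mobilities and non-positive masses are hard errors, never silent
  fallbacks.

## Known limitations

* The geometry is static: no shape evolution, no coupling of domain
  composition to curvature.
* The dumbbell min-union signed distance is not a true distance near
  the junction skeleton; closest points there are validated against a
  brute-force oracle to within two grid spacings, which is sufficient
  for band construction but not for sub-grid junction geometry.
* The discrete noise satisfies conservation and amplitude scaling, not
  an exact discrete fluctuation–dissipation balance.
* Single-threaded; production-scale ensembles are meant to be run as
  independent realizations (the seed derivation is counter-based
  precisely so they can be farmed out in any order).
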