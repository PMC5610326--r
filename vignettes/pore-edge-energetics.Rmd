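---
title: "Continuum energetics of pore edges in lipid bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum energetics of pore edges in lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`poredge` computes the elastic energy of the edge of a transversal pore in a
lipid bilayer within the tilt–splay continuum theory of monolayer
elasticity. A monolayer configuration is described by a director field
**n** (the mean lipid orientation) on its neutral surface; the deformation
energy density per monolayer is

$$ w = \frac{B}{2}\,(\mathrm{div}\,\mathbf n + J_0)^2 - \frac{B}{2}J_0^2
     + \frac{K_t}{2}\,\mathbf t^2 + \frac{K_A}{2}\,\alpha^2 , $$

with splay modulus $B$, tilt modulus $K_t$ (tilt $\mathbf t = \mathbf n -
\mathbf N$, the deviation of the director from the surface normal), lateral
stretch modulus $K_A$ (relative area change $\alpha$), and monolayer
spontaneous curvature $J_0$ (positive for lysolipid-like species). The
hydrophobic interior is treated as locally volumetrically incompressible,
which ties the thickness of a deformed element to the local splay and
stretch and eliminates one field from each region.

Deformations at a pore edge are not small relative to any single flat
reference, so the edge is decomposed into two conjugated parts:

* a **horizontal bilayer region** at distances $\rho \ge R_0$ from the pore
  axis, where directors deviate weakly from the membrane normal.
  Rotational symmetry reduces the Euler–Lagrange equations to a radial
  system whose decaying solutions are modified Bessel functions
  $K_{0,1}(q\rho)$ with two complex decay exponents $q$ (a damped
  oscillation; for all registered lipids the decay length is 1.5–4 nm, so
  deformations extend a few nanometres around the edge);
* a **vertical monolayer region** (the wall lining the pore lumen), a
  near-cylinder of neutral-surface radius $R(z) = R_v + u(z)$ with director
  $z$-projection $v(z)$ and lateral stretch $\beta(z)$. The second-order
  expansion of the energy about the reference cylinder is a
  constant-coefficient quadratic Lagrangian; its Euler–Lagrange system is
  built programmatically (see "Numerics") and solved on a basis of four
  exponentials. The lateral stretch $\beta \equiv 0$ emerges from the
  solve: $\beta$ enters the energy only through the combination
  $m + h\beta$ (via incompressibility) and through $K_A\beta^2/2$, so the
  minimizer always prefers $\beta = 0$.

The two parts are conjugated along a junction circle $(R_0, \pm Z_0)$ by
continuity of the neutral surfaces, $H(R_0) = Z_0$ and $R(Z_0) = R_0$, and
of the director, $n(R_0) - v(Z_0) = 1$ in linearized form. The junction
director value is the one remaining scalar freedom; because both regional
energies are exact quadratics in their boundary data it is eliminated in
closed form (the variational natural condition). The junction circle
$(R_0, Z_0)$ itself is optimized by gradient descent until
$|\nabla W| < 10^{-7}\,k_BT/\mathrm{nm}$.

A **hydrophobic defect** — the pre-pore intermediate — carries, in addition,
a water-filled cylindrical belt of radius $r$ and height $2L$ whose side
wall exposes lipid tails. Its energy follows mean-field water-ordering
theory, $W_h = 4\pi r L\,\sigma_h\, I_1(r/\xi_h)/I_0(r/\xi_h)$, with
interfacial tension $\sigma_h$ and decay length $\xi_h$; local
incompressibility of the belt fixes the wall director at the belt rim,
$v(L) = -L/\sqrt{L^2 + (h-L)^2}$.

The pore state is parametrized by the waist radius $r$ and belt half-height
$L$. Minimizing over $L$ at each radius yields the optimal trajectory
$W(r)$ from the intact bilayer ($W \equiv 0$) through the defect to the
hydrophilic pore, and the radius-dependent line tension
$\gamma(r) = W(r)/(2\pi r)$.

## Parameters

All internal quantities use $\{k_BT, \mathrm{nm}\}$ with
$k_BT = 4.14\times 10^{-21}$ J. Registered parameter sets
(`list_lipids()`): a reference model lipid ($B = 8\,k_BT$, $K_A = 100$
mN/m, $h = 2$ nm, $J_0 = 0$), its one-parameter variants
($J_0 = \pm 0.1\,\mathrm{nm}^{-1}$; $B = 5.3$ and $12\,k_BT$; $K_A = 67$
and $150$ mN/m; $h = 1.3$ and $3$ nm; and the equal-$B/h$ pairs), and
DOPC, POPC, DMPC with experimentally determined modules. The tilt modulus
is $K_t = 40$ mN/m for all species (it tracks the tail–water interfacial
tension and depends weakly on composition). DOPC spontaneous curvature is
registered as $-0.091\,\mathrm{nm}^{-1}$ (the literature also reports
$-0.11$; override via `lipid_parameters()` if needed). Environment
defaults: $\sigma_h = 36$ mN/m, $\xi_h = 1$ nm (1.5 nm emulates radially
mobile tails; it lowers the belt cost and shifts the defect-to-pore
transition out by about 0.1 nm), lateral tension $\sigma_0 = 0$. Nonzero
$\sigma_0$ is accepted by every interface and propagated through the
functionals as written, but the shipped reference results and tests cover
the tension-free membrane only.

## Numerics and design choices

**Characteristic exponents.** For the bilayer region the variational
reduction (splay $s = n' + n/\rho$, tilt $t$) gives a quadratic equation in
$x = q^2$,
$x^2\,(h^4/4 + l^2h^2/A) + x\,(h^2 - l^2) + 1 = 0$ at $\sigma_0 = 0$
($l^2 = B/K_t$, $A = K_A/K_t$), which we derived directly from the
functional and verified against a notation-independent finite-difference
minimization of the discretized functional (the package's test oracle).
For the wall, no closed form is transcribed at all: the quadratic
Lagrangian density is assembled as matrices $(Q, L)$ over the jet
$(v, v', v'', m, m', \beta, \beta')$, the Euler–Lagrange symbol
$M(q) = T(-q)^{\top} Q\, T(q)$ is evaluated numerically, $\det M$ is
fitted as a polynomial in $q^2$ and solved exactly, and null vectors give
the amplitude ratios. The hand-derived expansion is itself checked against
a numeric Taylor expansion of the raw integrand in the test suite.

**The radial force of the bent reference cylinder.** The reference
cylinder of the wall is not an equilibrium state, so the second-order
expansion carries first-order terms. The component conjugate to the
meridional director rotation $v'$ integrates exactly to a boundary term,
$\int v'\,dz = v(Z_0) - v(z_{lo})$, opens no interior relaxation channel,
and is kept: it carries the meridional-curvature relief that produces the
metastable pore. The component conjugate to the radial displacement $u$ is
the radial expansion force of the bent cylinder; solved literally it
drives $u \sim R_v/2$ and tail-surface displacements of several
nanometres — far outside the small-deviation regime in which the quadratic
expansion is meaningful, with the splay energy extrapolating to unphysical
negative values. Deviations are therefore penalized harmonically (the
radial first-order term is dropped; `radial_force = "drop"`). The literal
expansion remains available (`"literal"`) and is used in the tests to
verify the expansion itself — it reproduces the known constant particular
term of $m(z)$, $(2R_v^2 + h^2)(l^2 - 2\sigma R_v^2)/(4R_v l^2)$,
including its tension dependence. Along the optimal trajectory the
harmonic solution keeps $|u|/R_v \lesssim 0.45$, consistent with the
expansion's domain. This choice is the single most consequential design
decision in the package: it controls how deep the metastable
hydrophilic-pore minimum is (see "Limitations").

**Reference radius.** $R_v = r$ (the wall's constrained circle), so $u$
vanishes at the waist (hydrophilic) or belt rim (hydrophobic). $M_v$
follows from incompressibility and is bookkeeping only — the tail-surface
radius never enters the energy — so small waists ($r < h/2$) are admitted
in the solve paths even though a free-standing equilibrium cylinder would
require $R_v > h/2$ (`equilibrium_cylinder()` enforces the latter).

**Energy evaluation.** On Euler–Lagrange solutions the quadratic part of
the bilayer energy equals a boundary flux at $\rho = R_0$ (the fields
decay at infinity), which is exact and fast; the spontaneous-curvature
linear term integrates to $-4\pi B J_0 R_0\, n(R_0)$ exactly. Quadrature
(graded Gauss–Legendre panels out to $R_0 + \max(30, 15/\mathrm{Re}\,q)$
nm) is retained for the splay/tilt/stretch component breakdown and as a
cross-check; the two routes agree to $10^{-8}$ relative. Wall energies use
a 32-node Gauss–Legendre rule on $[z_{lo}, Z_0]$, evaluated on the
assembled solution jets rather than on basis quadratic forms: at large
$R_v$ the four exponentials are nearly degenerate ($|q| Z_0 \ll 1$), the
basis coefficients grow to $10^4$, and summing the jets first keeps the
cancellation in one well-conditioned place (energy noise $\sim 10^{-11}$
instead of $10^{-6}$ $k_BT$).

**Junction optimization.** Central differences (step $10^{-5}$ nm) with a
backtracking line search bring the iterate into the basin; the endgame
switches to damped Newton iterations on Richardson-extrapolated gradients
(step $2\times10^{-4}$ nm), which removes the finite-difference truncation
floor and reaches $|\nabla W| < 10^{-7}\,k_BT/\mathrm{nm}$ even where $W
\sim 700\,k_BT$. Two standard starts are tried and the lower optimum kept;
degenerate geometries (ill-conditioned wall systems) return a large finite
energy so the search is repelled rather than trapped. The wall height
$Z_0 - z_{lo}$ has a floor of 0.05 nm below which the wall degenerates;
for wide belts the optimum genuinely presses against this floor (the
bilayer then meets the belt rim almost directly), and convergence there is
judged on the projected gradient with one-sided differences in $Z_0$.

**Belt-height scan and features.** $W(L)$ is scanned on a grid of about
ten heights up to $0.95\,h$ (refined parabolically near minima; a coarser
grid than a fixed 0.05-nm step, with warm-started junction optima, keeps a
full trajectory at about a minute of CPU). The belt state is the local
minimum with the largest $L$ — at small radii the optimum sits at the top
of the grid, where the belt spans nearly the whole monolayer. The
defect-to-pore transition radius is the crossing of the defect and pore
branches (equivalently the maximum of the optimal $W(r)$); the metastable
pore is the local minimum of the hydrophilic branch, reported when its
depth exceeds $0.25\,k_BT$ (the numerical floor of the feature scan); the
asymptotic line tension $\gamma_0$ is evaluated at $r = 50$ nm, with the
slope of a linear fit of $W(r)$ over the top range reported alongside as a
curvature diagnostic ($\gamma(r)$ still rises by a few per cent between 20
and 50 nm, so the fit-based estimate sits 5–8% above the point estimate).

## What the default scans emulate — and what they do not

The default radius grid (dense at 0.55–1.1 nm around the transition, out
to 50 nm) and the belt grid reproduce the study conditions of the
tension-free single-component membrane: barriers of tens of $k_BT$,
metastable pores at a few nanometres, line tensions of 5–25 pN. Passing
tests demonstrate internal consistency of the elastic model and agreement
with its reference anchor values at the stated tolerances; they do not
validate the continuum description itself against molecular reality —
lipid protrusions, thermal undulations, finite-size effects and
multi-component mixtures are all outside the model.

## Known limitations

* The small-deformation expansion is strained at the wall (director
  rotations are of order one); the model inherits the known tendency of
  two-segment edge decompositions to overestimate line tension by up to
  tens of per cent.
* The depth of the metastable hydrophilic-pore minimum depends strongly on
  how much radial relaxation the wall expansion admits. Our harmonic
  treatment yields a deeper minimum (reverse barrier $\approx 30\,k_BT$
  for the reference lipid, line-tension minima of 2–7 pN) than the
  reference anchor landscape (reverse barrier $\approx 10\,k_BT$,
  minima of 5–14 pN), while transition radius, forward barrier, belt
  structure, component fractions and all asymptotic line tensions agree.
  No closure of the wall problem that we tested — literal radial force,
  symmetric (mirror-smooth) bases, continuity-determined junction director,
  or a tilt-free ramp ansatz, each solved to its own optimum — reproduces
  the shallow reference well together with the reference component
  breakdown; the package ships the treatment that is internally consistent
  and keeps deviations inside the expansion's validity, and reports the
  discrepancy openly rather than tuning it away.
* At $\sigma_0 > 0$ the area-change term of the bilayer functional has a
  factor ambiguity (the printed squared-gradient term versus the
  $\tfrac12 (H')^2$ definition of the area element); it vanishes at
  $\sigma_0 = 0$, the only regime exercised here.
* The classical-model utilities (`classical_energy()`,
  `critical_radius()`, `closure_rate()`) are thin-film relations provided
  for comparison; they ignore the radius dependence of $\gamma$ unless it
  is passed in explicitly.
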