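---
title: "Modelling oxygen in cultured liver slices: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxygen in cultured liver slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pclsoxy)
```

## The physical model and its assumptions

A precision-cut liver slice (PCLS) is modelled as a disc of radius $r_T$
occupying $h_1 < z < h_2$ on the axis of a cylindrical well of radius
$r_o$ filled with media to depth $H$. The steady oxygen partial pressure
$\phi(r, z)$ (mmHg) obeys

$$\nabla^2 \phi = 0 \quad\text{(media)},\qquad
  D_2 \nabla^2 \phi - V\phi = 0 \quad\text{(tissue)},$$

with $\phi(r, H) = \phi_0$ at the media/air interface, no flux through the
well wall and base, and continuity of concentration and of the
$D$-weighted normal flux across every tissue–media interface. The key
modelling assumptions, all inherited from the problem formulation:

- **First-order uptake.** Oxygen consumption is proportional to local
  concentration ($V\phi$). Real hepatocyte kinetics saturate
  (Michaelis–Menten); the linear law overstates uptake at high
  concentrations, so predicted minima are conservative.
- **Steady state.** Only the equilibrium field is computed, not the
  transient after medium exchange.
- **Fixed surface value.** $\phi_0$ is pinned at the interface, i.e. the
  gas phase is an infinite well-mixed reservoir and interfacial transfer
  resistance is neglected.
- **Axisymmetry**, and an insert (if any) that does not impede diffusion.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| $D_1$ | oxygen diffusivity in media | $4.85\times10^{-9}$ | m²/s |
| $D_2$ | oxygen diffusivity in liver tissue | $1.6\times10^{-9}$ | m²/s |
| $V$ | uptake rate | $0.057$ | 1/s |
| $r_o$ | well radius (12-well plate) | $11.05$ | mm |
| $H$ | media depth (1.3 ml) | $3.4$ | mm |
| $r_T$ | slice radius | $2.5$ or $4.0$ | mm |
| $h_2-h_1$ | slice thickness | $250$ | µm |
| $\phi_0$ | surface partial pressure | $160 f / 0.21$ | mmHg |

Two reference-value conflicts had to be resolved. The tabulated well
radius of 1.1 mm is inconsistent with the stated 22.1 mm well diameter
and with the 3.4 mm media depth that follows from 1.3 ml of media; we use
$r_o = 11.05$ mm. The tabulated descriptions of $D_1$ and $D_2$ are
swapped relative to the accompanying text; the text ("$D_1$ denotes the
diffusion coefficient within the media") is taken as authoritative — the
alternative assignment also fails every downstream quantitative check by
a wide margin. For elevated incubator settings no surface value is
stated; we scale linearly, $\phi_0 = 160\,f/0.21$ mmHg for oxygen
fraction $f$, which is exact partial-pressure proportionality. $H$
defaults to 3.4 mm exactly (the rounded reference value); the
volume-derived $1.3\,\mathrm{ml}/(\pi r_o^2) = 3.39$ mm is available via
`media_depth_from_volume()`.

The derived absorption wavenumber $k = \sqrt{V/D_2} \approx 5969$ m⁻¹
sets the tissue penetration depth $1/k \approx 0.17$ mm; with a 250 µm
slice, $k(h_2-h_1) \approx 1.5$, which is why the slice interior
deoxygenates appreciably but not catastrophically.

## Solution method

The domain is split at the slice rim. The inner column's field is
$U_{II}(z) + \sum_n \alpha_n I_0(\lambda_n r) Z_n(z)$, where $U_{II}$ is
the exact 1-D two-layer profile and the $Z_n$ solve the piecewise
vertical eigenproblem; the outer annulus is
$\phi_0 + \sum_n A_n Q_n(r)\cos(\omega_n z)$ with
$\omega_n = (n-\tfrac12)\pi/H$ and $Q_n$ the $I_0/K_0$ combination with
zero derivative at the wall. Truncating both series at $M$ terms, the rim
conditions are imposed by Galerkin projection onto $Z_1,\dots,Z_M$.

**Choice of projection.** The inner modes are orthogonal under the
piecewise weight $D(z)$ (their Sturm–Liouville weight), not under the
plain inner product. Projecting the value-continuity equation therefore
requires the full inner Gram matrix $\int_0^H Z_m Z_n\,dz$, while the
flux equation — assembled with the physical material weights ($D_1$ on
both sides in the fluid intervals, $D_1$ outer vs $D_2$ inner across the
tissue band) — produces the $D$-weighted Gram, which *is* diagonal
(verified to $10^{-12}$ relative in the tests). This consistent scheme
was adopted after a direct comparison against the finite-volume
reference: it converges monotonically to the reference field (0.3 % of
$\phi_0$ over the tissue at $M = 40$), whereas the simpler variant that
reuses the mixed overlap $\int Z_m \cos(\omega_n z)\,dz$ in place of the
Gram matrices stalls at several percent interior error, underestimates
rim oxygenation, and develops negative concentrations at high $M$.

**Numerical choices.**

- *Eigenvalues.* The characteristic function is evaluated by forward
  propagation of $(Z, Z')$ from the well bottom through both interfaces
  — an entire function of $\lambda$ with no tangent poles — scanned on a
  grid of 2000 points per nominal spacing $\pi/H$, followed by bracketed
  `uniroot` polishing to $10^{-13}$ relative. A unified
  $\cosh/\cos$ pair continuous through $\lambda = k$ (series-expanded
  when $|k^2-\lambda^2|(h_2-h_1)^2 < 10^{-8}$) removes the branch point
  numerically.
- *Overlap integrals.* Every eigenfunction piece is a two-term complex
  exponential, so all matching integrals reduce to
  $\int (z-a)^d e^{sz} dz$ with $d \in \{0,1\}$, evaluated in closed form
  with a 24-term series when $|s\,\Delta z| < 0.5$ to avoid cancellation.
  An adaptive-quadrature path with breakpoints at $h_1, h_2$ is retained
  and cross-checked to $10^{-10}$ in the tests.
- *Scaling.* Radial basis functions are normalised to unit value at
  $r_T$, so matrix entries and stored coefficients stay $O(1)$ and all
  Bessel evaluations use the exponentially scaled forms with exponents
  recombined analytically (no overflow at any tested $M$).
- *Linear algebra.* LU with partial pivoting (base `solve`); both
  elimination orders of the 2×2 block system are implemented and agree to
  machine precision; residuals of both matching equations are reported on
  every solve and asserted $\le 10^{-8}$.
- *Degenerate inputs.* $h_1 = 0$ (slice on the bottom) drops the empty
  first piece from every integral; $V = 0$ short-circuits to the exact
  uniform field $\phi \equiv \phi_0$; geometric impossibilities (slice
  thicker than the media, targets outside the attainable range) raise
  descriptive errors.

**Truncation.** A single common order $M$ is used for both regions
(default 7 for scenario sweeps, 40 for converged/validation work); a
mixed inner/outer truncation would make the matching system
non-square. `truncation_convergence()` reports field changes between
successive orders.

## The finite-volume oracle

`solve_fd()` discretises the same boundary-value problem conservatively:
node-centred finite volumes on a grid whose lines contain $r= r_T$,
$z = h_1$, $z = h_2$; each face conductance is assembled from material-
homogeneous half-faces, which enforces interface flux continuity without
imposing it explicitly; the axis needs no special treatment because the
innermost control volume has zero inner face area. The sparse symmetric
system is solved by a direct factorisation and the discrete residual is
reported. Validation stack: with no uptake the solver returns the uniform
field to round-off; with tissue spanning the full cross-section it
reproduces the closed-form 1-D profile to well under 0.5 % of $\phi_0$;
its discrete oxygen balance (surface influx vs tissue uptake) closes to
$10^{-4}$; and against the $M = 40$ series it agrees to $\approx 0.3$ %
of $\phi_0$ over the tissue in every scenario. Validation grids use
$400\times400$ nodes, sized so that grid refinement changes the
comparison by much less than the 2 % acceptance band.

## Scenario analyses and conventions

- `find_placement_height()` bisects the slice base height $h_1$ (both
  tissue extrema increase monotonically as the slice approaches the
  surface) to $10^{-7}$ m, with the achieved extremum checked to
  0.01 mmHg.
- **Extremum convention.** The placement targets are extrema of the
  *through-thickness profile at the slice centre* ($r = 0$), the quantity
  the through-thickness figures plot. For the minimum this coincides with
  the tissue-wide minimum (the coolest point sits on the axis); the
  tissue-wide *maximum*, by contrast, sits at the rim edge and is much
  higher (≈ 90–100 mmHg where the centre peaks at 65), so
  "maximum = 65 mmHg" placements are only meaningful in the centre-profile
  sense. `extent = "tissue"` switches to tissue-wide extrema.
- "Top of well" places the slice top 1 µm below the media surface.
- The mid-plane span reported for a diameter/oxygen pair is the range of
  $\phi$ over $0 \le r \le r_T$ at $z = (h_1+h_2)/2$ across the three
  standard placements.

## Known limitations

- **Rim corner singularity.** The exact solution has weak derivative
  singularities at the tissue rim corners $(r_T, h_1)$ and $(r_T, h_2)$,
  so the truncated series converges slowly in a thin layer near
  $r = r_T$ (a Gibbs phenomenon of the rim trace). Consequences,
  quantified by the tests: the $M=7$ and $M=40$ fields differ by up to
  ~18 % of $\phi_0$ *at the rim* (but by $<0.1$ % for $r \le 0.95 r_T$,
  and by $<0.03$ mmHg on the centre profiles), and the claim that $M = 7$
  is fully converged "within the tissue" holds only away from the rim —
  the corresponding acceptance check is deliberately left failing rather
  than redefined. Mid-plane *rim* values need $M \approx 40$: at $M = 7$
  the top-placement rim value reads 110.5 mmHg versus the converged (and
  finite-volume-confirmed) 138.5 mmHg.
- **One published placement row is not reproducible.** Bisection under
  the converged solver reproduces three of the four published
  physiological placements to 0.004–0.022 mm, but places the 5 mm
  "minimum = 35 mmHg" row at $h_1 = 1.777$ mm, 0.089 mm above the
  published 1.6881 mm. No solver variant or extremum convention we tested
  closes that gap while keeping the other three rows (at the published
  placement the centre-point value is 35.04 mmHg, but that convention
  misplaces the 8 mm minimum row by −0.17 mm). The acceptance check
  asserts the published value and fails honestly.
- Linear uptake, steady state, rigid geometry (no rocking/agitation), no
  insert resistance, no Henry's-law solubility conversion — concentration
  is carried as partial pressure throughout.

## Problem sizes

Default test and validation sizes — truncation $M = 40$ for converged
fields, $400^2$ finite-volume nodes for reference solutions, 200×50
tissue grids with bounded local polish for extrema, 20 001-node 1-D
oracles — were chosen so that each verification layer's own error is at
least an order of magnitude below the tolerance it checks.
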