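---
title: "Elastic energetics of raft boundaries and membrane inclusions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic energetics of raft boundaries and membrane inclusions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(raftline)
```

## The physical problem

Liquid-ordered (L~o~) lipid domains are thicker and stiffer than the
liquid-disordered (L~d~) membrane that surrounds them.  Where the two
phases meet, the bilayer must bridge a hydrophobic thickness mismatch of
about 1 nm (2 × 1.8 nm versus 2 × 1.3 nm per default parameters).  The
deformations that close this gap store elastic energy — the line tension
of the domain boundary — and produce a structured micro-environment:
a strip of intermediate bilayer thickness where the leaflet domain edges
are laterally offset, flanked by regions of alternating monolayer
curvature.  Membrane inclusions (peptides, proteins, lipid species of
unusual shape) interact with this structure; `raftline` computes the
resulting energy landscapes as functions of the interleaflet boundary
shift `L` and of the lateral inclusion position `X0`.

## The monolayer functional

Each leaflet is modelled as a tilt–splay elastic surface.  The system is
assumed translationally symmetric along the boundary (valid for domains
much larger than the nanometric deformation decay length), so all fields
depend on the single coordinate `x` across the boundary, and every energy
is an energy per unit boundary length (k~B~T/nm).  Per leaflet the areal
energy density is

$$ w = \frac{B}{2}\left(\mathrm{div}\,\mathbf n + J_0\right)^2
     + \frac{K_t}{2}\,t^2
     + \frac{K_a}{2}\,(\alpha-\alpha_0)^2
     + \frac{\sigma_0}{2}\left(\frac{dH}{dx}\right)^2 $$

with director x-projection $n(x)$ on the monolayer neutral surface
$H(x)$, splay $\mathrm{div}\,\mathbf n = dn/dx$, tilt $t$, stretching
$\alpha$, spontaneous curvature $J_0$ and lateral tension $\sigma_0$
(equilibrium stretching $\alpha_0 = \sigma_0/K_a$).  Directors and
normals of both leaflets point towards the monolayer interface $M(x)$;
linearizing $t = \mathbf n - \mathbf N$ in that convention gives

$$ t_u = n_u - \frac{dH_u}{dx}, \qquad t_l = n_l + \frac{dH_l}{dx}. $$

The relative sign between the tilt term and the splay term of the
incompressibility condition below is the one fixed by this geometry; it
is load-bearing: the opposite pairing is inconsistent with the tilt
geometry and misses the boundary line-tension benchmark by ~30%.  The
mirror-symmetry tests pin the convention numerically.

Lipid volume is locally conserved.  To quadratic order this ties the
leaflet thickness to splay and stretching,

$$ H_u - M = h_u - \frac{h_u^2}{2}\frac{dn_u}{dx} - h_u \alpha_u,
 \qquad M - H_l = h_l - \frac{h_l^2}{2}\frac{dn_l}{dx} - h_l \alpha_l, $$

which is used to eliminate $\alpha$ exactly; the leaflets remain coupled
through the shared interface $M(x)$.  Because the constraint is strict it
transmits forces without an associated coupling energy.

Each region's flat-state density ($B J_0^2/2$) is subtracted, so uniform
bulk phases contribute nothing and the integrated energy is finite — it
is the excess energy of the boundary and the inclusion, i.e. the line
tension when no inclusion is present.

**Not modelled:** thermal undulations and their entropic interleaflet
coupling, Gaussian-curvature terms (identically zero in 1D), lateral
shear (gel phases), large deformations, curved (2D) domain boundaries.

## Parameters

| quantity | symbol | default | units | rationale |
|---|---|---|---|---|
| splay modulus, ordered | `B_r` | 20 | k~B~T | stiffer, cholesterol-rich phase |
| splay modulus, disordered | `B_s` | 10 | k~B~T | typical fluid PC monolayer |
| monolayer thickness, ordered | `h_r` | 1.8 | nm | hydrophobic half-thickness |
| monolayer thickness, disordered | `h_s` | 1.3 | nm | |
| tilt modulus | `Kt` | 40 mN/m = 10 | k~B~T/nm² | ≈ oil/water surface tension, phase-insensitive |
| stretching modulus | `Ka` | 120 mN/m = 30 | k~B~T/nm² | large; term contributes little |
| lateral tension | `σ0` | 0.025 | k~B~T/nm² | ≈ 0.1 mN/m, taut but unstressed membrane |
| spontaneous curvatures | `J_r`, `J_s` | 0 | nm⁻¹ | both phases near-lamellar |
| inclusion width | `ΔL` | 1.3 | nm | diameter of one α-helix |
| thermal energy | `kBT` | 4 × 10⁻²¹ | J | conversion 1 mN/m = 0.25 k~B~T/nm² |

`mN_per_m_to_kBT_per_nm2()` converts literature values;
`read_membrane_config()` accepts YAML with either unit.

## Coordinates and inclusions

The lower-leaflet phase boundary is anchored at `x = 0`, the upper one at
`x = L` (signed shift); each leaflet is disordered below its boundary and
ordered above it, so bilayer thickness grows from `2 h_s` to `2 h_r`
across the transition.  Inclusion families translate into linear boundary
conditions:

* **amphipathic_shallow** — the upper leaflet is excluded over the
  peptide span; the boundary directors jump by the geometric estimate
  $|\Delta n| = \Delta L/\sqrt{(\Delta L/2)^2+(h/2)^2}$ with *negative*
  x-projection (heads apart), interpolated by the fraction `δ` of the
  span overlapping the ordered side of its host leaflet when the peptide
  straddles the phase boundary (this overlap rule makes $|\Delta n|(X_0)$
  continuous and collapses to the bulk formula away from it); helix
  rotation couples the edge-height offset to the mean edge director
  ($H_u$ offset $= \Delta L\,(n_1+n_2)/2$, kept linear, i.e. without the
  absolute value, and minimized over).  The opposing leaflet is free.
* **hydrophobic peptides** (upper-leaflet or midplane) — a point-like
  director jump `+dn_mag` (tails apart) applied across one grid cell at
  `X0`, neutral surfaces continuous; the midplane variant applies it in
  both leaflets.  The jump magnitude is a free input (0.2/0.4/0.6
  presets): its dependence on insertion depth is not modelled.
* **transmembrane** — both leaflets excluded over the span; at both edges
  the neutral-surface separation equals the hydrophobic length `h0` and
  the directors take fixed values $\mp \Delta n_x/2$ per leaflet
  (cylinder 0, hourglass −0.4, barrel +0.4; asymmetric variants set the
  lower-leaflet jump to zero).  The edge heights are tied together
  (rigid, non-rotating body) while the common vertical offset stays a
  free unknown resolved by minimization — a natural boundary condition
  rather than a guessed value.
* **lipid_stripe** — no exclusion: a fourth membrane region of width
  `ΔL` in the upper leaflet with its own `B0`, `J0`, `h0` (tilt and
  stretching moduli and tension follow the host phase); directors and
  neutral surfaces stay continuous at its edges.

Reflecting the whole stack through the bilayer midplane maps
`(X0, L) → (X0 − L, −L)` and swaps the leaflets; the tests verify this
symmetry exactly for the leaflet-symmetric and transmembrane families.
For single-leaflet families the convention of hosting them in the upper
leaflet and scanning both signs of `L` generates the mirror pairs, which
is why the scans always come in red/blue (`L = ±3`) pairs.

## Discretization and solver

The functional is discretized on a uniform grid (default `dx` = 0.025 nm,
box extending `half_width` = 20 nm beyond the outermost structure) with
first-order differences on cells and midpoint quadrature — the exact
energy of piecewise-linear fields, which keeps the quadratic form
symmetric positive semidefinite and O(dx²) accurate.  The stacked
unknowns are `(n_u, n_l, H_u, H_l, M)` at every node.  Constraints
(far-field decay and asymptotic thickness at the box edges, inclusion
conditions, pins of unknowns inside excluded spans) are linear equalities
solved together with the energy gradient as one sparse symmetric KKT
system (`Matrix` LU).  The global vertical-translation invariance is
gauge-fixed by pinning `M` at the left box edge; the solver refuses to
run if no constraint touches that mode.  The energy reported is
recomputed from the minimizing field through `total_energy()` and
cross-checked against the quadratic-form value to below 10⁻⁶ k~B~T/nm; an
independent test enumerates the discrete Hessian from scalar energy
evaluations and reproduces the same minimizer on small grids.

Degenerate inputs are refused rather than smeared: inclusions narrower
than `2 dx`, spans touching the box edge, non-positive moduli,
`rel_tol ≤ 0`.  `refine_until_converged()` halves `dx` and widens the box
until the energy moves by less than `rel_tol` (default 10⁻³) between
levels; the scans in the documentation use `dx` = 0.05 nm, which the
ladder places well inside the 1% band (a full profile then takes seconds,
193-point production scans a few minutes).

Characteristic bulk decay lengths come from the quadratic eigenvalue
problem of the linearized Euler–Lagrange system with the interface height
eliminated pointwise (`lambda_decay()`); thickness/tilt relaxation is
1.8–2.5 nm for the default phases.  Stiffening the tilt modulus
*lengthens* the decay — tilt is the short-wavelength relaxation channel,
and without it thickness perturbations must heal by bending.  The tension
term is omitted in this diagnostic: it regularizes the soft
whole-bilayer bending branch at $\sqrt{\Sigma B/2\sigma_0} \approx 25$ nm,
a scale that carries almost no energy but dominates the far tails.

## Plateaus, depths and their conventions

That soft tension tail has a practical consequence: inclusion profiles
approach their bulk levels over tens of nm, so a "plateau" is defined
operationally as the mean of the outer 10% of the scanned window
(default ±12 nm) — exactly how a plotted curve of that range is read —
with a flatness gate (regression slope of the outer 1.5 nm below
10⁻² k~B~T/nm², loose enough to tolerate the soft tail, strict enough to
reject a genuinely unconverged scan).  Depths are reported against
several references because figure-style statements mix them:
`depth` (plateau on the minimum's side of the scan), `depth_left`,
`depth_right`, and `depth_vs_max_plateau`.  Minima are refined by a local
parabola; ripple-split minima closer than 0.5 nm are merged and dips
shallower than 5 × 10⁻³ k~B~T/nm discarded.

## What the default scans show

All numbers below are computed by the test suite and the acceptance
script at `dx` = 0.05–0.025 nm.

* Bare boundary: `W(L)` is symmetric with minima at `L ≈ ±3 nm`,
  `W ≈ 0.28` k~B~T/nm ≈ 1.1 pN — in the range of measured raft line
  tensions.  `W(0) ≈ 0.75` k~B~T/nm: full leaflet registration is
  markedly more expensive than the 3 nm offset.
* Intermediate-thickness stripe (`h0` = 1.55 nm): two sharp minima
  flanking the hybrid region, depths ≈ 0.15–0.17 k~B~T/nm; thin and
  thick stripes sort into their matching bulk phase instead.
* Curved stripes couple thickness matching with curvature relief; the
  thick negative-curvature stripe binds the boundary from both sides
  (≥ 0.2 k~B~T/nm), the thick positive-curvature stripe only for
  `L = −3` (dip ≈ 0.2 below the ordered-bulk level).  For the latter the
  computed disordered-vs-ordered level difference is ≈ 0.63 k~B~T/nm.
* Amphipathic helix: boundary gain ≈ 0.65–0.76 k~B~T/nm on either side;
  hydrophobic helices prefer the positive-splay zone on the disordered
  side, and a midplane helix gains almost exactly twice as much as a
  single-leaflet one at equal jump.
* Short barrel-shaped transmembrane inclusion (`h0` = 2.6 nm,
  `Δn_x` = +0.4): ordered-bulk penalty ≈ 2.2 k~B~T/nm and a local trap of
  ≈ 0.34 k~B~T/nm at `X0 ≈ −1.6 nm`; with a 1 nm effective length the
  Boltzmann factors are `exp(2) ≈ 7.4` (bulk depletion) and
  `exp(0.4) ≈ 1.5` (boundary enrichment).

## Known limitations

* The elastic picture omits thermal fluctuations, specific chemistry
  (e.g. cholesterol binding motifs) and protein deformability; director
  jumps are geometric estimates that molecular simulations suggest can
  underestimate induced curvature for specific peptides.
* Quantities defined as levels of a finite plotting window (bulk
  plateau differences, eyeball minima depths) carry the window convention
  with them; two such figure-level readings in the transmembrane and
  curved-stripe scans sit at the edge of a 15% agreement band while all
  surrounding quantities agree to a few percent.
* The stripe stiffness `B0` leaves all reported quantities within 5%,
  but pointwise profile differences reach ~10% of the profile amplitude
  where the stripe overlaps the boundary deformation zone.
* Sub-grid scan steps (finer than `dx`) show a small quantization ripple
  because region edges snap to grid cells; the minima merging above
  absorbs it.
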