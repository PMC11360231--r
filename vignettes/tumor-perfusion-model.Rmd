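---
title: "Smeared-field modelling of tumor perfusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smeared-field modelling of tumor perfusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusim)
```

## The physical model

`perfusim` models fluid exchange in a tumor cross-section as two coupled
Darcy pressure fields on one mesh. Rather than resolving individual
capillaries, the capillary network is *smeared*: each finite-element node
carries volumetric fractions of capillary (`r_Vcap`), cell (`r_Vcell`) and
extracellular (`r_ex`) space, with `r_Vcap + r_Vcell + r_ex = 1` enforced
exactly. Within each domain, flux follows Darcy's law `v = -k_D grad(p)`
(lengths in um, pressure in Pa, time in s), and the element conductivity is
the volume integral of `r_V * grad(N_I) . k_D grad(N_J)` over the element,
evaluated with 2x2 Gauss quadrature on bilinear quadrilaterals and one-point
quadrature on the central linear triangles.

The two domains exchange fluid through the capillary wall. At every node a
fictitious zero-length *connectivity element* carries conductance

    k_J = (4 r_Vcap V_J / d) h_cap

where `V_J` is the node's tributary volume and `d` the local capillary
diameter. The factor `4/d` is the surface-to-volume ratio of a cylinder, so
`4 r_Vcap V_J / d` is the capillary wall area inside `V_J`, and `h_cap` is
the wall's hydraulic permeability per unit area. A note on provenance: the
conductance expression is sometimes written as a bare product of `4`, `d`,
`r_Vcap`, `V_J` and `h_cap`, which is dimensionally inconsistent (it has
units of um^5 x um/(Pa s) rather than flux per pressure). We implement the
division by `d`, which restores units of um^3/(Pa s) and matches the
surface-per-volume reading used to derive `r_Vcap` from areal coverage; this
is flagged here prominently because it is the one place where we had to
choose an interpretation of the printed formula.

### Boundary conditions and the screened Poisson limit

The default problem prescribes the capillary pressure everywhere at
10 mmHg = 1333.22 Pa — an effective value that folds hydrostatic and
oncotic contributions and arteriolar/venular participation — and zero
extracellular pressure on the tumor contour, expressing balance between
perfusion and reabsorption outside the domain. With the capillary field
fixed, only the extracellular field is unknown and it satisfies (in the
continuum limit) a screened Poisson equation

    div(r_ex k_t grad p) = (4 r_Vcap h_cap / d) (p - p_c)

with screening length `lambda = sqrt(r_ex k_t d / (4 r_Vcap h_cap))`
(`screening_length()`). On a uniform disc this has the Krogh-type closed
form `p(r) = p_c [1 - I0(r/lambda) / I0(R/lambda)]`, implemented with
exponentially scaled Bessel functions so it stays finite when
`R >> lambda`. These closed forms (`disc_pressure_analytic()`,
`strip_pressure_analytic()`, ...) are the package's verification oracles: the
test suite requires the FE solution to match the disc profile to better than
1% relative L2 error on a 32x64 polar mesh, with observed convergence order
about 2, and the strip profile to better than 0.5% on 200 elements.

A general two-field solve (capillary pressure not fixed) is retained:
`solve_pressure()` accepts arbitrary Dirichlet sets over both domains, and
the capillary Darcy tensor (Poiseuille conductivity `d^2/(32 mu)`,
orientation-resolved or orientation-averaged) is implemented even though it
is inert under the default boundary conditions.

### Sources, time stepping and conservation

The balance equations carry a generic volumetric source vector `Q`; it is
zero in the default problem (wall exchange enters through the matrix), but
`assemble_system()` exposes it for completeness. There is no storage term,
so each step is quasi-static: the system is linear and a single incremental
solve `K dP = Q - K P0` reaches steady state from any start field `P0`. Time
dependence enters only through the evolving geometry and parameters.
Because element row sums vanish and the connectivity matrix is
antisymmetric between domains, the discrete fields conserve fluid exactly:
`mass_balance()` reports total capillary-wall influx, total contour
outflux, and their relative difference, which is at rounding level (~1e-13
or better) on every solved case in the test suite.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `h_cap` | 1.57e-3 | um/(Pa s) | capillary wall filtration coefficient reduced to unit surface (literature value) |
| `p_cap` | 10 | mmHg | effective capillary pressure driving extravasation |
| `k_tissue` | 1.0 | um^2/(Pa s) | extracellular Darcy coefficient; not fixed by the source data, so it is configurable and the induced `lambda` is reported |
| `mu` | 3e-3 | Pa s | blood/plasma viscosity for the (inert by default) capillary tensor |
| `h_z` | 1 | um | model thickness normal to the section plane |
| grid | 9 x 9 | — | whole-section quantification grid |
| thresholds | 0.95 / 0.79 | fraction of full scale | vascular / perfusion channel over-threshold settings |
| mesh | 16 rings x 32 sectors | — | default remeshing density |
| IDW | power 2, k = 4 | — | inverse-distance interpolation exponent and neighbour count for mesh transfer |

With the default uniform benchmark fields (4% vasculature coverage, 5 um
capillaries, 75% perfused area) the fractions are `r_Vcap = 0.05`,
`r_Vcell = 0.75`, `r_ex = 0.20` and `lambda ~ 56 um`. Since tumor radii are
millimetres, the physical regime is `R >> lambda`: a thin boundary layer
carries nearly all the pressure drop, the interior plateaus near `p_cap`,
and velocities peak at the contour.

## The image-quantification stage

`build_heatmaps()` reproduces a whole-section quantification protocol:
threshold each channel, overlay an n x m grid, and per cell report coverage
of each stain and the mean capillary diameter. Two interpretations of a
"percent" threshold are implemented — a fixed fraction of full-scale
intensity (default) and a percentile of the image's own histogram — because
threshold settings quoted as percentages are ambiguous between the two; the
fraction reading matches an over/under display threshold and is
reproducible across images, so it is the default.

Capillary diameters are measured automatically rather than by manual
caliper: connected components of the vessel mask are assigned to grid cells
by centroid (a deterministic tie-break for components touching cell
borders), up to six per cell are sampled uniformly at random under a fixed
seed, and each component's width is `(2 x median ridge distance - 0.5) x`
pixel size, where ridge distances come from the Euclidean distance
transform along the component's medial ridge. The half-pixel term corrects
the centre-versus-edge bias of the transform: even-width-`w` bands give
ridge distance `w/2` and odd-width bands `(w+1)/2`, so the corrected
estimator stays within +/-15% across widths 4–10 px and orientations
0–90 degrees, which the tests verify against rendered constant-width bands.

## Geometry: averaging, interpolation, meshing, transfer

Tumor outlines are treated as star-shaped about their centroid — every
centroid ray crosses the boundary once — giving a single-valued radius
function `r(theta)`. This parameterisation decides three operations at
once, because no vertex-correspondence rule is available otherwise:
replicate outlines are averaged per angle, geometry between observation
days is interpolated linearly in per-angle radius and centroid, and the
polar transfinite mesher places `n_rings x n_sectors` quadrilaterals along
equal radius fractions with a triangle fan at the centroid (a collapsed
quad there would have a singular Jacobian). Non-star-shaped input is
rejected with an error rather than silently reparameterised.

One subtlety: sampling the boundary at `n_sectors` angles inscribes a
polygon that is slightly smaller than the input contour (0.64% for a
32-gon on a circle). The mesher therefore rescales all radii by a single
factor `sqrt(A_polygon / A_ngon)` so the mesh area equals the input polygon
area exactly; the boundary nodes sit on a contour dilated by that
sub-percent factor rather than exactly on the input vertices. We prefer
exact area (hence exact tributary volumes and mean-value weights) over
exact boundary interpolation; the residual shape error vanishes under
sector refinement, which the tests check.

Fields move between meshes by inverse-distance weighting (Shepard
interpolation) with power 2 over the `k = 4` nearest nodes — neither value
is dictated by the data, so both are configurable; IDW is exact at sample
points, preserves constants, and never overshoots the sample range, all of
which are asserted as invariants.

## The time-course driver

`run_timecourse()` walks the knot days (default 7, 10, 13, 16,
corresponding to roughly 15/25/60/80% of final tumor volume under the
default exponential growth fit `V(t) = 59.98 exp(0.1874 t)` mm^3), with 3
substeps per interval. Each substep interpolates contour and heatmap
linearly in time, remeshes, maps parameters, transfers the previous
pressures as the starting field, solves, and records area-weighted
summaries. Heatmap knots are aligned by `(row, col)` grid index; both cell
centres and values interpolate linearly, and a cell masked at only one
bracketing knot takes the other knot's value — an explicit, deterministic
rule where the source protocol says only that data were interpolated
linearly in time. One documented oddity: the source protocol mentions
interpolating "between the three data points" while four observation times
exist; the driver treats all four as knots. No extrapolation is performed
outside the first and last knot, since growth outside the observed window
would be assumed rather than measured.

## What the synthetic generator does and does not emulate

`gen_contour_series()` produces star-shaped outlines (low-order Fourier
radial perturbation, elliptic stretch for anisotropy) whose areas scale as
`V(t)^(2/3)` — a medial slice of a self-similar growing solid; the solid
volume-to-slice-area rule is not fixed by any measurement, so the 2/3 power
is a package choice, and a flag disables growth scaling for size-normalised
averaging. `gen_heatmaps()` draws each field as a linear base surface plus
independent Gaussian cell noise clipped to physical ranges; the defaults
(4 +/- 1% vasculature, 5 +/- 0.5 um diameter, 75 +/- 5% perfusion) are
typical of murine flank-tumor sections. `gen_fluorescence_image()` renders
vessels as constant-width bands and perfusion as halos around them, with
per-cell ground truth taken from the rendered masks themselves.

None of this emulates histology: no staining texture, background gradients,
necrotic cores, vessel branching or 3D structure. Passing tests therefore
demonstrate that the quantification, mapping and solver stages are correct
*given* images and outlines of this idealised kind; they do not validate
the thresholds or the star-shape assumption against real sections.

## Numerical choices and problem sizes

Direct sparse Cholesky factorisation solves the reduced symmetric system;
the relative residual is checked against 1e-10 (an iterative solve is
unnecessary at these sizes). Degenerate inputs error early: non-positive
Jacobians, contours through their centroid, duplicate IDW samples with
conflicting values, over-full volume fractions (reported with the offending
node), and Dirichlet-free (singular) systems.

The shipped verification problems are sized for seconds-scale runs: the
disc benchmark uses radius 100 um (about 1.8 screening lengths, so the
profile is well resolved at 8–32 rings), the strip 200 elements, the
synthetic time course a 16 x 32 mesh over 10 steps at the physical
3000–5300 um radius scale, and the image-recovery check a 2000 x 2000 px
frame with a 9 x 9 grid. At the physical scale the 56 um boundary layer is
thinner than a mesh ring; the qualitative findings (interior plateau,
boundary-peaked velocity, rising mean pressure, falling mean speed) are
robust to that under-resolution, but pointwise boundary-layer accuracy at
millimetre radii would require graded meshes, which are not implemented.

## Known limitations

- 2D sections only; flow is assumed identical in all parallel planes
  (thickness `h_z` enters the volumes but not the physics).
- No lymphatic sink domain, no oncotic/Starling decomposition (folded into
  the effective capillary pressure), no poroelastic deformation, and no
  solute/drug transport.
- Star-shaped geometry is required; strongly lobed or folded outlines are
  rejected.
- The tissue Darcy coefficient defaults to 1 um^2/(Pa s) for lack of a
  measured value; conclusions that depend on absolute velocities should be
  read with `screening_length()` in hand.
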