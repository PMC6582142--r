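---
title: "The differential haemodynamic model of intestinal wall perfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The differential haemodynamic model of intestinal wall perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucoflow)
```

## The model

The arterial supply of the stomach and duodenum is organised around the
submucous plexus, a two-dimensional arterial network lying between the
muscle mantle and the mucosa. Muscle-perforating arteries feed this plane
from outside; from it, terminal vessels perfuse the metabolically active
mucosa (and, retrogradely, part of the muscle layer); within it, collateral
arteries redistribute flow laterally. `mucoflow` treats a patch of wall as a
2-D resistor network in which each cell `(x, y)` carries

* a transmural influx conductivity `alpha(x, y)` — lowered by wall stress
  (intraluminal pressure working on the muscle mantle),
* a terminal outflow conductivity `omega(x, y)` — raised by metabolic
  demand (acid secretion, or acid attack on the duodenal mucosa),
* lateral resistances `lambda_x(x, y)`, `lambda_y(x, y)` of the submucous
  plexus, anisotropic where the vessels have a preferred direction.

With `delta_p0` the systemic perfusion-pressure gradient over the whole
wall and `p(x, y)` the gradient still available at the submucosal plane,
stationary Kirchhoff balance in every cell gives the heterogeneous elliptic
equation

```
alpha (delta_p0 - p) - omega p
  + d/dx[ (1/lambda_x) dp/dx ] + d/dy[ (1/lambda_y) dp/dy ] = 0 .
```

Terminal (mucosal) blood flow is `j_omega = omega * p`, transmural influx
`j_alpha = alpha * (delta_p0 - p)`, lateral collateral flow
`j_lambda = -(1/lambda) grad p`. Everything is dimensionless: the model's
claims are about spatial *patterns* and their orientation, not calibrated
physiological magnitudes, so `h = 1` and `delta_p0 = 1` throughout and the
conductivities carry the figure-caption values verbatim.

The storage capacity of the wall is negligible, so only the stationary
problem is posed; there is no time axis anywhere in the package (necrosis
"rounds" below are logical stages, not time steps).

## Discretisation and solvers

The equation is discretised by finite volumes on an `nx x ny` grid
(`grid_spec()`). The face between two cells gets conductance
`g = 1/(lambda h^2)`; by default `lambda` is taken from the lower-index
cell, the convention in which the pressure drop from `(x, y)` to
`(x+dx, y)` is carried by the resistance recorded at `(x, y)`. A
`harmonic_mean` alternative (the standard finite-volume average) is
available in `solver_options()`; the iterative solver and the direct
oracle always share the convention. Each cell's balance is

```
(alpha + omega + sum g) p - sum g p_neighbour = alpha delta_p0 ,
```

a strictly diagonally dominant M-matrix system wherever `alpha + omega > 0`.
Two consequences are load-bearing and tested: the **maximum principle**
(`0 <= p <= delta_p0` — every cell's value is a convex combination of its
neighbours and `delta_p0`) and the **steal direction** (raising `omega`
anywhere lowers `p`, and hence terminal flow, everywhere in the laterally
connected component).

`solve_gauss_seidel()` sweeps the cells in a fixed order (ascending x
within ascending y) with optional SOR relaxation; the solution at
convergence is sweep-order independent, iteration counts are not. The
initial guess is the cellwise closed form `alpha delta_p0 / (alpha +
omega)` (0/0 treated as 0), exact for homogeneous or laterally decoupled
fields. The stopping rule is the maximum absolute per-sweep update, default
tolerance `1e-10 * delta_p0` with a 200000-sweep cap — the update rule is
cheap per sweep, and the physically meaningful residual (cellwise Kirchhoff
balance) is audited separately by `balance_residuals()`, which also reports
the global influx/outflow imbalance. `solve_direct()` solves the same
sparse system exactly and serves as the independent oracle in the test
suite; agreement is held to `1e-6 * delta_p0` on randomised fixtures.

Boundary conditions are not part of the model's published statement; the
default is no-flux on all four edges (an isolated, self-contained patch,
matching the 50 x 50 matrices of the reference configurations), with
`periodic_y` available because y is an organ circumference. Degenerate
cells (`alpha = omega = 0`) are legal pure lateral conductors; the system
is singular only if an entire laterally connected component has
`alpha + omega = 0`, which `solve_direct()` reports with a cell of the
offending component.

## The built-in scenarios

The scenario builders carry the model's three reference configurations;
their constants are fixed, documented, and overridable only by name.
Stated index ranges such as "0 < x < 30" on a 50-wide grid are resolved as
1-based inclusive blocks (`[1, 30]`, `[31, 50]`, `[11, 40]`) so that the
regions tile the grid exactly.

* `scenario_antrum_borderline()` — gastric borderline ulcer: uniform
  limited influx `alpha = 0.1`; corpus `omega = 5.0` (x 1-30) against
  antrum `omega = 1.0` (x 31-50); lesser curvature (y 1-20) with axial
  arteries (`lambda_x = 3.82e-1`, `lambda_y = 3.82e3`), parietal wall
  (y 21-50) with the circumferential pattern (values swapped).
* `scenario_cardia()` — the same fields mirrored in x: the rare ulcer at
  the opposite (cranial) edge of the acid-secreting mucosa.
* `scenario_linear_ulcer()` — the distal antrum, where the plexus is
  isotropic (`lambda_x = lambda_y = 3.82e-1` everywhere): the trough rings
  the full circumference.
* `scenario_watershed(omega_level)` — a 30 x 30 block with essentially no
  direct influx (`alpha = 0.001` vs `1` around it), isotropic
  `lambda = 3.82e-1`, uniform `omega`; called with `omega_level` 1, 10,
  100 it reproduces the demand ramp (three separate uniform-`omega`
  solves, one per stated level, not a spatial gradient).
* `scenario_necrosis(stage)` — a circular watershed of diameter 18
  (`alpha` 0.05 inside vs 0.1 outside, `omega = 10` vital); stage
  `"post"` additionally collapses `omega` to 0.05 on the inner disc of
  diameter 15. Disc membership uses Euclidean cell-centre distance with
  ties (distance exactly the radius) inside.

`random_fixture(seed, nx, ny)` generates log-uniform random fields
(`alpha` in [1e-3, 1], `omega` in [1e-2, 1e2], `lambda` in [1e-1, 1e4])
for oracle testing; identical arguments give bit-identical scenarios and
the caller's RNG state is preserved.

What the synthetic configurations deliberately do **not** emulate: real
gastric geometry (curvature, wall thickness variation), the discrete
sub-millimetre vessel topology, haematocrit/rheology, any time dependence,
and calibrated units. A passing suite therefore shows that the *mechanism*
— redistribution, steal, watershed dips, self-limiting necrosis — follows
from Kirchhoff's laws in an anisotropic 2-D network with these parameter
contrasts; it does not validate magnitudes against tissue measurements.

## Necrosis feedback

`run_necrosis_iteration()` closes the loop that turns a flow dip into an
ulcer: solve, mark all active cells with `j_omega` below a viability
threshold `theta`, set their `omega` to the necrotic residual (default
0.05, the retrograde muscle-layer supply), re-solve. The update is
synchronous (the whole sub-threshold set dies per round), matching the
two-state presentation of the reference configuration; a cell-sequential
variant would be possible but is not offered. The necrotic set can only
grow, so the iteration terminates within `nx * ny` rounds.

The model does not state `theta` numerically, so the API requires it
explicitly and `find_self_limiting_theta()` scans the observed flow range
for a threshold whose fixed point is non-empty and strictly inside the
watershed — exhibiting the self-limiting regime: the dead core sheds its
collateral supply back across the rim, rim flow rises above threshold, and
the spread arrests. Both routes to the post-necrotic state exist (the
preset `scenario_necrosis("post")` disc and the iterated fixed point)
because the reference configuration does not say whether its diameter-15
core is a fixed point or an illustrative preset.

## Pattern metrics

The morphological claims the model makes are verbal (a steep proximal
edge, a central dip, a nearly circular profile, a contrast-enhanced
margin); every metric definition here is therefore the package's own, and
the exact choices are stated so they can be criticised:

* `reibungsform_asymmetry()` — locate the interior minimum of a row's
  `j_omega` profile; on each side, the half-width is the linearly
  interpolated distance to recovery at 50% of *that side's* plateau
  (median of its 10 outermost cells); report distal/proximal. Referencing
  each side to its own plateau makes the metric of a mirrored profile
  exactly the reciprocal — a single shared reference level would not,
  because the corpus and antral plateaus sit at different flow levels.
  Ratio > 1 is the classic gastric-ulcer orientation.
* `dip_depth()` — `1 - min(centre)/mean(reference)`, clipped to [0, 1].
* `circumferential_extent()` — fraction of rows whose profile has an
  interior minimum deeper than 5% (default) below that row's distal
  plateau.
* `steal_index()` — relative change of mean regional `j_omega` against a
  baseline solution.
* `contrast_enhancement()` — ratio post/pre of the maximum
  central-difference gradient magnitude of `j_omega` over the boundary
  cells of the necrotic region.
* `circularity()` — `4 pi A / P^2` of the largest 4-connected sublevel
  component, with `A` the cell count and `P` the boundary *edge* count,
  thresholded at `min + f (median - min)` within the search region. A
  single cell scores `4 pi / 16`. Note the limitation: an edge count is a
  taxicab perimeter, under which squares (not discs) maximise the index
  (any square scores `pi/4`, a rasterized disc about `pi^2/16`), and
  rounding a square's corners *lowers* the score. The index is therefore
  only comparable between rasterized shapes scored the same way, and the
  package's shape test for the watershed dip asserts the corner rounding
  geometrically (the sublevel contour excludes the corners of its own
  bounding box) rather than through this index.

All metrics are invariant under rescaling `delta_p0`, because the PDE is
linear in `p`.

## Numerical and design choices

* Sub-cell interpolation: 50%-recovery positions are interpolated linearly
  between cells so asymmetry ratios are stable on coarse grids.
* Connectivity: 4-neighbour throughout (components, perimeters, boundary
  rings).
* The published pressure range statement for this model reverses its
  inequality signs typographically; the implementation asserts and tests
  `0 <= p <= delta_p0`, which is what the discrete maximum principle
  yields.
* Tie-breaks: disc rasterisation counts cells at exactly the radius as
  inside; `which.min` takes the first of tied minima (profiles from the
  solver are strictly single-troughed in practice).
* Problem sizes: the reference configurations are 50 x 50 (as published);
  oracle fixtures run up to 20 x 20, 50 at a time, which keeps the whole
  suite in seconds while exercising every code path. Convergence on these
  systems takes tens to a few hundred Gauss-Seidel sweeps because the
  terminal conductivities dominate the diagonal.

## Worked example

```{r example}
sc <- scenario_antrum_borderline()
sol <- solve_scenario(sc)
sol

reibungsform_asymmetry(axial_profile(sol, 10))   # > 1: steep corpus edge
circumferential_extent(sol)                      # trough confined to y 1-20
```

```{r plot, fig.width = 5, fig.height = 4, eval = requireNamespace("ggplot2", quietly = TRUE)}
plot_field(sol, "j_omega")
```

## Known limitations

The model is 2-D and stationary; perforation depth, healing, and the
topography of recurrent arteries are explicitly out of scope. Figure-level
agreement with the original surface plots is qualitative: the original
solver's sweep order, stopping rule and relaxation are unpublished, so the
package asserts the pattern properties (orientation, confinement,
monotone deepening, sign reversals) rather than bit-level reproduction.
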