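---
title: "Methods: connectivity modelling and conservation-target accounting in panlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity modelling and conservation-target accounting in panlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panlink)
```

`panlink` models ecological connectivity between protected-area (PA)
patches on a raster landscape and accounts for the resulting protected-area
network (PAN) against area-based conservation targets. This vignette is the
package's own record of the model, its assumptions, the parameters that
matter, the numerical choices, and what the synthetic test landscapes do and
do not demonstrate.

## Grid model and conventions

All layers share one georeferenced grid: row 1 is north, cells are square,
coordinates are projected metres, and cell `(r, c)` covers a half-open
square so every point belongs to exactly one cell. Areas are always
`cell count × cell_size²`, reported in km². Layers entering one analysis
must be aligned exactly — the package refuses to resample, because silent
resampling is the classic source of irreproducible overlay results.
Missing cells (`NA`) propagate through every derived layer; open sea is
`NA` for terrestrial analyses by default, making it impassable.

Raster interchange uses the ESRI ASCII grid format — a plain-text,
single-band, georeferenced raster dialect that round-trips values, the
nodata mask and georeferencing exactly and is readable by every GIS.
Vectors travel as GeoJSON, tables as CSV.

## Resistance model

Movement resistance is scored on the conventional five-level scale
{1, 10, 25, 50, 100}: 1 is unimpeded movement, 100 a complete barrier.
Ten factors enter: five ecological-suitability factors (elevation, slope,
relief, NDVI, distance to water) and five anthropogenic-disturbance factors
(land use, distance to expressways / primary / secondary roads, distance to
settlements).

* Continuous factors are cut into five classes by **exact Jenks natural
  breaks** on their valid values, oriented by a per-factor `direction`
  (higher NDVI or greater road distance → *lower* resistance). The
  orientations are configurable per study; the defaults treat terrain
  ruggedness and proximity to infrastructure as movement costs.
* Land use maps through an explicit category table (defaults: forest and
  wetland 1, grassland 10, cropland 25, bare 50, urban and open-water
  crossings 100). No published table covers every legend, so the table is
  ordinary configuration and unknown codes are a hard error that names the
  offending code.

Factor weights come from the analytic hierarchy process. The weight vector
is the normalised principal right eigenvector of the pairwise comparison
matrix, computed by power iteration (tolerance 1e-10, cap 10,000
iterations) with the eigenvalue from the Rayleigh quotient; consistency is
`CI = (λmax − n)/(n − 1)` and `CR = CI / RI(n)` with Saaty's random-index
table (RI(10) = 1.49). Printed expert matrices are rounded, so reciprocity
`a_ij · a_ji = 1` is a soft check: relative error above 0.02 warns, above
0.10 rejects. The bundled ten-factor expert matrix has CR ≈ 0.00062, far
under the 0.10 acceptance bound; the package always reports weights derived
from the matrix itself rather than any separately published rounded vector,
because only the eigenvector is internally consistent with the stated CR
procedure.

The composite surface is the **unit-sum weighted overlay**
`R(x) = Σ wᵢ levelᵢ(x)`, which stays in [1, 100]. Scoring with
unnormalised weights would only rescale `R` globally; least-cost paths,
normalized corridors, current ratios and every Jenks classification are
invariant under positive rescaling (a property the test suite asserts), so
the bounded form is preferred for interpretability.

## Cost distance, least-cost paths and corridors

The grid graph is 8-connected with edge cost
`(Rᵢ + Rⱼ)/2 · cellsize · (√2 for diagonals)` — the standard cost-distance
convention — so cumulative cost-weighted distance (CWD) is in
resistance·metres. Dijkstra's algorithm (compiled, binary heap) computes
multi-source CWD fields with deterministic (row, col) tie-breaking, making
backlink fields and therefore traced paths reproducible across platforms.

Patch pairs are linked, by default, when their minimum-CWD **allocation
regions share a boundary**. On a planar mosaic of many patches this yields
the sparse, near-planar linkage set corridor-mapping practice expects;
all-pairs and k-nearest pairings are available. The least-cost path of a
pair is backtracked through the cell minimising `cwd_A + cwd_B`, and the
normalized least-cost corridor is `nlcc(x) = cwd_A(x) + cwd_B(x) − cost`,
zero exactly on the path. The corridor *threshold* is a single quantity in
CWD units wherever it appears; two presets are wired through the
configuration — 10,000 for corridor/current mapping and the mean LCP cost
for the assessment footprint — because published workflows quote both a
fixed cumulative-resistance cut and a mean-distance cut and the two are the
same kind of number in this unit system.

Per-path relative resistance is the ratio of cost to geometric path length
(so a ratio of `r` on a uniform surface of resistance `r` is exact), Jenks
k = 3 → low / medium / high.

## Circuit analysis

The same grid geometry becomes a resistor network with conductance equal to
the reciprocal of the edge cost, keeping the cost-distance and circuit
worlds consistent. Patch cells are short-circuited into one supernode per
patch. In all-to-one mode each patch serves as ground in turn while every
other patch injects 1 A; voltages solve the grounded Laplacian by sparse
Cholesky factorization (Matrix package), and per-cell current density is
half the sum of absolute incident edge currents plus half the external
current. Components with no ground are held at 0 V rather than crashing the
factorization, and an injection into such a component is an explicit
"disconnected" error. Analysis is restricted to the corridor band
(`nlcc ≤ width`, preset 10,000) plus the patches.

Pinch points are the top class of a Jenks k = 5 classification of in-band
current, kept as 8-connected regions of at least 0.1 km². A degenerate
(near-constant) current map yields an empty set with a warning, not an
error.

## Barrier detection

A circular window (radii 100, 300, 500 m — minimum 100, maximum 500, step
200) is restored to the landscape's minimum resistance and the pair's
least-cost distance is **re-solved exactly** (early-exit point-to-point
Dijkstra); the improvement `cost − cost_restored` is attributed to the
window centre, maximised over radii and linkages. The exact re-solve was
chosen over boundary approximations because the tests require equality with
an independent shortest-path oracle to 1e-6; windows whose cells are
already at minimum resistance short-circuit to zero. Scan centres cover the
corridor band (default extent 6,000 CWD units in the pipeline, keeping the
scan proportionate to the corridor width at the simulated scale).
Barrier points are the geometric centres (centroids) of top-Jenks-class
regions of at least 0.05 km²; improvement-per-metre normalization is
available behind a flag.

## Network prioritization

The patch–corridor graph carries edge resistance equal to LCP cost.
Current-flow centrality grounds each node in turn, injects 1 A at every
other node of its component, and accumulates absolute currents through
nodes and edges; isolated nodes get centrality 0 with a warning. Jenks
k = 3 classes are labelled I < II < III with III highest. The 3×3 cross of
relative-resistance class and centrality class yields the nine corridor
types; the documented priority order puts low-resistance, class-III links
first (cheap to build, most load-bearing). Pinch regions and barrier points
within 1 km of each other merge (union-find over mutual proximity) into
co-occurrence regions. OECM candidate screening is a conjunction of
individually toggleable predicates: outside PAs, on pinch focal areas, at
least 0.1 km², mean resistance below the landscape's 20th percentile, and
within 2 km of a settlement — the proximity radius operationalises
"surrounded by human communities", for which no standard number exists, and
is configurable.

## Conservation-target accounting

The PAN footprint is the union of PA cells and all cells whose minimum
normalized corridor value is within the threshold (default: mean LCP cost).
Coverage is the footprint share of the study area, compared with a
configurable 30% target. Priority-area overlap is
`100 · |BCPA ∩ footprint| / |BCPA|`; land-cover composition shares sum to
100 by construction. Four SDG 15 indicator capacities are computed per zone
(PA, PAN, whole region): forest share (15.1.1), protected share of the
priority area (15.1.2), degraded-land share (15.3.1 — lower is better,
reported raw with polarity noted), and mountain green cover (15.4.1: green
classes among cells above a 300 m elevation threshold, reported as missing
— never zero — for zones with no mountain cells). Degradation has no
universally computable definition from these inputs, so the degraded mask
is explicit configuration; the synthetic generator emits one (bare land).
The synergy analysis tiles the study area into city-like blocks (3×3 by
default, the generator having no administrative divisions) and computes the
Spearman rank correlation (average ranks on ties) across tiles; constant
columns are reported missing.

## The synthetic landscape generator

`generate_landscape()` is first-class, tested code, not a fixture dump. It
emulates the structure of a densely settled coastal province at 30 m
resolution: a wavy sea edge on one side; a low coastal strip holding
settlements and urban growth; a mountainous interior; rivers, lakes and a
coastal wetland fringe; a fragmented woodland mosaic in an agricultural
matrix; non-overlapping PA patches of six statutory categories on high
ground (patch interiors forested); BCPA rectangles partially overlapping
PAs; and a degraded (bare) fraction. All randomness flows from one seeded
stream in a fixed order, so a config plus seed reproduces bit-identical
bundles — the end-to-end pipeline test checks identical output checksums.

Planted ground truth drives recovery testing:

* **Planted corridors** are 210 m-wide forest strips between chosen PA
  pairs, carved as gentle valleys (elevation ramps between the endpoints)
  so terrain factors do not cancel the land-cover advantage, with ambient
  woodland kept off a 600 m buffer so the strip is the corridor rather than
  one option among adjacent patches — the remnant-strip-through-farmland
  situation corridor planning addresses. Corridor endpoints keep at least
  1.2 km of separation so a corridor exists at all.
* **Planted barriers** are 600 m-thick urban walls crossing a strip
  perpendicularly and extending 600 m beyond it on each side, emulating
  linear transport/urban infrastructure. The thickness is deliberately of
  the order of the largest detection window so that restoring one window
  just spans the wall; much thinner walls leave a detection plateau that
  extends far beyond the footprint and makes the centroid report
  uninformative.

What passing recovery tests shows: on landscapes with this planted
structure, least-cost paths stay inside the planted strips (all recovered
path cells in the strip on barrier-free seeds) and the barrier screen
relocates every planted wall (recall 1.0 over twenty seeds at the default
thresholds). What it does not show: performance on real remote-sensing
inputs, whose resistance contrasts, co-registration errors, and category
legends differ; nor anything about species-specific dispersal, which the
resistance model deliberately abstracts away.

## Numerical choices and degenerate inputs

* Jenks classification is the exact Fisher dynamic program (O(k·n²)), never
  a sampled approximation, because four downstream thresholds hang on the
  class boundaries; ties break toward the lowest breaks, deterministically.
  Fewer distinct values than classes is an error for the core classifier,
  but the wrappers that feed it (ratio, centrality, pinch, barrier classes)
  degrade to a single class or an empty set with a warning, since flat
  fields are legitimate on degenerate landscapes.
* Dijkstra and the circuit solver share one edge-cost definition; solver
  tolerances are 1e-10, oracle agreement is asserted at 1e-8 or tighter.
* Distance-to-features is the exact Euclidean distance transform
  (Felzenszwalb's separable lower-envelope algorithm), not a chamfer
  approximation, and is validated cell-by-cell against the brute-force
  all-pairs minimum.
* Problem sizes in the shipped tests — grids up to 20×20 for oracle
  equality, 90×90 two-patch landscapes for recovery screens, one 150×150
  eight-patch landscape for the end-to-end determinism check — were chosen
  as the smallest scales at which every planted feature (strip width, wall
  footprint, area thresholds in km²) remains faithfully representable at a
  30 m cell size.

## Known limitations

Corridor thresholds and area thresholds interact with cell size: at 30 m,
0.05 km² is 56 cells, so top-class regions on very small landscapes can
fall under the reporting thresholds. The all-to-one circuit mode scales as
one sparse solve per patch; hundreds of patches will want the corridor mask
kept narrow. Pinch-point *typing* (urban / coastal / mountainous) is a
visual-interpretation exercise, not a computation, and is out of scope; so
is any marine larval-dispersal modelling — open water is simply impassable
or, behind a flag, a finite-resistance medium.
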