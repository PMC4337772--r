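---
title: "Annotating movement tracks with gridded environmental data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating movement tracks with gridded environmental data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envtrack)
```

# The annotation model

A movement track is an ordered sequence of GPS fixes
$p_i(x_i, y_i, t_i)$ per individual, in WGS84 longitude/latitude and UTC
time. An environmental variable is an $n$-dimensional grid
($1 \le n \le 4$, axes drawn from $x, y, z, t$) in a declared native
coordinate reference system: a reanalysis wind component on a regular
lon/lat grid every 6 hours, a DEM with no time axis, an ocean colour
composite on a sinusoidal grid. Annotation attaches to each fix the value
of each requested variable, co-located in space and time.

The procedure is *space first, then time*. Each fix is transformed into
the variable's native CRS. The four grid nodes bracketing it in space are
located at the two scenes bracketing it in time; grid coordinates are
treated as **cell centers**, and the fractional position
$(f_x, f_y) \in [0,1]^2$ is measured between adjacent centers. The node
values are collapsed to one value per scene by the spatial method, and
the two spatial values are interpolated to $t_i$ by the temporal method:

* **Nearest neighbour** returns the value of the node at minimal
  geodesic distance from the fix (and, in time, the closer scene).
* **Bilinear** expands
  $(1-f_x)(1-f_y)v_1 + f_x(1-f_y)v_2 + (1-f_x)f_y v_3 + f_x f_y v_4$.
  On irregular grids the same expansion is applied to the fractional
  coordinates within the bracketing cell, i.e. a per-cell linear
  rescaling; this extends the textbook regular-grid definition and is
  exact for fields linear within each cell.
* **Inverse-distance weighting (IDW)** forms
  $\sum_k w_k v_k / \sum_k w_k$ with $w_k = d_k^{-p}$, $d_k$ the
  geodesic distance to node $k$.

All three are convex combinations, so an annotated value can never leave
the range of its contributing nodes; this is the property the test suite
leans on most heavily. Bilinear in space combined with power-1 IDW in
time (linear interpolation for two samples) reproduces any field affine
in $(x, y, t)$ exactly, which gives the pipeline a machine-precision
oracle.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `idw_power_space` | 2 | — | Shepard's classical weighting |
| `idw_power_time` | 1 | — | two-sample IDW then equals linear interpolation in time, the natural reading of space-then-time schemes |
| `idw_k` | 4 | nodes | the bracketing cell; larger values grow the neighborhood ring by ring |
| speed threshold (segmentation) | 5 | m/s | transit definition of the Galapagos albatross case study |
| transit / coastal bands | [−90, −82.5), [−82.5, −75) | °lon | case-study study area; half-open so the shared boundary has one owner |
| fix interval (synthetic tracks) | 5400 | s | 90-min GPS duty cycle typical of seabird loggers |
| `rho`, `c_p`, `g` (thermal uplift) | 1.225, 1005, 9.80665 | SI | standard surface air density, specific heat, standard gravity; all overridable |

## Distance and direction conventions

Distances are true ellipsoidal geodesics on WGS84 (Karney's algorithms
via `geosphere`); a spherical-haversine option (radius 6371 km) is
provided for comparison and agrees within 0.6%. "Great-circle distance
on the WGS84 ellipsoid" is a contradiction in terms, so the package
names both options explicitly and defaults to the ellipsoid.

Wind direction is reported as the azimuth the air moves **toward**
(`atan2(u, v)`), the convention under which the tail-wind decomposition
$\mathrm{tail} = u\sin\theta + v\cos\theta$,
$\mathrm{cross} = u\cos\theta - v\sin\theta$ is energy-preserving.
Meteorological "from" directions are the ±180° converter
`wind_dir_from_to()`. Positive crosswind means wind arriving from the
animal's left; `sign_flip = TRUE` selects the opposite convention.
Flight heading is the initial geodesic bearing from fix $i$ to fix
$i+1$, assigned to fix $i$; the last fix inherits the previous heading
and speed so every fix is labellable.

Note that on an ellipsoid the initial bearing differs from the spherical
great-circle azimuth by up to a few tenths of a degree away from the
cardinal directions, and forward/reverse bearings differ by 180° only up
to the meridian convergence $\Delta\lambda \sin\varphi$ — both effects
are real geometry, not numerical error, and the tests account for them.

# Grids, scenes and caching

Every spatial tile of a variable at one timestamp is a *scene*, the unit
of fetching and caching. `scenes_required()` maps a point set to the
de-duplicated, sorted list of scenes its neighborhoods touch, so an
annotation run can be laid out fetch-by-fetch; points are processed in
scene-sorted order internally while the output preserves input order.
The cache ranks scenes for eviction either by access frequency (LFU,
the default) or recency (LRU) — the two strategies published for the
original service are both implemented and selectable, with deterministic
tie-breaks (oldest access, then lexicographic key) and a logical clock
so replays are reproducible. Caching is transparent by construction:
cold, warm, and capacity-limited runs produce bit-identical annotations,
and the test suite checks the eviction decisions against an independent
brute-force replay simulator.

## Longitude and domain edges

Longitudes are normalized to $[-180, 180)$; grids published as
$[0, 360)$ are re-indexed on load. A grid whose x-axis spans the full
circle wraps across the antimeridian, so a fix at 179.5°E on a 2.5°
global grid correctly neighbours the 180°W column. There is **no
spatial extrapolation** — a fix outside the grid domain yields a flagged
missing value, never a silent zero. Temporal queries up to one scene
interval beyond the last (or before the first) scene clamp to the edge
scene with a warning; farther out is a domain error. The vertical axis,
when present, is resolved to the nearest level only: none of the
supported products publish tracks' pressure levels at a precision that
would justify vertical interpolation.

## Missing data

Missing nodes are dropped and the surviving weights renormalized, which
keeps every method a convex combination of the surviving nodes; nearest
neighbour falls through to the next-nearest finite node; a fully-missing
neighborhood yields a flagged missing value. An exact node hit (geodesic
distance < 1 m) returns the stored node value for every method.

## Numerical choices

* IDW weights are computed as $(d_{\min}/d_k)^p$ — algebraically the
  renormalized $d_k^{-p}$, but immune to floating-point underflow at
  large powers (raw $d^{-64}$ underflows for kilometre-scale
  distances).
* Distances below 1 m are floored before weighting to avoid division
  blow-ups adjacent to the exact-hit rule.
* Temporal nearest-neighbour ties at the exact midpoint resolve to the
  earlier scene.
* Lambert conformal conic and Albers inverses iterate the latitude
  relation to $10^{-13}$ rad, comfortably inside the 1e-6° round-trip
  contract; the far pole of the Lambert cone is rejected as a domain
  error.
* The sinusoidal projection uses the MODIS authalic sphere radius
  6371007.181 m — the grid definition of the products it represents —
  rather than the WGS84 ellipsoid.

# The synthetic data module

`make_field()` generates gridded variables whose node values equal a
closed form evaluated at the node coordinates, with the closed form
returned alongside as an oracle callable at arbitrary $(x, y, t)$:
affine fields (exactly reproducible by bilinear + linear-in-time, hence
the machine-precision pipeline check), separable sinusoidal fields
(resolvable structure with a known second-order interpolation error),
seeded categorical mosaics, uniform and banded u/v wind pairs, and
planar or Gaussian-hill DEMs. `make_track()` paces fixes along geodesic
waypoint legs at constant speed and cadence. All fixtures are
deterministic functions of (spec, seed).

The banded wind fixture places an easterly (trade-wind) band south of a
configurable latitude and a westerly band north of it. A foraging loop
flown inside the easterly band shows the qualitative signature expected
of the albatross case study — head winds on the eastbound outbound legs,
tail winds on the westbound return — and the acceptance script reports
the two mean tail-wind values.

What the generator deliberately does **not** emulate: spatially
correlated reanalysis error structure, cloud masks and orbital swath
gaps, biogeochemical covariance between variables, or GPS position
error. Passing tests therefore demonstrate the correctness of the
transformation/interpolation/derivation machinery on fields with known
truth, not skill on any particular real product.

# Problem sizes

The shipped checks run at: 1,000 random fixes against the affine oracle;
10,000 random neighborhoods × all six method combinations for convexity;
1,000 random projection round-trip points per CRS; 1,000 random
operation sequences against the cache-policy simulator; 100 random
analytic planes for the terrain operators; 10,000 random wind samples
for the energy identity. The full suite and the acceptance script each
complete in about a minute on a single CPU.

# Known limitations

* No reader for NetCDF/HDF/GRIB/GeoTIFF sources is bundled; gridded
  inputs arrive through the in-memory builders, the synthetic module, or
  the ESRI ASCII grid + YAML manifest loader. Area rasters are written
  as min/max-scaled 32-bit TIFF with a world file and a JSON sidecar
  carrying the linear scale (plus optional KML overlays).
* Bilinear on strongly irregular grids is a per-cell approximation, as
  described above.
* Vertical (z) interpolation is nearest-level only.
* The area mode assumes axis-aligned rectangles in the requested CRS.
* Datum support is WGS84 only; no vertical datums.
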