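---
title: "Coarse-grained capsid mechanics: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained capsid mechanics: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidstress)
```

## The model and its assumptions

A capsid is reduced to the set of its capsomer centroids: 12 pentamers on the
five-fold axes and 10(T−1) hexamers for a Caspar–Klug triangulation number
T = h² + hk + k². All hexamers are treated as mechanically indistinguishable,
and likewise all pentamers — the model deliberately knows nothing about the
internal protein composition of a capsomer, so any stress pattern it produces
reflects geometry alone. Two capsomers are adjacent when their centre
distance is below a cutoff δ of the order of one inter-capsomer spacing;
adjacent pairs interact through a Lennard-Jones potential with pair-class
equilibrium distance σ and depth ε0. The residual stress is the static
virial stress per capsomer, normalized by the total area |S| of the
triangulated surface through the centroids, then decomposed in the local
tangent plane into a lateral (mean in-plane tension) and a maximum shear
component.

The central assumption is that central pair forces are adequate. That holds
when curvature is spread smoothly — nearly spherical shells — and degrades
near sharp creases, where a bending energy would be needed. This is why the
package carries three discrete curvature measures: they are the diagnostic
for whether a given shell is in the regime where the stress model is
trustworthy. The Gaussian curvature (angle defect) separates "faceted"
(defect pinned at the 12 five-fold vertices, zero on flat faces) from
"spherical" (positive defect spread over all capsomers); the per-edge mean
curvature separates creased from smooth; the capsomer-plane curvature does
the same using the orientations of the capsomers themselves, available when
atomic coordinates exist.

## Parameters

* `eps0` (energy, arbitrary units; default 1): overall Lennard-Jones scale.
  Stresses are proportional to it, so only ratios and orderings of stress
  values are meaningful — all reported comparisons are scale-free.
* `sigma` (length, one value per unordered pair class pentamer–hexamer,
  hexamer–hexamer, pentamer–pentamer): equilibrium centre distances. When no
  table is supplied, `calibrate_model()` sets each class to the mean observed
  adjacent distance of that class in a reference configuration, which makes
  the reference near-equilibrium and lets the stress field express the
  *residual* distortion. A published σ table, when available, should be
  passed explicitly and takes precedence. Classes with no observed contact
  (pentamer–pentamer for every T > 1) fall back to the overall mean spacing;
  the adjacency rule itself does not forbid pentamer–pentamer contacts, which
  only arise for T = 1.
* `delta` (length; default `"auto"` = 1.4 × median nearest-neighbour
  distance): adjacency cutoff. The auto rule captures the first neighbour
  shell and excludes the second (at about √3 spacings) on both faceted and
  spherical embeddings; it is validated at run time by the coordination check
  (every pentamer 5 neighbours, every hexamer 6) and a warning reports the
  achieved degree histogram if the check fails. A model whose δ exceeds
  √3 × mean σ is flagged, since second shells would then enter the energy.
* `spacing` (default 1): synthetic shells are rescaled so the mean adjacent
  centre distance is 1, making stresses comparable across shapes; imported
  structures keep their Ångström scale.

## The synthetic generator

`ck_configuration(h, k, shape)` realizes the classical construction: the
planar hexagonal lattice of capsomer centres is laid over the 20 faces of an
icosahedron, with the face triangle spanning h steps along one lattice
direction and k along a second at a counter-clockwise π/3 angle — (2, 4) is
the dextro T = 28 layout; swapping h and k gives the mirror. Points shared
between faces are deduplicated deterministically (lowest face index wins),
and the emitted count is asserted to equal 10T + 2. `shape = "sphere"`
projects radially onto the circumsphere, which preserves the contact graph.

`spherical_code(T, seed, n_restarts)` produces the icosahedrally symmetric
arrangement on the unit sphere that locally maximizes convex-hull volume —
the standard proxy for the minimum-Lennard-Jones-energy shell, used when a
capsid (P23-77) has no deposited structure. Rather than consuming published
coordinate tables, the code is optimized in-repo under exact symmetry: the
12 pentamer directions and any hexamer orbits pinned to two- or three-fold
axes are frozen, and only free orbit representatives (two spherical angles
per orbit of 60) are optimized by multi-start Nelder–Mead from the radially
projected lattice. The result therefore never falls below the projected
lattice's volume, and the generated set is group-invariant to machine
precision by construction.

What the synthetic shells emulate: capsomer counts, icosahedral symmetry,
convexity, and the faceted-versus-spherical shape extremes. What they do
not: the irregular spacings, slight asphericity and capsomer orientations of
real capsids, the distinct material response of symmetry-broken hexamers,
and any effect of cementing proteins. Passing tests on synthetic shells
therefore validate the machinery and the geometric claims, not the
atomic-scale accuracy of any particular virus model.

## Numerical choices

* **Surface triangulation.** The surface through the centroids is the convex
  hull — canonical and deterministic for the convex-at-capsomer-resolution
  shells in scope. The hull is computed on the radially projected directions
  so that capsomers lying on flat icosahedral faces remain mesh vertices;
  points landing exactly on a facet (cocircular degeneracies) are re-inserted
  by deterministic facet splitting. A capsomer strictly interior to the hull
  of the raw coordinates is an error naming the offending index. Orientation
  is fixed outward per triangle; areas and normals are computed from the
  unprojected coordinates.
* **Node normals** are area-weighted means of incident-triangle outward
  normals. They are exactly radial at nodes whose triangle star is
  rotationally symmetric (all capsomers on symmetry axes) and deviate by
  O(spacing²) elsewhere; a degenerate normal falls back to the radial
  direction with a warning.
* **Tangential decomposition.** The virial tensor is symmetrized before
  projection (f ⊗ r is not exactly symmetric off equilibrium; symmetrization
  is the minimal choice consistent with a symmetric tangential stress). The
  in-plane eigenproblem is solved in an explicit orthonormal tangent basis,
  closed-form 2×2, so the normal direction is annihilated exactly and the
  discarded third eigenvalue is identically zero.
* **Sign conventions.** `pair_force(i, j, ...)` is the force on i exerted by
  j, i.e. the negative gradient of the pair potential in x_i — verified
  against finite differences — so tension comes out positive in the virial.
  Lateral stress and shear are unchanged by a global sign flip, so published
  magnitude comparisons are unaffected by this convention.
* **Energy bookkeeping.** The total energy is the ordered double sum, so each
  adjacent pair counts twice and a fully relaxed shell has E = −ε0 × 2 ×
  (number of adjacent pairs); per-pair values divide by two and say so.
* **Angles** (triangle interior angles, dihedrals, capsomer-normal angles)
  are computed as atan2(|a × b|, a · b), robust near 0 and π. Per-edge mean
  curvature uses triangulation edges; the capsomer-plane curvature uses
  adjacency edges (the two sets coincide for hull triangulations under the
  auto cutoff, and a run-time check warns when they differ). Gaussian
  curvature is reported in radians, the per-edge curvatures in inverse
  length.
* **Optimizer.** The hull-volume objective inside `spherical_code()`
  evaluates the volume of a frozen star-shaped triangulation — exact while
  that triangulation remains the hull, a strict lower bound otherwise — and
  re-freezes the combinatorics whenever a local optimum's true hull volume
  exceeds the frozen value. Restarts are seeded; the first starts from the
  projected lattice unperturbed.
* **Import.** Assembly operators from the structure file are applied
  explicitly; chain copies are clustered into capsomers by single-linkage,
  with the merge radius placed in the widest gap of the merge-height sequence
  (the stable plateau of the cluster-count curve) and an error when no clear
  plateau exists. Capsomer class is decided by coordination number (5 vs 6),
  not chain identity, because the model treats all hexamers alike; capsomer
  centroids are unweighted atom means (mass weighting changes centroids
  negligibly at capsomer scale, and stress units are arbitrary regardless).

## Problem sizes

The test suite and acceptance script run entirely on synthetic shells up to
T = 28 (282 capsomers): triangulation, stress and curvature of a T = 28
shell take on the order of a second, and the T = 28 spherical-code
optimization with its default 8 restarts well under a minute. These sizes
were chosen because T = 28 is the largest architecture in the lineage under
study; everything scales as the square of the capsomer count or better.

## Known limitations

* No bending or curvature energy: stress values on strongly creased shells
  (perfect icosahedra) are indicative only; the curvature diagnostics exist
  to flag exactly this.
* Thermal (kinetic) contributions to the virial, relaxation of imported
  configurations, multilayered shells, membranes and explicit cementing
  proteins are out of scope; auxiliary proteins enter only implicitly
  through the experimentally determined geometry.
* Published per-virus stress maxima are stated in arbitrary units with a σ
  table external to the main text; without that table the package's
  calibration reproduces scale-free ratios and orderings, not absolute
  printed values.
* The optimizer finds local volume maxima under the symmetry constraint;
  seeds and restarts make the search reproducible and, at the sizes studied,
  restarts agree to ~10⁻⁶, but global optimality is not certified.
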