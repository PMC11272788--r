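---
title: "Quantifying claw shape and function: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying claw shape and function: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clawmorph)
```

clawmorph analyses the shape and inferred function of ungual phalanges —
the terminal claw-bearing bones of digits — digitized as 2D landmark
outlines in lateral view, the setting typical of comparative studies of
theropod dinosaur claws (e.g. troodontids). This vignette explains the
models implemented, the parameters that matter, the synthetic data used to
validate the pipeline, and the design decisions taken where the
methodological literature leaves genuine freedom.

## Landmark scheme

Each claw is digitized as 16 ordered points: four fixed anatomical
landmarks — (1) the dorsoproximal corner of the articular facet, (2) the
ventroproximal corner, which doubles as the fulcrum of the lever model,
(3) the apex of the flexor tubercle, (4) the distal tip — and twelve
sliding semi-landmarks distributed along the dorsal outline curve (six,
between landmarks 1 and 4) and the ventral curve (three between the
fulcrum and the tubercle apex, three between the apex and the tip). Units
are millimetres throughout; no unit conversion is performed. Landmark
indices are 1-based in files and in the user-facing tables.

Semi-landmarks have no exact anatomical homology, so each is allowed to
slide along its outline during superimposition. The assignment of
semi-landmarks to curves travels with the data as a `(before, slide,
after)` sliders table, the common convention for landmark files that
cannot encode sliding themselves (TPS has no sliders field). Right-sided
elements are mirrored to left-lateral orientation on input so that
handedness is explicit and never silently absorbed by the
superimposition, which deliberately excludes reflections.

## Generalized Procrustes analysis with sliding

Superimposition is partial Procrustes: every configuration is centred and
scaled to unit centroid size, then rotated onto the running consensus by
the closed-form 2D rotation (never a reflection). The consensus is the
rescaled mean shape; iteration stops when its root-mean-square change
falls below `tol` (default 1e-8) or at `max_iter` (default 100, recorded
as a warning rather than an error if reached).

Semi-landmarks slide along the chord through their two neighbours on the
outline, once per iteration, under one of two objectives:

* **bending energy** (default): the slide steps of all twelve
  semi-landmarks are solved jointly as the minimizer of the thin-plate-
  spline bending energy of the consensus-to-specimen deformation, a
  quadratic problem with an exact solution. This is the default of the
  standard geometric-morphometrics toolchain.
* **Procrustes distance**: each semi-landmark moves to the foot of the
  perpendicular from the consensus position onto its tangent — the exact
  minimizer of the summed squared residuals along the tangent.

Two numerical choices deserve explanation:

* **Sliding passes are capped** (`slide_iter`, default 5). Tangent
  sliding has a nearly flat direction — the entire parametrization
  drifting along the outline together — so sliding at every iteration
  until the 1e-8 consensus tolerance would creep for a very long time
  without changing the answer meaningfully (the per-iteration objective
  decrease ratio sits just below one in that regime). Capping the
  sliding passes at a small fixed number, the
  long-standing convention of semi-landmark tools, lets the subsequent
  plain Procrustes iterations converge in a handful of steps.
* **The objective trace records the Procrustes sum of squares** after
  every iteration. Under the Procrustes-distance objective this trace is
  monotone non-increasing by construction. Under bending energy the first
  sliding passes may raise the Procrustes SS slightly — they are
  minimizing a different functional, trading residual distance for
  smoothness of correspondence — after which the trace decreases
  monotonically. The tests assert exactly this pattern rather than
  pretending both objectives minimize the same quantity.

After convergence the whole aligned set is rotated into a canonical
orientation (consensus principal axis along x, first landmark at
non-negative x, reflections never used), so the output is invariant to
the original orientation, position and scale of every input specimen —
including the one that seeds the consensus.

## Shape space

PCA is computed on the covariance matrix (divisor n − 1) of the flattened
aligned coordinates; scores are the centred data projected on the
eigenvectors, eigenvalues are clipped at zero, and all components are
retained. Eigenvector signs are mathematically arbitrary, so the axes are
*anchored* to read biologically:

* PC1 is flipped, if necessary, to correlate positively with a
  **curvature index**: 1 − chord/polyline along the dorsal curve. The
  chord runs from the dorsoproximal facet corner to the tip — the dorsal
  polyline's own endpoints — so the index is exactly 0 for a straight
  claw and grows toward 1 with recurvature. (An earlier variant measured
  the chord from the facet midpoint instead; because that chord does not
  share endpoints with the polyline, the resulting index could go
  negative and was not monotone in curvature, so it was rejected.)
* PC2 is flipped to correlate positively with a **robustness index**: the
  maximum landmark height perpendicular to the facet-midpoint-to-tip
  chord, divided by chord length, plus the flexor-tubercle development
  (DFT, below). Short, high claws with enlarged flexor tubercles
  therefore score positive.

Both indices are invariant to similarity transforms, and the anchoring
correlations are reported in the fitted object rather than hidden.
Anchoring changes signs only, never absolute scores, so range-type
statistics (`pc_range()`) are unaffected by it.

Thin-plate-spline deformation grids (`tps_warp()`) use the 2D kernel
r² log r²; the spline interpolates the reference landmarks onto the
target exactly, affine deformations carry zero bending energy by
construction, and duplicate or collinear reference landmarks are rejected
as singular.

## The claw lever model

The claw is treated as a class-3 lever: the flexor tendon pulls on the
flexor tubercle (input), the ventroproximal corner of the articular facet
is the fulcrum, and the tip bears the resistance. With

* `a` — output lever length, fulcrum → tip (mm),
* `d` — fulcrum → tubercle apex (mm),
* `θ` — angle of the input force vector to the output-lever line (degrees),
* `δ` — angle between the fulcrum→tubercle line and the output-lever line
  (degrees),

the mechanical advantage is MA = sin(θ + δ) · d / a, the fraction of the
input force delivered at the tip. MA is dimensionless and invariant to
rigid motion and uniform scaling of the configuration; it increases with
`d` and decreases with `a` whenever sin(θ + δ) > 0.

The construction of θ from landmarks is not standardized in the
literature, so it is a configuration option. The default
(`"facet_normal"`) takes the input force perpendicular to the proximal
articular facet line (landmark 1 → 2), directed proximally — a geometric
stand-in for the flexor tendon's pull across the joint — and folds the
angle to [0°, 90°] since only the lever line's orientation matters.
Alternatively, θ can be supplied per specimen (`"user_theta"`). The same
openness applies to the flexor-tubercle base: the package takes the two
outline semi-landmarks flanking the apex along the ventral curve
(landmarks 13 and 14 of the default scheme), the geometrically natural
reading, and the mapping is overridable via `landmark_roles()`.

Flexor-tubercle development is DFT = (perpendicular height of the apex
over its base segment) / (base-segment length), a dimensionless proxy for
the input force; the hypothesized output force is HO = DFT × MA, exactly.

## Shape–function regression and summaries

Standardized major axis (SMA) regression relates function scores to shape
scores symmetrically in x and y: slope = sign(r) · sd(y)/sd(x), intercept
through the means, R² = r². It is equivalently the line minimizing the
summed areas of the axis-parallel triangles between the points and the
line, which is how the tests cross-check it. The p-value tests r = 0 by
the t statistic on n − 2 degrees of freedom (two-sided); the slope
confidence interval uses the standard SMA pivot on r. The confidence band
around the fitted line is a percentile bootstrap of the fit (default
2,000 resamples) under a fixed default seed (20240725), because the band
method behind published figures of this kind is typically unstated; the
choice is documented and reproducible rather than implicit. Points
outside the band at their x are flagged as outliers.

Per-digit distributions of MA, DFT and HO are summarized boxplot-style:
quartiles by linear interpolation of order statistics (the default of
mainstream statistics environments, quantile type 7), whiskers at the
most extreme data within 1.5 IQR of the quartiles, outliers beyond.

## The synthetic claw generator

Real landmark data of the kind this package targets are published as
supplementary archives and are not redistributable inside a package, so
every pipeline stage is validated against a generator that emulates the
*statistical structure* of such a sample:

* The claw midline is a logarithmic spiral r = r₀·e^(kφ) whose swept
  polar angle is proportional to the curvature coefficient `spiral_k`, so
  `spiral_k = 0` is an exactly straight claw and the curvature index is
  strictly increasing in `spiral_k` — the generator's curvature factor is
  the PC1-like axis.
* Dorsal and ventral borders are normal offsets of the midline sharing
  the distal tip, with claw height `aspect` × length and a linear taper
  (chosen so a straight midline yields an exactly straight dorsal
  border). A triangular flexor-tubercle bump of relative height
  `tubercle_h` sits at fractional position `tubercle_pos` on the ventral
  border; `aspect` and `tubercle_h` together form the PC2-like
  robustness factor.
* The four fixed landmarks are placed at the facet corners, tubercle apex
  and tip; semi-landmarks are spaced equally by arc length on the
  noise-free borders; isotropic Gaussian digitization noise of standard
  deviation `noise_sd` × centroid size is then added.

Defaults emulate a study-sized sample: 20 unguals, digits I–III cycling
across specimens, one taxon per three specimens with the first labeled
troodontine (one focal derived taxon among non-troodontine outgroups),
curvature spiral_k ∈ [0.05, 0.5], aspect ∈ [0.35, 0.65], tubercle_h ∈
[0.10, 0.40], tubercle_pos ∈ [0.20, 0.40], centroid size 8–30 mm, and
0.5% digitization noise — values a morphometrician would call realistic
for small theropod manual unguals digitized from published figures.
Per-specimen parameters are drawn with independent sub-seeds, so
extending a population never changes the specimens already drawn.

What the generator does **not** emulate — and therefore what passing
tests do and do not show about real data: digit- or taxon-specific shape
differences (labels cycle independently of the shape factors), covariance
between curvature and robustness, anatomically realistic articular facet
geometry, correlated digitization error along outlines, allometry, and
the keratinous sheath. Recovery tests demonstrate that the pipeline
recovers known generating factors through GPA + PCA + anchoring; they do
not certify anatomical interpretations of real PC axes.

## Parsimony character fit

The phylogenetics module scores a fixed tree — heuristic tree search is
deliberately out of scope — against a morphological character matrix read
from TNT `xread` or NEXUS files, preserving missing (`?`), inapplicable
(`-`) and polymorphic (`[01]`, `{01}`, `(01)`) cells, with character
ordering taken from a TNT `ccode` block when present and unordered,
equally weighted characters as the default.

Per character, the minimum steps on the topology are computed by the
Sankoff dynamic program with unit step costs for unordered characters
(Fitch counting) and absolute numeric state differences for ordered ones
(Farris/Wagner counting); missing and inapplicable cells behave as the
full state set, and polymorphic tips may take any of their states at no
cost. This single exact recursion handles polytomies and either rooting,
and the score is invariant to re-rooting. The character-fit indices are
the classical ones: CI = Σm/Σs and RI = (Σg − Σs)/(Σg − Σm), with m the
minimum conceivable steps on any tree (smallest state set intersecting
every constrained tip set, minus one; state range for ordered characters)
and g the steps on the star tree (minimized over the central state). Both
are computed for every character; characters with g = m contribute zero
to the RI differences, and CI/RI are reported as undefined (NA) when
their denominators vanish.

`map_changes()` returns one most-parsimonious reconstruction per
character under accelerated transformation: the root takes its cheapest
state and each child the state minimizing subtree cost plus the step from
its parent, with ties broken in favour of changing (then the smallest
state), which places changes as close to the root as ties allow. The
summed cost of mapped changes always equals the tree length, which the
tests verify on random instances. The scorer itself is validated two
independent ways: exhaustive enumeration over all internal-node
assignments on trees of up to 7 tips, and an installed third-party Fitch
implementation on larger random instances.

## Problem sizes and runtime envelope

The validation suite uses sample sizes matching the scale of the study
design the package targets: populations of 20 (the pipeline default) and
40 (recovery experiments at 1% noise), several hundred random parsimony
instances of 4–7 tips against exhaustive enumeration, and rotation-grid
oracles at 1e-4 radian resolution. The full suite runs in well under a
minute on a single CPU; the standalone reproduction script
(`scripts/acceptance.R`) recomputes the headline quantities in a few
seconds.

## Interface notes and known limitations

The package's interface is its functions: data-frame-first verbs
returning tibbles, fitted objects with `tidy()`/`glance()`/`autoplot()`
methods, and three orchestration wrappers (`run_morpho()`,
`run_simulate()`, `run_parsimony()`) that write stamped, reproducible
output bundles; no shell entry point is shipped.

Limitations worth knowing: the analysis is strictly 2D lateral-view;
there is no missing-landmark estimation, no bilateral-symmetry
decomposition, no re-projection of slid semi-landmarks onto original
digitized outlines (the tangent-line approximation is used, as outline
curves are typically not distributed), no phylogenetically corrected PCA
or regression, and no allometric shape-on-size regression. The θ
convention of the lever model is a documented geometric choice, not an
anatomical measurement; analyses sensitive to it should use
per-specimen `"user_theta"` values.
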