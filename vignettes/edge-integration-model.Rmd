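---
title: "The edge-integration lightness model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The edge-integration lightness model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgelight)
```

## The model

Lightness is perceived surface reflectance, and it is not a pointwise
function of luminance: a surface's appearance depends on the luminance
steps at its borders and at borders some distance away. `edgelight`
implements an edge-integration account of this computation, organised the
way the cortical ventral stream is thought to be: a local contrast code
(V1), a segmentation and selection stage (V2 plus top-down feedback), a
long-range spatial integration stage (V4), and a final subtractive readout.

The primitive quantity is the *directed step in log luminance* at a border
between two regions,

$$\Delta_{ab} = \ln\frac{L_b}{L_a},$$

which is the logarithm of (Weber fraction + 1) at that edge. The lightness
of a target region is a weighted sum of the directed steps encountered
along a path through the image ending at the target:

$$\Lambda = \sum_j g_j \, w(\Delta_j)\, k(d_j)\, \Delta_j,$$

where

* $g_j \in [0,1]$ is a top-down gain on edge $j$ (attentional selection,
  edge interpretation, sharpness classification);
* $w(\Delta)$ is the contrast-polarity weight: `w_inc` $= 1/3$ when the
  light side of the step points toward the target, `w_dec` $= 1$ when the
  dark side does. The 3:1 asymmetry of darkness over lightness induction is
  the post-logarithm trace of a cube-root compressive ON channel and a
  linear OFF channel: a power-law exponent applied before a log transform
  becomes a multiplicative gain after it;
* $k(d)$ is a distance weight that decays over roughly 10 degrees of
  visual angle (below);
* $\Delta_j$ is the directed log step crossed toward the target.

With all weights equal to 1 the sum telescopes to
$\ln(L_\text{target}/L_\text{background})$ — the retinex limit — and the
model becomes an ideal reflectance observer. Every deviation of the model
from veridicality is therefore carried by the weights, which is what makes
the predictions below sharp.

## Stage by stage

### Contrast encoding

`extract_edges()` finds every 4-neighbour label change in the region map
and groups boundary pixel pairs into connected components per region pair,
one edge per component. That granularity matters: an interior paper in a
row of papers touches the background above *and* below, and a narrow-field
observer treats those as two of the paper's "four borders".

Each side's luminance is the mean over pixels within 2 px of the boundary
(not the whole-region mean), so shallow within-region gradients do not
corrupt the local step. Each boundary is also classified by its 10–90%
transition width along the boundary normal: widths at or below 0.5 deg are
`sharp` (candidate reflectance edges), wider ones are `gradient`
(candidate illumination variation, e.g. a shadow penumbra). The 0.5-deg
default reflects the scale of the lowest spatial-frequency channels in
human vision (about 0.5 cycle/deg); it is configurable. Gradient edges are
not deleted — they get gain `g_gradient` (default 0, full exclusion; the
alternative, mere down-weighting, is available by setting it above 0).
This is how the model "discounts the illuminant" across a shadow border
while leaving sharp reflectance edges intact.

### Selection

`build_region_graph()` turns the label map into a region adjacency graph
(one arc per boundary component), and `select_paths()` realises the
border-ownership rule: integration runs only along *direct paths from the
common background to the target*. We operationalise "direct path" as the
shortest path in the region graph, breaking ties by the total boundary
length of the crossed edges; for every stimulus this package generates,
the shortest path is unique. No recurrent border-ownership network is
simulated — the rule is the function such circuits are taken to compute.

The attentional spotlight enters here. In **wide** mode each target is
compared to the common background (for a row of papers: across the
paper/background border, never across inter-paper borders; for an
insulated row: background → frame → paper). In **narrow** mode the target
is compared to each immediately adjacent region across each of its
boundary components, and the per-border one-step sums are combined by an
unweighted mean — averaging, not summation, keeps narrow and wide outputs
on one scale. `apply_gain_field()` combines a spatial mask (custom mode),
the observer's interpretation of each edge (reflectance: gain 1;
illumination: gain `g_illum`, default 0) and the sharpness class into the
per-edge gain, recomputed from scratch so the operation is idempotent.
`mask_edge()` zeroes one edge's gain, which is how flicker-masking
adaptation of edge detectors is modelled: as a silenced input, with no
attempt at fatigue dynamics.

### Integration and readout

`path_lightness()` evaluates $\Lambda$. Distances for path sums follow one
convention: an edge incident to the target region abuts it and is at
distance 0; any other edge is at the Euclidean distance from the target's
centroid to the edge's nearest boundary pixel. This matches how
disk-annulus data are fit (the target's own border undiscounted, the
remote border distance-weighted) and makes the closed-form results below
exact rather than approximate.

`compute_channel_maps()` is the same machinery run for every pixel:
separate non-negative lightness `L(x)` and darkness `D(x)` activations,
each edge contributing $g\,w\,k(d(x))\,|\Delta|$ to the channel whose
polarity faces the pixel. "Faces" is region reachability — a pixel is
faced by the side of an edge from which its region can be reached without
recrossing that edge — so induction from an outer border reaches an
enclosed disk's interior. Filling-in is thus a byproduct of integration,
not a diffusion process stopped at borders. `compute_ac()` forms
$AC(x) = L(x) - D(x)$, the modelled achromatic color.

`anchor()` maps relative lightness onto an absolute reflectance scale.
The default rule is highest-*reflectance* anchoring: the region with
maximal $\Lambda$ is assigned `R_white = 0.9` (conventional white paper)
and others scale by $e^{\Lambda_i - \Lambda_\max}$. Highest-*luminance*
anchoring is selectable for comparison; on a plain staircase-Gelb display
the two agree. There is evidence that induction can shift even the
highest-lightness surface, which challenges both rules; no third rule is
implemented. For anchored AC maps the anchor is the maximum of
region-interior means (2-px margin), not the raw pixel maximum, to avoid
boundary-band artefacts, and anchored reflectance is clipped at `R_white`.

## Distance kernels and their calibration

Three kernel families are provided because the true receptive-field
profile is unknown:

* `exponential` (default): $k(d) = e^{-d/\tau}$ with
  $\tau = 10/\ln 20 \approx 3.34$ deg, so that $k(10^\circ) = 0.05$. This
  is our concrete reading of "contextual influence declines with distance
  up to about 10 deg": the calibrated 5% range is exactly 10 deg
  (`kernel_range()`).
* `linear`: $k(d) = \max(0, 1 - d/\text{cutoff})$.
* `log_linear`: $k(d) = \max(0, 1 - b\log_{10}(1 + d/d_0))$, with defaults
  also placing 5% of peak at 10 deg.

All are clipped to 0 beyond `range_cutoff` (10 deg). The kernel choice is
observable in the map mode: with the exponential kernel the interior AC
profile of a decremental disk is $C e^{|x|/\tau}$ with $C<0$ — a strictly
curved bowl with its maximum at the disk centre (the "inverted meniscus"
of disk-centre lightening) — whereas the linear kernel yields a
zero-curvature (piecewise linear) interior. The package tests this on
concentric squares, where the discrete distance transform is exact along
the central row; on circles, pixelation adds curvature noise of the same
order.

## Quantitative consequences (all computed by the tests and scripts)

* **Compression.** Wide-field staircase-Gelb: each paper is compared to
  the same background across its own (incremental, abutting) border, so
  $\Lambda_i = w_\text{inc}(\ln L_i - \ln L_\text{bg})$ and lightness is a
  power law of luminance with exponent exactly `w_inc` = 1/3, for any
  paper set and illuminant.
* **Insulation.** With a white frame (reflectance 0.9, at least every
  paper's) between papers and background, the last step frame → paper is
  decremental, so the exponent becomes `w_dec` = 1: the lightness scale
  linearises. The frame must outshine the papers or the construction
  errors out.
* **Matching slopes.** For incremental disk-annulus matching with unit
  weights, treating the outer edge as a reflectance edge gives luminance
  matching (log-log slope 0); treating it as an illumination edge (gain 0)
  gives ratio matching (slope −1). The match is solved in closed form:
  lightness is affine in log disk luminance, so two probe evaluations of
  the pipeline determine the inversion.
* **Scrambling.** Wide mode is invariant under any permutation of the
  papers. Narrow mode is sensitive to neighbours — with one caveat found
  while testing: permutations that preserve each paper's multiset of
  neighbour log ratios (e.g. reversing an equally log-spaced series) are
  also narrow-invariant. The default scramble therefore swaps the two
  middle papers.
* **Annulus width.** Widening an annulus moves the lightness-inducing
  outer border away from the disk, strictly lowering disk AC; with a
  uniform kernel the effect vanishes.
* **Contour masking.** Silencing the outer border darkens a decremental
  disk (its lightness induction is removed); silencing the inner border
  lightens the disk toward the annulus level.

## What the synthetic stimuli do and do not emulate

All inputs are generated in-package on a default 256 × 256 px canvas at
0.1 deg/px (a 25.6-deg field; the unit tests mostly use 12.8–19.2-deg
canvases to keep runtimes short). Region boundaries are pixel-aligned, so
edge extraction is exact and testable; luminances are exact region
constants (or exact ramps), and where stimuli are specified
photometrically the ground-truth $L = R \times I$ decomposition is stored.
The generators are deterministic — no noise, no optics, no eye movements.

Passing tests therefore demonstrate the *model's* internal consistency and
its closed-form consequences, not fit to data: there is no photon noise,
no blur (edges are perfectly sharp unless a ramp is constructed), no
real observers' variability. The paper luminances the experiments use are
free choices (the source demonstrations print none): Gelb spotlight
1000 cd/m² over a 1 cd/m² background with reflectances log-spaced
0.03–0.9, so every paper is a strong increment, which the compression
result presupposes.

## Numerical choices and degenerate inputs

* Natural logarithms throughout; every exponent and slope reported is
  base-invariant.
* Luminances must be strictly positive (logs must exist); generators and
  the `luminance_stimulus()` constructor validate this, and ramps that
  would cross zero are rejected.
* Zero-contrast edges ($\Delta = 0$) contribute exactly 0 everywhere and
  keep their region structure (a uniform disk-annulus still has three
  labelled regions).
* Boundary sampling: 2-px Euclidean band; sharpness from the median 10–90%
  width over up to 25 sampled normals; boundaries with fewer than 2 px of
  usable normal extent raise an error.
* Ties in path selection are broken by total boundary length, then
  lexicographically — deterministic by construction.
* All pipelines are seed-free; two runs of the same configuration produce
  byte-identical CSV/JSON/PGM outputs (hash-checked in the tests).

## Known limitations

* Border ownership, illusory-contour completion (Kanizsa figures),
  transparency/scission and chromatic (Watercolor) effects are out of
  scope; the selection stage implements the path rule, not the circuit.
* The sharpness classifier is a geometric stand-in for a spatial-frequency
  decomposition; no Gabor filter bank is applied.
* Channel-map reachability treats parallel boundary components
  independently: deleting one of two arcs between the same region pair
  leaves them connected through the twin, so both sides of such an edge
  face every region. The quantitative claims all use path mode, where this
  has no effect.
* Narrow-field quantitative fits to scrambling datasets are not attempted;
  the package asserts directions and invariances only. Custom spotlight
  masks are supported, but no semantics are claimed for intermediate
  spotlight sizes.
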