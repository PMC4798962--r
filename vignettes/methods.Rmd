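---
title: "Endothelial polarity versus flow: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endothelial polarity versus flow: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vesselpol` measures how endothelial cells orient their nucleus-to-Golgi
axis relative to blood flow across a vascular network, and whether that
orientation response switches on above a wall-shear-stress threshold. This
vignette explains the models behind each stage, the parameters that matter,
the design decisions taken where several choices were defensible, and what
the synthetic validation does and does not demonstrate about real data.

## The measurement model

A cell's *axial polarity* is the vector from its nucleus centroid to its
Golgi centroid — an established proxy for the direction the cell is about
to migrate. Given a flow field on the vessel network, each cell is
characterized by

* the angle $\theta \in [0^\circ, 360^\circ)$ from the local flow direction
  to its polarity vector (counter-clockwise; $180^\circ$ = polarized
  against flow),
* the scalar product $s = |p| \, \tau \cos\theta$ of the polarity vector
  (magnitude $|p|$, µm) with the WSS vector (magnitude $\tau$, Pa), which
  is negative exactly when the cell points against flow, and
* the *anti-aligned* indicator: $\theta$ within $45^\circ$ of $180^\circ$.
  Under a uniform orientation distribution this window covers a quarter of
  the circle, so 0.25 is the chance baseline for the anti-aligned fraction.

Regressing $s$ on $\tau$ separately for the positive and negative
scalar-product subsets gives gradients that estimate $|p|\cos\theta$ — the
projection of the polarity vector onto the flow axis — so a more negative
gradient in the negative subset means stronger polarization against flow
at a given shear.

## Flow model: 1D Poiseuille/Kirchhoff network

Full 3D computational fluid dynamics resolves wall-level WSS variation,
but the polarity analysis consumes only two quantities per sampling point:
the WSS magnitude and the flow direction along the vessel axis. A 1D
network model supplies both at a fraction of the cost. Each edge of the
vessel graph is a tube of varying circular cross-section with hydraulic
conductance

$$G \;=\; \left[\int \frac{8\mu}{\pi R(s)^4}\, ds\right]^{-1},$$

evaluated by the trapezoidal rule over the centreline's per-point radii
(series composition of Poiseuille resistances). Kirchhoff's current law at
every interior node gives a sparse symmetric linear system for the nodal
pressures (solved with `Matrix`); edge flows follow as $Q = G\,\Delta P$
and pointwise WSS from the Poiseuille wall formula
$\tau = 4\mu|Q|/(\pi R^3)$. The per-edge WSS is the arc-length-weighted
mean of the pointwise values; the direction field is the polyline tangent
oriented from high to low pressure. What this model deliberately does not
capture: pulsatility, vessel compliance, red-cell phase separation at
bifurcations, and circumferential WSS variation.

Boundary conditions: the artery root is held at the inlet pressure, the
vein root at 0 Pa, and every other terminal (sprout tips, trunk ends) is
blind-ended (no flow). The default inlet pressure is **2500 Pa
(≈ 19 mmHg)**, a physiological arteriovenous drop for a microvascular bed.
This value was calibrated once so that capillary WSS in the synthetic
plexus spans the 0–10 Pa range in which shear thresholds for endothelial
polarization are physiologically located (1–10 Pa); because the model is
linear in the driving pressure, this is purely a scale choice and every
relational statistic is unaffected by it. Viscosity defaults to constant
$\mu = 3.5\,$mPa·s (whole blood, Newtonian); the Pries in-vitro
viscosity law $\mu(R, H)$ is available where the Fåhræus–Lindqvist effect
matters.

## Network extraction

Masks are skeletonized by Guo–Hall topological thinning: iterative removal
of boundary pixels under local connectivity conditions, which preserves
the number of connected components and yields an 8-connected, one-pixel
centreline. Any algorithm meeting that contract would do; thinning was
chosen because it is simple, deterministic and needs no auxiliary
structures. Local radii are maximum-inscribed-circle radii: the Euclidean
distance transform (EBImage) at each skeleton pixel, minus half a pixel
because the true lumen boundary lies between the last foreground and first
background pixel centres. On rasterized ground truth this estimator's
per-edge median error is ~0.3 px.

Skeleton pixels with ≠ 2 neighbours become nodes (8-adjacent junction
pixels are merged to their centroid); maximal chains of 2-neighbour pixels
become edges carrying ordered polylines and per-point radii. Isolated
cycles are represented as a single self-loop anchored at their
lexicographically smallest pixel — an arbitrary but deterministic choice.
Two cleanup passes follow:

* **Spur pruning** removes terminal edges shorter than a threshold
  (default: twice the largest radius, i.e. one vessel diameter) — these
  are discretization whiskers, not vessels. Edges labelled as sprouting
  front are never pruned, so true blind sprouts survive when labels are
  available (from the generator, or transferred from a reference/label
  image *before* pruning).
* **Junction consolidation** contracts internal edges joining two
  junctions closer than the local vessel diameter. Thinning splits a
  four-way crossing of two vessels into two three-way junctions a few
  pixels apart; anatomically these are one branch point, and contracting
  them is what makes junction counts comparable to ground truth.

Pixel convention: x = column, y = row, 0-based indices, physical position
= (index + 0.5) · pixel size (pixel centres).

## Circular statistics

*Mean direction and confidence arc.* The mean direction is
$\operatorname{atan2}$ of the mean sine and cosine; the 95% arc uses the
large-sample circular dispersion
$\hat\delta = (1 - \hat m_2)/(2\bar R^2)$ with halfwidth
$\arcsin(z_{0.975}\sqrt{\hat\delta/n})$. The arc is reported only when the
Rayleigh test rejects uniformity — otherwise the mean direction is not
meaningfully localized.

*Kuiper two-sample test.* $V = \max(F_1 - F_2) + \max(F_2 - F_1)$ over
the pooled sample; because the difference path starts and ends at zero,
$V$ is invariant to a common rotation of both samples, which is the
property that makes it the correct circular analogue of the
Kolmogorov–Smirnov test. p-values come from label permutations (default
9,999, seeded). With equal sample sizes the statistic lives on a grid of
$1/n$ steps, so ties between the observed and permuted statistics are
common; the p-value therefore uses the mid-p convention (ties at half
weight). With plain tie counting the test's empirical type-I error falls
visibly below nominal (~0.036 at $\alpha = 0.05$, $n = 100$ per sample);
with mid-p it is ~0.045–0.048. Stephens' asymptotic series is available
as a faster alternative.

*Binned anti-alignment.* Cells are binned by WSS magnitude (default:
deciles of the observed distribution, so every bin is populated; fixed
edges available for cross-run comparability), with Wilson intervals on the
per-bin anti-aligned fraction — well-behaved at small bin counts. The
*threshold-crossing shear* is the smallest WSS at which the
piecewise-linear interpolation of fraction versus bin midpoint reaches a
target (default 60%), the readout used to compare how much shear different
genotypes need to reach the same level of polarization. Monotone increase
of the binned fraction is asserted statistically (one-sided Kendall trend
test) rather than bin-by-bin, since binomial noise violates strict
monotonicity at any finite cell count.

## The synthetic plexus and its polarity response

The generator emulates a developing retinal plexus at the scale the
analysis needs: an artery trunk (12 µm root radius, tapering to 75%) and a
vein trunk (14 µm) bridged by a capillary lattice (spacing 60 µm, radii
$\mathcal N(4, 0.8)$ µm truncated at 1 µm) with interior node jitter
(σ = 6 µm), random edge dropout (p = 0.15, resampled if the network
disconnects), and blind-ended sprouts on the distal margin. These
geometric values are fixtures chosen to be anatomically plausible for a
postnatal mouse retina (capillary diameters ~8 µm, arteriole ~25 µm);
they are not estimates of any particular animal.

Cells are placed along centrelines at a default linear density of 10 per
100 µm (nuclear spacing ~10–20 µm along a vessel, times a small
circumferential multiplicity). Each cell's angle to flow is $180^\circ$
plus von Mises noise — the standard circular analogue of Gaussian noise,
making concentration $\kappa$ the single noise knob — with

$$\kappa(\tau) = \frac{\kappa_{\max}}{1 + e^{-(\tau - \tau_0)/s}},$$

a logistic threshold response: the minimal smooth family with a threshold
location $\tau_0$ (default 4 Pa), a width $s$ (default 1 Pa) and a ceiling
$\kappa_{\max}$ (default 4, under which cells far above threshold are
~90% anti-aligned). Zero-flow segments get $\kappa(0)$ — nearly uniform
orientation — rather than an error, because blind sprouts legitimately
carry no flow. Polarity magnitudes are log-normal with natural-scale mean
7 µm (the order of a nucleus–Golgi offset); magnitude affects only scalar
products, never angles. With $\kappa_{\max} = 0$ every angle is uniform
regardless of shear, which provides the null calibration case.

All stages draw their randomness through per-stage integer seeds, and the
global RNG state is saved and restored around every seeded computation, so
identical parameters give byte-identical serialized scenes.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: analytic
Poiseuille formulas and hand-solved linear systems for the solver; a
brute-force ECDF evaluation and full label-assignment enumeration for the
Kuiper statistic and its permutation p; closed-form lattice combinatorics
for the generator; constructed images (strips, discs, rings, Y-shapes)
for the extraction; and generator round trips for the integrated chain.
Problem sizes were chosen to keep the full suite around a minute:
10 rasterized lattices (~360 × 270 px) for topology recovery, a ~10,500-cell
scene for the uniform null, 2,000 uniform-vs-uniform pairs (n = 100 each,
199 permutations per pair — an exact test at any permutation count) for
Kuiper calibration, and ~2,400-cell scenes at $\tau_0 = 2, 4, 6$ Pa for
threshold recovery.

Two aspects of the round trip deserve honesty about their conditioning.
Through the *polarity stage alone* (the scene's own graph and flow),
recomputed angles match the generated ones to ~1e-13 degrees for every
flow-matched cell. Through *full re-extraction from the rasterized mask*,
two geometric effects cap the achievable fidelity: cells within ~2.5 local
radii of a junction can hit the junction cluster's centroid stub, whose
tangent is not the vessel axis; and weakly driven mesh segments (flows an
order of magnitude below the main paths) can flip flow direction under the
±0.3 px radius-estimation noise, because their direction is genuinely
sensitive to the conductance balance. Away from those two regimes,
re-extracted angles also reproduce to ~1e-13 degrees, and vascular-bed
labels agree with ground truth for ≥ 99% of cells.

## What passing tests do and do not show

The synthetic plexus has straight or gently jittered segments, exact
binary masks, circular cross-sections and cells placed exactly on
centrelines. Real retinal data adds segmentation error from manual
masking, curved and tangent vessels, out-of-plane components, nuclei
displaced from the centreline, and a flow field whose boundary conditions
are unknown. Passing the suite therefore demonstrates the correctness of
the algorithms and the internal consistency of the chain — not that
absolute WSS values in any particular tissue are reproduced. Relational
statistics (angle distributions, binned fractions, threshold orderings,
regression gradients) are the quantities this pipeline is designed to
report, and they are invariant to the overall pressure scale.

## Known limitations

Planar networks only (the graph is 2D; a 3D plexus must be projected);
no junction-aware blending of flow directions (nearest-centreline rule
with a deterministic tie-break to the lower edge id); a single inlet and
outlet (multi-root retinas need user-supplied boundary conditions);
no mixed-effects structure across retinas (each dataset is analysed
independently); rose-plot data are exported as histograms, not rendered.
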