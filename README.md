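# vesselpol

Quantifying endothelial axial polarity against blood flow in planar
vascular networks.

During vascular remodelling, endothelial cells (ECs) polarize and migrate
against the direction of blood flow, and the strength of that response
depends on the local wall shear stress (WSS): below a shear threshold cells
orient almost at random, above it they align tightly anti-parallel to flow.
`vesselpol` is an R implementation of the full analysis chain needed to
measure this behaviour from segmented microscopy data:

1. **Network extraction** — a binary lumen mask is skeletonized
   (Guo–Hall topological thinning), local vessel radii are estimated as
   maximum-inscribed-circle radii from the Euclidean distance transform,
   and the centreline is decomposed into a measured vessel graph
   (junctions, endpoints, per-point radii, arc lengths, vascular-bed
   labels). Mask-level morphometrics (vessel area fraction, branch-point
   density) come from the same inputs.
2. **Hemodynamics** — steady flow is solved on the graph as a 1D
   Poiseuille/Kirchhoff network: each segment's hydraulic conductance is
   `G = [∫ 8μ/(πR(s)⁴) ds]⁻¹`, nodal pressures solve flow conservation,
   and the wall shear stress along a segment follows the Poiseuille wall
   formula `τ = 4μ|Q|/(πR³)`. Constant viscosity by default; the Pries
   in-vitro (Fåhræus–Lindqvist) law is available.
3. **Polarity** — each cell's nucleus→Golgi vector is joined to the WSS
   vector sampled at the nucleus, giving the angle to flow θ (0° = with
   flow, 180° = against), the scalar product `s = |p|·τ·cos θ`, and a
   vascular-bed assignment.
4. **Circular statistics** — mean directions with 95% confidence arcs,
   Rayleigh uniformity tests, rotation-invariant two-sample Kuiper tests
   (`V = max D⁺ + max D⁻`, permutation p-values), the fraction of cells
   polarized within 45° of anti-parallel binned by WSS, the crossing shear
   at which that fraction reaches a target (e.g. 60%), and OLS regressions
   of the scalar product on WSS whose gradient estimates `|p|·cos θ`.

A synthetic-plexus generator produces retinal-style ground truth — artery
and vein trunks bridged by a jittered capillary mesh with blind-ended
sprouts — plus cells whose orientation is drawn from a von Mises
distribution centred anti-parallel to the local flow with concentration
`κ(τ) = κ_max / (1 + exp(−(τ − τ₀)/s))`, so every stage of the pipeline can
be validated against known answers.

## Worked example

```r
library(vesselpol)

# a synthetic plexus with a 4 Pa polarization threshold
scene <- generate_scene(plexus_params(seed = 7),
                        polarity_response_params(tau0 = 4, seed = 7))
scene$graph
#> vessel_graph: 47 nodes, 66 edges, total length 3553 um
#>   junctions (deg >= 3): 32; endpoints (deg 1): 12
#>   beds: artery=6, capillary=46, sprouting_front=8, vein=6

# join the generated cells to the flow field and summarize
rec <- build_polarity_dataset(scene$cells, scene$graph, scene$flow)
rep <- polarity_statistics(rec, analysis_config(n_perm = 999, seed = 1))
rep
#> polarity_report: 351 cells (351 with flow)
#>   anti-aligned fraction: 0.604
#>   threshold shear (target 60%): 3.69 Pa
#>   negative-subset gradient: -6.357 um (r = -0.883, n = 269)
```

The anti-aligned fraction (60% of cells within 45° of anti-parallel) is far
above the 25% uniform baseline; the fitted crossing shear (~3.7 Pa) recovers
the generating threshold `tau0 = 4`; the negative regression gradient
(−6.4 µm) estimates the mean against-flow projection of the polarity
vectors.

The same analysis runs from files (mask TIFF + cell CSV) through
`run_pipeline()` or the CLI script:

```sh
Rscript inst/cli/vesselpol run-all --out results/ --seed 7
```

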