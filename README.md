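# FiberAlign

Local alignment vector analysis of fibrous networks — built for collagen
fibers extracted from second harmonic generation (SHG) microscopy of tumor
spheroids in 3D gels, and for anyone who needs a spatially resolved,
bounded measure of fiber alignment from polyline fiber data.

## The method

Fiber orientation is axial data: an angle α ∈ [0°, 180°) with no
head or tail. FiberAlign quantifies the alignment of a set of fiber angles
by angle doubling:

1. double each angle onto the circle, θᵢ = 2αᵢ;
2. form the mean resultant vector
   **R** = (1/N) Σᵢ (cos θᵢ, sin θᵢ);
3. halve the MRV angle back to the axial range, keeping the length.

The **alignment vector** length |**R**| ∈ [0, 1] is 1 for perfectly
parallel fibers and 0 when orientations cancel (e.g. equal mass at 45° and
135°); its axial angle is the dominant fiber axis. The length equals the
2D nematic orientational order parameter μ — the maximal eigenvalue of
the order tensor built from ⟨cos 2α⟩ and ⟨sin 2α⟩ — which the package
computes independently (by eigendecomposition) as a cross-check.

Because alignment around an invading spheroid is spatially heterogeneous,
the statistic is computed *locally*: fibers are quantized into 5-pixel
straight segments of equal weight, sampling circles (radius 25 px by
default) are centered on a 5-pixel grid (10,609 cells on a 512 × 512
image), cells whose circles cross the image boundary or the circular tumor
boundary, or hold too few segments, are excluded, and each remaining cell
carries one local alignment vector. Pooled over a z-stack, the valid cells
yield the normalized alignment distribution, the mean local alignment and
the strong-alignment ratio (fraction of cells above 0.7). Two seeded
in-silico fiber simulators (homogeneous Gaussian-perturbed and radial
around a quarter-disk boundary) generate validation data with known closed
forms.

## Worked example

Simulate fibers radiating from a quarter-disk tumor boundary with 20° of
angular noise, then run the full analysis:

```r
library(FiberAlign)

alignmentVector(c(30, 40, 50))
#> AlignmentVector: length 0.9598, axial angle 40 deg (3 segments)

ft  <- simulateRadial(radialSimConfig(noiseStd = 20, seed = 1))
res <- runPipeline(ft, 512, 512,
                   boundaries = data.frame(z_index = 1, cx = 0, cy = 0,
                                           r = 150),
                   config = analysisConfig())
#> pipeline: 1 z-slice(s), grid 512 x 512 px spacing 5, R = 25 px, F > 10, L = 5 px
#>   z = 1: 4000 segments; 6594 valid, 1960 image-boundary, 658 tumor-boundary, 1397 below min count
#>   pooled: 6594 valid cells; mean alignment 0.8032; strong ratio (> 0.7) 0.8417
```

Reading the numbers: the 500 simulated fibers quantize into 4000
equal-weight 5-px segments; of the 10,609 grid cells, 6594 survive the
exclusion rules (1960 circles cross the image edge, 658 touch the tumor
disk, 1397 contain ≤ 10 segments). The surviving local vectors average
0.80 — high residual radial order despite the 20° noise — and 84% of them
exceed the strong-alignment threshold of 0.7. `res$distribution` holds the
normalized histogram, `res$stack` the per-cell vectors
(`validCells(res$stack)`), and `plotField()` / `plotStack3D()` draw them.

A thin command-line front end over the same functions ships in
`inst/cli/fiberalign.R` (subcommands `simulate-uniform`, `simulate-radial`,
`analyze`, `sweep`, `plot`).

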