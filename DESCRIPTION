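Package: FiberAlign
Title: Local Alignment Vector Analysis of Fiber Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the alignment of fibrous networks (e.g. collagen
    fibers extracted from second harmonic generation microscopy) with local
    alignment vectors: axial fiber angles are doubled onto the circle, the
    mean resultant vector is computed inside local sampling circles on a
    regular grid, and its angle is halved back to the axial range. The
    alignment vector length equals the 2D nematic orientational order
    parameter. Includes fixed-arclength fiber quantization, grid exclusion
    rules (image boundary, circular tumor boundary, minimum segment count),
    z-stack aggregation, alignment distributions and strong-alignment
    ratios, in-silico fiber simulators with Gaussian angular noise for
    validation, plain-text fiber-table input and output, and quiver-style
    field plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'circular.R'
    'fibers.R'
    'field.R'
    'statistics.R'
    'simulate.R'
    'io.R'
    'pipeline.R'
    'plot.R'
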