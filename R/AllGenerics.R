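#' @rdname alignmentLength
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' @rdname axialAngle
#' @export
setGeneric("axialAngle", function(x) standardGeneric("axialAngle"))

#' @rdname nSegments
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' @rdname cells
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname validCells
#' @export
setGeneric("validCells", function(x) standardGeneric("validCells"))

#' @rdname meanAlignment
#' @export
setGeneric("meanAlignment", function(x) standardGeneric("meanAlignment"))

#' @rdname strongAlignmentRatio
#' @export
setGeneric("strongAlignmentRatio", function(x, threshold = 0.7)
  standardGeneric("strongAlignmentRatio"))

#' @rdname alignmentDistribution
#' @export
setGeneric("alignmentDistribution", function(x, binWidth = 0.05)
  standardGeneric("alignmentDistribution"))

#' @rdname filterHighAlignment
#' @export
setGeneric("filterHighAlignment", function(x, threshold = 0.8,
                                           zSpacing = NULL)
  standardGeneric("filterHighAlignment"))
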